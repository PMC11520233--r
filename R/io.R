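# Data containers and delimited-text IO. Expression tables are samples x
# genes with the first column holding sample IDs; survival is a three-plus
# column table (id, time_days, event, covariates...); drug matrices use
# empty cells for unscreened pairs.

#' Expression matrix container
#'
#' @param values numeric matrix (samples x genes) with unique row and
#'   column names; no missing values allowed.
#' @param domain per-sample domain indicator: 0 = patient, 1 = cell-line.
#'   A scalar is recycled.
#' @return an `omics_matrix`.
#' @export
omics_matrix <- function(values, domain) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_deconfae("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_deconfae("values must carry sample (row) and gene (column) names")
  }
  if (anyDuplicated(rownames(values))) stop_deconfae("duplicate sample IDs")
  if (anyDuplicated(colnames(values))) stop_deconfae("duplicate gene IDs")
  if (any(!is.finite(values))) stop_deconfae("expression values must be finite")
  domain <- as.integer(domain)
  if (length(domain) == 1L) domain <- rep(domain, nrow(values))
  if (length(domain) != nrow(values) || !all(domain %in% c(0L, 1L))) {
    stop_deconfae("domain must be 0/1, one per sample")
  }
  structure(list(values = values, sample_ids = rownames(values),
                 gene_ids = colnames(values), domain = domain),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d samples x %d genes (%s)\n",
              nrow(x$values), ncol(x$values),
              if (all(x$domain == 1L)) "cell-line"
              else if (all(x$domain == 0L)) "patient" else "mixed"))
  invisible(x)
}

#' Survival record container
#'
#' @param sample_id patient identifiers aligned with an expression matrix.
#' @param time follow-up time in days (finite, > 0).
#' @param event 0/1 event indicator.
#' @param covariates optional numeric covariate matrix (n x k).
#' @return a `survival_records`.
#' @export
survival_records <- function(sample_id, time, event, covariates = NULL) {
  time <- as.numeric(time); event <- as.integer(event)
  if (length(sample_id) != length(time) || length(time) != length(event)) {
    stop_deconfae("sample_id, time and event must align")
  }
  if (anyDuplicated(sample_id)) stop_deconfae("duplicate patient IDs")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_deconfae("times must be finite and strictly positive")
  }
  if (!all(event %in% c(0L, 1L))) stop_deconfae("event must be 0/1")
  if (!is.null(covariates)) {
    if (!is.matrix(covariates)) covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    if (nrow(covariates) != length(time)) {
      stop_deconfae("covariates must have one row per patient")
    }
    if (any(!is.finite(covariates))) stop_deconfae("covariates must be finite")
  }
  structure(list(sample_id = as.character(sample_id), time = time,
                 event = event, covariates = covariates),
            class = "survival_records")
}

#' Drug-response matrix container
#'
#' @param values numeric matrix (cell-lines x drugs); entries at observed
#'   positions must lie in `[0, 1]` (area above the dose-response curve).
#'   `NA` is permitted (and implies unobserved) at masked positions.
#' @param mask logical matrix marking observed entries; defaults to
#'   `!is.na(values)`. Every drug must retain at least one observation.
#' @return a `drug_response_matrix`.
#' @export
drug_response_matrix <- function(values, mask = NULL) {
  if (!is.matrix(values)) stop_deconfae("values must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_deconfae("values must carry cell-line (row) and drug (column) names")
  }
  if (is.null(mask)) mask <- !is.na(values)
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop_deconfae("mask must be a logical matrix matching values")
  }
  obs <- values[mask]
  if (any(!is.finite(obs)) || any(obs < 0) || any(obs > 1)) {
    stop_deconfae("observed drug-response values must lie in [0, 1]")
  }
  if (any(colSums(mask) == 0)) {
    stop_deconfae("every drug needs at least one observed entry: %s",
                  paste(colnames(values)[colSums(mask) == 0], collapse = ", "))
  }
  structure(list(values = values, observed_mask = mask,
                 drug_ids = colnames(values),
                 sample_ids = rownames(values)),
            class = "drug_response_matrix")
}

read_table_checked <- function(path) {
  if (!file.exists(path)) stop_deconfae("file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          data.table = FALSE, check.names = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop_deconfae("%s: expected an ID column plus data", path)
  dt
}

#' Read an expression table
#'
#' Accepts tab- or comma-separated text with the first column holding
#' sample IDs and the header row holding gene IDs. Values are expected on
#' a log2(TPM+1)-like scale; upstream normalization is out of scope.
#'
#' @param path file path.
#' @param domain 0 for patient samples, 1 for cell-lines.
#' @return an [omics_matrix()].
#' @export
load_expression <- function(path, domain) {
  dt <- read_table_checked(path)
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) {
    stop_deconfae("%s: duplicate sample ID '%s'", path,
                  ids[anyDuplicated(ids)])
  }
  if (anyDuplicated(names(dt)[-1L])) {
    stop_deconfae("%s: duplicate gene ID '%s'", path,
                  names(dt)[-1L][anyDuplicated(names(dt)[-1L])])
  }
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(apply(dt[, -1L, drop = FALSE], 1L,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    stop_deconfae("%s: non-numeric expression values in row '%s'", path,
                  ids[bad[1L]])
  }
  if (any(is.na(mat))) {
    bad <- ids[rowSums(is.na(mat)) > 0][1L]
    stop_deconfae("%s: missing/non-numeric values in row '%s'", path, bad)
  }
  rownames(mat) <- ids
  omics_matrix(mat, domain = domain)
}

#' Write an expression table
#' @param m an [omics_matrix()].
#' @param path output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "omics_matrix"))
  dt <- data.table::data.table(sample_id = m$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(m$values))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a survival table
#'
#' Expects columns `id, time_days, event` followed by optional numeric
#' covariate columns.
#' @param path file path.
#' @return a [survival_records()].
#' @export
load_survival <- function(path) {
  dt <- read_table_checked(path)
  if (ncol(dt) < 3L) stop_deconfae("%s: need id, time_days, event", path)
  covs <- NULL
  if (ncol(dt) > 3L) {
    covs <- as.matrix(dt[, -(1:3), drop = FALSE])
    storage.mode(covs) <- "double"
    rownames(covs) <- dt[[1L]]
  }
  survival_records(dt[[1L]], dt[[2L]], dt[[3L]], covariates = covs)
}

#' Write a survival table
#' @param s a [survival_records()].
#' @param path output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_survival <- function(s, path) {
  stopifnot(inherits(s, "survival_records"))
  dt <- data.table::data.table(id = s$sample_id, time_days = s$time,
                               event = s$event)
  if (!is.null(s$covariates)) {
    dt <- cbind(dt, data.table::as.data.table(s$covariates))
  }
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a drug-response matrix
#'
#' Tab-separated, cell-lines in rows, drugs in columns, empty cells for
#' unscreened pairs.
#' @param path file path.
#' @return a [drug_response_matrix()].
#' @export
load_drug_response <- function(path) {
  dt <- read_table_checked(path)
  mat <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- dt[[1L]]
  drug_response_matrix(mat)
}

#' Write a drug-response matrix
#' @param d a [drug_response_matrix()].
#' @param path output file (tab-separated; unobserved entries as empty
#'   cells).
#' @return `path`, invisibly.
#' @export
write_drug_response <- function(d, path) {
  stopifnot(inherits(d, "drug_response_matrix"))
  vals <- d$values
  vals[!d$observed_mask] <- NA_real_
  dt <- data.table::data.table(cell_line = rownames(vals))
  dt <- cbind(dt, data.table::as.data.table(vals))
  data.table::fwrite(dt, path, sep = "\t", na = "")
  invisible(path)
}
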