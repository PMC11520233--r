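# Preprocessing: gene filtering on mean log-expression, per-dataset
# standardization, follow-up capping, and survival-stratified fold
# assignment.

#' Filter genes by mean log-expression in both datasets
#'
#' Takes the intersection of the two gene universes, then retains exactly
#' the genes whose mean log-expression is at least `min_mean` in BOTH
#' datasets (genes below the threshold in either are excluded). Gene order
#' of the patient matrix is preserved. Inputs are expected on a
#' log2(TPM+1) scale.
#'
#' @param patient,cellline [omics_matrix()] objects.
#' @param min_mean threshold on the per-gene mean (default 1.0; the
#'   boundary value is kept, the rule is strictly "less than").
#' @return list with filtered `patient` and `cellline` matrices.
#' @export
filter_genes <- function(patient, cellline, min_mean = 1.0) {
  stopifnot(inherits(patient, "omics_matrix"),
            inherits(cellline, "omics_matrix"))
  shared <- intersect(patient$gene_ids, cellline$gene_ids)
  if (length(shared) == 0L) stop_deconfae("no genes shared between datasets")
  # preserve patient gene order
  shared <- patient$gene_ids[patient$gene_ids %in% shared]
  mp <- colMeans(patient$values[, shared, drop = FALSE])
  mc <- colMeans(cellline$values[, shared, drop = FALSE])
  keep <- shared[mp >= min_mean & mc >= min_mean]
  if (length(keep) == 0L) stop_deconfae("no genes pass the filter")
  list(patient = omics_matrix(patient$values[, keep, drop = FALSE],
                              patient$domain),
       cellline = omics_matrix(cellline$values[, keep, drop = FALSE],
                               cellline$domain))
}

#' Standardize an expression matrix gene-wise
#'
#' Centers and scales each gene to mean 0, standard deviation 1 within the
#' dataset (each dataset independently). The population convention
#' (divide by n) is used and fixed by a unit test. The fitted location and
#' scale are returned so held-out data can be transformed with discovery
#' statistics.
#'
#' @param m an [omics_matrix()].
#' @return list with `matrix` (standardized [omics_matrix()]), `center`
#'   and `scale` (named per-gene vectors).
#' @export
standardize <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  n <- nrow(m$values)
  center <- colMeans(m$values)
  centered <- sweep(m$values, 2L, center)
  scale <- sqrt(colSums(centered^2) / n)
  zero <- scale <= 0
  if (any(zero)) {
    stop_deconfae("zero-variance gene(s): %s (filter before standardizing)",
                  paste(m$gene_ids[zero], collapse = ", "))
  }
  std <- sweep(centered, 2L, scale, `/`)
  list(matrix = omics_matrix(std, m$domain), center = center, scale = scale)
}

#' Apply (or invert) a fitted standardization
#'
#' @param m an [omics_matrix()].
#' @param center,scale per-gene statistics from [standardize()] (matched by
#'   gene ID).
#' @param invert if TRUE, maps standardized values back to the original
#'   scale.
#' @return a transformed [omics_matrix()].
#' @export
apply_standardization <- function(m, center, scale, invert = FALSE) {
  stopifnot(inherits(m, "omics_matrix"))
  if (!all(m$gene_ids %in% names(center)) ||
      !all(m$gene_ids %in% names(scale))) {
    stop_deconfae("center/scale do not cover all genes")
  }
  center <- center[m$gene_ids]; scale <- scale[m$gene_ids]
  out <- if (invert) {
    sweep(sweep(m$values, 2L, scale, `*`), 2L, center, `+`)
  } else {
    sweep(sweep(m$values, 2L, center), 2L, scale, `/`)
  }
  omics_matrix(out, m$domain)
}

#' Cap follow-up time
#'
#' Records with follow-up strictly beyond `max_days` are administratively
#' censored at `max_days` (time set to the cap, event set to 0); records at
#' or below the cap are unchanged. Harmonizes cohorts with different study
#' durations.
#'
#' @param s a [survival_records()].
#' @param max_days cap in days (default 3000).
#' @return a capped [survival_records()].
#' @export
cap_followup <- function(s, max_days = 3000) {
  stopifnot(inherits(s, "survival_records"))
  over <- s$time > max_days
  time <- ifelse(over, max_days, s$time)
  event <- ifelse(over, 0L, s$event)
  survival_records(s$sample_id, time, as.integer(event), s$covariates)
}

#' Survival-stratified cross-validation folds
#'
#' Follow-up times are split into `n_quantiles` equally sized rank bins;
#' each (time-bin x event-status) stratum is shuffled and dealt round-robin
#' across folds, so within every stratum fold sizes differ by at most one
#' and event proportions are balanced across folds.
#'
#' @param s a [survival_records()].
#' @param k_folds number of folds (default 5).
#' @param n_quantiles number of time bins (default 10).
#' @param seed RNG seed.
#' @return a `fold_assignment` with `fold_id` and `stratum_id` per patient.
#' @export
stratified_survival_folds <- function(s, k_folds = 5L, n_quantiles = 10L,
                                      seed = 1L) {
  stopifnot(inherits(s, "survival_records"))
  if (k_folds < 2L) stop_deconfae("k_folds must be >= 2")
  n <- length(s$time)
  # rank-based equal-count bins; ties broken by stable sample order
  rnk <- rank(s$time, ties.method = "first")
  bin <- ceiling(rnk * n_quantiles / n)
  stratum <- paste0("q", bin, "_e", s$event)
  fold <- integer(n)
  with_seed(seed, {
    for (st in unique(stratum)) {
      idx <- which(stratum == st)
      idx <- idx[sample.int(length(idx))]
      start <- sample.int(k_folds, 1L)
      fold[idx] <- ((start - 1L + seq_along(idx) - 1L) %% k_folds) + 1L
    }
  })
  structure(list(sample_id = s$sample_id, fold_id = fold,
                 stratum_id = stratum, k_folds = as.integer(k_folds),
                 n_quantiles = as.integer(n_quantiles)),
            class = "fold_assignment")
}

#' Write a fold assignment as a two-column table
#' @param f a `fold_assignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_folds <- function(f, path) {
  stopifnot(inherits(f, "fold_assignment"))
  data.table::fwrite(data.table::data.table(id = f$sample_id,
                                            fold = f$fold_id),
                     path, sep = "\t")
  invisible(path)
}
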