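# Evaluation metrics and downstream stratification / dysregulation
# procedures.

#' Harrell's concordance index
#'
#' Fraction of comparable pairs whose predicted risk ordering matches the
#' observed event ordering. A pair is comparable iff the earlier time had
#' an event; ties in time with both events are not comparable; ties in
#' predicted risk count 1/2.
#'
#' @param risk predicted risk scores (higher = earlier expected event).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(risk, time, event) {
  risk <- as.numeric(risk); time <- as.numeric(time)
  event <- as.integer(event)
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  # comparable: i is the earlier time with an event, j survives longer
  earlier <- outer(time, time, `<`) & (event == 1L)
  d_risk <- outer(risk, risk, `-`)
  n_comp <- sum(earlier)
  if (n_comp == 0) stop_deconfae("no comparable pairs")
  concordant <- sum(earlier & (d_risk > 0))
  tied <- sum(earlier & (d_risk == 0))
  (concordant + 0.5 * tied) / n_comp
}

#' Per-drug coefficient of determination
#'
#' For each drug, `1 - SS_res/SS_tot` over observed entries in the
#' evaluation split. Drugs with fewer than two observed values or zero
#' variance in the observed values yield `NA` (flagged, excluded from
#' quantiles). Values may be negative; no truncation is applied.
#'
#' @param R_hat predicted matrix (cell-lines x drugs).
#' @param R observed matrix.
#' @param mask logical observed-entry matrix.
#' @param split row indices of the evaluation split (default all rows).
#' @return named numeric vector, one value (or `NA`) per drug.
#' @export
per_drug_r2 <- function(R_hat, R, mask, split = NULL) {
  stopifnot(identical(dim(R_hat), dim(R)), identical(dim(R), dim(mask)))
  if (is.null(split)) split <- seq_len(nrow(R))
  out <- rep(NA_real_, ncol(R))
  names(out) <- colnames(R)
  for (j in seq_len(ncol(R))) {
    rows <- split[mask[split, j]]
    if (length(rows) < 2L) next
    obs <- R[rows, j]
    ss_tot <- sum((obs - mean(obs))^2)
    if (ss_tot <= 0) next
    out[j] <- 1 - sum((R_hat[rows, j] - obs)^2) / ss_tot
  }
  out
}

#' 90th percentile of per-drug R-squared
#'
#' Linear-interpolation quantile (R type 7) over valid (non-`NA`) per-drug
#' values. Focuses evaluation on the drugs a model explains best.
#'
#' @param per_drug vector from [per_drug_r2()].
#' @return scalar 90th percentile.
#' @export
r2_quantile90 <- function(per_drug) {
  v <- per_drug[!is.na(per_drug)]
  if (length(v) == 0L) stop_deconfae("no valid per-drug R-squared values")
  unname(stats::quantile(v, 0.9, type = 7))
}

# ---- linear soft-margin classifier (squared hinge, BFGS) ------------------

# min_w,b 0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (x w + b))^2 ; y in {-1, 1}
fit_linear_svm <- function(X, y, cost = 1) {
  d <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + cost * sum(m^2)
  }
  grd <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    coef <- -2 * cost * m * y
    c(w + drop(crossprod(X, coef)), sum(coef))
  }
  fit <- stats::optim(numeric(d + 1L), obj, grd, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L])
}

#' Cross-validated domain-separability AUROC
#'
#' Stratified k-fold cross-validated AUROC of a linear soft-margin
#' classifier (squared-hinge SVM, cost `C = 1`, features standardized with
#' training-fold statistics) distinguishing patient from cell-line shared
#' embeddings; decision values are used as scores and per-fold AUROCs are
#' averaged. 0.5 means perfectly deconfounded, 1.0 fully separable.
#'
#' @param z_patients,z_celllines embedding matrices (rows = samples).
#' @param seed RNG seed for fold assignment.
#' @param n_folds number of folds (default 5).
#' @param cost soft-margin cost (default 1).
#' @return mean out-of-fold AUROC.
#' @export
domain_auroc <- function(z_patients, z_celllines, seed = 1L, n_folds = 5L,
                         cost = 1) {
  if (!is.matrix(z_patients)) z_patients <- as.matrix(z_patients)
  if (!is.matrix(z_celllines)) z_celllines <- as.matrix(z_celllines)
  np <- nrow(z_patients); nc <- nrow(z_celllines)
  if (min(np, nc) < n_folds) {
    stop_deconfae("each domain needs at least %d samples", n_folds)
  }
  X <- rbind(z_patients, z_celllines)
  lab <- c(rep(0L, np), rep(1L, nc))
  folds <- integer(np + nc)
  with_seed(seed, {
    folds[lab == 0L] <- ((sample.int(np) - 1L) %% n_folds) + 1L
    folds[lab == 1L] <- ((sample.int(nc) - 1L) %% n_folds) + 1L
  })
  aucs <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sd_ <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sd_[sd_ <= 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sd_, `/`)
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sd_, `/`)
    svm <- fit_linear_svm(Xtr, ifelse(lab[tr] == 1L, 1, -1), cost = cost)
    scores <- drop(Xte %*% svm$w) + svm$b
    aucs[f] <- auroc_from_scores(scores, lab[te])
  }
  mean(aucs)
}

#' Pareto front of metric tuples
#'
#' Returns the indices of all points not strictly dominated by any other
#' point: a dominator must be at least as good in every metric (under the
#' stated directions) and strictly better in at least one. Duplicates of a
#' front point are all retained.
#'
#' @param points numeric matrix (rows = points) or list of equal-length
#'   numeric vectors.
#' @param directions character vector, `"max"` or `"min"` per column
#'   (default all `"max"`).
#' @return integer indices of front members, in input order.
#' @export
pareto_front <- function(points, directions = NULL) {
  if (is.list(points) && !is.data.frame(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  k <- ncol(points)
  if (is.null(directions)) directions <- rep("max", k)
  stopifnot(length(directions) == k, all(directions %in% c("max", "min")))
  p <- points
  p[, directions == "min"] <- -p[, directions == "min", drop = FALSE]
  n <- nrow(p)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    dominated <- vapply(seq_len(n), function(j) {
      j != i && all(p[j, ] >= p[i, ]) && any(p[j, ] > p[i, ])
    }, logical(1))
    if (any(dominated)) keep[i] <- FALSE
  }
  which(keep)
}

#' Risk-tertile stratification transferred from a discovery cohort
#'
#' Cut points are the 1/3 and 2/3 quantiles (linear interpolation) of the
#' discovery risk scores; new scores are labelled `low` (<= lower cut),
#' `mid` (<= upper cut) or `high` using those fixed cut points, so a
#' validation cohort is stratified on the discovery scale.
#'
#' @param discovery_risk risk scores defining the cut points.
#' @param new_risk scores to label (defaults to `discovery_risk`).
#' @return a `risk_stratification` with `cuts` and a factor `labels`.
#' @export
stratify_risk <- function(discovery_risk, new_risk = discovery_risk) {
  if (length(discovery_risk) == 0L) stop_deconfae("empty discovery scores")
  cuts <- stats::quantile(discovery_risk, c(1, 2) / 3, type = 7, names = FALSE)
  labels <- cut(new_risk, breaks = c(-Inf, cuts, Inf),
                labels = c("low", "mid", "high"), right = TRUE)
  structure(list(cuts = cuts, labels = labels), class = "risk_stratification")
}

#' Drug-target dysregulation screen
#'
#' For each drug, patients are z-scored on their predicted sensitivity;
#' `resistant` patients have z below `z_low`, `sensitive` above `z_high`.
#' Each target gene of the drug is compared between the two groups with a
#' two-sided two-sample t-test, and a log2 fold-change (mean difference on
#' the log2 expression scale, sensitive minus resistant) is reported. A
#' gene is flagged `significant` when `p < alpha` and `substantial` when
#' the linear fold-change `2^|logFC|` exceeds `fc_threshold`.
#'
#' @param expression patient [omics_matrix()] on a log2 scale.
#' @param predicted_sensitivity matrix (patients x drugs) of predicted
#'   sensitivities.
#' @param drug_targets named list mapping drug IDs to character vectors of
#'   target genes (genes absent from the matrix are flagged and skipped).
#' @param z_low,z_high z-score thresholds defining the groups.
#' @param alpha significance level.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @return data.frame with one row per drug-target pair: `drug`, `gene`,
#'   `logFC`, `p`, `significant`, `substantial`, `status` (`"ok"`,
#'   `"untestable"` or `"gene_absent"`).
#' @export
dysregulation_test <- function(expression, predicted_sensitivity,
                               drug_targets, z_low = -1, z_high = 1,
                               alpha = 0.05, fc_threshold = 1.5) {
  stopifnot(inherits(expression, "omics_matrix"))
  if (!is.matrix(predicted_sensitivity)) {
    predicted_sensitivity <- as.matrix(predicted_sensitivity)
  }
  if (nrow(predicted_sensitivity) != nrow(expression$values)) {
    stop_deconfae("predictions must align with expression samples")
  }
  rows <- list()
  for (drug in names(drug_targets)) {
    if (!drug %in% colnames(predicted_sensitivity)) next
    pred <- predicted_sensitivity[, drug]
    sd_p <- stats::sd(pred)
    untestable <- FALSE
    if (!is.finite(sd_p) || sd_p <= 0) {
      untestable <- TRUE
    } else {
      z <- (pred - mean(pred)) / sd_p
      res_idx <- which(z < z_low)
      sen_idx <- which(z > z_high)
      if (length(res_idx) < 2L || length(sen_idx) < 2L) untestable <- TRUE
    }
    for (gene in drug_targets[[drug]]) {
      if (!gene %in% expression$gene_ids) {
        rows[[length(rows) + 1L]] <- data.frame(
          drug = drug, gene = gene, logFC = NA_real_, p = NA_real_,
          significant = NA, substantial = NA, status = "gene_absent")
        next
      }
      if (untestable) {
        rows[[length(rows) + 1L]] <- data.frame(
          drug = drug, gene = gene, logFC = NA_real_, p = NA_real_,
          significant = NA, substantial = NA, status = "untestable")
        next
      }
      xs <- expression$values[sen_idx, gene]
      xr <- expression$values[res_idx, gene]
      tt <- tryCatch(stats::t.test(xs, xr), error = function(e) NULL)
      lfc <- mean(xs) - mean(xr)
      p <- if (is.null(tt)) NA_real_ else tt$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        drug = drug, gene = gene, logFC = lfc, p = p,
        significant = is.finite(p) && p < alpha,
        substantial = 2^abs(lfc) > fc_threshold,
        status = if (is.null(tt)) "untestable" else "ok")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(drug = character(), gene = character(),
                      logFC = numeric(), p = numeric(),
                      significant = logical(), substantial = logical(),
                      status = character()))
  }
  do.call(rbind, rows)
}

#' Assemble an evaluation report
#'
#' The composite selection score is
#' `cindex + r2_q90 - domain_auroc`: survival concordance plus the top-10%
#' drug R-squared quantile minus the residual domain separability.
#'
#' @param cindex Harrell's C on held-out patients.
#' @param per_drug named per-drug R-squared vector.
#' @param domain_auroc residual domain AUROC on shared embeddings.
#' @return an `evaluation_report` list with `cindex`, `per_drug_r2`,
#'   `r2_q90`, `domain_auroc` and `composite`.
#' @export
evaluation_report <- function(cindex, per_drug, domain_auroc) {
  r2_q90 <- r2_quantile90(per_drug)
  structure(list(cindex = cindex, per_drug_r2 = per_drug, r2_q90 = r2_q90,
                 domain_auroc = domain_auroc,
                 composite = cindex + r2_q90 - domain_auroc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> C-index %.3f | R2 q90 %.3f | ",
                     "domain AUROC %.3f | composite %.3f\n"),
              x$cindex, x$r2_q90, x$domain_auroc, x$composite))
  invisible(x)
}
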