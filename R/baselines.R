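# Elastic-net reference models: penalized Cox for survival and penalized
# linear regression per drug, each on top of univariate top-k feature
# selection or principal components. Backed by glmnet; the feature
# reduction and the nested grid search are implemented here so that
# selection is always fitted inside training folds only.

#' Baseline model specification
#'
#' @param task `"survival"` (elastic-net Cox) or `"drug"` (elastic-net
#'   regression, one model per drug).
#' @param reducer `"univariate"` (top-k filter) or `"pca"`.
#' @param k_grid candidate top-k values (univariate reducer; must lie in
#'   `[100, 1000]` unless `enforce_k_range = FALSE` for toy problems).
#' @param n_components_grid candidate PCA component counts (capped at
#'   `min(n, p) - 1` at fit time).
#' @param penalty_grid elastic-net penalties (subset of `[1e-3, 1e-1]`).
#' @param l1_ratio_grid elastic-net mixing values (subset of
#'   `[0.1, 0.99]`).
#' @param enforce_k_range set FALSE to allow small k on toy data.
#' @return a `baseline_spec`.
#' @export
baseline_spec <- function(task = c("survival", "drug"),
                          reducer = c("univariate", "pca"),
                          k_grid = c(100L, 250L, 500L, 1000L),
                          n_components_grid = c(10L, 100L),
                          penalty_grid = 10^seq(-3, -1, length.out = 5),
                          l1_ratio_grid = seq(0.1, 0.99, length.out = 5),
                          enforce_k_range = TRUE) {
  task <- match.arg(task)
  reducer <- match.arg(reducer)
  if (length(penalty_grid) == 0L || length(l1_ratio_grid) == 0L) {
    stop_deconfae("penalty and l1-ratio grids must be non-empty")
  }
  if (reducer == "univariate" && enforce_k_range &&
      (any(k_grid < 100) || any(k_grid > 1000))) {
    stop_deconfae("k must lie in [100, 1000]")
  }
  structure(list(task = task, reducer = reducer,
                 k_grid = as.integer(k_grid),
                 n_components_grid = as.integer(n_components_grid),
                 penalty_grid = as.numeric(penalty_grid),
                 l1_ratio_grid = as.numeric(l1_ratio_grid)),
            class = "baseline_spec")
}

#' Univariate top-k feature selection
#'
#' Ranks features by the magnitude of their univariate association test
#' statistic with the target — a single-covariate Cox model z-statistic
#' for survival, the correlation t-statistic (equivalent to the
#' single-covariate linear-regression slope test) for continuous targets —
#' and returns the indices of the top `k`.
#'
#' @param features numeric matrix (samples x features).
#' @param target for `task = "drug"` a numeric vector; for
#'   `task = "survival"` a list with `time` and `event`.
#' @param k number of features to keep.
#' @param task `"drug"` or `"survival"`.
#' @return integer vector of `k` column indices.
#' @export
univariate_topk <- function(features, target, k, task = c("drug", "survival")) {
  task <- match.arg(task)
  if (k > ncol(features)) {
    stop_deconfae("k (%d) exceeds the number of features (%d)", k,
                  ncol(features))
  }
  if (task == "drug") {
    y <- as.numeric(target)
    n <- length(y)
    r <- suppressWarnings(stats::cor(features, y))
    r[is.na(r)] <- 0
    stat <- abs(r) * sqrt(pmax(n - 2, 1) / pmax(1 - r^2, 1e-12))
  } else {
    srv <- survival::Surv(target$time, target$event)
    stat <- vapply(seq_len(ncol(features)), function(j) {
      x <- features[, j]
      if (stats::sd(x) == 0) return(0)
      fit <- tryCatch(
        survival::coxph(srv ~ x, control = survival::coxph.control(iter.max = 20)),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(survival::coxph(srv ~ x))
        })
      if (is.null(fit)) return(0)
      z <- summary(fit)$coefficients[1, "z"]
      if (is.finite(z)) abs(z) else 0
    }, numeric(1))
  }
  order(stat, decreasing = TRUE)[seq_len(k)]
}

# glmnet needs >= 2 columns; pad with a zero column when necessary
fit_glmnet_safe <- function(x, y, family, alpha, lambda) {
  padded <- FALSE
  if (ncol(x) < 2L) {
    x <- cbind(x, pad__ = 0)
    padded <- TRUE
  }
  fit <- glmnet::glmnet(x, y, family = family, alpha = alpha,
                        lambda = lambda, standardize = TRUE)
  list(fit = fit, padded = padded)
}

predict_glmnet_safe <- function(model, newx) {
  if (model$padded) newx <- cbind(newx, pad__ = 0)
  drop(stats::predict(model$fit, newx = newx, type = "link"))
}

reduce_fit <- function(spec, x, target, size) {
  if (spec$reducer == "univariate") {
    idx <- univariate_topk(x, target, size, task = spec$task)
    list(kind = "univariate", idx = idx)
  } else {
    ncomp <- min(size, nrow(x) - 1L, ncol(x))
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)
    list(kind = "pca", center = pc$center, rotation = pc$rotation)
  }
}

reduce_apply <- function(red, x) {
  if (red$kind == "univariate") {
    x[, red$idx, drop = FALSE]
  } else {
    sweep(x, 2L, red$center) %*% red$rotation
  }
}

baseline_metric <- function(spec, lp, target) {
  if (spec$task == "survival") {
    harrell_cindex(lp, target$time, target$event)
  } else {
    y <- as.numeric(target)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot <= 0) return(NA_real_)
    1 - sum((lp - y)^2) / ss_tot
  }
}

subset_target <- function(spec, target, idx) {
  if (spec$task == "survival") {
    list(time = target$time[idx], event = target$event[idx])
  } else {
    target[idx]
  }
}

#' Fit an elastic-net baseline with nested grid search
#'
#' Runs an inner cross-validated grid search over penalty, L1-ratio and
#' reducer size (top-k or number of components), with the reducer refitted
#' inside every inner training fold (no selection leakage), then refits on
#' the full training data with the winning configuration.
#'
#' @param spec a [baseline_spec()].
#' @param features numeric matrix (samples x features), training split.
#' @param target survival list (`time`, `event`) or numeric drug response
#'   (with `NA` for unscreened; those rows are dropped).
#' @param folds integer fold ids for the inner search (e.g. from
#'   [stratified_survival_folds()] for survival tasks).
#' @return a `baseline_model` with the fitted reducer, glmnet fit and the
#'   chosen hyper-parameters.
#' @export
fit_baseline <- function(spec, features, target, folds) {
  stopifnot(inherits(spec, "baseline_spec"))
  if (spec$task == "drug") {
    y <- as.numeric(target)
    keep <- which(!is.na(y))
    features <- features[keep, , drop = FALSE]
    target <- y[keep]
    folds <- folds[keep]
  }
  sizes <- if (spec$reducer == "univariate") {
    pmin(spec$k_grid, ncol(features))
  } else {
    pmin(spec$n_components_grid, nrow(features) - 1L, ncol(features))
  }
  sizes <- sort(unique(sizes))
  grid <- expand.grid(size = sizes, penalty = spec$penalty_grid,
                      l1_ratio = spec$l1_ratio_grid)
  fold_ids <- sort(unique(folds))
  search_needed <- nrow(grid) > 1L
  scores <- rep(NA_real_, nrow(grid))
  if (search_needed) {
    for (gi in seq_len(nrow(grid))) {
      ms <- numeric(0)
      for (f in fold_ids) {
        tr <- which(folds != f); te <- which(folds == f)
        if (length(te) < 2L || length(tr) < 5L) next
        t_tr <- subset_target(spec, target, tr)
        if (spec$task == "survival" &&
            (sum(t_tr$event) == 0L ||
             sum(subset_target(spec, target, te)$event) == 0L)) {
          stop_deconfae("degenerate inner fold: no events")
        }
        red <- reduce_fit(spec, features[tr, , drop = FALSE], t_tr,
                          grid$size[gi])
        xtr <- reduce_apply(red, features[tr, , drop = FALSE])
        xte <- reduce_apply(red, features[te, , drop = FALSE])
        yob <- if (spec$task == "survival") {
          survival::Surv(t_tr$time, t_tr$event)
        } else t_tr
        fam <- if (spec$task == "survival") "cox" else "gaussian"
        mod <- fit_glmnet_safe(xtr, yob, fam, grid$l1_ratio[gi],
                               grid$penalty[gi])
        lp <- predict_glmnet_safe(mod, xte)
        ms <- c(ms, baseline_metric(spec, lp, subset_target(spec, target, te)))
      }
      scores[gi] <- mean(ms, na.rm = TRUE)
    }
    best <- which.max(scores)
  } else {
    best <- 1L
  }
  red <- reduce_fit(spec, features, target, grid$size[best])
  xall <- reduce_apply(red, features)
  yob <- if (spec$task == "survival") {
    survival::Surv(target$time, target$event)
  } else target
  fam <- if (spec$task == "survival") "cox" else "gaussian"
  mod <- fit_glmnet_safe(xall, yob, fam, grid$l1_ratio[best],
                         grid$penalty[best])
  structure(list(spec = spec, reducer = red, model = mod,
                 chosen = as.list(grid[best, ]),
                 grid_scores = if (search_needed) {
                   cbind(grid, score = scores)
                 } else NULL),
            class = "baseline_model")
}

#' Predict from a fitted baseline
#'
#' @param object a `baseline_model`.
#' @param newdata feature matrix on the training feature space.
#' @param ... unused.
#' @return linear predictor: log-risk for survival models, predicted
#'   response for drug models.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  x <- reduce_apply(object$reducer, newdata)
  predict_glmnet_safe(object$model, x)
}

#' Fit independent per-drug baselines
#'
#' @param spec a [baseline_spec()] with `task = "drug"`.
#' @param features training feature matrix (cell-lines x genes).
#' @param drugs a [drug_response_matrix()] aligned with `features`.
#' @param folds inner fold ids per cell-line.
#' @return named list of `baseline_model`s, one per drug.
#' @export
fit_drug_baselines <- function(spec, features, drugs, folds) {
  stopifnot(spec$task == "drug", inherits(drugs, "drug_response_matrix"))
  out <- list()
  for (j in seq_along(drugs$drug_ids)) {
    y <- drugs$values[, j]
    y[!drugs$observed_mask[, j]] <- NA
    out[[drugs$drug_ids[j]]] <- fit_baseline(spec, features, y, folds)
  }
  out
}
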