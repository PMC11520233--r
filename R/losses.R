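# Training objectives. All functions are pure; gradients used by the
# training loop live alongside the values so the two cannot drift apart.

#' Multi-task loss weights
#'
#' @param alpha1 reconstruction weight.
#' @param alpha2 deconfounding weight.
#' @param alpha3 survival weight (applied to the negative Efron
#'   log-likelihood).
#' @param alpha4 drug-sensitivity weight.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(alpha1 = 1, alpha2 = 1, alpha3 = 1, alpha4 = 1) {
  w <- c(alpha1, alpha2, alpha3, alpha4)
  if (!all(is.finite(w)) || any(w < 0)) {
    stop_deconfae("loss weights must be finite and non-negative")
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 alpha3 = alpha3, alpha4 = alpha4),
            class = "loss_weights")
}

#' Autoencoder reconstruction loss
#'
#' Mean squared reconstruction error normalized by both sample count and
#' input dimension: `(1/(n*d)) * sum_i ||x_hat_i - x_i||^2`. The `1/d`
#' factor keeps the reconstruction term on a scale comparable with the
#' other multi-task objectives.
#'
#' @param x,x_hat matrices of identical shape (n x d).
#' @return scalar loss.
#' @export
reconstruction_loss <- function(x, x_hat) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x_hat)) x_hat <- matrix(x_hat, nrow = 1L)
  if (!identical(dim(x), dim(x_hat))) {
    stop_deconfae("x and x_hat must have identical shape")
  }
  sum((x_hat - x)^2) / (nrow(x) * ncol(x))
}

#' Adversarial (critic) loss
#'
#' `(1/n) * sum_i C_i * (1 - 2*s_i)`: minimizing drives the critic output
#' down on patients (`s = 0`) and up on cell-lines (`s = 1`); the negated
#' value approximates the Wasserstein distance between the two embedding
#' distributions.
#'
#' @param critic_values critic outputs per sample.
#' @param s domain indicators (0 patient, 1 cell-line).
#' @return scalar loss.
#' @export
adversarial_loss <- function(critic_values, s) {
  critic_values <- as.numeric(critic_values)
  if (length(critic_values) != length(s)) {
    stop_deconfae("critic_values and s must have equal length")
  }
  mean(critic_values * (1 - 2 * as.numeric(s)))
}

#' Deconfounding loss
#'
#' Mean critic value over cell-line samples only:
#' `(1/sum(s)) * sum_i C_i * s_i`. Minimized by the autoencoder, it pulls
#' the cell-line embedding distribution toward the patient distribution
#' (where the trained critic outputs low values). Equals the cell-line
#' term of [adversarial_loss()] with the sign reversed, rescaled to a
#' per-cell-line mean.
#'
#' @inheritParams adversarial_loss
#' @return scalar loss.
#' @export
deconfounding_loss <- function(critic_values, s) {
  critic_values <- as.numeric(critic_values)
  s <- as.numeric(s)
  if (length(critic_values) != length(s)) {
    stop_deconfae("critic_values and s must have equal length")
  }
  if (sum(s) < 1) {
    stop_deconfae("deconfounding loss needs at least one cell-line in the batch")
  }
  sum(critic_values * s) / sum(s)
}

#' Wasserstein gradient penalty
#'
#' Enforces the critic's 1-Lipschitz constraint by penalizing the deviation
#' of its input-gradient norm from 1 at random interpolates between
#' patient and cell-line shared embeddings:
#' `lambda_gp * mean((||grad C(z_hat)|| - 1)^2)` with
#' `z_hat = u * z_p + (1 - u) * z_c`, `u ~ Uniform(0,1)` per pair. The two
#' embedding sets are trimmed to the smaller batch.
#'
#' @param critic the critic network (from a `module_set`).
#' @param z_patient,z_cellline shared-embedding matrices (rows = samples).
#' @param lambda_gp penalty coefficient (default 10, the WGAN-GP
#'   convention).
#' @param u optional vector of interpolation weights (drawn from the
#'   current RNG stream when `NULL`).
#' @return scalar penalty (always >= 0).
#' @export
gradient_penalty <- function(critic, z_patient, z_cellline, lambda_gp = 10,
                             u = NULL) {
  if (!is.matrix(z_patient)) z_patient <- matrix(z_patient, nrow = 1L)
  if (!is.matrix(z_cellline)) z_cellline <- matrix(z_cellline, nrow = 1L)
  n <- min(nrow(z_patient), nrow(z_cellline))
  if (n < 1L) stop_deconfae("need at least one embedding per domain")
  if (is.null(u)) u <- stats::runif(n)
  z_hat <- u * z_patient[seq_len(n), , drop = FALSE] +
    (1 - u) * z_cellline[seq_len(n), , drop = FALSE]
  critic_penalty_grads(critic, z_hat, lambda_gp)$value
}

#' Group survival records for Efron's tie correction
#'
#' Builds, for each unique event time `t_i`, the set `h_i` of tied events
#' and the risk set `{j : T_j >= t_i}`. Censored records never appear in
#' any `h_i` but do contribute to risk sets.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return an `efron_grouping` with `event_times`, `h` (list of event index
#'   sets), `risk_sets` (list of at-risk index sets) and `n_events`.
#' @export
build_efron_grouping <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) stop_deconfae("time/event length mismatch")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop_deconfae("times must be finite and strictly positive")
  }
  if (!all(event %in% c(0L, 1L))) stop_deconfae("event must be 0/1")
  if (sum(event) == 0L) {
    stop_deconfae("no events: the partial likelihood is undefined")
  }
  ts <- sort(unique(time[event == 1L]))
  h <- lapply(ts, function(t) which(event == 1L & time == t))
  risk <- lapply(ts, function(t) which(time >= t))
  structure(list(event_times = ts, h = h, risk_sets = risk,
                 n_events = sum(event)),
            class = "efron_grouping")
}

# value and gradient of the Efron-adjusted Cox partial log-likelihood,
# normalized by the number of events; log-sum-exp stabilized
efron_loglik_grad <- function(g, grouping) {
  g <- as.numeric(g)
  if (any(!is.finite(g))) stop_deconfae("non-finite risk scores")
  mstar <- max(g)
  eg <- exp(g - mstar)             # shifted exponentials
  total <- 0
  grad <- numeric(length(g))
  for (i in seq_along(grouping$h)) {
    hi <- grouping$h[[i]]
    ri <- grouping$risk_sets[[i]]
    m <- length(hi)
    S <- sum(eg[ri])               # risk-set sum (shifted)
    Tt <- sum(eg[hi])              # tied-event sum (shifted)
    total <- total + sum(g[hi])
    for (l in seq_len(m) - 1L) {
      denom <- S - (l / m) * Tt
      total <- total - (mstar + log(denom))
      grad[ri] <- grad[ri] - eg[ri] / denom
      grad[hi] <- grad[hi] + (l / m) * eg[hi] / denom
    }
  }
  n_ev <- grouping$n_events
  for (i in seq_along(grouping$h)) grad[grouping$h[[i]]] <-
    grad[grouping$h[[i]]] + 1
  list(value = total / n_ev, grad = grad / n_ev)
}

#' Efron-adjusted Cox partial log-likelihood
#'
#' Cox partial log-likelihood with Efron's correction for tied event times,
#' computed with log-sum-exp stabilization and normalized by the total
#' number of observed events (so its scale is comparable across batch
#' sizes). Larger is better; the training loss is the negation of this
#' value.
#'
#' @param g risk scores (log-hazards), one per record in the grouping's
#'   index space.
#' @param grouping a [build_efron_grouping()] result.
#' @return scalar log-likelihood (per event).
#' @export
efron_cox_loglik <- function(g, grouping) {
  stopifnot(inherits(grouping, "efron_grouping"))
  efron_loglik_grad(g, grouping)$value
}

#' Masked drug-sensitivity loss
#'
#' Mean squared error over observed entries only:
#' `(1/|O(R)|) * sum_{(i,j) in O(R)} (R_hat_ij - R_ij)^2`. Values at
#' unobserved positions never influence the loss.
#'
#' @param R_hat predicted matrix (cell-lines x drugs).
#' @param R observed matrix (may contain arbitrary values at unobserved
#'   positions).
#' @param mask logical matrix marking observed entries.
#' @return scalar loss.
#' @export
masked_drug_loss <- function(R_hat, R, mask) {
  if (!identical(dim(R_hat), dim(R)) || !identical(dim(R), dim(mask))) {
    stop_deconfae("R_hat, R and mask must share dimensions")
  }
  n_obs <- sum(mask)
  if (n_obs < 1) stop_deconfae("no observed drug entries in the batch")
  sum(((R_hat - R)[mask])^2) / n_obs
}

#' Weighted multi-task loss
#'
#' `alpha1*l_rec + alpha2*l_dc + alpha3*l_surv + alpha4*l_drug`, where
#' `l_surv` is the negative Efron log-likelihood.
#'
#' @param l_rec,l_dc,l_surv_negloglik,l_drug scalar loss components.
#' @param w a [loss_weights()] object.
#' @return scalar total loss.
#' @export
mtl_loss <- function(l_rec, l_dc, l_surv_negloglik, l_drug, w) {
  stopifnot(inherits(w, "loss_weights"))
  comps <- c(l_rec = l_rec, l_dc = l_dc, l_surv = l_surv_negloglik,
             l_drug = l_drug)
  bad <- names(comps)[!is.finite(comps)]
  if (length(bad) > 0) {
    stop_deconfae("non-finite loss component(s): %s",
                  paste(bad, collapse = ", "))
  }
  w$alpha1 * l_rec + w$alpha2 * l_dc + w$alpha3 * l_surv_negloglik +
    w$alpha4 * l_drug
}
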