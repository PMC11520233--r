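# Synthetic paired patient/cell-line cohorts with the statistical structure
# the model assumes: two expression domains driven by common latent factors
# but separated by a per-gene domain shift, survival hazards driven by the
# shared factors, and drug sensitivities that are logistic functions of the
# shared factors with missing-at-random screening entries.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a desk-scale cohort: a few hundred samples per domain,
#' a strong domain shift (raw-expression domain classifiers reach AUROC
#' near 1), exponential survival with a 3000-day follow-up cap and roughly
#' half of drugs carrying signal. See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_patients,n_celllines,n_genes cohort dimensions.
#' @param n_shared_factors latent factors common to both domains.
#' @param n_private_factors latent factors private to each domain.
#' @param domain_shift_scale magnitude of the constant per-gene offset added
#'   to cell-line expression (0 = identical domains).
#' @param hazard_coefficients log-hazard coefficients over shared factors
#'   (recycled/truncated to `n_shared_factors`).
#' @param baseline_hazard events per day for a patient at factor zero.
#' @param censoring_rate rate of the independent exponential censoring time.
#' @param max_followup administrative censoring cap in days.
#' @param n_drugs number of screened drugs.
#' @param drug_signal_fraction fraction of drugs whose sensitivity depends
#'   on the shared factors; the rest are pure noise.
#' @param missing_fraction fraction of drug-response entries masked as
#'   unobserved (drawn by fixed count, so the observed count is
#'   deterministic given the seed).
#' @param noise_sd standard deviation of the additive expression noise.
#' @param seed RNG seed; identical seeds give bit-identical cohorts.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 300L, n_celllines = 300L,
                             n_genes = 50L, n_shared_factors = 5L,
                             n_private_factors = 2L,
                             domain_shift_scale = 3,
                             hazard_coefficients = c(0.8, -0.8, 0.5, -0.5, 0.3),
                             baseline_hazard = 1 / 2000,
                             censoring_rate = 1 / 4000,
                             max_followup = 3000,
                             n_drugs = 20L, drug_signal_fraction = 0.5,
                             missing_fraction = 0.3, noise_sd = 0.5,
                             seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  n_celllines <- assert_count(n_celllines, "n_celllines")
  n_genes <- assert_count(n_genes, "n_genes")
  n_shared_factors <- assert_count(n_shared_factors, "n_shared_factors")
  if (length(n_private_factors) != 1L || n_private_factors < 0 ||
      n_private_factors != round(n_private_factors)) {
    stop_deconfae("n_private_factors must be a single integer >= 0")
  }
  n_drugs <- assert_count(n_drugs, "n_drugs")
  for (nm in c("domain_shift_scale", "baseline_hazard", "censoring_rate",
               "max_followup", "noise_sd")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop_deconfae("%s must be a single finite non-negative value", nm)
    }
  }
  if (baseline_hazard <= 0) stop_deconfae("baseline_hazard must be positive")
  if (max_followup <= 0) stop_deconfae("max_followup must be positive")
  assert_fraction(drug_signal_fraction, "drug_signal_fraction")
  assert_fraction(missing_fraction, "missing_fraction")
  hazard_coefficients <- rep_len(as.numeric(hazard_coefficients),
                                 n_shared_factors)
  assert_finite(hazard_coefficients, "hazard_coefficients")
  structure(list(n_patients = n_patients, n_celllines = n_celllines,
                 n_genes = n_genes, n_shared_factors = n_shared_factors,
                 n_private_factors = as.integer(n_private_factors),
                 domain_shift_scale = domain_shift_scale,
                 hazard_coefficients = hazard_coefficients,
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 max_followup = max_followup,
                 n_drugs = n_drugs,
                 drug_signal_fraction = drug_signal_fraction,
                 missing_fraction = missing_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate paired synthetic cohorts
#'
#' Expression in both domains is a linear map of shared factors plus
#' domain-private factors plus Gaussian noise, on a log-expression-like
#' scale (per-gene baseline means around 3). Cell-lines additionally
#' receive a fixed per-gene offset of magnitude `domain_shift_scale` with
#' random sign. Survival times are exponential with rate
#' `baseline_hazard * exp(hazard_coefficients . shared_factors)`, censored
#' at an independent exponential time and capped at `max_followup`. Signal
#' drugs are logistic squashes of linear functions of the shared factors;
#' noise drugs are logistic noise; a fixed count of entries
#' (`round(missing_fraction * n_celllines * n_drugs)`) is masked uniformly
#' at random.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_cohorts` list with elements `patient` and
#'   `cellline` ([omics_matrix()]), `survival` ([survival_records()]),
#'   `drugs` ([drug_response_matrix()]) and `truth` (latent factors,
#'   loadings, drug weights, signal-drug indices and the config).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    np <- config$n_patients; nc <- config$n_celllines
    g <- config$n_genes; ks <- config$n_shared_factors
    kp <- config$n_private_factors
    L_shared <- matrix(stats::rnorm(ks * g), ks, g)
    gene_mu <- abs(stats::rnorm(g, mean = 3, sd = 2))
    shift_sign <- sample(c(-1, 1), g, replace = TRUE)
    F_p <- matrix(stats::rnorm(np * ks), np, ks)
    F_c <- matrix(stats::rnorm(nc * ks), nc, ks)
    X_p <- F_p %*% L_shared
    X_c <- F_c %*% L_shared
    L_priv_p <- L_priv_c <- NULL
    P_p <- P_c <- NULL
    if (kp > 0) {
      L_priv_p <- matrix(stats::rnorm(kp * g), kp, g)
      L_priv_c <- matrix(stats::rnorm(kp * g), kp, g)
      P_p <- matrix(stats::rnorm(np * kp), np, kp)
      P_c <- matrix(stats::rnorm(nc * kp), nc, kp)
      X_p <- X_p + P_p %*% L_priv_p
      X_c <- X_c + P_c %*% L_priv_c
    }
    X_p <- sweep(X_p, 2L, gene_mu, `+`)
    X_c <- sweep(X_c, 2L, gene_mu + config$domain_shift_scale * shift_sign, `+`)
    if (config$noise_sd > 0) {
      X_p <- X_p + matrix(stats::rnorm(np * g, sd = config$noise_sd), np, g)
      X_c <- X_c + matrix(stats::rnorm(nc * g, sd = config$noise_sd), nc, g)
    }
    gene_ids <- sprintf("gene_%03d", seq_len(g))
    pat_ids <- sprintf("patient_%04d", seq_len(np))
    cl_ids <- sprintf("cellline_%04d", seq_len(nc))
    dimnames(X_p) <- list(pat_ids, gene_ids)
    dimnames(X_c) <- list(cl_ids, gene_ids)

    # survival: exponential event times with log-linear hazard in the
    # shared factors, independent exponential censoring, administrative cap
    rate <- config$baseline_hazard *
      exp(drop(F_p %*% config$hazard_coefficients))
    t_event <- stats::rexp(np, rate = rate)
    t_cens <- if (config$censoring_rate > 0) {
      stats::rexp(np, rate = config$censoring_rate)
    } else rep(Inf, np)
    time <- pmin(t_event, t_cens, config$max_followup)
    event <- as.integer(t_event <= pmin(t_cens, config$max_followup))
    time <- pmax(time, .Machine$double.eps)

    # drugs: logistic squash of a linear function of shared factors for
    # signal drugs, logistic noise otherwise
    m <- config$n_drugs
    n_signal <- round(config$drug_signal_fraction * m)
    signal_idx <- seq_len(n_signal)
    Wd <- matrix(0, ks, m)
    if (n_signal > 0) {
      Wd[, signal_idx] <- matrix(stats::rnorm(ks * n_signal, sd = 1.2),
                                 ks, n_signal)
    }
    intercepts <- stats::rnorm(m, mean = -0.5, sd = 0.5)
    lin <- sweep(F_c %*% Wd, 2L, intercepts, `+`)
    eps <- matrix(stats::rnorm(nc * m, sd = 0.4), nc, m)
    if (n_signal < m) {
      # noise drugs: no factor signal, unit-variance logistic noise
      eps[, setdiff(seq_len(m), signal_idx)] <-
        stats::rnorm(nc * (m - n_signal))
    }
    R <- stats::plogis(lin + eps)
    R <- pmin(pmax(R, 0), 1)
    drug_ids <- sprintf("drug_%02d", seq_len(m))
    dimnames(R) <- list(cl_ids, drug_ids)
    mask <- matrix(TRUE, nc, m, dimnames = dimnames(R))
    n_missing <- round(config$missing_fraction * nc * m)
    if (n_missing > 0) {
      mask[sample.int(nc * m, n_missing)] <- FALSE
    }

    list_out <- list(
      patient = omics_matrix(X_p, domain = 0L),
      cellline = omics_matrix(X_c, domain = 1L),
      survival = survival_records(pat_ids, time, event),
      drugs = drug_response_matrix(R, mask),
      truth = list(factors_patient = F_p, factors_cellline = F_c,
                   loadings_shared = L_shared,
                   loadings_private_patient = L_priv_p,
                   loadings_private_cellline = L_priv_c,
                   factors_private_patient = P_p,
                   factors_private_cellline = P_c,
                   gene_means = gene_mu,
                   shift_signs = shift_sign,
                   drug_weights = Wd, drug_intercepts = intercepts,
                   signal_drugs = signal_idx,
                   config = config))
    structure(list_out, class = "synthetic_cohorts")
  })
}

#' Write synthetic cohorts to a directory of text tables
#'
#' Writes the two expression matrices, the survival table and the drug
#' matrix as tab-separated files (samples in rows, first column = ID;
#' unobserved drug entries as empty cells) plus a JSON sidecar with the
#' generating configuration and true parameters.
#'
#' @param cohorts a [generate_cohorts()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(cohorts, dir) {
  stopifnot(inherits(cohorts, "synthetic_cohorts"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(cohorts$patient, file.path(dir, "expression_patient.tsv"))
  write_expression(cohorts$cellline, file.path(dir, "expression_cellline.tsv"))
  write_survival(cohorts$survival, file.path(dir, "survival.tsv"))
  write_drug_response(cohorts$drugs, file.path(dir, "drug_response.tsv"))
  truth <- cohorts$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       matrix = "rowmajor")
  invisible(dir)
}
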