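# Fixture builders shared across test files; everything is generated in
# code at test time.

tiny_cohorts <- function(seed = 1, ...) {
  generate_cohorts(synthetic_config(
    n_patients = 120, n_celllines = 120, n_genes = 25, n_drugs = 8,
    seed = seed, ...))
}

# preprocess a cohort set the way the pipeline does, returning standardized
# matrices plus capped survival
prep_cohorts <- function(coh, min_mean = 1) {
  filt <- filter_genes(coh$patient, coh$cellline, min_mean = min_mean)
  list(patient = standardize(filt$patient)$matrix,
       cellline = standardize(filt$cellline)$matrix,
       survival = cap_followup(coh$survival),
       drugs = coh$drugs)
}

subset_omics <- function(m, idx) {
  omics_matrix(m$values[idx, , drop = FALSE], m$domain[idx])
}

subset_survival <- function(s, idx) {
  survival_records(s$sample_id[idx], s$time[idx], s$event[idx],
                   if (!is.null(s$covariates)) s$covariates[idx, , drop = FALSE])
}

subset_drugs <- function(d, idx) {
  drug_response_matrix(d$values[idx, , drop = FALSE],
                       d$observed_mask[idx, , drop = FALSE])
}

# small module set on a given input dimension, deterministic
tiny_modules <- function(input_dim, latent_dim = 8, n_drugs = 4, seed = 1,
                         dropout = 0, l2 = 0) {
  cfg <- network_config(input_dim = input_dim, latent_dim = latent_dim,
                        n_drugs = n_drugs,
                        encoder_widths = c(16L, 16L),
                        decoder_widths = c(16L, 16L),
                        critic_widths = c(8L, 8L),
                        survival_widths = c(8L, 8L),
                        drug_widths = c(8L, 8L),
                        dropout = dropout, l2 = l2)
  build_modules(cfg, seed = seed)
}

# random survival data with controllable ties
random_survival <- function(n, tie_prob = 0.3, max_t = 10L) {
  time <- sample.int(max_t, n, replace = tie_prob > 0)
  event <- rbinom(n, 1, 0.6)
  if (sum(event) == 0) event[1] <- 1L
  list(time = as.numeric(time), event = as.integer(event))
}
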