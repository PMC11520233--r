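# Random hyper-parameter search with multi-objective bookkeeping: every
# trial records per-fold C-index, 90th-percentile drug R-squared and
# domain AUROC; selection maximizes the composite score
# cindex + r2_q90 - domain_auroc, which is always a member of the
# mean-metric Pareto front.

#' Hyper-parameter search space
#'
#' Distributions for the random search. Defaults: learning rate
#' log-uniform on `[1e-5, 1e-3]`; L2 log-uniform on `[1e-6, 1e-2]`;
#' dropout uniform on `[0, 0.3]`; task weights log-uniform on
#' `[1e-2, 1e2]`; hidden widths from {64, 128, 256, 512}; latent dimension
#' from {32, 64, 128} with shared fraction from {0.25, 0.5, 0.75};
#' batch size from {64, 128, 256}.
#'
#' @param lr_range,l2_range,alpha_range log-uniform bounds.
#' @param dropout_range uniform bounds.
#' @param width_choices,latent_choices,q_frac_choices,batch_choices
#'   discrete choices.
#' @return a `search_space` list.
#' @export
search_space <- function(lr_range = c(1e-5, 1e-3),
                         l2_range = c(1e-6, 1e-2),
                         dropout_range = c(0, 0.3),
                         alpha_range = c(1e-2, 1e2),
                         width_choices = c(64L, 128L, 256L, 512L),
                         latent_choices = c(32L, 64L, 128L),
                         q_frac_choices = c(0.25, 0.5, 0.75),
                         batch_choices = c(64L, 128L, 256L)) {
  structure(list(lr_range = lr_range, l2_range = l2_range,
                 dropout_range = dropout_range, alpha_range = alpha_range,
                 width_choices = as.integer(width_choices),
                 latent_choices = as.integer(latent_choices),
                 q_frac_choices = q_frac_choices,
                 batch_choices = as.integer(batch_choices)),
            class = "search_space")
}

r_log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Draw random hyper-parameter trials
#'
#' @param space a [search_space()].
#' @param n number of draws (default 100, the reference protocol's search
#'   budget).
#' @param seed RNG seed; identical seeds give identical draws.
#' @return list of draws, each `list(trial_id, params)` with a flat,
#'   JSON-serializable parameter list.
#' @export
sample_trials <- function(space = search_space(), n = 100L, seed = 1L) {
  stopifnot(inherits(space, "search_space"))
  if (n == 0L) return(list())
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      params <- list(
        lr = r_log_uniform(1, space$lr_range),
        l2 = r_log_uniform(1, space$l2_range),
        dropout = stats::runif(1, space$dropout_range[1],
                               space$dropout_range[2]),
        alpha1 = r_log_uniform(1, space$alpha_range),
        alpha2 = r_log_uniform(1, space$alpha_range),
        alpha3 = r_log_uniform(1, space$alpha_range),
        alpha4 = r_log_uniform(1, space$alpha_range),
        width = sample(space$width_choices, 1L),
        latent_dim = sample(space$latent_choices, 1L),
        q_frac = sample(space$q_frac_choices, 1L),
        batch_size = sample(space$batch_choices, 1L))
      list(trial_id = i, params = params)
    })
  })
}

# translate a sampled draw into config/schedule/weights; epoch budgets and
# dimensional caps come from `budget`
trial_setup <- function(draw, input_dim, n_drugs, n_covariates, budget,
                        trial_seed) {
  p <- min(draw$params$latent_dim, budget$max_latent %||% Inf)
  q <- max(1L, round(draw$params$q_frac * p))
  width <- min(draw$params$width, budget$max_width %||% Inf)
  cfg <- network_config(
    input_dim = input_dim, latent_dim = p, shared_dim = q,
    n_drugs = n_drugs, n_covariates = n_covariates,
    encoder_widths = rep(width, 2L), decoder_widths = rep(width, 2L),
    critic_widths = rep(min(width, 64L), 2L),
    survival_widths = rep(min(width, 64L), 2L),
    drug_widths = rep(min(width, 64L), 2L),
    dropout = draw$params$dropout, l2 = draw$params$l2)
  sch <- training_schedule(
    pretrain_dc_epochs = budget$pretrain_dc_epochs,
    pretrain_surv_epochs = budget$pretrain_surv_epochs,
    pretrain_drug_epochs = budget$pretrain_drug_epochs,
    joint_epochs = budget$joint_epochs,
    batch_size = min(draw$params$batch_size, budget$max_batch %||% Inf),
    lr = draw$params$lr, seed = trial_seed)
  w <- loss_weights(draw$params$alpha1, draw$params$alpha2,
                    draw$params$alpha3, draw$params$alpha4)
  list(config = cfg, schedule = sch, weights = w)
}

#' Search budgets
#'
#' `"full"` reproduces the reference epoch schedule (300/100/100/300);
#' `"small"` is a desk-scale preset for continuous integration (10 trials
#' suggested, 10/5/5/10 epochs, capped widths).
#'
#' @param name `"full"` or `"small"`.
#' @return a budget list consumed by [run_search()].
#' @export
search_budget <- function(name = c("full", "small")) {
  name <- match.arg(name)
  if (name == "full") {
    list(pretrain_dc_epochs = 300L, pretrain_surv_epochs = 100L,
         pretrain_drug_epochs = 100L, joint_epochs = 300L,
         max_width = Inf, max_latent = Inf, max_batch = Inf)
  } else {
    list(pretrain_dc_epochs = 10L, pretrain_surv_epochs = 5L,
         pretrain_drug_epochs = 5L, joint_epochs = 10L,
         max_width = 32L, max_latent = 16L, max_batch = 64L)
  }
}

subset_patients <- function(data, idx) {
  surv <- data$survival
  list(x = omics_matrix(data$patient$values[idx, , drop = FALSE], 0L),
       survival = survival_records(surv$sample_id[idx], surv$time[idx],
                                   surv$event[idx],
                                   if (!is.null(surv$covariates)) {
                                     surv$covariates[idx, , drop = FALSE]
                                   }),
       covariates = if (!is.null(data$covariates)) {
         data$covariates[idx, , drop = FALSE]
       })
}

subset_celllines <- function(data, idx) {
  list(x = omics_matrix(data$cellline$values[idx, , drop = FALSE], 1L),
       drugs = tryCatch(
         drug_response_matrix(data$drugs$values[idx, , drop = FALSE],
                              data$drugs$observed_mask[idx, , drop = FALSE]),
         error = function(e) NULL))
}

train_and_score <- function(setup, data, p_train, p_test, c_train, c_test,
                            eval_seed) {
  ptr <- subset_patients(data, p_train)
  pte <- subset_patients(data, p_test)
  ctr <- subset_celllines(data, c_train)
  cte <- subset_celllines(data, c_test)
  if (is.null(ctr$drugs) || is.null(cte$drugs)) {
    stop_deconfae("fold split left a drug without observations")
  }
  dtr <- model_data(ptr$x, ctr$x, ptr$survival, ctr$drugs)
  state <- train_model(dtr, setup$schedule, setup$weights,
                       config = setup$config)
  evaluate_model(state$modules, pte$x, cte$x, pte$survival, cte$drugs,
                 covariates = pte$covariates, seed = eval_seed)
}

#' Run the random search
#'
#' In `"flat"` mode each trial is trained on every training split and
#' evaluated on the held-out fold; selection then uses the mean
#' cross-validation composite (the protocol used for external-cohort
#' transfer). In `"nested"` mode one training fold per outer fold serves
#' as a validation set for selection and the per-fold winner is evaluated
#' on the outer test fold.
#'
#' @param trials from [sample_trials()].
#' @param data a [model_data()] discovery set.
#' @param folds a [stratified_survival_folds()] assignment for the
#'   patients.
#' @param mode `"flat"` or `"nested"`.
#' @param budget a [search_budget()].
#' @param seed base seed; per-trial seeds are derived as
#'   `derive_seed(seed, trial_id)` so results are independent of execution
#'   order.
#' @return list of `search_trial` records sorted by mean composite
#'   (failed trials last); in nested mode the result additionally carries
#'   an `outer` attribute with per-fold winners and test reports.
#' @export
run_search <- function(trials, data, folds, mode = c("flat", "nested"),
                       budget = search_budget("small"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(data, "model_data"), inherits(folds, "fold_assignment"))
  if (length(trials) == 0L) stop_deconfae("no trials to run")
  k <- folds$k_folds
  nc <- nrow(data$cellline$values)
  cell_folds <- with_seed(derive_seed(seed, 0L),
                          ((sample.int(nc) - 1L) %% k) + 1L)
  n_drugs <- if (!is.null(data$drugs)) length(data$drugs$drug_ids) else 0L
  n_cov <- if (!is.null(data$covariates)) ncol(data$covariates) else 0L
  input_dim <- ncol(data$patient$values)

  eval_fold <- function(setup, test_fold, train_folds, eval_seed) {
    p_tr <- which(folds$fold_id %in% train_folds)
    p_te <- which(folds$fold_id == test_fold)
    c_tr <- which(cell_folds %in% train_folds)
    c_te <- which(cell_folds == test_fold)
    train_and_score(setup, data, p_tr, p_te, c_tr, c_te, eval_seed)
  }

  score_trial <- function(draw, fold_plan) {
    trial_seed <- derive_seed(seed, draw$trial_id)
    setup <- trial_setup(draw, input_dim, n_drugs, n_cov, budget, trial_seed)
    reports <- lapply(fold_plan, function(fp) {
      eval_fold(setup, fp$test, fp$train, derive_seed(trial_seed, fp$test))
    })
    metrics <- vapply(reports, function(r) {
      c(r$cindex, r$r2_q90, r$domain_auroc)
    }, numeric(3))
    mean_metrics <- rowMeans(metrics)
    names(mean_metrics) <- c("cindex", "r2_q90", "domain_auroc")
    list(trial_id = draw$trial_id, params = draw$params, seed = trial_seed,
         reports = reports, mean_metrics = mean_metrics,
         composite = mean_metrics[["cindex"]] + mean_metrics[["r2_q90"]] -
           mean_metrics[["domain_auroc"]],
         status = "ok")
  }

  if (mode == "flat") {
    fold_plan <- lapply(seq_len(k), function(f) {
      list(test = f, train = setdiff(seq_len(k), f))
    })
    results <- lapply(trials, function(draw) {
      tryCatch(score_trial(draw, fold_plan), error = function(e) {
        list(trial_id = draw$trial_id, params = draw$params,
             seed = derive_seed(seed, draw$trial_id), reports = NULL,
             mean_metrics = NULL, composite = NA_real_,
             status = paste("failed:", conditionMessage(e)))
      })
    })
  } else {
    # nested: per outer fold, the lowest-numbered other fold is validation
    results <- lapply(trials, function(draw) {
      tryCatch({
        fold_plan <- lapply(seq_len(k), function(f) {
          v <- setdiff(seq_len(k), f)[1L]
          list(test = v, train = setdiff(seq_len(k), c(f, v)))
        })
        score_trial(draw, fold_plan)
      }, error = function(e) {
        list(trial_id = draw$trial_id, params = draw$params,
             seed = derive_seed(seed, draw$trial_id), reports = NULL,
             mean_metrics = NULL, composite = NA_real_,
             status = paste("failed:", conditionMessage(e)))
      })
    })
  }
  ok <- vapply(results, function(r) r$status == "ok", logical(1))
  ord <- order(!ok, -vapply(results, function(r) {
    if (is.na(r$composite)) -Inf else r$composite
  }, numeric(1)))
  results <- results[ord]
  if (mode == "nested" && any(ok)) {
    outer <- lapply(seq_len(k), function(f) {
      winner <- select_best(results)
      setup <- trial_setup(list(trial_id = winner$trial_id,
                                params = winner$params),
                          input_dim, n_drugs, n_cov, budget, winner$seed)
      report <- eval_fold(setup, f, setdiff(seq_len(k), f),
                          derive_seed(winner$seed, 100L + f))
      list(fold = f, trial_id = winner$trial_id, report = report)
    })
    attr(results, "outer") <- outer
  }
  results
}

#' Select the best trial by mean composite score
#'
#' Argmax of `cindex + r2_q90 - domain_auroc` over successful trials;
#' ties break deterministically by lowest trial id. The selected trial is
#' always a member of the mean-metric Pareto front (the composite is a
#' monotone aggregation of the three metrics).
#'
#' @param trials a [run_search()] result.
#' @return the winning `search_trial` record.
#' @export
select_best <- function(trials) {
  ok <- Filter(function(r) identical(r$status, "ok"), trials)
  if (length(ok) == 0L) stop_deconfae("all trials failed")
  comps <- vapply(ok, function(r) r$composite, numeric(1))
  ids <- vapply(ok, function(r) r$trial_id, numeric(1))
  best <- which(comps == max(comps))
  ok[[best[which.min(ids[best])]]]
}

#' Write search trials as JSON lines
#'
#' One serialized trial per line: id, parameters, per-fold metrics, mean
#' metrics, composite and status.
#'
#' @param trials a [run_search()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in trials) {
    rec <- list(trial_id = r$trial_id, params = r$params,
                mean_metrics = as.list(r$mean_metrics),
                composite = r$composite, status = r$status,
                fold_metrics = if (!is.null(r$reports)) {
                  lapply(r$reports, function(rep) {
                    list(cindex = rep$cindex, r2_q90 = rep$r2_q90,
                         domain_auroc = rep$domain_auroc,
                         composite = rep$composite)
                  })
                })
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}
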