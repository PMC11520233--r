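# End-to-end pipeline: simulate -> preprocess -> train -> evaluate ->
# search -> stratify -> dysregulation, driven by a single JSON config and
# writing every output into one run directory with a manifest.

default_pipeline_config <- function() {
  list(stages = c("simulate", "preprocess", "train", "evaluate"),
       seed = 1L,
       out_dir = NULL,
       synthetic = list(),
       network = list(latent_dim = 16L),
       schedule = list(),
       weights = list(alpha1 = 1, alpha2 = 1, alpha3 = 1, alpha4 = 1),
       preprocess = list(min_mean = 1.0, max_followup = 3000,
                         k_folds = 5L, n_quantiles = 10L),
       inputs = list(),
       evaluate = list(test_fold = 1L),
       search = list(n_trials = 10L, budget = "small", mode = "flat"),
       dysregulation = list(targets_file = NULL))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_pipeline_config <- function(config) {
  known <- c("simulate", "preprocess", "train", "evaluate", "search",
             "stratify", "dysregulation")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0) {
    stop_deconfae("unknown stage(s): %s", paste(bad, collapse = ", "))
  }
  needs_data <- setdiff(config$stages, "simulate")
  if (length(needs_data) > 0 && !"simulate" %in% config$stages &&
      length(config$inputs) == 0L) {
    stop_deconfae("stages %s need input files or a simulate stage",
                  paste(needs_data, collapse = ", "))
  }
  w <- config$weights
  if (any(c("train", "search") %in% config$stages)) {
    if ((w$alpha3 %||% 0) > 0 && !"simulate" %in% config$stages &&
        is.null(config$inputs$survival)) {
      stop_deconfae("survival weight alpha3 > 0 but no survival file given")
    }
    if ((w$alpha4 %||% 0) > 0 && !"simulate" %in% config$stages &&
        is.null(config$inputs$drugs)) {
      stop_deconfae("drug weight alpha4 > 0 but no drug file given")
    }
  }
  if ("dysregulation" %in% config$stages &&
      is.null(config$dysregulation$targets_file)) {
    stop_deconfae("dysregulation stage needs dysregulation$targets_file")
  }
  invisible(config)
}

file_digests <- function(paths) {
  paths <- as.character(paths)
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order inside a single run directory,
#' writing checkpoints, the evaluation report, the training-log CSV and a
#' manifest (config snapshot, input digests, seeds, package version,
#' per-stage timestamps) sufficient to re-run each stage. The config is a
#' JSON file or an R list; unspecified fields take protocol defaults.
#' Fails before any computation if the config is invalid; on a stage
#' failure, partial outputs are retained and the failure is recorded in
#' the manifest before the error propagates.
#'
#' @param config path to a JSON config file, or a named list.
#' @param out_dir run directory (overrides `config$out_dir`; defaults to a
#'   content-addressed directory under `tempdir()`).
#' @return the run directory path, invisibly; the evaluation report (when
#'   computed) is at `<out_dir>/evaluation_report.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  config <- merge_config(default_pipeline_config(), config)
  config$stages <- as.character(config$stages)
  validate_pipeline_config(config)
  digest <- substr(tools::md5sum(
    files <- {
      tf <- tempfile()
      writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                  null = "null"), tf)
      tf
    }), 1L, 12L)
  unlink(files)
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), paste0("run_", digest))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config, config_digest = unname(digest),
                   package_version = as.character(utils::packageVersion("deconfae")),
                   seed = config$seed, stages = list(),
                   input_digests = file_digests(unlist(config$inputs)))
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  env <- new.env()

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible())
    res <- tryCatch({
      fun()
      manifest$stages[[name]] <<- list(status = "ok",
                                       completed = format(Sys.time()))
      write_manifest()
    }, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e),
                                       completed = format(Sys.time()))
      write_manifest()
      stop(e)
    })
  }

  load_inputs <- function() {
    data_dir <- file.path(out_dir, "data")
    paths <- list(
      patient = config$inputs$patient %||%
        file.path(data_dir, "expression_patient.tsv"),
      cellline = config$inputs$cellline %||%
        file.path(data_dir, "expression_cellline.tsv"),
      survival = config$inputs$survival %||%
        file.path(data_dir, "survival.tsv"),
      drugs = config$inputs$drugs %||%
        file.path(data_dir, "drug_response.tsv"))
    env$patient_raw <- load_expression(paths$patient, domain = 0L)
    env$cellline_raw <- load_expression(paths$cellline, domain = 1L)
    env$survival_raw <- if (file.exists(paths$survival)) {
      load_survival(paths$survival)
    }
    env$drugs_raw <- if (file.exists(paths$drugs)) {
      load_drug_response(paths$drugs)
    }
  }

  run_stage("simulate", function() {
    sc <- do.call(synthetic_config,
                  merge_config(list(seed = config$seed), config$synthetic))
    cohorts <- generate_cohorts(sc)
    write_cohorts(cohorts, file.path(out_dir, "data"))
    env$cohorts <- cohorts
  })

  run_stage("preprocess", function() {
    load_inputs()
    pp <- config$preprocess
    filt <- filter_genes(env$patient_raw, env$cellline_raw,
                         min_mean = pp$min_mean)
    sp <- standardize(filt$patient)
    sc_ <- standardize(filt$cellline)
    env$patient <- sp$matrix
    env$cellline <- sc_$matrix
    env$scaling <- list(patient = list(center = sp$center, scale = sp$scale),
                        cellline = list(center = sc_$center,
                                        scale = sc_$scale))
    if (!is.null(env$survival_raw)) {
      env$survival <- cap_followup(env$survival_raw,
                                   max_days = pp$max_followup)
      env$folds <- stratified_survival_folds(env$survival,
                                             k_folds = pp$k_folds,
                                             n_quantiles = pp$n_quantiles,
                                             seed = config$seed)
      write_folds(env$folds, file.path(out_dir, "folds.tsv"))
    }
    pdir <- file.path(out_dir, "processed")
    dir.create(pdir, showWarnings = FALSE)
    write_expression(env$patient, file.path(pdir, "expression_patient.tsv"))
    write_expression(env$cellline, file.path(pdir, "expression_cellline.tsv"))
    if (!is.null(env$survival)) {
      write_survival(env$survival, file.path(pdir, "survival.tsv"))
    }
  })

  assemble_data <- function(p_idx = NULL, c_idx = NULL) {
    pat <- env$patient; cl <- env$cellline
    surv <- env$survival; drugs <- env$drugs_raw
    if (!is.null(p_idx)) {
      pat <- omics_matrix(pat$values[p_idx, , drop = FALSE], 0L)
      surv <- survival_records(surv$sample_id[p_idx], surv$time[p_idx],
                               surv$event[p_idx],
                               if (!is.null(surv$covariates)) {
                                 surv$covariates[p_idx, , drop = FALSE]
                               })
    }
    if (!is.null(c_idx)) {
      cl <- omics_matrix(cl$values[c_idx, , drop = FALSE], 1L)
      if (!is.null(drugs)) {
        drugs <- drug_response_matrix(
          drugs$values[c_idx, , drop = FALSE],
          drugs$observed_mask[c_idx, , drop = FALSE])
      }
    }
    model_data(pat, cl, surv, drugs)
  }

  run_stage("train", function() {
    test_fold <- config$evaluate$test_fold
    p_train <- which(env$folds$fold_id != test_fold)
    nc <- nrow(env$cellline$values)
    cell_folds <- with_seed(derive_seed(config$seed, 0L),
                            ((sample.int(nc) - 1L) %% env$folds$k_folds) + 1L)
    env$cell_folds <- cell_folds
    c_train <- which(cell_folds != test_fold)
    dtr <- assemble_data(p_train, c_train)
    cfg <- do.call(network_config,
                   merge_config(list(input_dim = ncol(dtr$patient$values),
                                     n_drugs = length(dtr$drugs$drug_ids)),
                                config$network))
    sch <- do.call(training_schedule,
                   merge_config(list(seed = config$seed), config$schedule))
    w <- do.call(loss_weights, config$weights)
    state <- train_model(dtr, sch, w, config = cfg)
    env$state <- state
    save_checkpoint(state$modules, file.path(out_dir, "checkpoint"),
                    extra = list(epoch = state$epoch))
    write_training_log(state, file.path(out_dir, "training_log.csv"))
  })

  run_stage("evaluate", function() {
    test_fold <- config$evaluate$test_fold
    p_test <- which(env$folds$fold_id == test_fold)
    c_test <- which(env$cell_folds == test_fold)
    dte <- assemble_data(p_test, c_test)
    report <- evaluate_model(env$state$modules, dte$patient, dte$cellline,
                             dte$survival, dte$drugs,
                             covariates = dte$covariates,
                             seed = config$seed)
    env$report <- report
    jsonlite::write_json(
      list(cindex = report$cindex, r2_q90 = report$r2_q90,
           domain_auroc = report$domain_auroc,
           composite = report$composite,
           per_drug_r2 = as.list(report$per_drug_r2)),
      file.path(out_dir, "evaluation_report.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  })

  run_stage("search", function() {
    trials <- sample_trials(search_space(), n = config$search$n_trials,
                            seed = config$seed)
    dall <- assemble_data()
    results <- run_search(trials, dall, env$folds,
                          mode = config$search$mode,
                          budget = search_budget(config$search$budget),
                          seed = config$seed)
    write_trials(results, file.path(out_dir, "search_trials.jsonl"))
    best <- select_best(results)
    jsonlite::write_json(list(trial_id = best$trial_id,
                              composite = best$composite,
                              mean_metrics = as.list(best$mean_metrics)),
                         file.path(out_dir, "search_best.json"),
                         auto_unbox = TRUE, digits = NA)
    ok <- Filter(function(r) r$status == "ok", results)
    mm <- t(vapply(ok, function(r) r$mean_metrics, numeric(3)))
    front <- pareto_front(mm, directions = c("max", "max", "min"))
    front_dt <- data.table::data.table(
      trial_id = vapply(ok[front], function(r) r$trial_id, numeric(1)),
      cindex = mm[front, 1], r2_q90 = mm[front, 2],
      domain_auroc = mm[front, 3])
    data.table::fwrite(front_dt, file.path(out_dir, "pareto_front.tsv"),
                       sep = "\t")
  })

  run_stage("stratify", function() {
    risk <- predict_risk(env$patient$values, env$state$modules)
    strat <- stratify_risk(risk)
    data.table::fwrite(
      data.table::data.table(id = env$patient$sample_ids, risk = risk,
                             group = as.character(strat$labels)),
      file.path(out_dir, "risk_groups.tsv"), sep = "\t")
  })

  run_stage("dysregulation", function() {
    targets <- data.table::fread(config$dysregulation$targets_file,
                                 header = TRUE, data.table = FALSE)
    target_map <- split(targets[[2L]], targets[[1L]])
    pred <- predict_drugs(env$patient$values, env$state$modules)
    colnames(pred) <- env$drugs_raw$drug_ids
    tab <- dysregulation_test(env$patient, pred, target_map)
    data.table::fwrite(tab, file.path(out_dir, "dysregulation.tsv"),
                       sep = "\t")
  })

  write_manifest()
  invisible(out_dir)
}
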