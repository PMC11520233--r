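# Training: staged pre-training (deconfounding autoencoder, survival head,
# drug head) followed by joint multi-task epochs, with the Wasserstein
# critic trained in alternating epochs throughout.

#' Training schedule
#'
#' Defaults reproduce the reference protocol: 300 deconfounding
#' pre-training epochs, 100 survival and 100 drug pre-training epochs,
#' 300 joint epochs, 5 critic epochs per autoencoder/joint epoch, critic
#' Adam momenta (0, 0.9) and standard momenta (0.9, 0.999) for all other
#' modules.
#'
#' @param pretrain_dc_epochs,pretrain_surv_epochs,pretrain_drug_epochs,joint_epochs
#'   epoch budgets per phase.
#' @param n_adv_per_ae critic epochs run after every autoencoder/joint
#'   epoch.
#' @param batch_size mini-batch size per domain.
#' @param lr learning rate, either a scalar or a named list with entries
#'   `encoder`, `decoder`, `critic`, `survival`, `drug`.
#' @param critic_betas,other_betas Adam momentum pairs.
#' @param lambda_gp gradient-penalty coefficient.
#' @param seed seed initializing the training RNG stream.
#' @return a `training_schedule` list.
#' @export
training_schedule <- function(pretrain_dc_epochs = 300L,
                              pretrain_surv_epochs = 100L,
                              pretrain_drug_epochs = 100L,
                              joint_epochs = 300L,
                              n_adv_per_ae = 5L,
                              batch_size = 128L,
                              lr = 1e-4,
                              critic_betas = c(0, 0.9),
                              other_betas = c(0.9, 0.999),
                              lambda_gp = 10,
                              seed = 1L) {
  for (nm in c("pretrain_dc_epochs", "pretrain_surv_epochs",
               "pretrain_drug_epochs", "joint_epochs")) {
    v <- get(nm)
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v)) {
      stop_deconfae("%s must be a single integer >= 0", nm)
    }
  }
  n_adv_per_ae <- assert_count(n_adv_per_ae, "n_adv_per_ae")
  batch_size <- assert_count(batch_size, "batch_size", min = 2L)
  modules <- c("encoder", "decoder", "critic", "survival", "drug")
  if (!is.list(lr)) lr <- stats::setNames(as.list(rep(lr, 5L)), modules)
  if (!all(modules %in% names(lr))) {
    stop_deconfae("lr list must name all of: %s", paste(modules, collapse = ", "))
  }
  structure(list(pretrain_dc_epochs = as.integer(pretrain_dc_epochs),
                 pretrain_surv_epochs = as.integer(pretrain_surv_epochs),
                 pretrain_drug_epochs = as.integer(pretrain_drug_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 n_adv_per_ae = n_adv_per_ae,
                 batch_size = batch_size, lr = lr,
                 critic_betas = as.numeric(critic_betas),
                 other_betas = as.numeric(other_betas),
                 lambda_gp = as.numeric(lambda_gp),
                 seed = as.integer(seed)),
            class = "training_schedule")
}

#' Bundle aligned training data
#'
#' Validates that survival records align with patient samples and the drug
#' matrix aligns with cell-line samples. Covariates, when present, are
#' standardized here with patient-training statistics (stored for reuse on
#' validation data).
#'
#' @param patient,cellline standardized [omics_matrix()] objects sharing a
#'   gene set.
#' @param survival a [survival_records()] aligned with `patient`
#'   (optional if no survival task is trained).
#' @param drugs a [drug_response_matrix()] aligned with `cellline`
#'   (optional if no drug task is trained).
#' @return a `model_data` list.
#' @export
model_data <- function(patient, cellline, survival = NULL, drugs = NULL) {
  stopifnot(inherits(patient, "omics_matrix"),
            inherits(cellline, "omics_matrix"))
  if (!identical(patient$gene_ids, cellline$gene_ids)) {
    stop_deconfae("patient and cell-line matrices must share the gene set")
  }
  cov <- NULL; cov_center <- NULL; cov_scale <- NULL
  if (!is.null(survival)) {
    stopifnot(inherits(survival, "survival_records"))
    if (!identical(survival$sample_id, patient$sample_ids)) {
      stop_deconfae("survival records must align 1:1 with patient samples")
    }
    if (!is.null(survival$covariates)) {
      cov_center <- colMeans(survival$covariates)
      cov_scale <- apply(survival$covariates, 2L, stats::sd)
      cov_scale[cov_scale <= 0] <- 1
      cov <- sweep(sweep(survival$covariates, 2L, cov_center), 2L,
                   cov_scale, `/`)
    }
  }
  if (!is.null(drugs)) {
    stopifnot(inherits(drugs, "drug_response_matrix"))
    if (!identical(drugs$sample_ids, cellline$sample_ids)) {
      stop_deconfae("drug matrix must align 1:1 with cell-line samples")
    }
  }
  structure(list(patient = patient, cellline = cellline,
                 survival = survival, drugs = drugs,
                 covariates = cov, cov_center = cov_center,
                 cov_scale = cov_scale),
            class = "model_data")
}

#' Initialize a training state
#'
#' @param modules a [build_modules()] result.
#' @param schedule a [training_schedule()].
#' @return a `training_state` holding modules, per-module Adam states, the
#'   epoch counter, loss history and the RNG state.
#' @export
init_training_state <- function(modules, schedule) {
  stopifnot(inherits(modules, "module_set"),
            inherits(schedule, "training_schedule"))
  opt <- list()
  for (nm in c("encoder", "decoder", "survival", "drug")) {
    opt[[nm]] <- adam_new(modules[[nm]], lr = schedule$lr[[nm]],
                          beta1 = schedule$other_betas[1],
                          beta2 = schedule$other_betas[2])
  }
  opt$critic <- adam_new(modules$critic, lr = schedule$lr$critic,
                         beta1 = schedule$critic_betas[1],
                         beta2 = schedule$critic_betas[2])
  rng <- with_seed(schedule$seed, get(".Random.seed", envir = globalenv()))
  structure(list(modules = modules, opt = opt, epoch = 0L,
                 history = NULL, rng = rng),
            class = "training_state")
}

restore_rng <- function(state) {
  assign(".Random.seed", state$rng, envir = globalenv())
}

capture_rng <- function(state) {
  state$rng <- get(".Random.seed", envir = globalenv())
  state
}

log_epoch <- function(state, phase, comps) {
  row <- data.frame(epoch = state$epoch, phase = phase,
                    l_rec = comps[["l_rec"]], l_adv = comps[["l_adv"]],
                    l_dc = comps[["l_dc"]], l_surv = comps[["l_surv"]],
                    l_drug = comps[["l_drug"]], l_mtl = comps[["l_mtl"]])
  state$history <- rbind(state$history, row)
  state
}

#' Write the training log as CSV
#' @param state a `training_state`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(state, path) {
  stopifnot(inherits(state, "training_state"))
  utils::write.csv(state$history %||%
                     data.frame(epoch = integer(), phase = character()),
                   path, row.names = FALSE)
  invisible(path)
}

#' Domain-balanced oversampled mini-batches
#'
#' The larger domain is shuffled and partitioned once (every index appears
#' exactly once per epoch); the smaller domain is resampled with
#' replacement to supply the same number of indices per batch, so every
#' batch carries equal counts from both domains. When the two domains have
#' equal size, both are partitioned without replacement.
#'
#' @param n_patients,n_celllines domain sizes.
#' @param batch_size indices per domain per batch.
#' @param seed optional seed; when `NULL` the ambient RNG stream is used.
#' @return list of batches, each `list(patients = idx, celllines = idx)`.
#' @export
make_balanced_minibatches <- function(n_patients, n_celllines, batch_size,
                                      seed = NULL) {
  n_patients <- assert_count(n_patients, "n_patients")
  n_celllines <- assert_count(n_celllines, "n_celllines")
  batch_size <- assert_count(batch_size, "batch_size")
  draw <- function() {
    n_max <- max(n_patients, n_celllines)
    n_batches <- ceiling(n_max / batch_size)
    chunk <- function(idx) {
      split(idx, ceiling(seq_along(idx) / batch_size))
    }
    if (n_patients >= n_celllines) {
      p_chunks <- chunk(sample.int(n_patients))
      c_chunks <- if (n_celllines == n_patients) {
        chunk(sample.int(n_celllines))
      } else {
        lapply(p_chunks, function(ch) {
          sample.int(n_celllines, length(ch), replace = TRUE)
        })
      }
    } else {
      c_chunks <- chunk(sample.int(n_celllines))
      p_chunks <- lapply(c_chunks, function(ch) {
        sample.int(n_patients, length(ch), replace = TRUE)
      })
    }
    lapply(seq_len(n_batches), function(i) {
      list(patients = unname(p_chunks[[i]]), celllines = unname(c_chunks[[i]]))
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# ---- batch updates --------------------------------------------------------

# One gradient step of the non-critic modules on a mini-batch.
# `update` selects which of E, D, A, B receive gradients; weights are the
# multi-task alphas. Returns state plus the batch loss components.
multitask_batch_update <- function(state, data, idx_p, idx_c, weights,
                                   update = c("E", "D", "A", "B")) {
  modules <- state$modules
  part <- modules$partition
  cfg <- modules$config
  n_p <- length(idx_p); n_c <- length(idx_c)
  x <- rbind(if (n_p > 0) data$patient$values[idx_p, , drop = FALSE],
             if (n_c > 0) data$cellline$values[idx_c, , drop = FALSE])
  s <- c(rep(0L, n_p), rep(1L, n_c))
  n <- n_p + n_c
  train_E <- "E" %in% update
  enc <- mlp_forward(modules$encoder, x, training = train_E)
  z <- enc$out
  dz <- matrix(0, n, part$p)
  comps <- c(l_rec = NA_real_, l_adv = NA_real_, l_dc = NA_real_,
             l_surv = NA_real_, l_drug = NA_real_, l_mtl = NA_real_)
  grads <- list()

  # reconstruction over both domains
  if (weights$alpha1 > 0) {
    zm <- latent_mask(z, s, part)
    dec <- mlp_forward(modules$decoder, zm, training = "D" %in% update)
    l_rec <- reconstruction_loss(x, dec$out)
    comps["l_rec"] <- l_rec
    dxhat <- weights$alpha1 * 2 * (dec$out - x) / (n * cfg$input_dim)
    bd <- mlp_backward(modules$decoder, dec$cache, dxhat)
    if ("D" %in% update) grads$decoder <- bd
    dz <- dz + latent_mask(bd$dX, s, part)
  }

  # deconfounding: mean critic value over cell-lines (critic frozen)
  if (weights$alpha2 > 0 && n_c > 0) {
    z_s_c <- z[s == 1L, part$U, drop = FALSE]
    cvals <- drop(mlp_forward(modules$critic, z_s_c)$out)
    comps["l_dc"] <- mean(cvals)
    gin <- mlp_input_grad(modules$critic, z_s_c)
    dz[s == 1L, part$U] <- dz[s == 1L, part$U] + weights$alpha2 * gin / n_c
  }

  # survival: negative Efron partial log-likelihood on the patient rows
  if (weights$alpha3 > 0 && n_p > 0 && !is.null(data$survival)) {
    tb <- data$survival$time[idx_p]
    eb <- data$survival$event[idx_p]
    if (sum(eb) > 0) {
      z_s_p <- z[s == 0L, part$U, drop = FALSE]
      inp <- if (!is.null(data$covariates)) {
        cbind(z_s_p, data$covariates[idx_p, , drop = FALSE])
      } else z_s_p
      sv <- mlp_forward(modules$survival, inp, training = "A" %in% update)
      grouping <- build_efron_grouping(tb, eb)
      eg <- efron_loglik_grad(drop(sv$out), grouping)
      comps["l_surv"] <- -eg$value
      ba <- mlp_backward(modules$survival, sv$cache,
                         matrix(-weights$alpha3 * eg$grad, ncol = 1L))
      if ("A" %in% update) grads$survival <- ba
      dz[s == 0L, part$U] <- dz[s == 0L, part$U] +
        ba$dX[, seq_len(part$q), drop = FALSE]
    }
  }

  # drugs: masked MSE on the cell-line rows
  if (weights$alpha4 > 0 && n_c > 0 && !is.null(data$drugs)) {
    maskb <- data$drugs$observed_mask[idx_c, , drop = FALSE]
    if (sum(maskb) > 0) {
      Rb <- data$drugs$values[idx_c, , drop = FALSE]
      Rb[!maskb] <- 0
      z_s_c <- z[s == 1L, part$U, drop = FALSE]
      dr <- mlp_forward(modules$drug, z_s_c, training = "B" %in% update)
      comps["l_drug"] <- masked_drug_loss(dr$out, Rb, maskb)
      dRhat <- weights$alpha4 * 2 * (dr$out - Rb) * maskb / sum(maskb)
      bb <- mlp_backward(modules$drug, dr$cache, dRhat)
      if ("B" %in% update) grads$drug <- bb
      dz[s == 1L, part$U] <- dz[s == 1L, part$U] + bb$dX
    }
  }

  known <- comps[c("l_rec", "l_dc", "l_surv", "l_drug")]
  contrib <- c(weights$alpha1, weights$alpha2, weights$alpha3,
               weights$alpha4) * ifelse(is.na(known), 0, known)
  comps["l_mtl"] <- sum(contrib)
  if (!is.finite(comps[["l_mtl"]])) {
    stop_deconfae("non-finite multi-task loss at epoch %d", state$epoch + 1L)
  }

  if (train_E) grads$encoder <- mlp_backward(modules$encoder, enc$cache, dz)
  for (nm in names(grads)) {
    gW <- add_l2_grads(modules[[nm]], grads[[nm]]$gW, cfg$l2)
    step <- adam_step(modules[[nm]], state$opt[[nm]], gW, grads[[nm]]$gb)
    modules[[nm]] <- step$net
    state$opt[[nm]] <- step$opt
  }
  state$modules <- modules
  list(state = state, comps = comps)
}

# one critic gradient step: adversarial loss + gradient penalty, L2 decay;
# encoder and all other modules untouched
critic_batch_update <- function(state, data, idx_p, idx_c, lambda_gp) {
  modules <- state$modules
  part <- modules$partition
  x <- rbind(data$patient$values[idx_p, , drop = FALSE],
             data$cellline$values[idx_c, , drop = FALSE])
  s <- c(rep(0L, length(idx_p)), rep(1L, length(idx_c)))
  z_s <- extract_shared(mlp_forward(modules$encoder, x)$out, part)
  cr <- mlp_forward(modules$critic, z_s,
                    training = modules$config$critic_dropout > 0)
  l_adv <- adversarial_loss(drop(cr$out), s)
  if (!is.finite(l_adv)) stop_deconfae("non-finite critic loss")
  dC <- matrix((1 - 2 * s) / length(s), ncol = 1L)
  g_adv <- mlp_backward(modules$critic, cr$cache, dC)
  acc <- list(gW = g_adv$gW, gb = g_adv$gb)
  z_p <- z_s[s == 0L, , drop = FALSE]
  z_c <- z_s[s == 1L, , drop = FALSE]
  gp_val <- 0
  if (nrow(z_p) > 0 && nrow(z_c) > 0 && lambda_gp > 0) {
    m <- min(nrow(z_p), nrow(z_c))
    u <- stats::runif(m)
    z_hat <- u * z_p[seq_len(m), , drop = FALSE] +
      (1 - u) * z_c[seq_len(m), , drop = FALSE]
    gp <- critic_penalty_grads(modules$critic, z_hat, lambda_gp)
    gp_val <- gp$value
    acc <- accumulate_grads(acc, list(gW = gp$gW, gb = gp$gb))
  }
  gW <- add_l2_grads(modules$critic, acc$gW, modules$config$l2)
  step <- adam_step(modules$critic, state$opt$critic, gW, acc$gb)
  state$modules$critic <- step$net
  state$opt$critic <- step$opt
  list(state = state, l_adv = l_adv, gp = gp_val)
}

#' One critic training epoch
#'
#' Updates only the critic (Adam with the critic momenta) on the
#' adversarial loss plus gradient penalty over the given balanced batches;
#' the encoder is frozen.
#'
#' @param state a `training_state`.
#' @param data a [model_data()].
#' @param batches from [make_balanced_minibatches()].
#' @param lambda_gp gradient-penalty coefficient.
#' @return the updated `training_state` (with `last_adv_loss` attribute in
#'   `$last_critic`).
#' @export
critic_epoch <- function(state, data, batches, lambda_gp = 10) {
  advs <- numeric(length(batches))
  for (i in seq_along(batches)) {
    res <- critic_batch_update(state, data, batches[[i]]$patients,
                               batches[[i]]$celllines, lambda_gp)
    state <- res$state
    advs[i] <- res$l_adv
  }
  state$last_critic <- mean(advs)
  state
}

run_phase_epoch <- function(state, data, schedule, weights, update,
                            phase, with_critic) {
  np <- nrow(data$patient$values)
  nc <- nrow(data$cellline$values)
  batches <- make_balanced_minibatches(np, nc, schedule$batch_size)
  comp_sum <- NULL
  for (b in batches) {
    res <- multitask_batch_update(state, data, b$patients, b$celllines,
                                  weights, update)
    state <- res$state
    comp_sum <- if (is.null(comp_sum)) rbind(res$comps) else
      rbind(comp_sum, res$comps)
  }
  comps <- colMeans(comp_sum, na.rm = TRUE)
  comps[is.nan(comps)] <- NA_real_
  if (with_critic) {
    for (k in seq_len(schedule$n_adv_per_ae)) {
      cb <- make_balanced_minibatches(np, nc, schedule$batch_size)
      state <- critic_epoch(state, data, cb, schedule$lambda_gp)
    }
    comps["l_adv"] <- state$last_critic
  }
  state$epoch <- state$epoch + 1L
  log_epoch(state, phase, comps)
}

#' Deconfounding autoencoder pre-training
#'
#' Alternates one autoencoder epoch minimizing
#' `alpha1 * L_rec + alpha2 * L_dc` (updating encoder and decoder) with
#' `n_adv_per_ae` critic epochs, for `pretrain_dc_epochs` rounds.
#'
#' @param state a [init_training_state()] result.
#' @param data a [model_data()].
#' @param schedule a [training_schedule()].
#' @param weights a [loss_weights()]; only `alpha1` and `alpha2` are used
#'   in this phase.
#' @return the updated `training_state`.
#' @export
pretrain_deconfounding <- function(state, data, schedule,
                                   weights = loss_weights()) {
  stopifnot(inherits(state, "training_state"), inherits(data, "model_data"))
  if (schedule$pretrain_dc_epochs == 0L) return(state)
  restore_rng(state)
  w <- loss_weights(weights$alpha1, weights$alpha2, 0, 0)
  for (e in seq_len(schedule$pretrain_dc_epochs)) {
    state <- run_phase_epoch(state, data, schedule, w, c("E", "D"),
                             "pretrain_dc", with_critic = w$alpha2 > 0)
  }
  capture_rng(state)
}

#' Survival-head pre-training
#'
#' Minimizes the negative Efron partial log-likelihood on patient
#' mini-batches for `pretrain_surv_epochs` epochs, updating the survival
#' head and (by default) the encoder end-to-end.
#'
#' @inheritParams pretrain_deconfounding
#' @param update_encoder if FALSE the encoder is frozen and only the head
#'   trains.
#' @return the updated `training_state`.
#' @export
pretrain_survival <- function(state, data, schedule,
                              weights = loss_weights(),
                              update_encoder = TRUE) {
  stopifnot(inherits(state, "training_state"), inherits(data, "model_data"))
  if (is.null(data$survival) || sum(data$survival$event) == 0L) {
    stop_deconfae("survival pre-training needs at least one event")
  }
  if (schedule$pretrain_surv_epochs == 0L) return(state)
  restore_rng(state)
  w <- loss_weights(0, 0, weights$alpha3, 0)
  update <- if (update_encoder) c("E", "A") else "A"
  np <- nrow(data$patient$values)
  for (e in seq_len(schedule$pretrain_surv_epochs)) {
    idx <- sample.int(np)
    chunks <- split(idx, ceiling(seq_along(idx) / schedule$batch_size))
    comp_sum <- NULL
    for (ch in chunks) {
      res <- multitask_batch_update(state, data, ch, integer(0), w, update)
      state <- res$state
      comp_sum <- rbind(comp_sum, res$comps)
    }
    comps <- colMeans(comp_sum, na.rm = TRUE)
    comps[is.nan(comps)] <- NA_real_
    state$epoch <- state$epoch + 1L
    state <- log_epoch(state, "pretrain_surv", comps)
  }
  capture_rng(state)
}

#' Drug-head pre-training
#'
#' Minimizes the masked drug loss on cell-line mini-batches for
#' `pretrain_drug_epochs` epochs, updating the drug head and (by default)
#' the encoder.
#'
#' @inheritParams pretrain_survival
#' @return the updated `training_state`.
#' @export
pretrain_drugs <- function(state, data, schedule, weights = loss_weights(),
                           update_encoder = TRUE) {
  stopifnot(inherits(state, "training_state"), inherits(data, "model_data"))
  if (is.null(data$drugs) || sum(data$drugs$observed_mask) == 0L) {
    stop_deconfae("drug pre-training needs observed drug responses")
  }
  if (schedule$pretrain_drug_epochs == 0L) return(state)
  restore_rng(state)
  w <- loss_weights(0, 0, 0, weights$alpha4)
  update <- if (update_encoder) c("E", "B") else "B"
  nc <- nrow(data$cellline$values)
  for (e in seq_len(schedule$pretrain_drug_epochs)) {
    idx <- sample.int(nc)
    chunks <- split(idx, ceiling(seq_along(idx) / schedule$batch_size))
    comp_sum <- NULL
    for (ch in chunks) {
      res <- multitask_batch_update(state, data, integer(0), ch, w, update)
      state <- res$state
      comp_sum <- rbind(comp_sum, res$comps)
    }
    comps <- colMeans(comp_sum, na.rm = TRUE)
    comps[is.nan(comps)] <- NA_real_
    state$epoch <- state$epoch + 1L
    state <- log_epoch(state, "pretrain_drug", comps)
  }
  capture_rng(state)
}

#' Joint multi-task training
#'
#' For each epoch: over domain-balanced mini-batches, encode both domains,
#' mask private coordinates, and update the survival head, drug head,
#' decoder and encoder on the weighted multi-task loss; then run
#' `n_adv_per_ae` critic epochs. Repeats `joint_epochs` times.
#'
#' @inheritParams pretrain_deconfounding
#' @param weights a [loss_weights()] with all four task weights.
#' @return the updated `training_state`.
#' @export
train_joint <- function(state, data, schedule, weights = loss_weights()) {
  stopifnot(inherits(state, "training_state"), inherits(data, "model_data"))
  if (schedule$joint_epochs == 0L) return(state)
  restore_rng(state)
  any_update <- sum(c(weights$alpha1, weights$alpha2, weights$alpha3,
                      weights$alpha4)) > 0
  update <- if (any_update) c("E", "D", "A", "B") else character(0)
  for (e in seq_len(schedule$joint_epochs)) {
    state <- run_phase_epoch(state, data, schedule, weights, update,
                             "joint", with_critic = TRUE)
  }
  capture_rng(state)
}

#' Run the full staged training protocol
#'
#' Deconfounding pre-training, survival pre-training, drug pre-training,
#' then joint multi-task training, per the schedule's epoch budgets.
#' Phases with a zero budget (or missing data for the task) are skipped.
#'
#' @inheritParams train_joint
#' @param modules optional pre-built [build_modules()]; built from
#'   `network_config` defaults when omitted.
#' @param config a [network_config()] used when `modules` is `NULL`.
#' @return the final `training_state`.
#' @export
train_model <- function(data, schedule = training_schedule(),
                        weights = loss_weights(), config = NULL,
                        modules = NULL) {
  stopifnot(inherits(data, "model_data"))
  if (is.null(modules)) {
    if (is.null(config)) stop_deconfae("provide either modules or config")
    modules <- build_modules(config, seed = schedule$seed)
  }
  state <- init_training_state(modules, schedule)
  state <- pretrain_deconfounding(state, data, schedule, weights)
  if (!is.null(data$survival) && schedule$pretrain_surv_epochs > 0L) {
    state <- pretrain_survival(state, data, schedule, weights)
  }
  if (!is.null(data$drugs) && schedule$pretrain_drug_epochs > 0L) {
    state <- pretrain_drugs(state, data, schedule, weights)
  }
  train_joint(state, data, schedule, weights)
}

#' Evaluate a trained model
#'
#' Computes Harrell's C-index on held-out patients, per-drug R-squared on
#' held-out cell-lines, the residual domain AUROC on shared embeddings of
#' both held-out sets, and the composite selection score.
#'
#' @param modules a trained `module_set`.
#' @param patient,cellline held-out [omics_matrix()] objects.
#' @param survival held-out [survival_records()] aligned with `patient`.
#' @param drugs held-out [drug_response_matrix()] aligned with `cellline`.
#' @param covariates optional standardized covariate matrix for the
#'   survival head.
#' @param seed seed for the domain-AUROC fold split.
#' @return an [evaluation_report()].
#' @export
evaluate_model <- function(modules, patient, cellline, survival, drugs,
                           covariates = NULL, seed = 1L) {
  stopifnot(inherits(modules, "module_set"))
  risk <- predict_risk(patient$values, modules, k = covariates)
  ci <- harrell_cindex(risk, survival$time, survival$event)
  R_hat <- predict_drugs(cellline$values, modules)
  r2 <- per_drug_r2(R_hat, drugs$values, drugs$observed_mask)
  z_p <- forward_autoencode(patient$values, 0L, modules)$z_shared
  z_c <- forward_autoencode(cellline$values, 1L, modules)$z_shared
  auc <- domain_auroc(z_p, z_c, seed = seed)
  evaluation_report(ci, r2, auc)
}
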