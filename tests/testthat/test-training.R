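# Training mechanics: batching, module isolation during critic updates,
# determinism, regularization, and small optimization smoke tests.
# End-to-end recovery properties at protocol scale live in
# test-acceptance.R.

test_that("balanced minibatches partition the larger domain and oversample the smaller", {
  b <- make_balanced_minibatches(100, 100, 20, seed = 1)
  expect_length(b, 5L)
  expect_setequal(unlist(lapply(b, `[[`, "patients")), 1:100)
  expect_setequal(unlist(lapply(b, `[[`, "celllines")), 1:100)
  expect_true(all(vapply(b, function(x) length(x$patients) == 20 &&
                           length(x$celllines) == 20, logical(1))))

  b2 <- make_balanced_minibatches(100, 30, 20, seed = 2)
  expect_length(b2, 5L)
  pat <- unlist(lapply(b2, `[[`, "patients"))
  expect_equal(sort(pat), 1:100) # each patient exactly once
  cl <- unlist(lapply(b2, `[[`, "celllines"))
  expect_length(cl, 100L) # 100 draws with replacement from 30
  expect_true(all(cl %in% 1:30))
  # equal counts within every batch
  expect_true(all(vapply(b2, function(x) {
    length(x$patients) == length(x$celllines)
  }, logical(1))))

  # reversed imbalance partitions cell-lines instead
  b3 <- make_balanced_minibatches(30, 100, 20, seed = 3)
  expect_equal(sort(unlist(lapply(b3, `[[`, "celllines"))), 1:100)

  expect_identical(make_balanced_minibatches(50, 20, 15, seed = 7),
                   make_balanced_minibatches(50, 20, 15, seed = 7))
})

make_tiny_training <- function(seed = 1, n = 60, genes = 12) {
  coh <- generate_cohorts(synthetic_config(
    n_patients = n, n_celllines = n, n_genes = genes, n_drugs = 4,
    seed = seed))
  prep <- prep_cohorts(coh)
  data <- model_data(prep$patient, prep$cellline, prep$survival, prep$drugs)
  mods <- tiny_modules(input_dim = ncol(prep$patient$values), n_drugs = 4,
                       seed = seed)
  list(data = data, mods = mods, coh = coh)
}

test_that("critic epochs touch only critic weights and respect zero lr", {
  tt <- make_tiny_training()
  sch <- training_schedule(batch_size = 16, lr = 1e-3, seed = 1,
                           pretrain_dc_epochs = 1)
  state <- init_training_state(tt$mods, sch)
  batches <- make_balanced_minibatches(60, 60, 16, seed = 1)
  before <- state$modules
  state2 <- critic_epoch(state, tt$data, batches)
  expect_identical(state2$modules$encoder$W, before$encoder$W)
  expect_identical(state2$modules$decoder$W, before$decoder$W)
  expect_identical(state2$modules$survival$W, before$survival$W)
  expect_identical(state2$modules$drug$W, before$drug$W)
  expect_false(identical(state2$modules$critic$W, before$critic$W))

  sch0 <- training_schedule(batch_size = 16, lr = 0, seed = 1)
  state0 <- init_training_state(tt$mods, sch0)
  state0 <- critic_epoch(state0, tt$data, batches)
  expect_identical(state0$modules$critic$W, tt$mods$critic$W)
})

test_that("critic training decreases the adversarial loss on separated embeddings", {
  # raw (unstandardized) cohorts keep the domain shift, so the untrained
  # encoder produces well-separated embeddings
  coh <- generate_cohorts(synthetic_config(
    n_patients = 60, n_celllines = 60, n_genes = 12, n_drugs = 4, seed = 5))
  data <- model_data(coh$patient, coh$cellline, coh$survival, coh$drugs)
  mods <- tiny_modules(input_dim = 12, n_drugs = 4, seed = 5)
  sch <- training_schedule(batch_size = 30, lr = 1e-3, seed = 5)
  state <- init_training_state(mods, sch)
  batches <- make_balanced_minibatches(60, 60, 30, seed = 5)
  eval_adv <- function(st) {
    zs_p <- forward_autoencode(data$patient$values, 0L, st$modules)$z_shared
    zs_c <- forward_autoencode(data$cellline$values, 1L, st$modules)$z_shared
    cp <- deconfae:::mlp_forward(st$modules$critic, rbind(zs_p, zs_c))$out
    adversarial_loss(drop(cp), c(rep(0, 60), rep(1, 60)))
  }
  before <- eval_adv(state)
  for (i in 1:5) state <- critic_epoch(state, data, batches)
  expect_lt(eval_adv(state), before)
})

test_that("zero-epoch phases leave the state untouched", {
  tt <- make_tiny_training()
  sch <- training_schedule(pretrain_dc_epochs = 0, pretrain_surv_epochs = 0,
                           pretrain_drug_epochs = 0, joint_epochs = 0,
                           batch_size = 16, seed = 1)
  state <- init_training_state(tt$mods, sch)
  s2 <- pretrain_deconfounding(state, tt$data, sch)
  s3 <- pretrain_survival(s2, tt$data, sch)
  s4 <- pretrain_drugs(s3, tt$data, sch)
  s5 <- train_joint(s4, tt$data, sch)
  expect_identical(s5$modules$encoder$W, tt$mods$encoder$W)
  expect_equal(s5$epoch, 0L)
})

test_that("all-zero task weights leave non-critic weights unchanged in joint training", {
  tt <- make_tiny_training()
  sch <- training_schedule(pretrain_dc_epochs = 0, pretrain_surv_epochs = 0,
                           pretrain_drug_epochs = 0, joint_epochs = 2,
                           batch_size = 16, seed = 1)
  state <- init_training_state(tt$mods, sch)
  state <- train_joint(state, tt$data, sch, loss_weights(0, 0, 0, 0))
  expect_identical(state$modules$encoder$W, tt$mods$encoder$W)
  expect_identical(state$modules$decoder$W, tt$mods$decoder$W)
  expect_identical(state$modules$survival$W, tt$mods$survival$W)
  expect_identical(state$modules$drug$W, tt$mods$drug$W)
  # the critic still trains in its alternating epochs
  expect_false(identical(state$modules$critic$W, tt$mods$critic$W))
  # and the critic update count per joint epoch equals n_adv_per_ae
  expect_equal(state$opt$critic$t,
               2L * sch$n_adv_per_ae * length(make_balanced_minibatches(60, 60, 16, seed = 1)))
})

test_that("plain autoencoder pre-training reduces reconstruction loss", {
  tt <- make_tiny_training(seed = 3)
  sch <- training_schedule(pretrain_dc_epochs = 20, batch_size = 16,
                           lr = 1e-3, seed = 3)
  state <- init_training_state(tt$mods, sch)
  state <- pretrain_deconfounding(state, tt$data, sch, loss_weights(1, 0, 0, 0))
  h <- state$history$l_rec
  expect_lt(mean(tail(h, 5)), mean(head(h, 5)))
})

test_that("training is deterministic given the schedule seed", {
  tt <- make_tiny_training(seed = 4)
  sch <- training_schedule(pretrain_dc_epochs = 2, pretrain_surv_epochs = 2,
                           pretrain_drug_epochs = 2, joint_epochs = 2,
                           batch_size = 16, lr = 1e-3, seed = 11)
  w <- loss_weights(1, 0.03, 1, 1)
  s1 <- train_model(tt$data, sch, w, modules = tt$mods)
  s2 <- train_model(tt$data, sch, w, modules = tt$mods)
  expect_identical(s1$modules$encoder$W, s2$modules$encoder$W)
  expect_identical(s1$modules$critic$W, s2$modules$critic$W)
  expect_identical(s1$history, s2$history)
})

test_that("checkpoint round-trip reproduces continued training bitwise", {
  tt <- make_tiny_training(seed = 6)
  sch1 <- training_schedule(pretrain_dc_epochs = 2, pretrain_surv_epochs = 0,
                            pretrain_drug_epochs = 0, joint_epochs = 0,
                            batch_size = 16, lr = 1e-3, seed = 6)
  state <- init_training_state(tt$mods, sch1)
  state <- pretrain_deconfounding(state, tt$data, sch1)
  # continue directly
  direct <- pretrain_deconfounding(state, tt$data, sch1)
  # save, reload weights + rng, continue
  dir <- withr::local_tempdir()
  save_checkpoint(state$modules, dir, extra = list(rng = state$rng))
  loaded <- load_checkpoint(dir)
  resumed <- state
  resumed$modules <- loaded$modules
  resumed$rng <- as.integer(unlist(loaded$extra$rng))
  resumed <- pretrain_deconfounding(resumed, tt$data, sch1)
  expect_identical(resumed$modules$encoder$W, direct$modules$encoder$W)
  expect_identical(resumed$modules$critic$W, direct$modules$critic$W)
})

test_that("stronger L2 regularization shrinks fitted weight norms", {
  norms <- vapply(c(0, 1e-2), function(l2) {
    coh <- generate_cohorts(synthetic_config(
      n_patients = 40, n_celllines = 40, n_genes = 10, n_drugs = 3, seed = 9))
    prep <- prep_cohorts(coh)
    data <- model_data(prep$patient, prep$cellline, prep$survival, prep$drugs)
    mods <- tiny_modules(input_dim = ncol(prep$patient$values), n_drugs = 3,
                         seed = 9, l2 = l2)
    sch <- training_schedule(pretrain_dc_epochs = 10, pretrain_surv_epochs = 0,
                             pretrain_drug_epochs = 0, joint_epochs = 0,
                             batch_size = 20, lr = 1e-3, seed = 9)
    state <- init_training_state(mods, sch)
    state <- pretrain_deconfounding(state, data, sch, loss_weights(1, 0, 0, 0))
    deconfae:::mlp_weight_norm(state$modules$encoder) +
      deconfae:::mlp_weight_norm(state$modules$decoder)
  }, numeric(1))
  expect_lt(norms[2], norms[1])
})

test_that("loss history records finite constituent losses per epoch and phase", {
  tt <- make_tiny_training(seed = 8)
  sch <- training_schedule(pretrain_dc_epochs = 2, pretrain_surv_epochs = 2,
                           pretrain_drug_epochs = 2, joint_epochs = 2,
                           batch_size = 16, lr = 1e-3, seed = 8)
  state <- train_model(tt$data, sch, loss_weights(1, 0.03, 1, 1),
                       modules = tt$mods)
  h <- state$history
  expect_equal(nrow(h), 8L)
  expect_equal(as.character(unique(h$phase)),
               c("pretrain_dc", "pretrain_surv", "pretrain_drug", "joint"))
  expect_true(all(is.finite(h$l_mtl)))
  joint <- h[h$phase == "joint", ]
  expect_true(all(is.finite(unlist(joint[, c("l_rec", "l_adv", "l_dc",
                                             "l_surv", "l_drug")]))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_training_log(state, path)
  expect_equal(nrow(utils::read.csv(path)), 8L)
})

test_that("missing-task data is rejected where the contract demands it", {
  tt <- make_tiny_training()
  sch <- training_schedule(batch_size = 16, seed = 1)
  state <- init_training_state(tt$mods, sch)
  no_surv <- model_data(tt$data$patient, tt$data$cellline,
                        drugs = tt$data$drugs)
  expect_error(pretrain_survival(state, no_surv, sch), "event")
  no_drugs <- model_data(tt$data$patient, tt$data$cellline,
                         survival = tt$data$survival)
  expect_error(pretrain_drugs(state, no_drugs, sch), "drug")
})
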