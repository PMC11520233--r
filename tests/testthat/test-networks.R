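# Latent partition, masking, module forwards and checkpointing.

test_that("latent partition defaults and invariants hold", {
  p <- latent_partition(8)
  expect_equal(p$q, 4L)
  expect_length(p$V, 2L)
  expect_length(p$W, 2L)
  expect_equal(sort(c(p$U, p$V, p$W)), 1:8)
  # remainder goes to the patient-private block
  p10 <- latent_partition(10)
  expect_equal(p10$q, 5L)
  expect_length(p10$V, 3L)
  expect_length(p10$W, 2L)
  expect_error(latent_partition(4, q = 5), "exceeds")
  expect_error(latent_partition(4, q = 2, n_v = 3, n_w = 3), "sum to")
})

test_that("latent_mask follows the case table on the worked example", {
  part <- latent_partition(4, q = 2, n_v = 1, n_w = 1)
  z <- c(a = 1.1, b = 2.2, c = 3.3, d = 4.4)
  expect_equal(unname(latent_mask(z, 0L, part)), c(1.1, 2.2, 3.3, 0))
  expect_equal(unname(latent_mask(z, 1L, part)), c(1.1, 2.2, 0, 4.4))
  # idempotence
  once <- latent_mask(z, 0L, part)
  expect_identical(latent_mask(once, 0L, part), once)
  expect_error(latent_mask(z[1:3], 0L, part), "match")
})

test_that("latent_mask zeroes exactly the opposite private block on random partitions", {
  set.seed(21)
  for (i in 1:25) {
    p <- sample(3:16, 1)
    q <- sample.int(p - 1, 1)
    rest <- p - q
    n_v <- sample(0:rest, 1)
    part <- latent_partition(p, q = q, n_v = n_v, n_w = rest - n_v)
    z <- rnorm(p) + 10 # bounded away from zero
    for (s in 0:1) {
      out <- latent_mask(z, s, part)
      zeroed <- which(out == 0)
      expect_equal(zeroed, sort(if (s == 0) part$W else part$V))
      expect_equal(out[part$U], z[part$U])
    }
  }
})

test_that("extract_shared subsets U and commutes with masking", {
  part <- latent_partition(4, q = 2, n_v = 1, n_w = 1)
  z <- c(5, 6, 7, 8)
  expect_equal(extract_shared(z, part), c(5, 6))
  full <- latent_partition(3, q = 3, n_v = 0, n_w = 0)
  expect_equal(extract_shared(c(1, 2, 3), full), c(1, 2, 3))
  for (s in 0:1) {
    expect_equal(extract_shared(latent_mask(z, s, part), part),
                 extract_shared(z, part))
  }
})

test_that("autoencoder forward has the right shapes and batch consistency", {
  mods <- tiny_modules(input_dim = 10)
  set.seed(2)
  x <- matrix(rnorm(30), 3, 10)
  s <- c(0L, 1L, 0L)
  out <- forward_autoencode(x, s, mods)
  expect_equal(dim(out$z), c(3L, 8L))
  expect_equal(dim(out$z_shared), c(3L, 4L))
  expect_equal(dim(out$x_hat), c(3L, 10L))
  expect_identical(out$x_hat, forward_autoencode(x, s, mods)$x_hat)
  singles <- do.call(rbind, lapply(1:3, function(i) {
    forward_autoencode(x[i, , drop = FALSE], s[i], mods)$x_hat
  }))
  expect_equal(out$x_hat, singles, tolerance = 1e-12)
})

test_that("decoder built as an identity map reproduces hand-computed output", {
  # one-layer linear encoder/decoder on a 2-unit toy
  cfg <- network_config(input_dim = 2, latent_dim = 2, shared_dim = 2,
                        n_drugs = 1, encoder_widths = integer(0),
                        decoder_widths = integer(0),
                        critic_widths = 4L, survival_widths = 4L,
                        drug_widths = 4L, dropout = 0, l2 = 0)
  mods <- build_modules(cfg, seed = 1)
  mods$encoder$W[[1]] <- diag(2); mods$encoder$b[[1]] <- c(0, 0)
  mods$decoder$W[[1]] <- matrix(c(2, 0, 1, -1), 2, 2)
  mods$decoder$b[[1]] <- c(0.5, 0)
  x <- matrix(c(3, 4), 1, 2)
  out <- forward_autoencode(x, 0L, mods)
  expect_equal(out$x_hat, x %*% mods$decoder$W[[1]] +
                 rep(mods$decoder$b[[1]], each = 1), tolerance = 1e-12)
})

test_that("predict_risk composes head over shared embedding and covariates", {
  cfg <- network_config(input_dim = 3, latent_dim = 4, shared_dim = 2,
                        n_drugs = 1, n_covariates = 1,
                        encoder_widths = integer(0),
                        decoder_widths = 4L, critic_widths = 4L,
                        survival_widths = integer(0), drug_widths = 4L,
                        dropout = 0, l2 = 0)
  mods <- build_modules(cfg, seed = 1)
  # linear encoder and linear survival head with known weights
  E <- matrix(rnorm(12), 3, 4)
  mods$encoder$W[[1]] <- E; mods$encoder$b[[1]] <- rep(0, 4)
  wA <- c(0.5, -1, 2)
  mods$survival$W[[1]] <- matrix(wA, 3, 1); mods$survival$b[[1]] <- 0.25
  x <- matrix(c(1, 2, 3), 1, 3)
  k <- matrix(0.7, 1, 1)
  z_s <- (x %*% E)[, 1:2, drop = FALSE]
  expect_equal(predict_risk(x, mods, k = k),
               drop(cbind(z_s, k) %*% wA) + 0.25, tolerance = 1e-12)
  expect_error(predict_risk(x, mods), "covariates")
  # Cox partial likelihood is invariant to the head's output bias
  g0 <- predict_risk(rbind(x, 2 * x, -x), mods, k = matrix(0.7, 3, 1))
  mods$survival$b[[1]] <- mods$survival$b[[1]] + 3
  g1 <- predict_risk(rbind(x, 2 * x, -x), mods, k = matrix(0.7, 3, 1))
  grouping <- build_efron_grouping(c(1, 2, 3), c(1, 1, 0))
  expect_equal(efron_cox_loglik(g0, grouping), efron_cox_loglik(g1, grouping),
               tolerance = 1e-10)
})

test_that("predict_drugs returns one column per drug with linear hand-check", {
  cfg <- network_config(input_dim = 3, latent_dim = 4, shared_dim = 2,
                        n_drugs = 3, encoder_widths = integer(0),
                        decoder_widths = 4L, critic_widths = 4L,
                        survival_widths = 4L, drug_widths = integer(0),
                        dropout = 0, l2 = 0)
  mods <- build_modules(cfg, seed = 1)
  E <- matrix(rnorm(12), 3, 4)
  mods$encoder$W[[1]] <- E; mods$encoder$b[[1]] <- rep(0, 4)
  B <- matrix(rnorm(6), 2, 3)
  mods$drug$W[[1]] <- B; mods$drug$b[[1]] <- c(0.1, 0.2, 0.3)
  x <- matrix(rnorm(6), 2, 3)
  expected <- (x %*% E)[, 1:2] %*% B +
    matrix(c(0.1, 0.2, 0.3), 2, 3, byrow = TRUE)
  expect_equal(predict_drugs(x, mods), expected, tolerance = 1e-12)
})

test_that("checkpoints round-trip bitwise and fail loudly on mismatch", {
  mods <- tiny_modules(input_dim = 7, seed = 42)
  dir <- withr::local_tempdir()
  save_checkpoint(mods, dir, extra = list(epoch = 3L))
  loaded <- load_checkpoint(dir)
  expect_identical(loaded$modules$encoder$W, mods$encoder$W)
  expect_identical(loaded$modules$drug$b, mods$drug$b)
  expect_equal(loaded$extra$epoch, 3L)
  # corrupt the stored architecture
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"),
                            simplifyVector = TRUE)
  cfg$config$input_dim <- 99
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  expect_error(load_checkpoint(dir), "does not match")
  expect_error(load_checkpoint(file.path(dir, "nope")), "incomplete")
})
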