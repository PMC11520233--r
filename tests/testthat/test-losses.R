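# Unit tests for every training objective, anchored on hand-computed and
# oracle-computed expected values.

test_that("reconstruction loss matches hand arithmetic and scale convention", {
  x <- matrix(c(1, 0), nrow = 1)
  expect_identical(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, matrix(0, 1, 2)), 0.5)
  # appending perfectly reconstructed columns halves the loss
  set.seed(1)
  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(12), 3, 4)
  pad <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(cbind(a, pad), cbind(b, pad)),
               reconstruction_loss(a, b) / 2)
  expect_error(reconstruction_loss(a, matrix(0, 3, 5)), "shape")
})

test_that("adversarial loss follows the domain-sign convention", {
  expect_equal(adversarial_loss(c(2, 3), c(0, 1)), -0.5)
  # balanced batch, constant critic -> 0
  expect_equal(adversarial_loss(rep(1.7, 10), rep(c(0, 1), 5)), 0)
  # all-patient batch with constant output c -> c
  expect_equal(adversarial_loss(rep(2.5, 4), rep(0, 4)), 2.5)
})

test_that("deconfounding loss is the cell-line mean and errors without cell-lines", {
  expect_equal(deconfounding_loss(c(4, 100), c(1, 0)), 4)
  expect_equal(deconfounding_loss(rep(3.3, 5), rep(1, 5)), 3.3)
  expect_error(deconfounding_loss(c(1, 2), c(0, 0)), "cell-line")
})

test_that("deconfounding equals the negated rescaled cell-line term of the adversarial loss", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    s <- rbinom(n, 1, 0.5)
    if (sum(s) == 0) s[1] <- 1L
    cv <- rnorm(n, sd = 3)
    cell_term <- mean(cv * (1 - 2 * s) * (s == 1))
    expect_equal(deconfounding_loss(cv, s), -(n / sum(s)) * cell_term)
  }
})

test_that("efron grouping separates ties, risk sets and censored records", {
  g <- build_efron_grouping(c(5, 5, 3), c(1, 1, 0))
  expect_equal(g$event_times, 5)
  expect_equal(g$h[[1]], c(1L, 2L))
  expect_equal(g$risk_sets[[1]], c(1L, 2L))
  expect_equal(g$n_events, 2L)
  g2 <- build_efron_grouping(c(1, 2, 3), c(1, 1, 1))
  expect_true(all(lengths(g2$h) == 1L))
  expect_error(build_efron_grouping(c(1, 2), c(0, 0)), "no events")
  expect_error(build_efron_grouping(c(0, 1), c(1, 1)), "positive")
})

test_that("efron log-likelihood reproduces hand-computed cases", {
  # 2 at risk, 1 event, all scores zero
  g1 <- build_efron_grouping(c(2, 5), c(1, 0))
  expect_equal(efron_cox_loglik(c(0, 0), g1), -log(2), tolerance = 1e-12)
  # 3 at risk, 2 tied events: inner sum ln3 + ln2
  g2 <- build_efron_grouping(c(2, 2, 5), c(1, 1, 0))
  expect_equal(efron_cox_loglik(c(0, 0, 0), g2), -log(6) / 2,
               tolerance = 1e-12)
})

test_that("efron matches the brute-force partial likelihood on no-tie instances", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    time <- sample(seq(1, 100), n) # distinct times
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[sample.int(n, 1)] <- 1L
    g <- rnorm(n)
    grouping <- build_efron_grouping(time, event)
    expect_equal(efron_cox_loglik(g, grouping),
                 oracle_cox_loglik(g, time, event), tolerance = 1e-10)
  }
})

test_that("efron log-likelihood is shift invariant and overflow safe", {
  set.seed(3)
  time <- c(3, 3, 7, 9, 12, 12, 15)
  event <- c(1, 1, 0, 1, 1, 1, 0)
  g <- rnorm(7)
  grouping <- build_efron_grouping(time, event)
  base <- efron_cox_loglik(g, grouping)
  expect_equal(efron_cox_loglik(g + 5, grouping), base, tolerance = 1e-9)
  expect_lt(abs(efron_cox_loglik(g + 1000, grouping) - base), 1e-6)
  expect_error(efron_cox_loglik(c(g[-7], NaN), grouping), "non-finite")
})

test_that("efron gradient matches finite differences", {
  set.seed(11)
  time <- c(2, 2, 5, 8, 8, 9)
  event <- c(1, 1, 1, 1, 1, 0)
  g <- rnorm(6)
  grouping <- build_efron_grouping(time, event)
  an <- deconfae:::efron_loglik_grad(g, grouping)$grad
  eps <- 1e-6
  fd <- vapply(seq_along(g), function(i) {
    gp <- g; gp[i] <- gp[i] + eps
    gm <- g; gm[i] <- gm[i] - eps
    (efron_cox_loglik(gp, grouping) - efron_cox_loglik(gm, grouping)) / (2 * eps)
  }, numeric(1))
  expect_equal(an, fd, tolerance = 1e-6)
})

test_that("masked drug loss ignores unobserved entries", {
  R <- matrix(c(1, 0, NA, 1), 2, 2)
  mask <- !is.na(R)
  R[!mask] <- 0
  R_hat <- matrix(0.5, 2, 2)
  expect_equal(masked_drug_loss(R_hat, R, mask), 0.25)
  # invariance to arbitrary values at masked positions
  set.seed(5)
  for (i in 1:10) {
    A <- matrix(rnorm(24), 4, 6)
    B <- matrix(rnorm(24), 4, 6)
    m <- matrix(runif(24) < 0.6, 4, 6)
    if (sum(m) == 0) m[1] <- TRUE
    B2 <- B; B2[!m] <- rnorm(sum(!m), sd = 100)
    expect_identical(masked_drug_loss(A, B, m), masked_drug_loss(A, B2, m))
  }
  # fully observed mask degenerates to plain MSE
  full <- matrix(TRUE, 4, 6)
  expect_equal(masked_drug_loss(A, B, full), mean((A - B)^2))
  expect_error(masked_drug_loss(A, B, matrix(FALSE, 4, 6)), "observed")
})

test_that("multi-task loss is the stated weighted sum", {
  w0 <- loss_weights(0, 0, 0, 0)
  expect_equal(mtl_loss(1, 2, 3, 4, w0), 0)
  expect_equal(mtl_loss(1.5, 9, 9, 9, loss_weights(1, 0, 0, 0)), 1.5)
  expect_equal(mtl_loss(0.2, -0.3, 0.4, 99, loss_weights(0.5, 1, 2, 0)), 0.6)
  expect_error(mtl_loss(0.1, Inf, 0.2, 0.3, loss_weights()), "l_dc")
  expect_error(loss_weights(-1, 0, 0, 0), "non-negative")
})

test_that("gradient penalty has the linear-critic closed form", {
  part_dim <- 3L
  lin <- deconfae:::mlp_new(c(part_dim, 1L))
  set.seed(9)
  zp <- matrix(rnorm(15), 5, 3)
  zc <- matrix(rnorm(15), 5, 3)
  # weight norm 1 -> penalty 0 regardless of inputs
  lin$W[[1]][] <- c(1, 0, 0)
  expect_equal(gradient_penalty(lin, zp, zc, lambda_gp = 10), 0,
               tolerance = 1e-12)
  # weight norm 2 -> 10 * (2 - 1)^2
  lin$W[[1]][] <- c(0, 2, 0)
  expect_equal(gradient_penalty(lin, zp, zc, lambda_gp = 10), 10,
               tolerance = 1e-12)
  # constant critic (all-zero weights) -> lambda
  lin$W[[1]][] <- 0
  expect_equal(gradient_penalty(lin, zp, zc, lambda_gp = 7), 7,
               tolerance = 1e-12)
})

test_that("gradient penalty is non-negative with interpolation trimming", {
  set.seed(13)
  critic <- deconfae:::mlp_new(c(4, 6, 1))
  zp <- matrix(rnorm(8 * 4), 8, 4)
  zc <- matrix(rnorm(3 * 4), 3, 4)
  vals <- replicate(20, gradient_penalty(critic, zp, zc, lambda_gp = 10))
  expect_true(all(vals >= 0))
})
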