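# Evaluation metrics against exhaustive-enumeration oracles and worked
# examples.

test_that("harrell_cindex reproduces the worked example and edge cases", {
  # perfectly ordered risks, no censoring
  expect_equal(harrell_cindex(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  # constant risk -> all ties
  expect_equal(harrell_cindex(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  # worked example: comparable pairs (1,2),(1,3),(2,3); two concordant
  expect_equal(harrell_cindex(c(3, 1, 2), c(2, 4, 6), c(1, 1, 0)), 2 / 3)
  expect_error(harrell_cindex(1, 5, 0), "comparable")
})

test_that("harrell_cindex equals exhaustive pair enumeration on random instances", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(3:15, 1)
    sv <- random_survival(n)
    risk <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE) # force risk ties
    ci <- tryCatch(harrell_cindex(risk, sv$time, sv$event),
                   error = function(e) NA_real_)
    oc <- tryCatch(oracle_cindex(risk, sv$time, sv$event),
                   error = function(e) NA_real_)
    expect_identical(ci, oc)
  }
})

test_that("per-drug R2 matches hand arithmetic and flags degenerate drugs", {
  R <- cbind(d1 = c(0.2, 0.4, 0.6), d2 = c(0.5, 0.5, 0.5),
             d3 = c(0.1, 0.9, NA))
  mask <- !is.na(R)
  R[!mask] <- 0
  R_hat <- cbind(rep(0.3, 3), rep(0.4, 3), rep(0.1, 3))
  r2 <- per_drug_r2(R_hat, R, mask)
  expect_equal(unname(r2["d1"]), 1 - (0.01 + 0.01 + 0.09) / 0.08)
  expect_equal(unname(r2["d1"]), -0.375)
  expect_true(is.na(r2["d2"])) # zero variance -> flagged
  # perfect predictions and mean predictions
  expect_equal(unname(per_drug_r2(R, R, mask)["d1"]), 1)
  mean_pred <- matrix(rep(colMeans(R), each = 3), 3, 3)
  expect_equal(unname(per_drug_r2(mean_pred, R, mask)["d1"]), 0)
  # split argument restricts rows: d1 over rows 1:2 has SS_res == SS_tot
  r2_split <- per_drug_r2(R_hat, R, mask, split = 1:2)
  expect_equal(unname(r2_split["d1"]), 0)
  expect_equal(unname(r2_split["d3"]), 1 - 0.64 / 0.32)
})

test_that("r2_quantile90 uses the linear interpolation convention", {
  expect_equal(r2_quantile90(seq(0, 1, by = 0.1)), 0.9)
  expect_equal(r2_quantile90(rep(0.42, 5)), 0.42)
  expect_equal(r2_quantile90(c(NA, 0.7)), 0.7)
  expect_error(r2_quantile90(c(NA_real_, NA_real_)), "no valid")
})

test_that("domain_auroc behaves at both signal extremes and is seed-stable", {
  set.seed(31)
  a <- matrix(rnorm(200 * 5), 200, 5)
  b <- matrix(rnorm(200 * 5), 200, 5)
  auc_null <- domain_auroc(a, b, seed = 11)
  expect_lt(abs(auc_null - 0.5), 0.07)
  b_sep <- b; b_sep[, 2] <- b_sep[, 2] + 10
  expect_gte(domain_auroc(a, b_sep, seed = 11), 0.99)
  expect_identical(domain_auroc(a, b, seed = 11), auc_null)
  expect_error(domain_auroc(a[1:3, ], b, seed = 1), "at least")
})

test_that("pareto_front matches the dominance oracle", {
  pts <- rbind(c(1, 0), c(0, 1), c(0.4, 0.4), c(0.2, 0.2))
  expect_equal(pareto_front(pts), c(1L, 2L, 3L))
  expect_equal(pareto_front(rbind(c(1, 2))), 1L)
  same <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(pareto_front(same), 1:3)
  # min direction flips dominance: (0.2,0.2) now dominates (0.4,0.4)
  expect_equal(pareto_front(pts, directions = c("min", "min")), c(1L, 2L, 4L))
  set.seed(77)
  for (i in 1:40) {
    n <- sample(2:200, 1)
    k <- sample(2:4, 1)
    p <- matrix(sample(seq(0, 1, 0.25), n * k, replace = TRUE), n, k)
    expect_identical(pareto_front(p), oracle_pareto(p))
  }
})

test_that("risk stratification transfers discovery cut points", {
  strat <- stratify_risk(1:9, c(2, 5, 8))
  expect_equal(as.character(strat$labels), c("low", "mid", "high"))
  # uniform discovery scores split into thirds
  self <- stratify_risk(1:90)
  expect_true(all(abs(table(self$labels) - 30) <= 1))
  # new scores beyond the discovery range are all high
  high <- stratify_risk(1:10, c(11, 12, 13))
  expect_true(all(high$labels == "high"))
  expect_error(stratify_risk(numeric(0)), "empty")
})

test_that("dysregulation test recovers a planted effect and flags degenerates", {
  set.seed(55)
  n <- 200
  pred <- cbind(drugA = rnorm(n), drugB = rep(0.5, n))
  z <- (pred[, 1] - mean(pred[, 1])) / sd(pred[, 1])
  expr <- matrix(rnorm(n * 3, sd = 0.1), n, 3,
                 dimnames = list(sprintf("p%03d", 1:n), c("g1", "g2", "g3")))
  # plant a 1-unit log2 difference in g1 between sensitive and resistant
  expr[z > 1, "g1"] <- expr[z > 1, "g1"] + 1
  em <- omics_matrix(expr, 0L)
  rownames(pred) <- rownames(expr)
  tab <- dysregulation_test(em, pred,
                            list(drugA = c("g1", "g2", "absent_gene"),
                                 drugB = "g1"))
  a1 <- tab[tab$drug == "drugA" & tab$gene == "g1", ]
  expect_equal(a1$logFC, 1, tolerance = 0.15)
  expect_lt(a1$p, 1e-6)
  expect_true(a1$significant)
  expect_true(a1$substantial) # 2^1 = 2 > 1.5
  a2 <- tab[tab$drug == "drugA" & tab$gene == "g2", ]
  expect_equal(a2$logFC, 0, tolerance = 0.15)
  expect_false(a2$substantial)
  expect_equal(tab[tab$gene == "absent_gene", "status"], "gene_absent")
  expect_equal(tab[tab$drug == "drugB", "status"], "untestable")
})

test_that("evaluation report maintains the composite invariant", {
  rep <- evaluation_report(0.72, c(a = 0.1, b = 0.5, c = -0.2), 0.55)
  expect_equal(rep$r2_q90, r2_quantile90(c(0.1, 0.5, -0.2)))
  expect_equal(rep$composite, rep$cindex + rep$r2_q90 - rep$domain_auroc)
})
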