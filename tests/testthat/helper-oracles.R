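# Independent oracles: deliberately naive implementations used to freeze
# expected values; they never share code with the package paths they check.

# Cox partial log-likelihood by direct evaluation (no ties expected),
# normalized by the number of events; plain exp, no stabilization
oracle_cox_loglik <- function(g, time, event) {
  ev <- which(event == 1)
  total <- 0
  for (i in ev) {
    at_risk <- which(time >= time[i])
    total <- total + g[i] - log(sum(exp(g[at_risk])))
  }
  total / length(ev)
}

# Harrell's C by exhaustive pair enumeration
oracle_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        den <- den + 1
        if (risk[i] > risk[j]) num <- num + 1
        else if (risk[i] == risk[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

# Pareto front by O(n^2) dominance check (maximization in all columns)
oracle_pareto <- function(points) {
  n <- nrow(points)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(points[j, ] >= points[i, ]) && any(points[j, ] > points[i, ])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

# finite-difference gradient of a scalar function of a network's weights
fd_net_grad <- function(net, fn, eps = 1e-6) {
  gW <- lapply(net$W, function(w) array(0, dim(w)))
  gb <- lapply(net$b, function(v) numeric(length(v)))
  for (l in seq_along(net$W)) {
    for (i in seq_along(net$W[[l]])) {
      np <- net; np$W[[l]][i] <- np$W[[l]][i] + eps
      nm <- net; nm$W[[l]][i] <- nm$W[[l]][i] - eps
      gW[[l]][i] <- (fn(np) - fn(nm)) / (2 * eps)
    }
    for (i in seq_along(net$b[[l]])) {
      np <- net; np$b[[l]][i] <- np$b[[l]][i] + eps
      nm <- net; nm$b[[l]][i] <- nm$b[[l]][i] - eps
      gb[[l]][i] <- (fn(np) - fn(nm)) / (2 * eps)
    }
  }
  list(gW = gW, gb = gb)
}
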