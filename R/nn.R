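# Minimal fully-connected network core used by all five model modules.
#
# Networks are plain lists of weight matrices W[[l]] (fan_in x fan_out) and
# bias vectors b[[l]], with SELU hidden units and a linear output layer.
# Backprop is analytic; the Wasserstein critic additionally supports an exact
# double-backward pass for the gradient penalty (the penalty depends on the
# critic's input gradient, so its weight gradient needs second derivatives of
# the activations). All passes are verified against finite differences in the
# test suite.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(pmin(x, 0)) - 1))
}

selu_grad <- function(x) {
  SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(pmin(x, 0)))
}

# second derivative, needed by the gradient-penalty double-backward
selu_grad2 <- function(x) {
  ifelse(x > 0, 0, SELU_LAMBDA * SELU_ALPHA * exp(pmin(x, 0)))
}

#' Initialize a fully-connected network
#'
#' Weights follow the self-normalizing-network convention: normal with
#' variance 1/fan-in, which keeps SELU activations approximately
#' zero-mean/unit-variance at initialization. Biases start at zero.
#'
#' @param sizes integer vector of layer sizes, `c(input, hidden..., output)`.
#' @param dropout dropout rate applied after each hidden activation during
#'   training (inverted dropout); never applied to the output layer.
#' @return an object of class `mlp`.
#' @noRd
mlp_new <- function(sizes, dropout = 0) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  n_layers <- length(sizes) - 1L
  W <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = 1 / sqrt(sizes[l])),
                     nrow = sizes[l], ncol = sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, sizes = as.integer(sizes),
                 dropout = as.numeric(dropout)),
            class = "mlp")
}

#' Forward pass
#'
#' @param net an `mlp`.
#' @param X numeric matrix (n x input_dim).
#' @param training if TRUE, dropout masks are sampled from the current RNG
#'   stream; if FALSE the pass is deterministic.
#' @return list(out, cache) where cache holds pre-activations, activations
#'   and dropout masks for the backward pass.
#' @noRd
mlp_forward <- function(net, X, training = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$sizes[1L]) {
    stop_deconfae("network expects %d inputs, got %d", net$sizes[1L], ncol(X))
  }
  L <- length(net$W)
  S <- vector("list", L)
  A <- vector("list", L)
  M <- vector("list", L)
  a <- X
  rate <- net$dropout
  for (l in seq_len(L)) {
    s <- a %*% net$W[[l]]
    s <- sweep(s, 2L, net$b[[l]], `+`)
    S[[l]] <- s
    if (l < L) {
      a <- selu(s)
      if (training && rate > 0) {
        keep <- matrix(stats::runif(length(a)) >= rate, nrow = nrow(a))
        m <- keep / (1 - rate)
        a <- a * m
        M[[l]] <- m
      }
    } else {
      a <- s
    }
    A[[l]] <- a
  }
  list(out = a, cache = list(X = X, S = S, A = A, M = M))
}

#' Backward pass: gradients of a scalar loss w.r.t. weights and inputs
#'
#' @param net an `mlp`.
#' @param cache forward cache.
#' @param dY gradient of the loss w.r.t. the network output (n x out_dim).
#' @return list(gW, gb, dX).
#' @noRd
mlp_backward <- function(net, cache, dY) {
  L <- length(net$W)
  if (!is.matrix(dY)) dY <- matrix(dY, nrow = nrow(cache$X))
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dY
  for (l in rev(seq_len(L))) {
    a_prev <- if (l == 1L) cache$X else cache$A[[l - 1L]]
    gW[[l]] <- crossprod(a_prev, delta)
    gb[[l]] <- colSums(delta)
    dprev <- delta %*% t(net$W[[l]])
    if (l > 1L) {
      if (!is.null(cache$M[[l - 1L]])) dprev <- dprev * cache$M[[l - 1L]]
      delta <- dprev * selu_grad(cache$S[[l - 1L]])
    } else {
      delta <- dprev
    }
  }
  list(gW = gW, gb = gb, dX = delta)
}

# gradient of the (deterministic) network output w.r.t. its input, for a
# scalar-output network: returns an n x input_dim matrix
mlp_input_grad <- function(net, X) {
  fwd <- mlp_forward(net, X, training = FALSE)
  n <- nrow(fwd$cache$X)
  dY <- matrix(1, nrow = n, ncol = net$sizes[length(net$sizes)])
  mlp_backward(net, fwd$cache, dY)$dX
}

#' Gradient-penalty value and exact weight gradients for a scalar critic
#'
#' Computes P = lambda * mean_i (||grad_z C(z_i)|| - 1)^2 over the rows of
#' `Z`, together with dP/dW and dP/db. Dropout is disabled: the Lipschitz
#' penalty is evaluated on the deterministic critic. The implementation is a
#' manual reverse pass over the computation graph that produced the input
#' gradient (double backprop), using the second derivative of SELU.
#' @noRd
critic_penalty_grads <- function(net, Z, lambda_gp) {
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1L)
  L <- length(net$W)
  n <- nrow(Z)
  # deterministic forward
  S <- vector("list", L)
  A <- vector("list", L)
  a <- Z
  for (l in seq_len(L)) {
    s <- sweep(a %*% net$W[[l]], 2L, net$b[[l]], `+`)
    S[[l]] <- s
    a <- if (l < L) selu(s) else s
    A[[l]] <- a
  }
  P1 <- lapply(seq_len(L - 1L), function(l) selu_grad(S[[l]]))
  P2 <- lapply(seq_len(L - 1L), function(l) selu_grad2(S[[l]]))
  # reverse pass producing the input gradient g = dC/dz
  gamma <- vector("list", L)       # gradient of C w.r.t. S[[l]]
  E <- vector("list", L)           # gamma_{l+1} %*% t(W_{l+1}) cached
  gamma[[L]] <- matrix(1, nrow = n, ncol = 1L)
  if (L > 1L) {
    for (l in rev(seq_len(L - 1L))) {
      E[[l]] <- gamma[[l + 1L]] %*% t(net$W[[l + 1L]])
      gamma[[l]] <- E[[l]] * P1[[l]]
    }
  }
  g <- gamma[[1L]] %*% t(net$W[[1L]])
  nrm <- sqrt(rowSums(g^2))
  penalty <- lambda_gp * mean((nrm - 1)^2)
  # adjoint of g under P
  safe <- pmax(nrm, .Machine$double.eps)
  u <- g * ((2 * lambda_gp / n) * (nrm - 1) / safe)
  u[nrm == 0, ] <- 0
  gW <- lapply(net$W, function(w) array(0, dim(w)))
  gb <- lapply(net$b, function(v) numeric(length(v)))
  # reverse through g = gamma_1 W_1^T
  gW[[1L]] <- gW[[1L]] + crossprod(u, gamma[[1L]])
  gamma_bar <- vector("list", L)
  gamma_bar[[1L]] <- u %*% net$W[[1L]]
  s_bar <- lapply(seq_len(L), function(l) NULL)
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      e_bar <- gamma_bar[[l]] * P1[[l]]
      contrib <- gamma_bar[[l]] * E[[l]] * P2[[l]]
      s_bar[[l]] <- if (is.null(s_bar[[l]])) contrib else s_bar[[l]] + contrib
      gW[[l + 1L]] <- gW[[l + 1L]] + crossprod(e_bar, gamma[[l + 1L]])
      gamma_bar[[l + 1L]] <- e_bar %*% net$W[[l + 1L]]
    }
    # reverse through the forward chain (activations feeding deeper layers)
    for (l in rev(seq_len(L - 1L))) {
      if (l < L - 1L && !is.null(s_bar[[l + 1L]])) {
        gW[[l + 1L]] <- gW[[l + 1L]] + crossprod(A[[l]], s_bar[[l + 1L]])
        gb[[l + 1L]] <- gb[[l + 1L]] + colSums(s_bar[[l + 1L]])
        down <- (s_bar[[l + 1L]] %*% t(net$W[[l + 1L]])) * P1[[l]]
        s_bar[[l]] <- if (is.null(s_bar[[l]])) down else s_bar[[l]] + down
      }
      if (l == 1L && !is.null(s_bar[[1L]])) {
        gW[[1L]] <- gW[[1L]] + crossprod(Z, s_bar[[1L]])
        gb[[1L]] <- gb[[1L]] + colSums(s_bar[[1L]])
      }
    }
  }
  list(value = penalty, gW = gW, gb = gb)
}

# ---- Adam optimizer -------------------------------------------------------

adam_new <- function(net, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       mW = lapply(net$W, function(w) array(0, dim(w))),
       vW = lapply(net$W, function(w) array(0, dim(w))),
       mb = lapply(net$b, function(v) numeric(length(v))),
       vb = lapply(net$b, function(v) numeric(length(v))))
}

adam_step <- function(net, opt, gW, gb) {
  opt$t <- opt$t + 1L
  c1 <- 1 - opt$beta1^opt$t
  c2 <- 1 - opt$beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- opt$beta1 * opt$mW[[l]] + (1 - opt$beta1) * gW[[l]]
    opt$vW[[l]] <- opt$beta2 * opt$vW[[l]] + (1 - opt$beta2) * gW[[l]]^2
    net$W[[l]] <- net$W[[l]] -
      opt$lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + opt$eps)
    opt$mb[[l]] <- opt$beta1 * opt$mb[[l]] + (1 - opt$beta1) * gb[[l]]
    opt$vb[[l]] <- opt$beta2 * opt$vb[[l]] + (1 - opt$beta2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      opt$lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + opt$eps)
  }
  list(net = net, opt = opt)
}

# L2 weight decay: adds 2 * l2 * W to existing weight gradients (biases are
# not penalized); returns the updated gradient list
add_l2_grads <- function(net, gW, l2) {
  if (l2 > 0) {
    for (l in seq_along(gW)) gW[[l]] <- gW[[l]] + 2 * l2 * net$W[[l]]
  }
  gW
}

mlp_weight_norm <- function(net) {
  sqrt(sum(vapply(net$W, function(w) sum(w^2), numeric(1))))
}

zero_grads_like <- function(net) {
  list(gW = lapply(net$W, function(w) array(0, dim(w))),
       gb = lapply(net$b, function(v) numeric(length(v))))
}

accumulate_grads <- function(acc, g) {
  for (l in seq_along(acc$gW)) {
    acc$gW[[l]] <- acc$gW[[l]] + g$gW[[l]]
    acc$gb[[l]] <- acc$gb[[l]] + g$gb[[l]]
  }
  acc
}
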