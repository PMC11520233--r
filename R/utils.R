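# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not perturb
#' the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# deterministic 32-bit seed derived from a base seed and an index
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  as.integer(s %% 2147483629) + 1L
}

stop_deconfae <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_deconfae("non-finite values in %s", what)
  invisible(x)
}

assert_count <- function(x, what, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop_deconfae("%s must be a single integer >= %d", what, min)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop_deconfae("%s must be a single value in [0, 1]", what)
  }
  invisible(as.numeric(x))
}

#' Area under the ROC curve from scores and binary labels
#'
#' Rank-based (Mann-Whitney) AUROC; ties in scores count 1/2.
#' @noRd
auroc_from_scores <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop_deconfae("AUROC needs both classes present")
  }
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
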