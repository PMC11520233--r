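#' Latent-space partition into shared and domain-private coordinates
#'
#' The latent vector of dimension `p` is split into three disjoint index
#' sets: `U` (shared between patients and cell-lines, dimension `q`), `V`
#' (patient-private) and `W` (cell-line-private). By default
#' `q = ceiling(p/2)` and the private blocks each take `floor(p/4)`
#' coordinates, with any remainder assigned to `V`.
#'
#' @param p total latent dimension.
#' @param q shared dimension (defaults to `ceiling(p/2)`).
#' @param n_v,n_w sizes of the private blocks; defaults split `p - q` as
#'   described above. Must satisfy `q + n_v + n_w == p`.
#' @return an object of class `latent_partition` with integer index vectors
#'   `U`, `V`, `W` and fields `p`, `q`.
#' @export
#' @examples
#' latent_partition(8)
latent_partition <- function(p, q = NULL, n_v = NULL, n_w = NULL) {
  p <- assert_count(p, "p")
  if (is.null(q)) q <- ceiling(p / 2)
  q <- assert_count(q, "q")
  if (q > p) stop_deconfae("shared dimension q (%d) exceeds p (%d)", q, p)
  if (is.null(n_w)) n_w <- min(floor(p / 4), p - q)
  if (is.null(n_v)) n_v <- p - q - n_w
  n_v <- as.integer(n_v); n_w <- as.integer(n_w)
  if (n_v < 0 || n_w < 0 || q + n_v + n_w != p) {
    stop_deconfae("partition sizes (q=%d, |V|=%d, |W|=%d) must sum to p=%d",
                  q, n_v, n_w, p)
  }
  structure(list(p = p, q = q,
                 U = seq_len(q),
                 V = if (n_v > 0) q + seq_len(n_v) else integer(0),
                 W = if (n_w > 0) q + n_v + seq_len(n_w) else integer(0)),
            class = "latent_partition")
}

#' Network architecture configuration
#'
#' Describes the five trainable modules: encoder `E: R^d -> R^p`, decoder
#' `D: R^p -> R^d`, critic `C: R^q -> R`, survival head
#' `A: R^(q + n_covariates) -> R` and drug head `B: R^q -> R^m`. Hidden
#' units are SELU; output layers are linear; dropout follows every hidden
#' layer except in the critic (the Lipschitz penalty is evaluated on the
#' deterministic critic, see the methods vignette).
#'
#' @param input_dim number of genes `d`.
#' @param latent_dim total latent dimension `p`.
#' @param shared_dim shared dimension `q` (default `ceiling(p/2)`).
#' @param n_drugs number of drug outputs `m`.
#' @param n_covariates number of clinical covariates concatenated to the
#'   shared embedding for the survival head only.
#' @param encoder_widths,decoder_widths,critic_widths,survival_widths,drug_widths
#'   hidden-layer widths per module.
#' @param dropout dropout rate for encoder/decoder/survival/drug hidden
#'   layers.
#' @param critic_dropout dropout rate for the critic (default 0).
#' @param l2 L2 weight-decay coefficient applied to all module weights.
#' @return a `network_config` list.
#' @export
network_config <- function(input_dim, latent_dim = 16L,
                           shared_dim = NULL,
                           n_drugs = 0L, n_covariates = 0L,
                           encoder_widths = c(256L, 256L),
                           decoder_widths = c(256L, 256L),
                           critic_widths = c(64L, 64L),
                           survival_widths = c(64L, 64L),
                           drug_widths = c(64L, 64L),
                           dropout = 0.1, critic_dropout = 0,
                           l2 = 1e-4) {
  input_dim <- assert_count(input_dim, "input_dim")
  latent_dim <- assert_count(latent_dim, "latent_dim")
  if (is.null(shared_dim)) shared_dim <- ceiling(latent_dim / 2)
  shared_dim <- assert_count(shared_dim, "shared_dim")
  if (shared_dim > latent_dim) stop_deconfae("shared_dim must be <= latent_dim")
  cfg <- list(input_dim = input_dim, latent_dim = latent_dim,
              shared_dim = shared_dim,
              n_drugs = as.integer(n_drugs),
              n_covariates = as.integer(n_covariates),
              encoder_widths = as.integer(encoder_widths),
              decoder_widths = as.integer(decoder_widths),
              critic_widths = as.integer(critic_widths),
              survival_widths = as.integer(survival_widths),
              drug_widths = as.integer(drug_widths),
              dropout = assert_fraction(dropout, "dropout"),
              critic_dropout = assert_fraction(critic_dropout, "critic_dropout"),
              l2 = as.numeric(l2))
  structure(cfg, class = "network_config")
}

#' Construct the five trainable modules
#'
#' @param config a [network_config()].
#' @param partition optional [latent_partition()]; defaults are derived from
#'   the config dimensions.
#' @param seed RNG seed for weight initialization.
#' @return a `module_set` holding `encoder`, `decoder`, `critic`,
#'   `survival`, `drug` networks plus the partition and config.
#' @export
build_modules <- function(config, partition = NULL, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (is.null(partition)) {
    partition <- latent_partition(config$latent_dim, config$shared_dim)
  }
  if (partition$p != config$latent_dim || partition$q != config$shared_dim) {
    stop_deconfae("partition (p=%d, q=%d) disagrees with config (p=%d, q=%d)",
                  partition$p, partition$q, config$latent_dim, config$shared_dim)
  }
  with_seed(seed, {
    modules <- list(
      encoder = mlp_new(c(config$input_dim, config$encoder_widths,
                          config$latent_dim), dropout = config$dropout),
      decoder = mlp_new(c(config$latent_dim, config$decoder_widths,
                          config$input_dim), dropout = config$dropout),
      critic = mlp_new(c(config$shared_dim, config$critic_widths, 1L),
                       dropout = config$critic_dropout),
      survival = mlp_new(c(config$shared_dim + config$n_covariates,
                           config$survival_widths, 1L),
                         dropout = config$dropout),
      drug = mlp_new(c(config$shared_dim, config$drug_widths,
                       max(config$n_drugs, 1L)), dropout = config$dropout)
    )
    structure(list(encoder = modules$encoder, decoder = modules$decoder,
                   critic = modules$critic, survival = modules$survival,
                   drug = modules$drug, partition = partition,
                   config = config),
              class = "module_set")
  })
}

#' Mask domain-private latent coordinates
#'
#' Shared coordinates (`U`) always pass through; patient-private
#' coordinates (`V`) pass only for patient samples (`s = 0`); cell-line
#' private coordinates (`W`) pass only for cell-line samples (`s = 1`);
#' everything else is set to zero. Applied between encoder and decoder so a
#' single encoder can learn shared and private representations.
#'
#' @param z latent matrix (n x p) or a single latent vector.
#' @param s domain indicator per sample: 0 = patient, 1 = cell-line.
#' @param partition a [latent_partition()].
#' @return masked latent values, same shape as `z`.
#' @export
latent_mask <- function(z, s, partition) {
  vec <- !is.matrix(z)
  if (vec) z <- matrix(z, nrow = 1L)
  if (ncol(z) != partition$p) {
    stop_deconfae("latent width %d does not match partition p=%d",
                  ncol(z), partition$p)
  }
  s <- as.integer(s)
  if (length(s) == 1L) s <- rep(s, nrow(z))
  if (length(s) != nrow(z) || !all(s %in% c(0L, 1L))) {
    stop_deconfae("domain indicator must be 0/1, one per row of z")
  }
  out <- z
  if (length(partition$V) > 0) out[s == 1L, partition$V] <- 0
  if (length(partition$W) > 0) out[s == 0L, partition$W] <- 0
  if (vec) out[1L, ] else out
}

#' Extract the shared latent coordinates
#'
#' @inheritParams latent_mask
#' @return matrix (n x q) or vector of length q.
#' @export
extract_shared <- function(z, partition) {
  vec <- !is.matrix(z)
  if (vec) z <- matrix(z, nrow = 1L)
  if (ncol(z) != partition$p) {
    stop_deconfae("latent width %d does not match partition p=%d",
                  ncol(z), partition$p)
  }
  out <- z[, partition$U, drop = FALSE]
  if (vec) out[1L, ] else out
}

#' Encode and reconstruct omics profiles
#'
#' Runs `z = E(x)`, masks private coordinates by domain and decodes
#' `x_hat = D(f(z, s))`. Deterministic (dropout disabled).
#'
#' @param x matrix of omics rows (n x d).
#' @param s domain indicator per row (0 patient, 1 cell-line).
#' @param modules a [build_modules()] result.
#' @return list with `z` (n x p), `z_shared` (n x q) and `x_hat` (n x d).
#' @export
forward_autoencode <- function(x, s, modules) {
  stopifnot(inherits(modules, "module_set"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  z <- mlp_forward(modules$encoder, x)$out
  zm <- latent_mask(z, s, modules$partition)
  x_hat <- mlp_forward(modules$decoder, zm)$out
  list(z = z, z_shared = extract_shared(z, modules$partition), x_hat = x_hat)
}

#' Predict log-risk scores for patients
#'
#' `g(x) = A([z_shared; k])`; the hazard is proportional to `exp(g(x))`.
#'
#' @param x patient omics matrix (n x d).
#' @param k optional covariate matrix (n x n_covariates); must match the
#'   width the survival head was built with.
#' @param modules a [build_modules()] result.
#' @return numeric vector of log-risk scores.
#' @export
predict_risk <- function(x, modules, k = NULL) {
  stopifnot(inherits(modules, "module_set"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  z_s <- extract_shared(mlp_forward(modules$encoder, x)$out, modules$partition)
  n_cov <- modules$config$n_covariates
  if (n_cov > 0) {
    if (is.null(k)) stop_deconfae("survival head expects %d covariates", n_cov)
    if (!is.matrix(k)) k <- matrix(k, nrow = nrow(x))
    if (ncol(k) != n_cov || nrow(k) != nrow(x)) {
      stop_deconfae("covariate matrix must be %d x %d", nrow(x), n_cov)
    }
    z_s <- cbind(z_s, k)
  } else if (!is.null(k) && length(k) > 0) {
    stop_deconfae("model was built without covariates")
  }
  drop(mlp_forward(modules$survival, z_s)$out)
}

#' Predict drug sensitivities for cell-lines
#'
#' One prediction per drug for every sample, regardless of which entries
#' were observed during training. Outputs are unbounded; clip to `[0, 1]`
#' only for presentation.
#'
#' @param x cell-line omics matrix (n x d).
#' @param modules a [build_modules()] result.
#' @return matrix (n x m) of predicted sensitivities.
#' @export
predict_drugs <- function(x, modules) {
  stopifnot(inherits(modules, "module_set"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  z_s <- extract_shared(mlp_forward(modules$encoder, x)$out, modules$partition)
  mlp_forward(modules$drug, z_s)$out
}

# ---- checkpoints ----------------------------------------------------------

# serialize a double vector at full precision (round-trips bitwise through
# the JSON parser)
format_full <- function(x) sprintf("%.17g", x)

#' Save a module set as a text checkpoint directory
#'
#' Writes `config.json` (architecture + partition) and `weights.json`
#' (all weights at full precision, round-trip exact).
#'
#' @param modules a `module_set`.
#' @param dir target directory (created if needed).
#' @param extra optional named list stored verbatim in `config.json`
#'   (e.g. training progress or RNG state).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(modules, dir, extra = NULL) {
  stopifnot(inherits(modules, "module_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(config = unclass(modules$config),
              partition = unclass(modules$partition),
              extra = extra)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  nets <- list()
  for (name in c("encoder", "decoder", "critic", "survival", "drug")) {
    net <- modules[[name]]
    nets[[name]] <- list(
      sizes = net$sizes, dropout = format_full(net$dropout),
      W = lapply(net$W, function(w) list(dim = dim(w), x = format_full(w))),
      b = lapply(net$b, format_full))
  }
  jsonlite::write_json(nets, file.path(dir, "weights.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Load a checkpoint directory
#'
#' Fails loudly if the stored architecture disagrees with the weights.
#'
#' @param dir directory produced by [save_checkpoint()].
#' @return list with `modules` (a `module_set`) and `extra`.
#' @export
load_checkpoint <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  w_path <- file.path(dir, "weights.json")
  if (!file.exists(cfg_path) || !file.exists(w_path)) {
    stop_deconfae("checkpoint directory %s is incomplete", dir)
  }
  cfg <- jsonlite::fromJSON(cfg_path, simplifyVector = TRUE)
  config <- structure(cfg$config, class = "network_config")
  partition <- structure(lapply(cfg$partition, as.integer),
                         class = "latent_partition")
  nets <- jsonlite::fromJSON(w_path, simplifyVector = FALSE)
  modules <- list()
  for (name in c("encoder", "decoder", "critic", "survival", "drug")) {
    spec <- nets[[name]]
    if (is.null(spec)) stop_deconfae("checkpoint missing module '%s'", name)
    sizes <- as.integer(unlist(spec$sizes))
    W <- lapply(spec$W, function(w) {
      matrix(as.numeric(unlist(w$x)), nrow = as.integer(w$dim[[1]]),
             ncol = as.integer(w$dim[[2]]))
    })
    b <- lapply(spec$b, function(v) as.numeric(unlist(v)))
    for (l in seq_along(W)) {
      if (nrow(W[[l]]) != sizes[l] || ncol(W[[l]]) != sizes[l + 1L]) {
        stop_deconfae("checkpoint '%s': weight shapes disagree with sizes", name)
      }
    }
    modules[[name]] <- structure(
      list(W = W, b = b, sizes = sizes,
           dropout = as.numeric(unlist(spec$dropout))), class = "mlp")
  }
  if (modules$encoder$sizes[1L] != config$input_dim ||
      utils::tail(modules$encoder$sizes, 1L) != config$latent_dim) {
    stop_deconfae("checkpoint config does not match encoder dimensions")
  }
  ms <- structure(c(modules, list(partition = partition, config = config)),
                  class = "module_set")
  list(modules = ms, extra = cfg$extra)
}
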