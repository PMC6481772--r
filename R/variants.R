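#' Configuration for the accelerated MNF variants
#'
#' @param khat_fraction fraction of `S` used as the initial truncation
#'   rank `Khat` (default 0.03, the empirical 2--3% selected-band rate
#'   for FTIR tissue spectra).
#' @param epsilon target Frobenius relative-error factor of the
#'   randomized decomposition (metadata; the default sketch parameters
#'   meet `1 + epsilon` with `epsilon = 0.1` comfortably).
#' @param oversampling extra sketch columns beyond `Khat` (default 10).
#' @param power_iterations refinement sweeps of the randomized range
#'   finder (default 4).
#' @param krylov_blocks block-Krylov depth of the truncated
#'   eigendecomposition (default 6; depth 4 leaves the leading subspace
#'   only marginally converged when the retained eigenvalues cluster).
#' @param seed integer seed for the random sketches.
#' @return a `variant_config` list.
#' @export
variant_config <- function(khat_fraction = 0.03, epsilon = 0.1,
                           oversampling = 10L, power_iterations = 4L,
                           krylov_blocks = 6L, seed = 42L) {
  if (khat_fraction <= 0 || khat_fraction > 1)
    stop("khat_fraction must be in (0, 1]")
  if (epsilon <= 0) stop("epsilon must be positive")
  if (oversampling < 0) stop("oversampling must be >= 0")
  structure(list(khat_fraction = khat_fraction, epsilon = epsilon,
                 oversampling = as.integer(oversampling),
                 power_iterations = as.integer(power_iterations),
                 krylov_blocks = as.integer(krylov_blocks),
                 seed = as.integer(seed)),
            class = "variant_config")
}

#' Fast MNF
#'
#' Computes the full eigendecomposition of the whitened covariance (as
#' standard MNF does) but materializes only the `S x K` transform pair
#' and the `N x K` transformed matrix after automatic band selection,
#' replacing every inversion by a transpose.  The output is numerically
#' identical to standard MNF.
#'
#' @inheritParams mnf_standard
#' @return as [mnf_standard()].
#' @export
mnf_fast <- function(pm, noise, snr_threshold = 5.0, K = NULL) {
  cov <- compute_covariance(pm)
  sigma_W <- whiten_covariance(cov, noise)
  eg <- mnf_eigendecomposition(sigma_W)
  if (is.null(K)) K <- select_bands(eg$lambda_mnf, snr_threshold)
  model <- build_transforms(noise, eg$G, eg$lambda_mnf, K, cov$mean_Y,
                            snr_threshold, variant = "fast")
  list(model = model, denoised = inverse_reconstruct(pm, model),
       covariance = cov)
}

#' Truncated eigendecomposition by block-Krylov iteration
#'
#' Top-`khat` eigenpairs of a symmetric PSD matrix from a block-Krylov
#' subspace (a Block Lanczos scheme: the orthonormalized stack of
#' `A Omega, A^2 Omega, ..., A^depth Omega` followed by a small
#' Rayleigh--Ritz eigenproblem).  Preferred over plain power iteration,
#' which can stagnate when leading eigenvalues cluster.
#'
#' @param sigma_W symmetric matrix.
#' @param khat number of eigenpairs, `1 <= khat <= nrow(sigma_W)`.
#' @param depth Krylov depth (default 4).
#' @param seed seed for the random start block.
#' @return list with `G` (`m x khat`, orthonormal) and descending
#'   `lambda` of length `khat`.
#' @export
truncated_eig_krylov <- function(sigma_W, khat, depth = 4L, seed = 1L) {
  n <- nrow(sigma_W)
  khat <- as.integer(khat)
  if (khat < 1 || khat > n) stop("khat out of range [1, ", n, "]")
  b <- min(n, khat + 10L)
  if (b * depth >= n) {
    eg <- mnf_eigendecomposition(sigma_W)
    return(list(G = eg$G[, seq_len(khat), drop = FALSE],
                lambda = eg$lambda_mnf[seq_len(khat)]))
  }
  Om <- with_seed(split_seed(seed, "krylov"),
                  matrix(stats::rnorm(n * b), n, b))
  Kr <- matrix(0, n, b * depth)
  Z <- sigma_W %*% Om
  for (i in seq_len(depth)) {
    Z <- qr.Q(qr(Z))
    Kr[, (i - 1L) * b + seq_len(b)] <- Z
    if (i < depth) Z <- sigma_W %*% Z
  }
  Q <- qr.Q(qr(Kr))
  M <- crossprod(Q, sigma_W %*% Q)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  G <- fix_eigvec_signs(Q %*% eg$vectors[, seq_len(khat), drop = FALSE])
  list(G = G, lambda = pmax(eg$values[seq_len(khat)], 0))
}

#' Randomized truncated eigendecomposition
#'
#' Gaussian sketch of `khat + oversampling` columns, refined by power
#' iterations with re-orthonormalization, followed by a small dense
#' Rayleigh--Ritz step.  Satisfies the `(1 + epsilon)` Frobenius
#' low-rank error bound with high probability at the default parameters,
#' and is deterministic given the seed.  The decomposition never touches
#' an `m x m` eigenvector matrix: its working set is `m x (khat +
#' oversampling)`.
#'
#' @param sigma_W symmetric matrix.
#' @param khat number of eigenpairs.
#' @param config a [variant_config()] (oversampling, power iterations,
#'   seed).
#' @return list with `G` (`m x khat`) and descending `lambda`.
#' @export
randomized_svd_sym <- function(sigma_W, khat, config = variant_config()) {
  n <- nrow(sigma_W)
  khat <- as.integer(khat)
  if (khat < 1 || khat > n) stop("khat out of range [1, ", n, "]")
  b <- min(n, khat + config$oversampling)
  Om <- with_seed(split_seed(config$seed, "sketch"),
                  matrix(stats::rnorm(n * b), n, b))
  Q <- qr.Q(qr(sigma_W %*% Om))
  for (i in seq_len(config$power_iterations))
    Q <- qr.Q(qr(sigma_W %*% Q))
  M <- crossprod(Q, sigma_W %*% Q)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  G <- fix_eigvec_signs(Q %*% eg$vectors[, seq_len(khat), drop = FALSE])
  list(G = G, lambda = pmax(eg$values[seq_len(khat)], 0))
}

# shared driver for the truncated variants: decompose at rank Khat, let
# band selection pick K, and double Khat whenever selection saturates the
# truncation (K == Khat), so K is never silently clipped.
.mnf_truncated <- function(pm, noise, snr_threshold, config, variant,
                           decompose) {
  cov <- compute_covariance(pm)
  sigma_W <- whiten_covariance(cov, noise)
  m <- nrow(sigma_W)
  S <- ncol(pm$Y)
  khat <- min(m, max(1L, as.integer(ceiling(config$khat_fraction * S))))
  repeat {
    eg <- decompose(sigma_W, khat)
    K <- select_bands(eg$lambda, snr_threshold)
    if (K < khat || khat >= m) break
    khat <- min(2L * khat, m)
  }
  model <- build_transforms(noise, eg$G, eg$lambda, K, cov$mean_Y,
                            snr_threshold, variant = variant)
  model$khat <- khat
  if (variant == "rand") model$seed <- config$seed
  list(model = model, denoised = inverse_reconstruct(pm, model),
       covariance = cov)
}

#' Approx MNF
#'
#' Rank-`Khat` truncated eigendecomposition (block-Krylov) of the
#' whitened covariance with `Khat = ceiling(khat_fraction * S)`,
#' followed by automatic band selection.  If selection saturates the
#' truncation (`K == Khat`), `Khat` is doubled and the decomposition
#' repeated, so the selected count is never clipped by the truncation
#' rank.
#'
#' @inheritParams mnf_standard
#' @param config a [variant_config()].
#' @return as [mnf_standard()]; the model records `khat`.
#' @export
mnf_approx <- function(pm, noise, snr_threshold = 5.0,
                       config = variant_config()) {
  .mnf_truncated(pm, noise, snr_threshold, config, "approx",
                 function(sw, k) truncated_eig_krylov(
                   sw, k, depth = config$krylov_blocks, seed = config$seed))
}

#' Rand MNF
#'
#' As [mnf_approx()], but the truncated decomposition is the randomized
#' sketch of [randomized_svd_sym()] -- faster and memory-light, at the
#' price of a small stochastic reconstruction error (the `1 + epsilon`
#' Frobenius guarantee).
#'
#' @inheritParams mnf_approx
#' @return as [mnf_approx()]; the model additionally records the sketch
#'   `seed`.
#' @export
mnf_rand <- function(pm, noise, snr_threshold = 5.0,
                     config = variant_config()) {
  .mnf_truncated(pm, noise, snr_threshold, config, "rand",
                 function(sw, k) randomized_svd_sym(sw, k, config))
}
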