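#' Data covariance of a pixel matrix
#'
#' Per-band means and the unbiased sample covariance
#' `Sigma_Y = Yc' Yc / (N - 1)` of the centred pixel spectra.  Under the
#' additive model `Y = D + delta` with uncorrelated signal and noise,
#' `Sigma_Y = Sigma_D + Sigma_delta`.
#'
#' @param pm a [pixel_matrix()].
#' @return a `covariance_pair` list: `sigma_Y`, `mean_Y`, `n_pixels`.
#' @export
compute_covariance <- function(pm) {
  stopifnot(inherits(pm, "pixel_matrix"))
  n <- nrow(pm$Y)
  if (n < 2) stop("covariance needs at least 2 pixels")
  mu <- colMeans(pm$Y)
  Yc <- sweep(pm$Y, 2, mu)
  sig <- crossprod(Yc) / (n - 1)
  structure(list(sigma_Y = (sig + t(sig)) / 2, mean_Y = mu, n_pixels = n),
            class = "covariance_pair")
}

#' Noise-whiten a data covariance
#'
#' Rotates `Sigma_Y` into the retained noise eigenbasis and rescales by
#' the inverse square roots of the noise eigenvalues:
#' `Sigma_W = Lambda^{-1/2} E' Sigma_Y E Lambda^{-1/2}`.  In these
#' coordinates the noise contribution is the identity, so the subsequent
#' eigendecomposition orders components by SNR rather than raw variance.
#'
#' @param cov a `covariance_pair` from [compute_covariance()].
#' @param noise a [noise_model].
#' @return an `m x m` symmetric matrix (`m` = retained noise dimension).
#' @export
whiten_covariance <- function(cov, noise) {
  stopifnot(inherits(cov, "covariance_pair"), inherits(noise, "noise_model"))
  if (nrow(noise$E) != nrow(cov$sigma_Y))
    stop("noise model and covariance have different band counts")
  lam <- noise$lambda_delta
  if (any(lam <= 1e-12 * max(lam)))
    stop("noise eigenvalues below the numerical floor; re-run decompose_noise")
  Es <- sweep(noise$E, 2, sqrt(lam), "/")   # E Lambda^{-1/2}
  W <- crossprod(Es, cov$sigma_Y %*% Es)
  (W + t(W)) / 2
}

#' Eigendecomposition of the whitened covariance
#'
#' Eigenvalues sorted descending (`lambda_1 >= ... >= lambda_m`), so
#' components show decreasing image quality; each `lambda_i` equals
#' band SNR + 1 in MNF space.  Tiny negative eigenvalues from roundoff
#' are clamped to zero; eigenvector signs follow the fixed convention of
#' [decompose_noise()].
#'
#' @param sigma_W symmetric matrix from [whiten_covariance()].
#' @return a list with orthonormal `G` and descending `lambda_mnf`.
#' @export
mnf_eigendecomposition <- function(sigma_W) {
  sigma_W <- as.matrix(sigma_W)
  amax <- max(abs(sigma_W))
  if (amax > 0 && max(abs(sigma_W - t(sigma_W))) > 1e-8 * amax)
    stop("`sigma_W` is not symmetric within tolerance")
  eg <- eigen((sigma_W + t(sigma_W)) / 2, symmetric = TRUE)
  list(G = fix_eigvec_signs(eg$vectors), lambda_mnf = pmax(eg$values, 0))
}

#' Automatic band selection by the Rose criterion
#'
#' Imaging rule of thumb: an SNR of at least 5 is needed to distinguish
#' image features with certainty.  In MNF space the SNR of component `i`
#' is `lambda_i - 1`, so the selected count is the number of components
#' with `lambda_i - 1 >= snr_threshold` (boundary inclusive).  If nothing
#' qualifies, `K = 1` is returned with a warning rather than an empty
#' basis.
#'
#' @param lambda_mnf descending MNF eigenvalues.
#' @param snr_threshold Rose threshold, default 5.0.
#' @return integer `K >= 1`.
#' @export
select_bands <- function(lambda_mnf, snr_threshold = 5.0) {
  if (length(lambda_mnf) == 0) stop("empty eigenvalue vector")
  if (is.unsorted(rev(lambda_mnf), strictly = FALSE))
    stop("`lambda_mnf` must be sorted descending")
  K <- sum(lambda_mnf - 1 >= snr_threshold)
  if (K == 0L) {
    warning("no MNF component reaches SNR >= ", snr_threshold,
            "; keeping the single best component")
    K <- 1L
  }
  as.integer(K)
}

#' Build forward and inverse MNF transforms
#'
#' Inversion-free construction: the forward transform is
#' `Phi_hat = E Lambda_delta^{-1/2} G[, 1:K]` and the inverse transform
#' `Phi_tilde = E Lambda_delta^{+1/2} G[, 1:K]`, so reconstruction is the
#' product `Y_c Phi_hat Phi_tilde'` with no matrix inversion anywhere --
#' only diagonal reciprocal square roots and transposes.
#'
#' @param noise a [noise_model].
#' @param G eigenvector matrix from [mnf_eigendecomposition()] (or a
#'   truncated variant), `m x Kbar`.
#' @param lambda_mnf the corresponding descending eigenvalues.
#' @param K number of retained bands, `1 <= K <= ncol(G)`.
#' @param mean_Y per-band mean used for centring/re-centring.
#' @param snr_threshold,variant metadata stored in the model.
#' @return an `mnf_model`: `phi_forward` and `phi_inverse` (`S x K`),
#'   `lambda_mnf`, `K`, `R_rank`, `snr_threshold`, `variant`, `mean_Y`,
#'   `G`.
#' @export
build_transforms <- function(noise, G, lambda_mnf, K, mean_Y,
                             snr_threshold = 5.0, variant = "standard") {
  stopifnot(inherits(noise, "noise_model"))
  K <- as.integer(K)
  if (K < 1 || K > ncol(G)) stop("K out of range [1, ", ncol(G), "]")
  if (nrow(G) != length(noise$lambda_delta))
    stop("G rows must match retained noise dimension")
  sl <- sqrt(noise$lambda_delta)
  GK <- G[, seq_len(K), drop = FALSE]
  phi_forward <- noise$E %*% (GK / sl)   # E Lambda^{-1/2} G R
  phi_inverse <- noise$E %*% (GK * sl)   # E Lambda^{+1/2} G R
  structure(list(phi_forward = phi_forward, phi_inverse = phi_inverse,
                 lambda_mnf = lambda_mnf, K = K, R_rank = K,
                 snr_threshold = snr_threshold, variant = variant,
                 mean_Y = mean_Y, G = G),
            class = "mnf_model")
}

#' @export
print.mnf_model <- function(x, ...) {
  cat(sprintf("<mnf_model> variant: %s, S = %d bands, K = %d selected (threshold SNR >= %g)\n",
              x$variant, nrow(x$phi_forward), x$K, x$snr_threshold))
  cat(sprintf("  top eigenvalues: %s\n",
              paste(signif(utils::head(x$lambda_mnf, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Project pixels into MNF space
#'
#' Returns `(Y - mean_Y) Phi_hat`; column `i` is the `i`-th eigenimage
#' (flattened), in decreasing SNR order.
#'
#' @param pm a [pixel_matrix()].
#' @param model an `mnf_model`.
#' @return an `N x K` matrix.
#' @export
forward_transform <- function(pm, model) {
  stopifnot(inherits(pm, "pixel_matrix"), inherits(model, "mnf_model"))
  if (ncol(pm$Y) != nrow(model$phi_forward))
    stop("band count of data and model differ")
  sweep(pm$Y, 2, model$mean_Y) %*% model$phi_forward
}

#' Reconstruct a denoised pixel matrix
#'
#' `D_hat = (Y - mean_Y) Phi_hat Phi_tilde' + mean_Y`: forward transform,
#' implicit zeroing of all bands beyond `K`, inversion-free back
#' projection, and mean restoration.  With `K = S` and the full noise
#' basis retained this is the identity up to roundoff.
#'
#' @param pm a [pixel_matrix()].
#' @param model an `mnf_model`.
#' @return a denoised [pixel_matrix()] of the same shape.
#' @export
inverse_reconstruct <- function(pm, model) {
  scores <- forward_transform(pm, model)
  D_hat <- sweep(scores %*% t(model$phi_inverse), 2, model$mean_Y, "+")
  pixel_matrix(D_hat, pm$width, pm$height, pm$wavenumbers)
}

#' Per-band SNR and noise-fraction diagnostics
#'
#' In MNF space the SNR of component `i` is `lambda_i - 1` and its noise
#' fraction is `1 / lambda_i`.  If a pixel matrix is supplied, an
#' `eigenimage(i)` accessor returning the `W x H` image of component `i`
#' is attached (the classical visual check of decreasing image quality).
#'
#' @param model an `mnf_model`.
#' @param pm optionally, the [pixel_matrix()] the model was fitted to.
#' @return a `band_diagnostics` list: `snr`, `noise_fraction`,
#'   `lambda`, `K`, and `eigenimage` (or `NULL`).
#' @export
band_diagnostics <- function(model, pm = NULL) {
  stopifnot(inherits(model, "mnf_model"))
  lam <- model$lambda_mnf
  eig_fun <- NULL
  if (!is.null(pm)) {
    scores <- forward_transform(pm, model)
    W <- pm$width; H <- pm$height
    eig_fun <- function(i) {
      if (i < 1 || i > ncol(scores)) stop("band index out of range")
      matrix(scores[, i], W, H)
    }
  }
  structure(list(snr = lam - 1, noise_fraction = 1 / lam, lambda = lam,
                 K = model$K, eigenimage = eig_fun),
            class = "band_diagnostics")
}

#' Standard MNF denoising
#'
#' The reference implementation: full eigendecomposition of the whitened
#' covariance, automatic band selection, full `N x m` MNF-space
#' projection, and inversion-free reconstruction with all bands beyond
#' `K` zeroed.
#'
#' @param pm a [pixel_matrix()].
#' @param noise a [noise_model].
#' @param snr_threshold Rose threshold for [select_bands()].
#' @param K optional fixed band count overriding automatic selection.
#' @return a list: `model` (an `mnf_model`), `denoised`
#'   (a [pixel_matrix()]), `covariance` (the `covariance_pair`).
#' @export
mnf_standard <- function(pm, noise, snr_threshold = 5.0, K = NULL) {
  cov <- compute_covariance(pm)
  sigma_W <- whiten_covariance(cov, noise)
  eg <- mnf_eigendecomposition(sigma_W)
  if (is.null(K)) K <- select_bands(eg$lambda_mnf, snr_threshold)
  model <- build_transforms(noise, eg$G, eg$lambda_mnf, K, cov$mean_Y,
                            snr_threshold, variant = "standard")
  # standard route: materialize the full MNF-space data, then apply the
  # block-identity truncation R before back-projection
  sl <- sqrt(noise$lambda_delta)
  phi_all <- noise$E %*% (eg$G / sl)
  scores_all <- sweep(pm$Y, 2, cov$mean_Y) %*% phi_all
  D_hat <- scores_all[, seq_len(K), drop = FALSE] %*% t(model$phi_inverse)
  D_hat <- sweep(D_hat, 2, cov$mean_Y, "+")
  list(model = model,
       denoised = pixel_matrix(D_hat, pm$width, pm$height, pm$wavenumbers),
       covariance = cov)
}
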