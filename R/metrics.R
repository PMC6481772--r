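#' Method noise of a denoiser
#'
#' The elementwise difference `noisy - denoised`.  For an ideal denoiser
#' the method noise resembles pure noise and carries no structure.
#'
#' @param noisy,denoised [pixel_matrix()] objects of identical shape.
#' @return a [pixel_matrix()].
#' @export
method_noise <- function(noisy, denoised) {
  stopifnot(inherits(noisy, "pixel_matrix"), inherits(denoised, "pixel_matrix"))
  if (!identical(dim(noisy$Y), dim(denoised$Y)))
    stop("noisy and denoised matrices have different shapes")
  pixel_matrix(noisy$Y - denoised$Y, noisy$width, noisy$height,
               noisy$wavenumbers)
}

#' Local structural similarity (SSIM) map
#'
#' Standard SSIM with local means, variances and covariance computed
#' over a Gaussian-weighted window, and stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` where `L` is the dynamic range.
#'
#' @param imageA,imageB numeric matrices of equal shape.
#' @param window odd window size `>= 3` (default 11).
#' @param dynamic_range value range `L`; defaults to `max - min` of
#'   `imageA`.
#' @param sigma Gaussian window width (default 1.5).
#' @return a matrix of SSIM values in `[-1, 1]`, same shape as the
#'   inputs.
#' @export
ssim_map <- function(imageA, imageB, window = 11L, dynamic_range = NULL,
                     sigma = 1.5) {
  imageA <- as.matrix(imageA); imageB <- as.matrix(imageB)
  if (!identical(dim(imageA), dim(imageB)))
    stop("images have different shapes")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (window > min(dim(imageA)))
    stop("window larger than image")
  if (is.null(dynamic_range)) dynamic_range <- diff(range(imageA))
  L <- max(dynamic_range, .Machine$double.eps)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  gf <- function(m) gaussian_filter2d(m, sigma = sigma, size = window)
  muA <- gf(imageA); muB <- gf(imageB)
  vA <- pmax(gf(imageA * imageA) - muA^2, 0)
  vB <- pmax(gf(imageB * imageB) - muB^2, 0)
  cAB <- gf(imageA * imageB) - muA * muB
  ((2 * muA * muB + C1) * (2 * cAB + C2)) /
    ((muA^2 + muB^2 + C1) * (vA + vB + C2))
}

#' Method-noise-image (MNI) score per band
#'
#' No-reference denoising quality: for each band, the SSIM map between
#' the noisy image and its method noise (which should agree only on
#' homogeneous regions) and the SSIM map between the noisy and denoised
#' images (which should agree on structured regions) are correlated;
#' the MNI score of the band is that Pearson correlation.  Lower values
#' indicate better denoising with structure preserved.  Bands where
#' either map is constant are flagged undefined rather than scored 0.
#'
#' @param noisy,denoised [hsi_cube()] objects of identical shape.
#' @param window SSIM window, see [ssim_map()].
#' @param keep_maps if `TRUE`, retain the per-band SSIM maps (memory
#'   heavy for large cubes).
#' @return an `mni_result`: `mni_per_band`, logical `defined`,
#'   `wavenumbers`, and optionally `ssim_map_noise` /
#'   `ssim_map_denoised` (lists of `W x H` maps).
#' @export
mni_per_band <- function(noisy, denoised, window = 11L, keep_maps = FALSE) {
  stopifnot(inherits(noisy, "hsi_cube"), inherits(denoised, "hsi_cube"))
  if (!identical(dim(noisy$data), dim(denoised$data)))
    stop("cubes have different shapes")
  S <- dim(noisy$data)[3]
  mni <- rep(NA_real_, S)
  defined <- rep(FALSE, S)
  maps1 <- if (keep_maps) vector("list", S)
  maps2 <- if (keep_maps) vector("list", S)
  for (i in seq_len(S)) {
    n_img <- noisy$data[, , i]
    d_img <- denoised$data[, , i]
    mn_img <- n_img - d_img
    L <- diff(range(n_img))
    map1 <- ssim_map(n_img, mn_img, window, dynamic_range = L)
    map2 <- ssim_map(n_img, d_img, window, dynamic_range = L)
    if (keep_maps) { maps1[[i]] <- map1; maps2[[i]] <- map2 }
    if (stats::sd(map1) > 0 && stats::sd(map2) > 0) {
      mni[i] <- stats::cor(as.vector(map1), as.vector(map2))
      defined[i] <- TRUE
    }
  }
  structure(list(mni_per_band = mni, defined = defined,
                 wavenumbers = noisy$wavenumbers,
                 ssim_map_noise = maps1, ssim_map_denoised = maps2),
            class = "mni_result")
}

#' Root-mean-square error
#'
#' @param a,b [pixel_matrix()] objects or numeric arrays of equal shape.
#' @return `sqrt(mean((a - b)^2))` over all entries.
#' @export
rmse <- function(a, b) {
  A <- if (inherits(a, "pixel_matrix")) a$Y else as.array(a)
  B <- if (inherits(b, "pixel_matrix")) b$Y else as.array(b)
  if (!identical(dim(A), dim(B))) stop("shapes differ")
  sqrt(mean((A - B)^2))
}

#' Empirical SNR of a reconstruction against ground truth
#'
#' `Var(D) / Var(D_hat - D)` pooled over all entries, in linear units.
#' A zero-residual (perfect) reconstruction reports `Inf`.
#'
#' @param truth a `synthetic_truth` (see [assemble_cube()]).
#' @param denoised a [pixel_matrix()] (or matrix) of the same shape as
#'   `truth$D`.
#' @return a single number (possibly `Inf`).
#' @export
empirical_snr <- function(truth, denoised) {
  stopifnot(inherits(truth, "synthetic_truth"))
  Dh <- if (inherits(denoised, "pixel_matrix")) denoised$Y else
    as.matrix(denoised)
  if (!identical(dim(Dh), dim(truth$D))) stop("shapes differ")
  num <- stats::var(as.vector(truth$D))
  den <- stats::var(as.vector(Dh - truth$D))
  if (den == 0) return(Inf)
  num / den
}
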