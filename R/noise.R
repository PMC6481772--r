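#' Noise covariance model
#'
#' Holds the noise covariance `Sigma_delta` together with its truncated
#' eigendecomposition `E diag(lambda_delta) E^T`, the basis used to
#' whiten the data before the MNF eigenproblem.  Construct with
#' [decompose_noise()]; estimate the covariance with
#' [estimate_noise_shift_difference()] or pass a known one through.
#'
#' @name noise_model
NULL

new_noise_model <- function(sigma_delta, E, lambda_delta, variance_retained,
                            estimator_tag) {
  structure(list(sigma_delta = sigma_delta, E = E,
                 lambda_delta = lambda_delta,
                 variance_retained = variance_retained,
                 estimator_tag = estimator_tag),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> S = %d bands, m = %d retained (%.4g%% variance), estimator: %s\n",
              nrow(x$sigma_delta), length(x$lambda_delta),
              100 * sum(x$lambda_delta) / sum(diag(x$sigma_delta)),
              x$estimator_tag))
  invisible(x)
}

#' Shift-difference estimate of the noise covariance
#'
#' Classical estimator for spatially smooth scenes: differences of
#' spatially adjacent pixel spectra cancel the (smooth) signal and leave
#' twice the noise, so `Cov(y_p - y_q) / 2` over all adjacent pairs
#' estimates `Sigma_delta`.  The difference spectra are mean-centred
#' before the covariance is formed.
#'
#' @param pm a [pixel_matrix()].
#' @param direction `"horizontal"` (adjacent samples within a line) or
#'   `"vertical"` (adjacent lines).
#' @return an `S x S` symmetric matrix.
#' @export
estimate_noise_shift_difference <- function(pm,
                                            direction = c("horizontal",
                                                          "vertical")) {
  stopifnot(inherits(pm, "pixel_matrix"))
  direction <- match.arg(direction)
  W <- pm$width; H <- pm$height; S <- ncol(pm$Y)
  arr <- array(pm$Y, dim = c(W, H, S))
  if (direction == "horizontal") {
    if (W < 2) stop("horizontal shift-difference needs at least 2 samples per line")
    d <- arr[-1, , , drop = FALSE] - arr[-W, , , drop = FALSE]
    dm <- matrix(d, nrow = (W - 1) * H, ncol = S)
  } else {
    if (H < 2) stop("vertical shift-difference needs at least 2 lines")
    d <- arr[, -1, , drop = FALSE] - arr[, -H, , drop = FALSE]
    dm <- matrix(d, nrow = W * (H - 1), ncol = S)
  }
  dm <- sweep(dm, 2, colMeans(dm))
  sig <- crossprod(dm) / (2 * (nrow(dm) - 1))
  (sig + t(sig)) / 2
}

#' Eigendecompose a noise covariance, retaining a variance fraction
#'
#' Eigenvalues are sorted descending and the smallest retained count `m`
#' whose cumulative sum reaches `variance_retained` of the total variance
#' (the trace) is kept; in addition, eigenvalues below a numerical floor
#' of `1e-12 * lambda_max` are always dropped, because the whitening step
#' divides by their square roots.  Retaining less than the full noise
#' space (default 99%) is both a speed and a conditioning device.
#'
#' Eigenvector signs follow a fixed convention (largest-magnitude entry
#' positive) so fitted transforms are reproducible across platforms.
#'
#' @param sigma_delta symmetric positive semidefinite `S x S` matrix.
#' @param variance_retained fraction of total noise variance to keep,
#'   in `(0, 1]`; default 0.99.
#' @param estimator_tag provenance label stored in the model
#'   (`"shift_difference"`, `"provided"` or `"truth"`).
#' @return a [noise_model].
#' @export
decompose_noise <- function(sigma_delta, variance_retained = 0.99,
                            estimator_tag = "provided") {
  sigma_delta <- as.matrix(sigma_delta)
  if (nrow(sigma_delta) != ncol(sigma_delta))
    stop("`sigma_delta` must be square")
  amax <- max(abs(sigma_delta))
  if (amax == 0) stop("noise covariance is identically zero; nothing to whiten")
  if (max(abs(sigma_delta - t(sigma_delta))) > 1e-8 * amax)
    stop("`sigma_delta` is not symmetric within tolerance")
  if (variance_retained <= 0 || variance_retained > 1)
    stop("`variance_retained` must be in (0, 1]")
  sym <- (sigma_delta + t(sigma_delta)) / 2
  eg <- eigen(sym, symmetric = TRUE)
  tot <- sum(diag(sym))
  if (min(eg$values) < -1e-10 * tot)
    stop("`sigma_delta` is not positive semidefinite within tolerance")
  vals <- pmax(eg$values, 0)
  m <- which(cumsum(vals) >= variance_retained * tot - 1e-12 * tot)[1]
  if (is.na(m)) m <- length(vals)
  keep <- seq_len(m)
  floor_val <- 1e-12 * vals[1]
  keep <- keep[vals[keep] > floor_val]
  if (length(keep) == 0) stop("no noise eigenvalue above the numerical floor")
  E <- fix_eigvec_signs(eg$vectors[, keep, drop = FALSE])
  new_noise_model(sym, E, vals[keep], variance_retained, estimator_tag)
}

#' Noise model from synthetic ground truth
#'
#' Passes the generator's true `Sigma_delta` straight into
#' [decompose_noise()], isolating transform correctness from estimator
#' error in validation runs.
#'
#' @param truth a `synthetic_truth` (see [assemble_cube()]).
#' @param variance_retained see [decompose_noise()].
#' @return a [noise_model].
#' @export
noise_model_from_truth <- function(truth, variance_retained = 0.99) {
  stopifnot(inherits(truth, "synthetic_truth"))
  decompose_noise(truth$sigma_delta_true, variance_retained,
                  estimator_tag = "truth")
}

# sign convention: make each column's largest-magnitude entry positive
fix_eigvec_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}
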