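#' Configuration for the synthetic FTIR-like cube generator
#'
#' The generator emulates an infrared tissue image under the additive
#' model `Y = D + delta`: a low-rank signal `D` (smooth endmember spectra
#' built from Gaussian peaks, mixed by spatially smooth abundance maps)
#' plus zero-mean Gaussian noise that is independent across pixels and
#' optionally correlated across bands with a known covariance.
#'
#' Per-component signal-to-noise ratios are defined in the noise-whitened
#' coordinate system (signal variance over noise variance along each MNF
#' component), which is the scale on which automatic band selection
#' operates.
#'
#' @param width,height spatial dimensions (pixels).
#' @param bands number of spectral bands `S`.
#' @param rank true signal rank `r` (number of independent spectral
#'   components); must satisfy `r < S` and `r <= min(width*height, S)`.
#' @param snr per-component SNR targets (length `r`, or a scalar recycled);
#'   all must be positive.
#' @param wavenumber_range spectral axis limits in cm^-1.
#' @param peak_range sub-range of the axis in which Gaussian peaks are
#'   placed; defaults to the full range.  Restricting it leaves the rest
#'   of the axis as signal-free ("IR silent") bands.
#' @param noise covariance family: `"iid"` (sigma^2 I), `"ar1"`
#'   (sigma^2 rho^|i-j|) or `"diag"` (given per-band variances).
#' @param rho AR(1) inter-band correlation, `0 <= rho < 1`.
#' @param noise_sd base noise standard deviation sigma; `0` produces a
#'   noiseless cube (no SNR calibration possible).
#' @param band_variances length-`S` per-band variances for the `"diag"`
#'   family.
#' @param seed master integer seed; all randomness derives from it through
#'   named sub-streams.
#' @return a `synth_config` list.
#' @export
synth_config <- function(width, height, bands, rank,
                         snr = 20,
                         wavenumber_range = c(900, 3800),
                         peak_range = NULL,
                         noise = c("iid", "ar1", "diag"),
                         rho = 0.9,
                         noise_sd = 1,
                         band_variances = NULL,
                         seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(width >= 1, height >= 1, bands >= 2)
  if (rank >= bands || rank > min(width * height, bands))
    stop("rank must satisfy r < S and r <= min(N, S)")
  snr <- rep_len(as.numeric(snr), rank)
  if (any(snr <= 0)) stop("SNR targets must be positive")
  if (rho < 0 || rho >= 1) stop("rho must satisfy 0 <= rho < 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(peak_range)) peak_range <- wavenumber_range
  if (noise == "diag") {
    if (is.null(band_variances) || length(band_variances) != bands ||
        any(band_variances <= 0))
      stop("'diag' noise needs positive `band_variances` of length S")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 bands = as.integer(bands), rank = as.integer(rank),
                 snr = snr, wavenumber_range = as.numeric(wavenumber_range),
                 peak_range = as.numeric(peak_range), noise = noise,
                 rho = rho, noise_sd = noise_sd,
                 band_variances = band_variances, seed = as.integer(seed)),
            class = "synth_config")
}

# spectral axis implied by a config (ascending)
synth_wavenumbers <- function(config) {
  seq(config$wavenumber_range[1], config$wavenumber_range[2],
      length.out = config$bands)
}

#' Generate endmember spectra
#'
#' Each endmember is a nonnegative sum of 3--8 Gaussian peaks with widths
#' 10--60 cm^-1 placed inside `config$peak_range`.  The stack is checked
#' for linear independence (smallest singular value > 1e-6 times the
#' largest) and redrawn a bounded number of times if degenerate.
#'
#' @param config a [synth_config()].
#' @return an `r x S` matrix of spectra.
#' @export
generate_spectra <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  wn <- synth_wavenumbers(config)
  r <- config$rank
  for (attempt in 0:49) {
    spectra <- with_seed(split_seed(config$seed, "spectra", attempt), {
      t(vapply(seq_len(r), function(i) {
        n_peaks <- sample(3:8, 1L)
        centers <- stats::runif(n_peaks, config$peak_range[1],
                                config$peak_range[2])
        widths <- stats::runif(n_peaks, 10, 60)
        heights <- stats::runif(n_peaks, 0.2, 1)
        colSums(heights * exp(-outer(centers, wn, "-")^2 /
                                (2 * widths^2)))
      }, numeric(config$bands)))
    })
    sv <- svd(spectra, nu = 0, nv = 0)$d
    if (length(sv) == r && sv[r] > 1e-6 * sv[1]) return(spectra)
  }
  stop("could not generate ", r, " linearly independent spectra; ",
       "reduce rank or widen the peak range")
}

#' Generate spatially smooth abundance maps
#'
#' Low-frequency nonnegative random fields: white noise blurred with a
#' Gaussian filter whose width scales with the image, then shifted into
#' `[0.05, 1.05]`.  Each map has nonzero variance (unless `constant`).
#'
#' @param config a [synth_config()].
#' @param constant if `TRUE`, every map is the constant 1 (useful for
#'   noise-estimator tests on signal-free scenes).
#' @return an `N x r` matrix, `N = width * height`.
#' @export
generate_abundances <- function(config, constant = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  N <- config$width * config$height
  r <- config$rank
  if (constant) return(matrix(1, N, r))
  sigma <- max(1.5, min(config$width, config$height) / 8)
  with_seed(split_seed(config$seed, "abundances"), {
    A <- matrix(0, N, r)
    for (i in seq_len(r)) {
      f <- matrix(stats::rnorm(N), config$width, config$height)
      f <- gaussian_filter2d(f, sigma = sigma,
                             size = min(2L * ceiling(3 * sigma) + 1L,
                                        2L * min(config$width,
                                                 config$height) - 1L))
      if (stats::sd(f) > 0) f <- (f - min(f)) / (max(f) - min(f))
      A[, i] <- as.vector(f) + 0.05
    }
    A
  })
}

# covariance matrix of the configured noise family (includes noise_sd^2)
noise_covariance <- function(config) {
  S <- config$bands
  base <- switch(config$noise,
    iid = diag(S),
    ar1 = config$rho^abs(outer(seq_len(S), seq_len(S), "-")),
    diag = diag(config$band_variances / max(config$band_variances)))
  # for "diag", band_variances set the profile; noise_sd^2 scales the max
  config$noise_sd^2 * base
}

#' Assemble a synthetic cube with known ground truth
#'
#' Builds the noiseless signal `D = abundances %*% spectra`, rescales its
#' components in noise-whitened coordinates so the realized per-component
#' SNRs match `config$snr` exactly, draws noise from the configured
#' Gaussian covariance, and returns the cube together with a
#' `synthetic_truth` record.
#'
#' The emitted truth is self-consistent by construction:
#' `Y - D == delta` bit-exactly, and `D` has matrix rank exactly `r`.
#'
#' @param abundances `N x r` matrix (see [generate_abundances()]).
#' @param spectra `r x S` matrix (see [generate_spectra()]).
#' @param config a [synth_config()].
#' @return a list with elements `cube` (an [hsi_cube()]) and `truth`
#'   (class `synthetic_truth`: fields `D`, `delta`, `sigma_delta_true`,
#'   `rank`, `component_snrs`).
#' @export
assemble_cube <- function(abundances, spectra, config) {
  stopifnot(inherits(config, "synth_config"))
  N <- config$width * config$height
  r <- config$rank
  S <- config$bands
  if (nrow(abundances) != N || ncol(abundances) != r)
    stop("abundances must be N x r")
  if (nrow(spectra) != r || ncol(spectra) != S)
    stop("spectra must be r x S")
  wn <- synth_wavenumbers(config)

  D <- abundances %*% spectra
  sigma_delta <- noise_covariance(config)

  if (config$noise_sd > 0) {
    # calibrate per-component SNRs in the whitened frame.  D's centered
    # part factors as Ac %*% spectra, so the SVD of the whitened signal
    # is computed from small factors (r x S), never from N x S.
    mu_D <- colMeans(D)
    Ac <- sweep(abundances, 2, colMeans(abundances))
    ed <- eigen(sigma_delta, symmetric = TRUE)
    if (min(ed$values) <= 0) stop("noise covariance must be positive definite")
    Ewh <- sweep(ed$vectors, 2, sqrt(ed$values), "/")   # E Lambda^{-1/2}
    qa <- qr(Ac)
    if (qa$rank < r)
      stop("requested SNRs unreachable: abundance maps are rank deficient")
    M <- qr.R(qa) %*% (spectra %*% Ewh)                  # r x S
    sv <- svd(M)
    if (min(sv$d) <= 1e-12 * max(sv$d))
      stop("requested SNRs unreachable: signal has zero variance along ",
           "some component")
    d_target <- sqrt(config$snr * (N - 1))
    Dw <- qr.Q(qa) %*% (sv$u %*% (d_target * t(sv$v)))   # N x S, whitened
    Eun <- sweep(ed$vectors, 2, sqrt(ed$values), "*")    # E Lambda^{+1/2}
    D <- Dw %*% t(Eun) + rep(1, N) %*% t(mu_D)
    delta <- with_seed(split_seed(config$seed, "noise"), {
      matrix(stats::rnorm(N * S), N, S) %*% chol(sigma_delta)
    })
  } else {
    delta <- matrix(0, N, S)
  }

  Y <- D + delta
  delta <- Y - D  # re-derive so Y - D == delta holds bit-exactly
  cube <- matrix_to_cube(pixel_matrix(Y, config$width, config$height, wn))
  truth <- structure(list(D = D, delta = delta,
                          sigma_delta_true = sigma_delta,
                          rank = r, component_snrs = config$snr),
                     class = "synthetic_truth")
  list(cube = cube, truth = truth)
}

#' Simulate a synthetic FTIR-like cube end to end
#'
#' Convenience wrapper chaining [generate_spectra()],
#' [generate_abundances()] and [assemble_cube()].
#'
#' @param config a [synth_config()].
#' @return as [assemble_cube()].
#' @export
simulate_hsi <- function(config) {
  assemble_cube(generate_abundances(config), generate_spectra(config), config)
}
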