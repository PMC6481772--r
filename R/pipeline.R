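#' Run configuration for the denoising pipeline
#'
#' Collects every tunable of the simulate -> denoise -> evaluate
#' workflow.  Round-trips losslessly through a DCF text file via
#' [write_run_config()] / [read_run_config()].
#'
#' @param input path to an ENVI header of the noisy cube.
#' @param output path for the denoised ENVI header.
#' @param method `"standard"`, `"fast"`, `"approx"` or `"rand"`.
#' @param snr_threshold Rose threshold (default 5.0).
#' @param noise_estimator `"shift-diff"`, `"provided"` or `"truth"`.
#' @param noise_cov path to a CSV holding a provided `S x S`
#'   `Sigma_delta` (for `noise_estimator = "provided"`).
#' @param truth path to an RDS holding a `synthetic_truth` (for
#'   `noise_estimator = "truth"`).
#' @param variance_retained noise-eigenvalue retention (default 0.99).
#' @param khat_fraction,epsilon,seed variant parameters, see
#'   [variant_config()].
#' @param window SSIM window for evaluation.
#' @param model_out optional RDS path for the fitted model.
#' @param diagnostics_out optional CSV path for per-band diagnostics.
#' @return a `run_config` list.
#' @export
run_config <- function(input = NULL, output = NULL,
                       method = c("standard", "fast", "approx", "rand"),
                       snr_threshold = 5.0,
                       noise_estimator = c("shift-diff", "provided", "truth"),
                       noise_cov = NULL, truth = NULL,
                       variance_retained = 0.99,
                       khat_fraction = 0.03, epsilon = 0.1, seed = 42L,
                       window = 11L, model_out = NULL,
                       diagnostics_out = NULL) {
  method <- match.arg(method)
  noise_estimator <- match.arg(noise_estimator)
  if (snr_threshold < 0) stop("snr_threshold must be non-negative")
  if (variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must be in (0, 1]")
  structure(list(input = input, output = output, method = method,
                 snr_threshold = snr_threshold,
                 noise_estimator = noise_estimator, noise_cov = noise_cov,
                 truth = truth, variance_retained = variance_retained,
                 khat_fraction = khat_fraction, epsilon = epsilon,
                 seed = as.integer(seed), window = as.integer(window),
                 model_out = model_out, diagnostics_out = diagnostics_out),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path text file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  flat <- lapply(config, function(x)
    if (is.null(x)) "" else
      if (is.numeric(x)) sprintf("%.17g", x) else as.character(x))
  write.dcf(as.data.frame(flat, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  d <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  blank_to_null <- function(x) if (identical(x, "")) NULL else x
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  run_config(
    input = blank_to_null(d$input), output = blank_to_null(d$output),
    method = d$method, snr_threshold = num(d$snr_threshold),
    noise_estimator = d$noise_estimator,
    noise_cov = blank_to_null(d$noise_cov),
    truth = blank_to_null(d$truth),
    variance_retained = num(d$variance_retained),
    khat_fraction = num(d$khat_fraction), epsilon = num(d$epsilon),
    seed = as.integer(num(d$seed)), window = as.integer(num(d$window)),
    model_out = blank_to_null(d$model_out),
    diagnostics_out = blank_to_null(d$diagnostics_out))
}

# resolve the configured noise model for a pixel matrix
.resolve_noise <- function(pm, config) {
  switch(config$noise_estimator,
    "shift-diff" = decompose_noise(
      estimate_noise_shift_difference(pm, "horizontal"),
      config$variance_retained, estimator_tag = "shift_difference"),
    "provided" = {
      if (is.null(config$noise_cov))
        stop("noise_estimator 'provided' needs `noise_cov`")
      sig <- as.matrix(utils::read.csv(config$noise_cov, header = FALSE))
      dimnames(sig) <- NULL
      decompose_noise(sig, config$variance_retained,
                      estimator_tag = "provided")
    },
    "truth" = {
      if (is.null(config$truth))
        stop("noise_estimator 'truth' needs `truth` (RDS path)")
      noise_model_from_truth(readRDS(config$truth),
                             config$variance_retained)
    })
}

.fit_variant <- function(pm, noise, config) {
  vc <- variant_config(khat_fraction = config$khat_fraction,
                       epsilon = config$epsilon, seed = config$seed)
  switch(config$method,
    standard = mnf_standard(pm, noise, config$snr_threshold),
    fast = mnf_fast(pm, noise, config$snr_threshold),
    approx = mnf_approx(pm, noise, config$snr_threshold, vc),
    rand = mnf_rand(pm, noise, config$snr_threshold, vc))
}

#' Denoise a cube end to end
#'
#' Reads the input cube, resolves the noise model, fits the configured
#' MNF variant, and writes the denoised cube plus optional model and
#' per-band diagnostics files.  Partial outputs are removed on error.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `model`, `denoised` (pixel matrix) and
#'   `diagnostics` (data frame: band, wavenumber, lambda, snr,
#'   noise_fraction).
#' @export
run_denoise <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outputs <- c(config$output, config$model_out, config$diagnostics_out)
  ok <- FALSE
  on.exit(if (!ok) {
    existing <- outputs[!vapply(outputs, is.null, logical(1))]
    suppressWarnings(file.remove(existing[file.exists(existing)]))
  })
  cube <- read_envi(config$input)
  pm <- cube_to_matrix(cube)
  noise <- .resolve_noise(pm, config)
  fit <- .fit_variant(pm, noise, config)
  model <- fit$model
  message(sprintf(
    "fastMNF: S=%d bands, m=%d retained noise dims%s, selected K=%d (SNR >= %g), variant=%s, seed=%d",
    ncol(pm$Y), length(noise$lambda_delta),
    if (!is.null(model$khat)) sprintf(", Khat=%d", model$khat) else "",
    model$K, config$snr_threshold, model$variant, config$seed))
  diag_df <- data.frame(
    band = seq_along(model$lambda_mnf),
    lambda = model$lambda_mnf,
    snr = model$lambda_mnf - 1,
    noise_fraction = 1 / model$lambda_mnf)
  if (!is.null(config$output))
    write_envi(matrix_to_cube(fit$denoised), config$output)
  if (!is.null(config$model_out)) saveRDS(model, config$model_out)
  if (!is.null(config$diagnostics_out))
    utils::write.csv(diag_df, config$diagnostics_out, row.names = FALSE)
  ok <- TRUE
  invisible(list(model = model, denoised = fit$denoised,
                 diagnostics = diag_df))
}

#' Compare the four MNF variants on one cube
#'
#' Fits standard, fast, approx and rand MNF with a shared noise model
#' and reports, per variant: the selected `K`, the RMSE between the
#' noisy input and the reconstruction, the relative Frobenius deviation
#' from the standard reconstruction, and (optionally) the mean defined
#' MNI score.
#'
#' @param config a [run_config()] (`method` is ignored).
#' @param mni if `TRUE`, compute the per-band MNI for every variant
#'   (costly for large cubes).
#' @param report_out optional CSV path for the comparison table.
#' @return a data frame with one row per variant.
#' @export
run_compare <- function(config, mni = FALSE, report_out = NULL) {
  stopifnot(inherits(config, "run_config"))
  cube <- read_envi(config$input)
  pm <- cube_to_matrix(cube)
  noise <- .resolve_noise(pm, config)
  methods <- c("standard", "fast", "approx", "rand")
  fits <- lapply(methods, function(m) {
    cfg <- config; cfg$method <- m
    .fit_variant(pm, noise, cfg)
  })
  names(fits) <- methods
  std <- fits$standard$denoised$Y
  std_norm <- sqrt(sum(std^2))
  rows <- lapply(methods, function(m) {
    dn <- fits[[m]]$denoised
    data.frame(
      variant = m,
      K = fits[[m]]$model$K,
      rmse_to_noisy = rmse(pm, dn),
      rel_delta_vs_standard = sqrt(sum((dn$Y - std)^2)) / std_norm,
      mean_mni = if (mni) {
        r <- mni_per_band(cube, matrix_to_cube(dn), config$window)
        mean(r$mni_per_band[r$defined])
      } else NA_real_)
  })
  report <- do.call(rbind, rows)
  if (!is.null(report_out))
    utils::write.csv(report, report_out, row.names = FALSE)
  report
}
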