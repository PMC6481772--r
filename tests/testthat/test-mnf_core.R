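test_that("compute_covariance matches hand computation and the additive model", {
  pm <- pixel_matrix(matrix(c(0, 2, 0, 2), 2, 2), width = 2, height = 1)
  cov <- compute_covariance(pm)
  expect_equal(cov$mean_Y, c(1, 1))
  expect_equal(cov$sigma_Y, matrix(2, 2, 2))
  expect_equal(cov$n_pixels, 2)

  const <- pixel_matrix(matrix(7, 6, 3), width = 3, height = 2)
  expect_equal(compute_covariance(const)$sigma_Y, matrix(0, 3, 3))
  expect_error(compute_covariance(pixel_matrix(matrix(1, 1, 3), 1, 1)),
               "at least 2")

  # Sigma_Y ~ Sigma_D + Sigma_delta for independent draws at N = 1e5
  sim <- gapped_sim(seed = 41, W = 400, H = 250, S = 10, r = 2)
  sY <- compute_covariance(sim$pm)$sigma_Y
  Dc <- sweep(sim$truth$D, 2, colMeans(sim$truth$D))
  sD <- crossprod(Dc) / (nrow(Dc) - 1)
  tot <- sD + sim$truth$sigma_delta_true
  expect_lt(sqrt(sum((sY - tot)^2)) / sqrt(sum(tot^2)), 0.05)
})

test_that("whitening turns the noise contribution into the identity", {
  S <- 10
  cp <- function(sig) structure(list(sigma_Y = sig, mean_Y = rep(0, S),
                                     n_pixels = 100),
                                class = "covariance_pair")
  nm_id <- decompose_noise(diag(S), 1.0)
  expect_equal(whiten_covariance(cp(diag(S)), nm_id), diag(S))

  sig_d <- random_spd(S, seed = 6)
  nm <- decompose_noise(sig_d, 1.0)
  W2 <- whiten_covariance(cp(2 * sig_d), nm)
  expect_lt(max(abs(W2 - 2 * diag(S))), 1e-8)

  # dense oracle with explicit inversion
  sig_y <- random_spd(S, seed = 7)
  eg <- eigen(sig_d, symmetric = TRUE)
  ihalf <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  # oracle in the eigenbasis: Lambda^{-1/2} E' Sigma_Y E Lambda^{-1/2}
  oracle <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors) %*% sig_y %*%
    eg$vectors %*% diag(1 / sqrt(eg$values))
  got <- whiten_covariance(cp(sig_y), nm)
  # same quadratic form up to the sign convention on E's columns
  signs <- diag(crossprod(eg$vectors, nm$E))
  oracle_signed <- diag(signs) %*% oracle %*% diag(signs)
  expect_lt(max(abs(got - oracle_signed)), 1e-10)
})

test_that("the MNF eigenproblem sorts by SNR and reconstructs", {
  eg <- mnf_eigendecomposition(diag(c(5, 2, 9)))
  expect_equal(eg$lambda_mnf, c(9, 5, 2))
  expect_equal(abs(eg$G), diag(3)[, c(3, 1, 2)])   # signed permutation

  eg2 <- mnf_eigendecomposition(diag(4))
  expect_equal(eg2$lambda_mnf, rep(1, 4))

  A <- random_spd(15, seed = 9); A <- (A + t(A)) / 2
  eg3 <- mnf_eigendecomposition(A)
  rec <- eg3$G %*% (eg3$lambda_mnf * t(eg3$G))
  expect_lt(sqrt(sum((rec - A)^2)) / sqrt(sum(A^2)), 1e-10)
  expect_lt(max(abs(crossprod(eg3$G) - diag(15))), 1e-8)
  expect_error(mnf_eigendecomposition(matrix(1:9, 3, 3)), "symmetric")
})

test_that("Rose-criterion band selection thresholds inclusively and never returns 0", {
  expect_equal(select_bands(c(101, 10, 6.01, 5.99, 1.5), 5.0), 3)
  expect_equal(select_bands(6.0, 5.0), 1)   # boundary: SNR 5.0 >= 5.0
  expect_warning(K <- select_bands(c(2, 1.5, 1), 5.0), "SNR")
  expect_equal(K, 1)
  expect_error(select_bands(numeric(0)), "empty")
  expect_error(select_bands(c(1, 5, 2)), "descending")
})

test_that("transform construction obeys the algebraic identities", {
  S <- 12; K <- 4
  nm_id <- decompose_noise(diag(S), 1.0)
  G <- qr.Q(qr(fastMNF:::with_seed(3, matrix(rnorm(S * S), S))))
  lam <- sort(runif(S, 1, 30), decreasing = TRUE)
  model <- build_transforms(nm_id, G, lam, K, rep(0, S))
  # identity noise: forward and inverse transforms coincide (no rescaling;
  # the tied noise eigenbasis E is an arbitrary rotation, so compare to
  # E G rather than to G directly)
  expect_equal(model$phi_forward, model$phi_inverse)
  expect_equal(model$phi_forward, nm_id$E %*% G[, 1:K])
  expect_lt(max(abs(crossprod(model$phi_forward) - diag(K))), 1e-10)

  # general SPD noise: Phi_tilde' Phi_hat = I_K; full rank: Phi_hat Phi_tilde' = I_S
  nm <- decompose_noise(random_spd(S, seed = 5), 1.0)
  mk <- build_transforms(nm, G, lam, K, rep(0, S))
  expect_lt(max(abs(crossprod(mk$phi_inverse, mk$phi_forward) - diag(K))),
            1e-8)
  mfull <- build_transforms(nm, G, lam, S, rep(0, S))
  expect_lt(max(abs(mfull$phi_forward %*% t(mfull$phi_inverse) - diag(S))),
            1e-8)
  expect_error(build_transforms(nm, G, lam, S + 1, rep(0, S)), "out of range")
})

test_that("MNF-space columns carry the stated variances and eigenimage 1 leads in SNR", {
  s <- default_gapped()
  fit <- default_standard_fit()
  scores <- forward_transform(s$pm, fit$model)
  expect_equal(ncol(scores), fit$model$K)
  v <- apply(scores, 2, var)
  expect_equal(v, fit$model$lambda_mnf[seq_len(fit$model$K)],
               tolerance = 0.02)

  # empirical per-eigenimage SNR (projected truth vs projected noise):
  # with distinct component SNRs, eigenimage 1 must lead
  s2 <- gapped_sim(seed = 23, W = 30, H = 30, S = 100, r = 4,
                   snr = c(80, 40, 20, 10))
  fit2 <- mnf_standard(s2$pm, s2$noise)
  phi <- fit2$model$phi_forward
  snr_emp <- vapply(seq_len(ncol(phi)), function(i) {
    var(s2$truth$D %*% phi[, i]) / var(s2$truth$delta %*% phi[, i])
  }, 0)
  expect_equal(which.max(snr_emp), 1L)
  expect_true(all(diff(snr_emp) < 0))
})

test_that("full-band reconstruction is the identity and truncation denoises", {
  s <- default_gapped()
  nm_full <- noise_model_from_truth(s$truth, variance_retained = 1.0)
  fit_full <- mnf_standard(s$pm, nm_full, K = ncol(s$pm$Y))
  expect_lt(rel_frob(fit_full$denoised, s$pm), 1e-8)

  fit <- default_standard_fit()
  expect_equal(fit$model$K, 5)
  D <- pixel_matrix(s$truth$D, s$pm$width, s$pm$height)
  expect_lt(rmse(fit$denoised, D), rmse(s$pm, D))
})

test_that("the inversion-free factorization equals the naive inverse-based transform", {
  # random 20-band instances; oracle uses Y Phi R Phi^{-1} with solve()
  for (seed in 1:5) {
    S <- 20; N <- 150
    Y <- fastMNF:::with_seed(seed, matrix(rnorm(N * S), N, S))
    pm <- pixel_matrix(Y, width = N, height = 1)
    nm <- decompose_noise(random_spd(S, seed = seed + 100), 1.0)
    cov <- compute_covariance(pm)
    eg <- mnf_eigendecomposition(whiten_covariance(cov, nm))
    K <- 5
    model <- build_transforms(nm, eg$G, eg$lambda_mnf, K, cov$mean_Y)
    ours <- inverse_reconstruct(pm, model)$Y

    Phi <- nm$E %*% diag(1 / sqrt(nm$lambda_delta)) %*% eg$G
    R <- diag(c(rep(1, K), rep(0, S - K)))
    Yc <- sweep(Y, 2, cov$mean_Y)
    naive <- Yc %*% Phi %*% R %*% solve(Phi)
    naive <- sweep(naive, 2, cov$mean_Y, "+")
    expect_lt(rel_frob(ours, naive), 1e-8)
  }
})

test_that("band diagnostics expose SNR, noise fraction and eigenimages", {
  s <- default_gapped()
  fit <- default_standard_fit()
  d <- band_diagnostics(fit$model, s$pm)
  expect_equal(d$snr, fit$model$lambda_mnf - 1)
  expect_equal(d$noise_fraction, 1 / fit$model$lambda_mnf)
  expect_true(all(diff(d$snr) <= 1e-8))
  i1 <- d$eigenimage(1)
  expect_identical(dim(i1), c(30L, 30L))
  expect_error(d$eigenimage(fit$model$K + 1), "out of range")

  # lambda = 6 -> SNR 5, NF 1/6; lambda = 1 -> SNR 0; lambda = 2 -> NF 0.5
  m <- fit$model; m$lambda_mnf <- c(6, 2, 1); m$K <- 3L
  d2 <- band_diagnostics(m)
  expect_equal(d2$snr, c(5, 1, 0))
  expect_equal(d2$noise_fraction, c(1 / 6, 0.5, 1))
})

test_that("fitted models honour the whitening and diagonalization contracts", {
  s <- default_gapped()
  fit <- default_standard_fit()
  phi <- fit$model$phi_forward
  K <- fit$model$K
  expect_lt(max(abs(crossprod(phi, s$noise$sigma_delta %*% phi) - diag(K))),
            1e-6)
  sigma_Y <- fit$covariance$sigma_Y
  expect_lt(max(abs(crossprod(phi, sigma_Y %*% phi) -
                      diag(fit$model$lambda_mnf[1:K], K))), 1e-6)
})
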