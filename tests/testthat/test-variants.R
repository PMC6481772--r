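test_that("block-Krylov truncated eigendecomposition matches the dense solver", {
  # diagonal case
  kr <- truncated_eig_krylov(diag(10:1), khat = 3)
  expect_equal(kr$lambda, c(10, 9, 8), tolerance = 1e-8)

  # 120x120 SPD with a clean spectral gap at rank 5, large enough that
  # the Krylov path (not the dense fallback) is exercised
  n <- 120
  spec <- fastMNF:::with_seed(12, c(seq(20, 12, length.out = 5),
                                    runif(n - 5, 0, 1)))
  Q <- qr.Q(qr(fastMNF:::with_seed(13, matrix(rnorm(n * n), n))))
  A <- Q %*% (spec * t(Q)); A <- (A + t(A)) / 2
  full <- eigen(A, symmetric = TRUE)
  kr2 <- truncated_eig_krylov(A, khat = 5)
  expect_equal(kr2$lambda, full$values[1:5], tolerance = 1e-6)
  expect_lt(max(abs(crossprod(kr2$G) - diag(5))), 1e-8)
  # subspace alignment: projector distance
  P1 <- tcrossprod(kr2$G)
  P2 <- tcrossprod(full$vectors[, 1:5])
  expect_lt(max(abs(P1 - P2)), 1e-6)

  # degenerate truncation khat = S falls back to the dense path
  B <- random_spd(50, seed = 12)
  kr3 <- truncated_eig_krylov(B, khat = 50)
  expect_equal(kr3$lambda, eigen(B, symmetric = TRUE)$values,
               tolerance = 1e-8)
  expect_error(truncated_eig_krylov(B, khat = 0), "out of range")
  expect_error(truncated_eig_krylov(B, khat = 51), "out of range")
})

test_that("randomized decomposition meets the 1+eps Frobenius bound and is seed-deterministic", {
  # exact rank-3 PSD: reconstruction error collapses to ~0
  B <- fastMNF:::with_seed(5, matrix(rnorm(100 * 3), 100, 3))
  A3 <- tcrossprod(B)
  rz <- randomized_svd_sym(A3, khat = 3)
  expect_lt(sqrt(sum((A3 - rz$G %*% (rz$lambda * t(rz$G)))^2)), 1e-8)

  # 1 + eps bound (eps = 0.1) against the dense best-rank oracle, 20 seeds
  A <- random_spd(100, seed = 3)
  full <- eigen(A, symmetric = TRUE)
  best10 <- sqrt(sum(full$values[11:100]^2))
  hits <- vapply(1:20, function(s) {
    r <- randomized_svd_sym(A, khat = 10, variant_config(seed = s))
    err <- sqrt(sum((A - r$G %*% (r$lambda * t(r$G)))^2))
    err <= (1 + 0.1) * best10
  }, logical(1))
  expect_gte(sum(hits), 19)

  r1 <- randomized_svd_sym(A, khat = 10, variant_config(seed = 7))
  r2 <- randomized_svd_sym(A, khat = 10, variant_config(seed = 7))
  expect_identical(r1, r2)
})

test_that("Fast MNF reproduces standard MNF with K-column storage", {
  s <- default_gapped()
  std <- default_standard_fit()
  fast <- mnf_fast(s$pm, s$noise)
  expect_identical(fast$model$K, std$model$K)
  expect_lt(rel_frob(fast$denoised, std$denoised), 1e-8)
  expect_equal(ncol(fast$model$phi_forward), fast$model$K)
  expect_equal(ncol(forward_transform(s$pm, fast$model)), fast$model$K)
})

test_that("Approx MNF matches standard on well-gapped scenes and records Khat", {
  s <- default_gapped()
  std <- default_standard_fit()
  ap <- mnf_approx(s$pm, s$noise)
  # Khat = ceiling(0.03 * 200) = 6 > K = 5: no saturation
  expect_equal(ap$model$khat, 6L)
  expect_equal(ap$model$K, std$model$K)
  expect_lt(rel_frob(ap$denoised, std$denoised), 1e-6)
  expect_lte(length(ap$model$lambda_mnf), ap$model$khat)
})

test_that("saturated band selection doubles Khat until the cut is genuine", {
  # r = 15 strong components in 300 bands: initial Khat = 9 saturates
  s <- gapped_sim(seed = 6, W = 35, H = 35, S = 300, r = 15)
  std <- mnf_standard(s$pm, s$noise)
  expect_equal(std$model$K, 15L)
  ap <- mnf_approx(s$pm, s$noise)
  expect_equal(ap$model$K, 15L)
  expect_gt(ap$model$khat, 15L)   # 9 -> 18
  expect_lt(rel_frob(ap$denoised, std$denoised), 1e-6)
  rd <- mnf_rand(s$pm, s$noise)
  expect_equal(rd$model$K, 15L)
  expect_lt(rel_frob(rd$denoised, std$denoised), 1e-3)
})

test_that("Rand MNF tracks standard within its stochastic tolerance, deterministically per seed", {
  s <- default_gapped()
  std <- default_standard_fit()
  rd <- mnf_rand(s$pm, s$noise)
  expect_equal(rd$model$K, std$model$K)
  expect_lt(rel_frob(rd$denoised, std$denoised), 1e-3)
  expect_identical(rd$model$seed, 42L)
  rd2 <- mnf_rand(s$pm, s$noise)
  expect_identical(rd$denoised$Y, rd2$denoised$Y)

  # space contract: truncated decompositions never hold an m x m basis
  expect_lte(ncol(rd$model$G), rd$model$khat)
  ap <- mnf_approx(s$pm, s$noise)
  expect_lte(ncol(ap$model$G), ap$model$khat)
})

test_that("per-band MNI of Rand stays close to standard on signal-bearing bands", {
  s <- default_gapped()
  std <- default_standard_fit()
  rd <- mnf_rand(s$pm, s$noise)
  cube <- matrix_to_cube(s$pm)
  bands <- order(apply(s$truth$D, 2, var), decreasing = TRUE)[1:12]
  sub <- function(pm) {
    hsi_cube(array(pm$Y, c(30, 30, 200))[, , sort(bands)],
             wavenumbers = s$pm$wavenumbers[sort(bands)])
  }
  m_std <- mni_per_band(sub(s$pm), sub(std$denoised))
  m_rd <- mni_per_band(sub(s$pm), sub(rd$denoised))
  ok <- m_std$defined & m_rd$defined
  expect_true(all(abs(m_std$mni_per_band[ok] - m_rd$mni_per_band[ok]) < 0.05))
})
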