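# Shared fixtures, memoised so expensive simulations run once per session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# random SPD matrix with eigenvalues bounded away from zero
random_spd <- function(n, seed = 1) {
  fastMNF:::with_seed(seed, {
    A <- matrix(rnorm(n * n), n, n)
    crossprod(A) / n + diag(n)
  })
}

# random small cube for round-trip tests
random_cube <- function(W, H, S, seed = 1) {
  fastMNF:::with_seed(seed, {
    hsi_cube(array(rnorm(W * H * S), dim = c(W, H, S)),
             wavenumbers = seq(900, 1800, length.out = S))
  })
}

# a well-gapped synthetic scene: r strong components, everything else noise
gapped_sim <- function(seed = 3, W = 30, H = 30, S = 200, r = 5, snr = 20,
                       noise = "iid", ...) {
  sim <- simulate_hsi(synth_config(W, H, S, rank = r, snr = snr,
                                   noise = noise, seed = seed, ...))
  sim$pm <- cube_to_matrix(sim$cube)
  sim$noise <- noise_model_from_truth(sim$truth)
  sim
}

default_gapped <- function() fixture("default_gapped", gapped_sim())

default_standard_fit <- function() fixture("default_standard_fit", {
  s <- default_gapped()
  mnf_standard(s$pm, s$noise)
})

# the 10-seed parameter-recovery suite: 40x40 x 200 bands, rank 8, SNR 20
recovery_suite <- function() fixture("recovery_suite", {
  lapply(1:10, function(seed) {
    s <- gapped_sim(seed = seed, W = 40, H = 40, S = 200, r = 8)
    fit <- mnf_standard(s$pm, s$noise)
    list(sim = s, fit = fit)
  })
})

# the large FTIR-scale scene: 50x50 pixels, 1506 bands, 30 components
t1_fit <- function() fixture("t1_fit", {
  cfg <- synth_config(50, 50, 1506, rank = 30, snr = 20, noise = "iid",
                      seed = 1)
  sim <- simulate_hsi(cfg)
  pm <- cube_to_matrix(sim$cube)
  noise <- noise_model_from_truth(sim$truth)
  list(sim = sim, pm = pm, noise = noise, fit = mnf_standard(pm, noise))
})

rel_frob <- function(A, B) {
  a <- if (inherits(A, "pixel_matrix")) A$Y else A
  b <- if (inherits(B, "pixel_matrix")) B$Y else B
  sqrt(sum((a - b)^2)) / sqrt(sum(b^2))
}
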