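test_that("mvar_stability matches the analytic AR(2) root modulus", {
  net <- uncoupled_network(1)
  # roots of z^2 - 1.5 z + 0.75: modulus sqrt(0.75)
  expect_equal(mvar_stability(net), sqrt(0.75), tolerance = 1e-9)
  expect_equal(mvar_stability(net, ar = c(0, 0)), 0)
  expect_equal(mvar_stability(net, ar = c(2, 0)), 2, tolerance = 1e-9)
  expect_error(simulate_mvar(net, 2, 50, ar = c(2, 0)), "unstable.*2\\.0")
})

test_that("stock networks are stable and carry the published couplings", {
  expect_lt(mvar_stability(network_mvar_3roi()), 1)
  expect_lt(mvar_stability(network_mvar_5roi()), 1)
  e5 <- network_mvar_5roi()$edges
  expect_equal(sort(e5$C), sort(c(0.1, 0.1, 0.1, 0.1, -0.1)))
  expect_equal(network_nmm_3roi()$edges$C, rep(200, 3))
})

test_that("delay bookkeeping converts samples to milliseconds at fs = 250", {
  expect_equal(delay_samples_to_ms(12, 250), 48)
  expect_equal(delay_samples_to_ms(1, 250), 4)
})

test_that("the AR(2) source has its spectral peak at 20 +/- 1 Hz", {
  x <- simulate_mvar(uncoupled_network(1), n_trials = 100, n_samples = 250,
                     seed = 1)
  expect_equal(psd_peak_hz(x), 20, tolerance = 1)
})

test_that("uncoupled MVAR ROIs are uncorrelated", {
  x <- simulate_mvar(uncoupled_network(3), n_trials = 50, n_samples = 250,
                     seed = 2)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    r <- cor(as.vector(x$data[, pr[1], ]), as.vector(x$data[, pr[2], ]))
    expect_lt(abs(r), 3 / sqrt(50 * 250))
  }
})

test_that("MVAR simulation is reproducible given a seed", {
  net <- ar_pair_network()
  a <- simulate_mvar(net, 3, 100, seed = 5)
  b <- simulate_mvar(net, 3, 100, seed = 5)
  expect_identical(a$data, b$data)
})

test_that("the sigmoid passes through e0 at v0 and the state count is 6/ROI", {
  p <- nmm_params()
  expect_equal(nmm_sigmoid(p$v0, p), p$e0)
  expect_equal(nmm_sigmoid(1e6, p), 2 * p$e0, tolerance = 1e-9)
  expect_equal(nmm_state_count(network_nmm_5roi()), 30L)
  expect_equal(nmm_state_count(network_nmm_3roi()), 18L)
  expect_equal(nmm_state_count(2), 12L)
})

test_that("noise-free uncoupled neural masses follow identical trajectories", {
  net <- uncoupled_network(2, "nmm")
  p <- nmm_params(sigma_w = 0, dt = 0.2)
  x <- simulate_nmm_sdde(net, n_trials = 1, epoch_s = 1, params = p,
                         burn_in_s = 1, seed = 1)
  expect_equal(x$data[1, 1, ], x$data[1, 2, ], tolerance = 1e-12)
  # deterministic run is reproducible without any seed
  y <- simulate_nmm_sdde(net, n_trials = 1, epoch_s = 1, params = p,
                         burn_in_s = 1)
  expect_equal(x$data, y$data, tolerance = 1e-12)
})

test_that("the stochastic neural-mass pair oscillates in the alpha band", {
  net <- fc_network(data.frame(from = 2, to = 1, C = 200, delay = 20),
                    n_roi = 2, kind = "nmm")
  x <- simulate_nmm_sdde(net, n_trials = 4, epoch_s = 4, seed = 3)
  expect_equal(psd_peak_hz(x), 10.87, tolerance = 0.75)
})

test_that("halving the integration step moves the spectral peak < 0.5 Hz", {
  net <- uncoupled_network(1, "nmm")
  peaks <- vapply(c(0.1, 0.05), function(dt) {
    x <- simulate_nmm_sdde(net, n_trials = 2, epoch_s = 4,
                           params = nmm_params(dt = dt), seed = 4)
    psd_peak_hz(x)
  }, numeric(1))
  expect_lt(abs(diff(peaks)), 0.5)
})

test_that("band-limited pairs respect the ideal-filter contract", {
  # with delay 0 no slicing occurs, so the source must be exactly
  # band-limited on the analysis grid
  x <- simulate_bandlimited_pair(bandwidth = 2, delay = 0, beta = 1,
                                 n_trials = 20, seed = 5,
                                 return_sources = TRUE)
  src <- attr(x, "sources")
  spec <- epoch_fft(center_epochs(src))
  px <- colMeans(Mod(matrix(spec$coeffs[, 1, ], 20))^2)
  inband <- spec$freqs >= 14.625 & spec$freqs <= 16.625
  expect_lt(sum(px[!inband]) / sum(px[inband]), 1e-6)
})

test_that("the cross-spectral phase at the centre frequency matches 2 pi f d / fs", {
  x <- simulate_bandlimited_pair(bandwidth = 2, delay = 4, beta = 1,
                                 n_trials = 100, seed = 6,
                                 return_sources = TRUE)
  spec <- epoch_fft(center_epochs(attr(x, "sources")))
  cs <- cross_spectrum(spec, "x", "y")
  bin <- which.min(abs(cs$freqs - 15.625))
  expected <- 2 * pi * 15.625 * 4 / 250   # = pi/2
  expect_equal(abs(Arg(cs$S_uv[bin])), expected, tolerance = 0.2)
})

test_that("zero delay leaves no imaginary cross-spectrum", {
  x <- simulate_bandlimited_pair(bandwidth = 2, delay = 0, beta = 1,
                                 n_trials = 100, seed = 7)
  spec <- epoch_fft(center_epochs(x))
  cs <- cross_spectrum(spec, "u", "v")
  expect_lt(max(abs(Im(cs$S_uv))) / max(Mod(cs$S_uv)), 1e-9)
})

test_that("beta = 1 returns the normalised noiseless mixture exactly", {
  x <- simulate_bandlimited_pair(delay = 2, beta = 1, n_trials = 3,
                                 seed = 8, return_sources = TRUE)
  src <- attr(x, "sources")
  cf <- mixing_coeffs()
  for (tr in 1:3) {
    Ys <- rbind(cf$a1 * src$data[tr, 1, ] + cf$b1 * src$data[tr, 2, ],
                cf$a2 * src$data[tr, 1, ] + cf$b2 * src$data[tr, 2, ])
    expect_equal(x$data[tr, , ], Ys / sqrt(sum(Ys^2)), tolerance = 1e-12)
  }
})

test_that("band outside Nyquist and oversized delays are rejected", {
  expect_error(simulate_bandlimited_pair(center = 124, bandwidth = 10,
                                         n_samples = 250, fs = 250),
               "inside")
  expect_error(simulate_bandlimited_pair(delay = 300, n_samples = 250),
               "delay")
})
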