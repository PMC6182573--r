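test_that("center_epochs removes per-epoch means and is idempotent", {
  # hand oracle: [[1,2,3],[4,5,6]] -> [[-1,0,1],[-1,0,1]]
  x <- epoched_signals(array(c(1, 4, 2, 5, 3, 6), c(2, 1, 3)), fs = 10)
  cx <- center_epochs(x)
  expect_equal(cx$data[1, 1, ], c(-1, 0, 1))
  expect_equal(cx$data[2, 1, ], c(-1, 0, 1))

  # constant channel becomes all-zero
  k <- epoched_signals(array(5, c(1, 1, 8)), fs = 10)
  expect_equal(max(abs(center_epochs(k)$data)), 0)

  # zero-mean sine unchanged
  s <- sin(2 * pi * (0:63) / 8)
  xs <- epoched_signals(array(s, c(1, 1, 64)), fs = 64)
  expect_equal(center_epochs(xs)$data[1, 1, ], s, tolerance = 1e-12)

  # residual mean is ~0 for random data
  r <- center_epochs(white_epochs(4, 3, 50, seed = 7))
  expect_lt(max(abs(apply(r$data, c(1, 2), mean))), 1e-12 * sd(r$data))
})

test_that("non-finite input is rejected with a located diagnostic", {
  d <- array(rnorm(2 * 2 * 10), c(2, 2, 10))
  d[2, 1, 3] <- NaN
  expect_error(epoched_signals(d, fs = 100), "trial 2, channel 1, sample 3")
})

test_that("epoch_fft produces the one-sided grid with fs/Nt resolution", {
  x <- white_epochs(2, 1, 250, fs = 250, seed = 3)
  spec <- epoch_fft(center_epochs(x))
  expect_length(spec$freqs, 126)
  expect_equal(spec$freqs, 0:125)
  expect_equal(unique(diff(spec$freqs)), 1)
})

test_that("a pure cosine at an exact bin concentrates its energy there", {
  nt <- 64; fs <- 64
  x <- epoched_signals(array(cos(2 * pi * 10 * (0:(nt - 1)) / fs), c(1, 1, nt)),
                       fs = fs)
  spec <- epoch_fft(x)
  p <- Mod(spec$coeffs[1, 1, ])^2
  expect_equal(spec$freqs[which.max(p)], 10)
  expect_lt(sum(p[-which.max(p)]) / max(p), 1e-20)
})

test_that("one-sided spectrum satisfies Parseval's identity", {
  for (seed in 1:5) {
    nt <- sample(c(50, 63, 64, 101), 1)
    x <- white_epochs(1, 1, nt, fs = nt, seed = seed)
    spec <- epoch_fft(x)
    p <- Mod(spec$coeffs[1, 1, ])^2
    w <- rep(2, length(p)); w[1] <- 1
    if (nt %% 2 == 0) w[length(p)] <- 1
    expect_equal(sum(w * p) / nt, sum(x$data^2), tolerance = 1e-9)
  }
})

test_that("cross_spectrum matches direct summation and its symmetries", {
  spec <- toy_ensemble(n_trials = 2, n_freq = 5, seed = 11)
  cs <- cross_spectrum(spec, "u", "v")
  # brute-force oracle: loop over trials
  U <- spec$coeffs[, 1, ]; V <- spec$coeffs[, 2, ]
  manual <- (U[1, ] * Conj(V[1, ]) + U[2, ] * Conj(V[2, ])) / 2
  expect_equal(cs$S_uv, manual, tolerance = 1e-12)
  expect_equal(cs$S_uu, Re((U[1, ] * Conj(U[1, ]) + U[2, ] * Conj(U[2, ])) / 2),
               tolerance = 1e-12)

  # self cross-spectrum is the (real) auto-spectrum
  self <- cross_spectrum(spec, "u", "u")
  expect_equal(Im(self$S_uv), rep(0, 5), tolerance = 1e-12)
  expect_equal(Re(self$S_uv), self$S_uu, tolerance = 1e-12)

  # sign linearity: v = -u
  neg <- spec
  neg$coeffs[, 2, ] <- -spec$coeffs[, 1, ]
  csn <- cross_spectrum(neg, "u", "v")
  expect_equal(csn$S_uv, -csn$S_uu + 0i, tolerance = 1e-12)

  # Hermitian symmetry under channel swap
  swap <- cross_spectrum(spec, "v", "u")
  expect_equal(swap$S_uv, Conj(cs$S_uv), tolerance = 1e-12)

  expect_error(cross_spectrum(spec, "u", "nope"), "unknown channel")
})

test_that("complex coherence is bounded, scale-invariant and Hermitian", {
  spec <- toy_ensemble(n_trials = 6, n_freq = 9, seed = 5)
  C <- complex_coherence(cross_spectrum(spec, "u", "v"))
  expect_true(all(Mod(C) <= 1 + 1e-9))

  # scale invariance under c > 0 on one channel
  sc <- spec; sc$coeffs[, 1, ] <- 3.7 * sc$coeffs[, 1, ]
  expect_equal(complex_coherence(cross_spectrum(sc, "u", "v")), C,
               tolerance = 1e-12)

  # swap conjugates
  expect_equal(complex_coherence(cross_spectrum(spec, "v", "u")), Conj(C),
               tolerance = 1e-12)
})

test_that("coherence degenerate cases behave as specified", {
  spec <- toy_ensemble(n_trials = 4, n_freq = 6, seed = 9)
  # identical channels -> 1 at all bins with power
  dup <- spec; dup$coeffs[, 2, ] <- dup$coeffs[, 1, ]
  C <- complex_coherence(cross_spectrum(dup, "u", "v"))
  expect_equal(C, rep(1 + 0i, 6), tolerance = 1e-12)

  # single trial: |C| = 1 everywhere (degenerate estimator)
  one <- toy_ensemble(n_trials = 1, n_freq = 7, seed = 2)
  C1 <- complex_coherence(cross_spectrum(one, "u", "v"))
  expect_equal(Mod(C1), rep(1, 7), tolerance = 1e-9)

  # zero-power bin -> 0 with warning
  z <- spec; z$coeffs[, , 3] <- 0
  expect_warning(Cz <- complex_coherence(cross_spectrum(z, "u", "v")),
                 "zero auto-spectral power")
  expect_identical(Cz[3], 0 + 0i)
})

test_that("small-sample coherence bias of independent noise is ~1/sqrt(N)", {
  # Monte-Carlo check against the permutation-free analytic magnitude
  N <- 100
  x <- white_epochs(N, 2, 64, fs = 64, seed = 21)
  spec <- epoch_fft(center_epochs(x))
  C <- suppressWarnings(complex_coherence(cross_spectrum(spec, 1, 2)))
  m <- mean(Mod(C)[-1])
  expect_gt(m, 0.3 / sqrt(N))
  expect_lt(m, 3 / sqrt(N))
})
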