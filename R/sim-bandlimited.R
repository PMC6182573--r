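#' Simulate a band-limited noise pair observed through sensor mixing
#'
#' Model-free ground truth for phase-lag experiments: per trial, `x(t)` is
#' white Gaussian noise passed through a zero-phase ideal band-pass (a
#' frequency-domain mask keeping `center +/- bandwidth/2`), and
#' `y(t) = x(t - delay)` is its delayed copy (implemented by generating
#' `n_samples + delay` points and slicing, so no wrap-around artefact). The
#' sources are mixed into two sensors `u = a1 x + b1 y`, `v = a2 x + b2 y`
#' and white measurement noise is blended in with the Frobenius-normalised
#' convex combination
#' `Y = beta * Ys/||Ys|| + (1 - beta) * U/||U||` per trial.
#'
#' At `center = 15.625` Hz and `fs = 250`, delays of 0, 2, 4, 8, 16, 32
#' samples correspond to phase differences of 0, pi/4, pi/2, pi, 2pi, 4pi
#' at the centre frequency.
#'
#' @param center centre frequency in Hz (default 15.625 = 1000/64).
#' @param bandwidth pass-band width in Hz (band is `center +/- bandwidth/2`).
#' @param delay transmission delay in samples (`y` lags `x`).
#' @param beta SNR mixing weight in `[0, 1]`; 0.9, 0.5, 0.1 emulate roughly
#'   +20, 0, -20 dB.
#' @param coeffs a [mixing_coeffs] set (sensor-noise sds are ignored here;
#'   noise enters through `beta`).
#' @param n_trials,n_samples,fs epoch geometry (defaults 100 trials of 1 s at
#'   250 Hz).
#' @param seed integer seed.
#' @param return_sources also return the unmixed `(x, y)` pair.
#' @return An [epoched_signals] with channels `u`, `v` (and, if requested, an
#'   attribute `"sources"` holding the `(x, y)` pair).
#' @export
simulate_bandlimited_pair <- function(center = 15.625, bandwidth = 2,
                                      delay = 8, beta = 0.9,
                                      coeffs = mixing_coeffs(),
                                      n_trials = 100, n_samples = 250,
                                      fs = 250, seed = NULL,
                                      return_sources = FALSE) {
  stopifnot(bandwidth > 0, beta >= 0, beta <= 1, delay >= 0)
  if (delay >= n_samples) stop("delay must be smaller than n_samples")
  lo <- center - bandwidth / 2
  hi <- center + bandwidth / 2
  if (lo <= 0 || hi >= fs / 2)
    stop("pass-band must lie strictly inside (0, fs/2)")
  ntot <- n_samples + delay
  f <- (0:(ntot - 1)) * fs / ntot
  f <- pmin(f, fs - f)                    # two-sided grid folded to [0, fs/2]
  mask <- as.numeric(f >= lo & f <= hi)
  with_seed(seed, {
    dat <- array(0, c(n_trials, 2L, n_samples))
    src <- if (return_sources) array(0, c(n_trials, 2L, n_samples)) else NULL
    for (tr in seq_len(n_trials)) {
      w <- rnorm(ntot)
      xf <- Re(fft(fft(w) * mask, inverse = TRUE)) / ntot
      x <- xf[(delay + 1):ntot]
      y <- xf[seq_len(n_samples)]
      Ys <- rbind(coeffs$a1 * x + coeffs$b1 * y,
                  coeffs$a2 * x + coeffs$b2 * y)
      U <- matrix(rnorm(2L * n_samples), 2L)
      dat[tr, , ] <- beta * Ys / frobenius(Ys) + (1 - beta) * U / frobenius(U)
      if (return_sources) src[tr, , ] <- rbind(x, y)
    }
    out <- epoched_signals(dat, fs = fs, channel_ids = c("u", "v"))
    if (return_sources)
      attr(out, "sources") <- epoched_signals(src, fs = fs,
                                              channel_ids = c("x", "y"))
    out
  })
}

frobenius <- function(m) sqrt(sum(m^2))
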