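# shared fixtures, all generated in code

# deterministic pseudo-random spectral ensemble [n_trials x 2 x n_freq]
toy_ensemble <- function(n_trials = 3, n_freq = 8, seed = 42, fs = 2 * (n_freq - 1)) {
  co <- eiconn:::with_seed(seed, {
    array(complex(real = rnorm(n_trials * 2 * n_freq),
                  imaginary = rnorm(n_trials * 2 * n_freq)),
          c(n_trials, 2, n_freq))
  })
  structure(list(coeffs = co, freqs = seq(0, fs / 2, length.out = n_freq),
                 fs = fs, n_trials = as.integer(n_trials),
                 nt = 2L * (n_freq - 1L), channel_ids = c("u", "v")),
            class = "spectral_ensemble")
}

# independent white-noise epochs
white_epochs <- function(n_trials, n_channels, n_samples, fs = 250, seed = 1) {
  eiconn:::with_seed(seed, {
    epoched_signals(array(rnorm(n_trials * n_channels * n_samples),
                          c(n_trials, n_channels, n_samples)), fs = fs)
  })
}

# coupled two-source AR network (y -> x with delay, coupling 0.5)
ar_pair_network <- function(delay = 3, C = 0.5) {
  fc_network(data.frame(from = 2, to = 1, C = C, delay = delay),
             n_roi = 2, kind = "mvar")
}

uncoupled_network <- function(n_roi, kind = "mvar") {
  fc_network(data.frame(from = integer(), to = integer(),
                        C = numeric(), delay = numeric()),
             n_roi = n_roi, kind = kind)
}

# frequency of the maximum of a trial-averaged power spectrum, DC excluded
psd_peak_hz <- function(epochs) {
  spec <- epoch_fft(center_epochs(epochs))
  psd <- rep(0, length(spec$freqs))
  for (ch in seq_along(spec$channel_ids)) {
    psd <- psd + colMeans(Mod(matrix(spec$coeffs[, ch, ], spec$n_trials))^2)
  }
  spec$freqs[-1][which.max(psd[-1])]
}
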