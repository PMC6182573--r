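#' Jansen-Rit neural-mass parameters
#'
#' Standard parameter set for the Jansen-Rit cortical-column model plus the
#' additions needed for the delayed stochastic variant: a Wiener-increment
#' scale and the Euler-Maruyama step size.
#'
#' @param A,a excitatory synaptic gain (mV) and rate constant (1/s).
#' @param B,b inhibitory synaptic gain (mV) and rate constant (1/s).
#' @param e0 half of the maximum firing rate (1/s).
#' @param v0 sigmoid midpoint potential (mV).
#' @param rho sigmoid slope (1/mV).
#' @param C_conn global connectivity constant; `C1..C4` default to the usual
#'   `(C, 0.8C, 0.25C, 0.25C)` proportions.
#' @param C1,C2,C3,C4 intra-column connectivity constants.
#' @param I mean input drive to the excitatory interneurons (1/s); 220
#'   places the column in its alpha-rhythm regime (~10.87 Hz).
#' @param sigma_w Wiener process scale. The default 2.5 is the largest value
#'   (on a calibration grid, see `scripts/calibrate_sigma_w.R`) that keeps
#'   the trial-averaged spectral peak within 10.87 +/- 0.5 Hz.
#' @param dt integration step in ms. Default 0.05 ms; halving it moves the
#'   spectral peak by < 0.5 Hz (numerical-convergence contract).
#' @return A named list of class `nmm_params`.
#' @export
nmm_params <- function(A = 3.25, a = 100, B = 22, b = 50,
                       e0 = 2.5, v0 = 6, rho = 0.56,
                       C_conn = 135, C1 = C_conn, C2 = 0.8 * C_conn,
                       C3 = 0.25 * C_conn, C4 = 0.25 * C_conn,
                       I = 220, sigma_w = 2.5, dt = 0.05) {
  stopifnot(a > 0, b > 0, dt > 0, sigma_w >= 0)
  structure(list(A = A, a = a, B = B, b = b, e0 = e0, v0 = v0, rho = rho,
                 C1 = C1, C2 = C2, C3 = C3, C4 = C4, I = I,
                 sigma_w = sigma_w, dt = dt),
            class = "nmm_params")
}

#' Jansen-Rit sigmoid firing-rate function
#'
#' `S(v) = 2 e0 / (1 + exp(-rho (v - v0)))`; `S(v0) = e0`.
#'
#' @param v membrane potential (mV), vectorised.
#' @param params an [nmm_params] list.
#' @return Firing rate (1/s).
#' @export
nmm_sigmoid <- function(v, params = nmm_params()) {
  2 * params$e0 / (1 + exp(-params$rho * (v - params$v0)))
}

#' Number of state variables of the assembled SDDE system
#'
#' Six first-order equations per ROI (three potentials and their
#' velocities), so 18 states for 3 ROIs and 30 for 5.
#'
#' @param network an [fc_network] (or an integer ROI count).
#' @return Integer state count.
#' @export
nmm_state_count <- function(network) {
  n <- if (inherits(network, "fc_network")) network$n_roi else as.integer(network)
  6L * n
}

#' Simulate a delayed stochastic Jansen-Rit network
#'
#' Integrates the network of stochastic delay differential equations by
#' Euler-Maruyama at step `params$dt` (ms): six states per ROI, with each
#' network edge adding `C * y1(t - tau)` to the excitatory-interneuron drive
#' of its target and a Wiener increment (scaled by `A a sigma_w sqrt(dt)`)
#' perturbing the same equation. The local potential `x2 - x3` is recorded,
#' low-pass filtered and decimated to `fs_out`, and the initial
#' `burn_in_s` seconds are discarded. Epochs are simulated independently
#' with initial-state-valued (zero) delay buffers.
#'
#' @param network an [fc_network] of kind `"nmm"` (delays in ms).
#' @param n_trials number of epochs.
#' @param epoch_s epoch length kept, in seconds.
#' @param fs_out output sampling rate in Hz (default 250).
#' @param params an [nmm_params] list.
#' @param burn_in_s transient discarded at the start of every epoch (s).
#' @param strict_printed use `-a^2 x3` instead of the standard `-b^2 x3`
#'   leak term in the inhibitory velocity equation (an alternative published
#'   form of the system; the default keeps the standard Jansen-Rit rate
#'   constant).
#' @param seed integer seed (ambient RNG restored afterwards).
#' @return An [epoched_signals] of local potentials, one channel per ROI.
#' @export
simulate_nmm_sdde <- function(network, n_trials = 100, epoch_s = 1,
                              fs_out = 250, params = nmm_params(),
                              burn_in_s = 2, strict_printed = FALSE,
                              seed = NULL) {
  stopifnot(inherits(network, "fc_network"), network$kind == "nmm",
            n_trials >= 1, epoch_s > 0, fs_out > 0)
  dt_s <- params$dt / 1000
  fs_sim <- 1 / dt_s
  if (abs(fs_sim - round(fs_sim)) > 1e-6 || round(fs_sim) %% fs_out != 0)
    stop("1000/dt must be an integer multiple of fs_out")
  fs_sim <- round(fs_sim)
  total_s <- burn_in_s + epoch_s
  n_steps <- round(total_s * fs_sim)
  e <- network$edges
  delay_steps <- if (nrow(e) > 0L) as.integer(round(e$delay / params$dt)) else integer()
  par <- unlist(params[c("A", "a", "B", "b", "e0", "v0", "rho",
                         "C1", "C2", "C3", "C4")])
  k <- network$n_roi
  raw <- with_seed(seed, {
    nmm_integrate_cpp(k, n_trials, n_steps,
                      as.integer(e$from) - 1L, as.integer(e$to) - 1L,
                      as.numeric(e$C), delay_steps,
                      par, rep(params$I, k), params$sigma_w, dt_s,
                      strict_printed)
  })
  raw <- array(raw, c(n_steps, k, n_trials))
  n_keep <- round(epoch_s * fs_out)
  out <- array(0, c(n_trials, k, n_keep))
  burn_out <- round(burn_in_s * fs_out)
  for (tr in seq_len(n_trials)) {
    for (r in seq_len(k)) {
      z <- decimate_series(raw[, r, tr], fs_sim, fs_out)
      out[tr, r, ] <- z[(burn_out + 1):(burn_out + n_keep)]
    }
  }
  epoched_signals(out, fs = fs_out, channel_ids = network$roi_ids)
}

# multi-stage decimation: FIR stages down to 4*fs_out, then an 8th-order
# Butterworth low-pass at 0.4*fs_out (100 Hz for fs_out = 250) applied
# forward-backward, then stride-4 downsampling
decimate_series <- function(z, fs_in, fs_out) {
  stopifnot(fs_in %% fs_out == 0)
  mid <- 4 * fs_out
  q <- fs_in / mid
  if (q != round(q)) stop("fs_in must be a multiple of 4*fs_out")
  q <- as.integer(q)
  while (q > 1L) {
    step <- max(factors_leq(q, 8L))
    z <- signal::decimate(z, step, ftype = "fir")
    q <- q %/% step
  }
  bt <- signal::butter(8, (0.4 * fs_out) / (mid / 2))
  z <- signal::filtfilt(bt, z)
  z[seq(1, length(z), by = 4L)]
}

factors_leq <- function(q, m) {
  f <- seq_len(min(q, m))
  f[q %% f == 0L]
}
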