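#' Trial-averaged cross- and auto-spectra of a channel pair
#'
#' The cross-spectrum is the epoch average `S_uv(f) = mean_n U_n(f) V_n*(f)`;
#' the auto-spectra `S_uu`, `S_vv` use the same average with the channel
#' paired with itself.
#'
#' @param spec a `spectral_ensemble` from [epoch_fft()].
#' @param ch_u,ch_v channel ids (names or indices).
#' @return An object of class `cross_spectrum`: complex curve `S_uv`, real
#'   non-negative curves `S_uu`, `S_vv`, and `freqs`.
#' @export
cross_spectrum <- function(spec, ch_u, ch_v) {
  stopifnot(inherits(spec, "spectral_ensemble"))
  U <- coeff_matrix(spec, ch_u)
  V <- coeff_matrix(spec, ch_v)
  structure(list(S_uv = colMeans(U * Conj(V)),
                 S_uu = colMeans(Mod(U)^2),
                 S_vv = colMeans(Mod(V)^2),
                 freqs = spec$freqs,
                 n_trials = spec$n_trials,
                 pair = c(as.character(ch_u), as.character(ch_v))),
            class = "cross_spectrum")
}

#' Complex coherence from a cross-spectrum
#'
#' `C_uv(f) = S_uv(f) / sqrt(S_uu(f) S_vv(f))`. Bins where either
#' auto-spectrum vanishes (e.g. the DC bin after centring) are set to 0 and a
#' single warning reports how many bins were affected.
#'
#' @param cs a `cross_spectrum`.
#' @param warn emit the zero-power warning (set `FALSE` in tight loops).
#' @return Complex vector over `cs$freqs` with `|C_uv| <= 1` up to round-off.
#' @export
complex_coherence <- function(cs, warn = TRUE) {
  stopifnot(inherits(cs, "cross_spectrum"))
  den <- sqrt(cs$S_uu * cs$S_vv)
  ok <- den > 0
  out <- complex(length.out = length(den))
  out[ok] <- cs$S_uv[ok] / den[ok]
  if (warn && any(!ok)) {
    warning(sum(!ok), " bin(s) with zero auto-spectral power; coherence set to 0 there",
            call. = FALSE)
  }
  out
}

#' Discrete analytic signal of a real sequence
#'
#' Standard frequency-domain construction: double the positive-frequency DFT
#' coefficients, zero the negative ones (DC, and Nyquist for even length, are
#' kept unscaled) and invert. Columns of a matrix are processed
#' independently. No padding is applied by default; `pad = "reflect"`
#' mirror-pads both ends by half the sequence length before the transform to
#' soften edge effects.
#'
#' @param z real vector (length >= 4) or matrix (columns are sequences).
#' @param pad `"none"` (default) or `"reflect"`.
#' @return Complex vector/matrix of the same size: `z + i * quadrature(z)`.
#' @export
analytic_signal <- function(z, pad = c("none", "reflect")) {
  pad <- match.arg(pad)
  vec <- is.null(dim(z))
  m <- as.matrix(z)
  if (!is.numeric(m) || any(!is.finite(m))) stop("input must be finite and real")
  L0 <- nrow(m)
  if (L0 < 4L) stop("sequence too short for an analytic signal (length >= 4 required)")
  if (pad == "reflect") {
    k <- L0 %/% 2L
    m <- rbind(m[(k + 1):2, , drop = FALSE], m,
               m[(L0 - 1):(L0 - k), , drop = FALSE])
  }
  L <- nrow(m)
  wgt <- numeric(L)
  if (L %% 2L == 0L) {
    wgt[1] <- 1; wgt[L / 2 + 1] <- 1; wgt[2:(L / 2)] <- 2
  } else {
    wgt[1] <- 1; wgt[2:((L + 1) / 2)] <- 2
  }
  h <- mvfft(mvfft(m) * wgt, inverse = TRUE) / L
  if (pad == "reflect") h <- h[(L0 %/% 2L + 1):(L0 %/% 2L + L0), , drop = FALSE]
  if (vec) h[, 1] else h
}

#' Envelope of a real curve via the Hilbert transform
#'
#' Pairs the input with its quadrature (90-degree shifted) counterpart and
#' returns the magnitude of the resulting analytic signal. In this package
#' the input is typically a connectivity curve regarded as a function of
#' frequency, so the "envelope" smooths over the waxing-waning oscillation of
#' the imaginary part across frequency bins.
#'
#' @inheritParams analytic_signal
#' @return An object of class `envelope_curve`: `signal` (the input),
#'   `quadrature`, and `envelope = |signal + i quadrature|`, which dominates
#'   `|signal|` pointwise.
#' @export
hilbert_envelope <- function(z, pad = c("none", "reflect")) {
  h <- analytic_signal(z, pad)
  structure(list(signal = z, quadrature = Im(h), envelope = Mod(h)),
            class = "envelope_curve")
}
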