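#' Connectivity measure curves
#'
#' Computes one of the nine frequency-resolved functional-connectivity
#' measures for a channel pair from an epoch-wise spectral ensemble. All
#' measures derive from the per-trial cross products
#' `P_n(f) = U_n(f) V_n*(f)` and/or the complex coherence `C_uv(f)`:
#'
#' * `COH`:   `|C_uv(f)|`
#' * `PLV`:   `|mean_n exp(i (arg U_n - arg V_n))|`
#' * `ICOH1`: `Im C_uv(f)` (classical imaginary coherence)
#' * `ICOH2`: `mean_n Im P_n(f) / mean_n |H(Im P_n)|(f)` - imaginary
#'   cross-spectrum renormalised by the trial-average Hilbert envelope of the
#'   per-trial imaginary cross-spectrum curves, avoiding the auto-spectral
#'   denominator that volume conduction contaminates
#' * `PLI`:   `|mean_n sgn(Im P_n(f))|` with `sgn(0) = 0`
#' * `WPLI`:  `|mean_n Im P_n(f)| / mean_n |Im P_n(f)|` (0/0 -> 0)
#' * `LCOH`:  `Im{C_uv}^2 / (1 - Re{C_uv}^2)` (lagged coherence; denominator
#'   underflow -> 0)
#' * `EIC1`:  `|H(ICOH1)|(f)` - envelope of the imaginary coherence
#' * `EIC2`:  `|H(ICOH2)|(f)` - envelope of the renormalised version
#'   (the preferred estimator)
#'
#' where `H` is the analytic-signal operator of [hilbert_envelope()] applied
#' along the frequency axis.
#'
#' @param spec a `spectral_ensemble` from [epoch_fft()].
#' @param ch_u,ch_v channel ids (names or indices).
#' @param measure one of `"COH"`, `"PLV"`, `"ICOH1"`, `"ICOH2"`, `"PLI"`,
#'   `"WPLI"`, `"LCOH"`, `"EIC1"`, `"EIC2"` (case-insensitive).
#' @param icoh2_denominator placement of the expectation in the `ICOH2`/
#'   `EIC2` denominator: `"per_trial"` (default) applies the Hilbert envelope
#'   to each trial's imaginary cross-spectrum curve and averages the
#'   magnitudes; `"post_average"` applies it once to the trial-averaged
#'   curve.
#' @param warn emit degenerate-denominator warnings.
#' @return An object of class `fc_curve`: `measure`, real `values` over
#'   `freqs`, and the channel `pair`.
#' @export
measure_curve <- function(spec, ch_u, ch_v, measure,
                          icoh2_denominator = c("per_trial", "post_average"),
                          warn = TRUE) {
  stopifnot(inherits(spec, "spectral_ensemble"))
  measure <- match_measure(measure)
  icoh2_denominator <- match.arg(icoh2_denominator)
  U <- coeff_matrix(spec, ch_u)
  V <- coeff_matrix(spec, ch_v)
  vals <- fc_measure_values(U, V, measure, icoh2_denominator, warn = warn)
  structure(list(measure = measure, values = vals, freqs = spec$freqs,
                 pair = c(as.character(ch_u), as.character(ch_v)),
                 n_trials = spec$n_trials),
            class = "fc_curve")
}

#' @export
print.fc_curve <- function(x, ...) {
  cat(sprintf("<fc_curve> %s for pair (%s, %s), %d bins, peak %.4g at %g Hz\n",
              x$measure, x$pair[1], x$pair[2], length(x$freqs),
              max(abs(x$values)), x$freqs[which.max(abs(x$values))]))
  invisible(x)
}

# core computation on coefficient matrices U, V [trial x freq]
fc_measure_values <- function(U, V, measure,
                              icoh2_denominator = "per_trial", warn = TRUE) {
  P <- U * Conj(V)
  switch(measure,
    COH = Mod(coherence_from_products(U, V, P, warn)),
    ICOH1 = Im(coherence_from_products(U, V, P, warn)),
    LCOH = {
      C <- coherence_from_products(U, V, P, warn)
      den <- 1 - Re(C)^2
      out <- numeric(length(den))
      ok <- den > 1e-12
      out[ok] <- Im(C)[ok]^2 / den[ok]
      if (warn && any(!ok))
        warning(sum(!ok), " bin(s) with |Re C| ~ 1; lagged coherence set to 0 there",
                call. = FALSE)
      out
    },
    PLV = {
      A <- Mod(P)
      ph <- P
      ph[A > 0] <- P[A > 0] / A[A > 0]
      ph[A == 0] <- 0
      Mod(colMeans(ph))
    },
    PLI = Mod(colMeans(sign(Im(P)))),
    WPLI = {
      num <- abs(colMeans(Im(P)))
      den <- colMeans(abs(Im(P)))
      out <- numeric(length(num))
      ok <- den > 0
      out[ok] <- num[ok] / den[ok]
      out
    },
    ICOH2 = icoh2_values(P, icoh2_denominator, warn),
    EIC1 = {
      C <- coherence_from_products(U, V, P, warn)
      Mod(analytic_signal(Im(C)))
    },
    EIC2 = Mod(analytic_signal(icoh2_values(P, icoh2_denominator, warn))),
    stop("unhandled measure ", measure)
  )
}

coherence_from_products <- function(U, V, P, warn = TRUE) {
  den <- sqrt(colMeans(Mod(U)^2) * colMeans(Mod(V)^2))
  out <- complex(length.out = length(den))
  ok <- den > 0
  out[ok] <- colMeans(P)[ok] / den[ok]
  if (warn && any(!ok))
    warning(sum(!ok), " bin(s) with zero auto-spectral power; coherence set to 0 there",
            call. = FALSE)
  out
}

icoh2_values <- function(P, icoh2_denominator, warn = TRUE) {
  ip <- Im(P)                      # [trial x freq]
  num <- colMeans(ip)
  den <- if (icoh2_denominator == "per_trial") {
    rowMeans(Mod(analytic_signal(t(ip))))   # envelope per trial, then E[.]
  } else {
    Mod(analytic_signal(num))
  }
  if (all(den == 0)) {
    if (warn) warning("all-zero imaginary cross-spectrum; ICOH2 set to 0", call. = FALSE)
    return(numeric(length(num)))
  }
  out <- numeric(length(num))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' All-pairs measure curves
#'
#' Evaluates one measure for every unordered channel pair of a spectral
#' ensemble.
#'
#' @inheritParams measure_curve
#' @return Named list of `fc_curve` objects, one per unordered pair, named
#'   `"<u>|<v>"`.
#' @export
fc_all_pairs <- function(spec, measure,
                         icoh2_denominator = c("per_trial", "post_average")) {
  stopifnot(inherits(spec, "spectral_ensemble"))
  measure <- match_measure(measure)
  icoh2_denominator <- match.arg(icoh2_denominator)
  nch <- length(spec$channel_ids)
  if (nch < 2L) stop("need at least 2 channels")
  pairs <- combn(nch, 2L)
  out <- vector("list", ncol(pairs))
  names(out) <- paste(spec$channel_ids[pairs[1, ]],
                      spec$channel_ids[pairs[2, ]], sep = "|")
  for (k in seq_len(ncol(pairs))) {
    out[[k]] <- measure_curve(spec, pairs[1, k], pairs[2, k], measure,
                              icoh2_denominator, warn = FALSE)
  }
  out
}
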