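#' Trial-shuffling surrogate significance thresholds
#'
#' Builds per-frequency significance cutoffs for a measure by destroying the
#' trial correspondence between the two channels: for each surrogate the
#' trial index of channel `v` is permuted uniformly at random (identity not
#' excluded), the measure recomputed, and the extreme-value (or percentile)
#' statistic taken per frequency bin, separately. With `percentile = 1` the
#' upper threshold is the maximum over surrogates, the classical
#' max-statistic construction for phase-synchrony measures; for signed
#' measures the lower threshold uses the minimum analogously.
#'
#' @inheritParams measure_curve
#' @param n_surrogates number of random trial permutations (default 1000).
#' @param percentile fraction in (0, 1]; 1 gives the max/min statistic.
#' @param seed integer seed for the permutation stream (the ambient RNG state
#'   is restored afterwards); `NULL` uses the ambient stream.
#' @return An object of class `surrogate_threshold`: `upper` and `lower`
#'   curves over `freqs`, plus `measure`, `signed`, `n_surrogates`,
#'   `percentile`, `seed`.
#' @export
surrogate_threshold <- function(spec, ch_u, ch_v, measure,
                                n_surrogates = 1000, percentile = 1,
                                icoh2_denominator = c("per_trial", "post_average"),
                                seed = NULL) {
  stopifnot(inherits(spec, "spectral_ensemble"))
  measure <- match_measure(measure)
  icoh2_denominator <- match.arg(icoh2_denominator)
  if (spec$n_trials < 2L) stop("surrogates require at least 2 trials")
  if (n_surrogates < 1L) stop("n_surrogates must be >= 1")
  if (percentile <= 0 || percentile > 1) stop("percentile must be in (0, 1]")
  U <- coeff_matrix(spec, ch_u)
  V <- coeff_matrix(spec, ch_v)
  N <- nrow(U)
  vals <- with_seed(seed, {
    vapply(seq_len(n_surrogates), function(s) {
      perm <- sample.int(N)
      fc_measure_values(U, V[perm, , drop = FALSE], measure,
                        icoh2_denominator, warn = FALSE)
    }, numeric(ncol(U)))
  })                                        # [freq x surrogate]
  upper <- apply(vals, 1, quantile, probs = percentile, type = 1, names = FALSE)
  lower <- apply(vals, 1, quantile, probs = 1 - percentile, type = 1, names = FALSE)
  structure(list(upper = upper, lower = lower, freqs = spec$freqs,
                 measure = measure, signed = measure %in% SIGNED_MEASURES,
                 n_surrogates = as.integer(n_surrogates),
                 percentile = percentile, seed = seed),
            class = "surrogate_threshold")
}

#' @export
print.surrogate_threshold <- function(x, ...) {
  cat(sprintf("<surrogate_threshold> %s, %d surrogates, percentile %g%s\n",
              x$measure, x$n_surrogates, x$percentile,
              if (x$signed) " (two-sided)" else ""))
  invisible(x)
}

#' Significance mask of a measure curve against a surrogate threshold
#'
#' `TRUE` where the curve strictly exceeds the upper threshold, or (for
#' signed measures) falls strictly below the lower one.
#'
#' @param curve an `fc_curve`.
#' @param thr a `surrogate_threshold` on the same frequency grid and for the
#'   same measure.
#' @return Logical vector over the frequency grid.
#' @export
significant_mask <- function(curve, thr) {
  stopifnot(inherits(curve, "fc_curve"), inherits(thr, "surrogate_threshold"))
  if (length(curve$freqs) != length(thr$freqs) ||
      any(abs(curve$freqs - thr$freqs) > 1e-9))
    stop("frequency grids of curve and threshold do not match")
  if (curve$measure != thr$measure)
    stop("curve measure (", curve$measure, ") differs from threshold measure (",
         thr$measure, ")")
  mask <- curve$values > thr$upper
  if (thr$signed) mask <- mask | (curve$values < thr$lower)
  mask
}
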