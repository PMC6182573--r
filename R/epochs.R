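#' Multi-trial, multi-channel epoched signals
#'
#' Container for segmented recordings: a numeric array indexed
#' `[trial, channel, sample]` plus the sampling rate and channel labels.
#' All estimators in the package consume this class, and both simulators
#' and file readers produce it.
#'
#' @param data numeric array `[n_trials, n_channels, n_samples]`, or a
#'   `[n_channels, n_samples]` matrix for a single trial. All values must
#'   be finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_ids optional character vector of channel labels; defaults
#'   to `ch1, ch2, ...`.
#' @return An object of class `epoched_signals` with elements `data`, `fs`,
#'   `channel_ids`.
#' @examples
#' x <- epoched_signals(array(rnorm(2 * 3 * 100), c(2, 3, 100)), fs = 250)
#' x
#' @export
epoched_signals <- function(data, fs, channel_ids = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[1] < 1L) stop("need at least one trial")
  if (dim(data)[3] < 2L) stop("need at least two samples per epoch")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite value in trial %d, channel %d, sample %d",
                 bad[1, 1], bad[1, 2], bad[1, 3]))
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[2]))
  stopifnot(length(channel_ids) == dim(data)[2])
  structure(list(data = data, fs = as.numeric(fs),
                 channel_ids = as.character(channel_ids)),
            class = "epoched_signals")
}

#' @export
print.epoched_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_signals> %d trial(s) x %d channel(s) x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("channels:", paste(x$channel_ids, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.epoched_signals <- function(x) dim(x$data)

n_trials  <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

channel_index <- function(x, ch) {
  ids <- if (inherits(x, "epoched_signals")) x$channel_ids else x$channel_ids
  if (is.character(ch)) {
    i <- match(ch, ids)
    if (is.na(i)) stop("unknown channel id '", ch, "'", call. = FALSE)
    return(i)
  }
  i <- as.integer(ch)
  if (i < 1L || i > length(ids)) stop("channel index out of range", call. = FALSE)
  i
}

#' Remove the per-epoch mean from every trial and channel
#'
#' Centring each epoch separately removes the DC offset before Fourier
#' analysis; it is idempotent and shape-preserving.
#'
#' @param x an [epoched_signals] object.
#' @return An [epoched_signals] object in which every (trial, channel) series
#'   has zero mean.
#' @export
center_epochs <- function(x) {
  stopifnot(inherits(x, "epoched_signals"))
  mu <- apply(x$data, c(1, 2), mean)
  x$data <- x$data - as.vector(mu)  # recycles over samples (dim 3)
  x
}

#' Epoch-wise one-sided Fourier coefficients
#'
#' Computes the raw discrete Fourier transform of every trial and channel
#' (no taper, no zero padding, optional Hann window) and keeps the one-sided
#' coefficients on the grid `0, fs/Nt, ..., fs/2`. DC and Nyquist bins are
#' included; after [center_epochs] the DC coefficient is numerically zero.
#'
#' @param x an [epoched_signals] object (centre it first with
#'   [center_epochs]).
#' @param window `"rectangular"` (default; plain DFT of the raw epoch) or
#'   `"hann"`.
#' @return An object of class `spectral_ensemble`: complex array `coeffs`
#'   `[trial, channel, frequency]`, the frequency grid `freqs` (Hz), `fs`,
#'   `n_trials`, `nt` (epoch length in samples) and `channel_ids`.
#' @export
epoch_fft <- function(x, window = c("rectangular", "hann")) {
  stopifnot(inherits(x, "epoched_signals"))
  window <- match.arg(window)
  nt <- n_samples(x)
  if (nt < 2L) stop("epochs must contain at least 2 samples")
  nf <- nt %/% 2L + 1L
  freqs <- (seq_len(nf) - 1L) * x$fs / nt
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(nt - 1)) / nt) else rep(1, nt)
  ntr <- n_trials(x); nch <- n_channels(x)
  # mvfft over columns: reshape so each (trial, channel) series is a column,
  # trial index varying fastest
  m <- matrix(aperm(x$data, c(3, 1, 2)), nrow = nt) * w
  ft <- mvfft(m)[seq_len(nf), , drop = FALSE]
  coeffs <- array(t(ft), c(ntr, nch, nf))
  structure(list(coeffs = coeffs, freqs = freqs, fs = x$fs,
                 n_trials = ntr, nt = nt, channel_ids = x$channel_ids),
            class = "spectral_ensemble")
}

#' @export
print.spectral_ensemble <- function(x, ...) {
  cat(sprintf("<spectral_ensemble> %d trial(s) x %d channel(s) x %d bins (%g-%g Hz, step %g Hz)\n",
              x$n_trials, length(x$channel_ids), length(x$freqs),
              min(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1]))
  invisible(x)
}

# complex coefficient matrices [trial x freq] for one channel
coeff_matrix <- function(spec, ch) {
  i <- channel_index(spec, ch)
  matrix(spec$coeffs[, i, ], nrow = spec$n_trials)
}
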