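#' Ground-truth connectivity networks
#'
#' Directed coupling graphs over named ROIs used by the simulators. Delays
#' are stored in model units: samples for the autoregressive model
#' (`kind = "mvar"`, one sample = `1000/fs` ms) and milliseconds for the
#' neural-mass model (`kind = "nmm"`).
#'
#' @param edges data frame with columns `from`, `to` (1-based ROI indices),
#'   `C` (coupling strength) and `delay` (samples for `"mvar"`, ms for
#'   `"nmm"`). May have zero rows for uncoupled ROIs.
#' @param n_roi number of ROIs.
#' @param kind `"mvar"` or `"nmm"`.
#' @return An object of class `fc_network`.
#' @seealso [network_mvar_3roi()], [network_mvar_5roi()],
#'   [network_nmm_3roi()], [network_nmm_5roi()] for the stock scenarios.
#' @export
fc_network <- function(edges = data.frame(from = integer(), to = integer(),
                                          C = numeric(), delay = numeric()),
                       n_roi, kind = c("mvar", "nmm")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "C", "delay") %in% names(edges)))
  n_roi <- as.integer(n_roi)
  if (n_roi < 1L) stop("n_roi must be >= 1")
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    if (any(edges$delay < 0)) stop("delays must be >= 0")
    if (any(!is.finite(edges$C))) stop("couplings must be finite")
    if (any(edges$from < 1 | edges$from > n_roi | edges$to < 1 | edges$to > n_roi))
      stop("edge endpoints must be ROI indices in 1..n_roi")
  }
  structure(list(edges = edges, n_roi = n_roi, kind = kind,
                 roi_ids = paste0("roi", seq_len(n_roi))),
            class = "fc_network")
}

#' @export
print.fc_network <- function(x, ...) {
  cat(sprintf("<fc_network> %s, %d ROI(s), %d edge(s)\n",
              x$kind, x$n_roi, nrow(x$edges)))
  if (nrow(x$edges) > 0L) {
    e <- x$edges
    unit <- if (x$kind == "mvar") "samples" else "ms"
    for (i in seq_len(nrow(e))) {
      cat(sprintf("  %d -> %d  C = %g, delay = %g %s\n",
                  e$from[i], e$to[i], e$C[i], e$delay[i], unit))
    }
  }
  invisible(x)
}

#' Convert a transmission delay from samples to milliseconds
#'
#' @param delta delay in samples.
#' @param fs sampling rate in Hz.
#' @return Delay in ms (`delta * 1000 / fs`); e.g. 12 samples at 250 Hz are
#'   48 ms.
#' @export
delay_samples_to_ms <- function(delta, fs) {
  stopifnot(fs > 0, all(delta >= 0))
  delta * 1000 / fs
}

#' Stock ground-truth scenarios
#'
#' Pre-defined 3- and 5-ROI networks used throughout the simulation study.
#' The MVAR variants use coupling 0.1 (one feedback edge -0.1) with delays of
#' a few samples; the neural-mass variants use coupling 200 with delays of
#' 1-20 ms.
#'
#' @return An [fc_network].
#' @name stock_networks
NULL

#' @rdname stock_networks
#' @export
network_mvar_3roi <- function() {
  fc_network(data.frame(from = c(1, 2, 3), to = c(2, 3, 2),
                        C = c(0.1, 0.1, -0.1), delay = c(2, 3, 3)),
             n_roi = 3, kind = "mvar")
}

#' @rdname stock_networks
#' @export
network_mvar_5roi <- function() {
  fc_network(data.frame(from = c(1, 1, 1, 4, 5), to = c(2, 3, 4, 5, 4),
                        C = c(0.1, 0.1, 0.1, 0.1, -0.1),
                        delay = c(1, 2, 3, 5, 5)),
             n_roi = 5, kind = "mvar")
}

#' @rdname stock_networks
#' @export
network_nmm_3roi <- function() {
  fc_network(data.frame(from = c(1, 2, 3), to = c(2, 3, 2),
                        C = c(200, 200, 200), delay = c(1, 10, 10)),
             n_roi = 3, kind = "nmm")
}

#' @rdname stock_networks
#' @export
network_nmm_5roi <- function() {
  fc_network(data.frame(from = c(1, 1, 1, 4, 5), to = c(2, 3, 4, 5, 4),
                        C = c(200, 200, 200, 200, 200),
                        delay = c(1, 5, 10, 20, 20)),
             n_roi = 5, kind = "nmm")
}

#' Export a network's edge list as TSV
#'
#' Columns: `src`, `dst`, `C`, `delay_ms`.
#'
#' @param network an [fc_network].
#' @param path output file.
#' @param fs sampling rate used to convert sample delays to ms (required for
#'   `"mvar"` networks).
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path, fs = 250) {
  stopifnot(inherits(network, "fc_network"))
  e <- network$edges
  delay_ms <- if (network$kind == "mvar") delay_samples_to_ms(e$delay, fs) else e$delay
  out <- data.frame(src = e$from, dst = e$to, C = e$C, delay_ms = delay_ms)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
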