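#' Full functional-connectivity map over sensors
#'
#' Collapses a measure's frequency curve into one non-negative scalar per
#' unordered sensor pair, producing the dense weighted graph used by the ROC
#' analysis. The default aggregation is the maximum of the measure's
#' magnitude over a frequency band around the simulated rhythm.
#'
#' @param x an [epoched_signals] over sensors, or a `spectral_ensemble`
#'   (epochs are centred and transformed if needed).
#' @param measure measure id (see [measure_curve()]).
#' @param band numeric length-2 band in Hz over which curves are aggregated,
#'   e.g. `c(18, 22)` for a 20 Hz rhythm.
#' @param aggregate `"max"` (default), `"mean"`, or `"bin"` (value at the
#'   bin nearest the band centre).
#' @param icoh2_denominator see [measure_curve()].
#' @return A symmetric matrix of class `fc_map` (diagonal `NA`) with
#'   attributes `measure`, `band`, `aggregate`, `freqs`.
#' @export
full_fc_map <- function(x, measure, band,
                        aggregate = c("max", "mean", "bin"),
                        icoh2_denominator = c("per_trial", "post_average")) {
  aggregate <- match.arg(aggregate)
  icoh2_denominator <- match.arg(icoh2_denominator)
  measure <- match_measure(measure)
  spec <- if (inherits(x, "spectral_ensemble")) x else epoch_fft(center_epochs(x))
  nch <- length(spec$channel_ids)
  if (nch < 2L) stop("need at least 2 sensors")
  stopifnot(length(band) == 2L, band[1] <= band[2])
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(sel) == 0L) stop("band contains no frequency bins")
  mid <- sel[which.min(abs(spec$freqs[sel] - mean(band)))]
  m <- matrix(NA_real_, nch, nch,
              dimnames = list(spec$channel_ids, spec$channel_ids))
  pairs <- combn(nch, 2L)
  envelope_global <- measure %in% c("EIC1", "EIC2", "ICOH2")
  if (measure %in% c("ICOH2", "EIC2")) {
    # batch the per-trial Hilbert envelopes across pairs
    curves <- icoh2_pair_matrix(spec, pairs, icoh2_denominator)
    if (measure == "EIC2") curves <- Mod(analytic_signal(curves))
    for (k in seq_len(ncol(pairs))) {
      vals <- abs(curves[, k])
      w <- switch(aggregate, max = max(vals[sel]), mean = mean(vals[sel]),
                  bin = vals[mid])
      m[pairs[1, k], pairs[2, k]] <- m[pairs[2, k], pairs[1, k]] <- w
    }
  } else {
    # point-wise measures only need the band's bins; envelope measures the
    # full grid
    cols <- if (envelope_global) seq_along(spec$freqs) else sel
    sel_l <- if (envelope_global) sel else seq_along(sel)
    mid_l <- if (envelope_global) mid else which(sel == mid)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      vals <- abs(fc_measure_values(
        matrix(spec$coeffs[, i, cols], spec$n_trials),
        matrix(spec$coeffs[, j, cols], spec$n_trials),
        measure, icoh2_denominator, warn = FALSE))
      w <- switch(aggregate,
                  max = max(vals[sel_l]),
                  mean = mean(vals[sel_l]),
                  bin = vals[mid_l])
      m[i, j] <- m[j, i] <- w
    }
  }
  structure(m, class = c("fc_map", "matrix"),
            measure = measure, band = band, aggregate = aggregate,
            freqs = spec$freqs)
}

# ICOH2 curves for many pairs at once: the per-trial imaginary
# cross-spectrum curves of a chunk of pairs are stacked as columns so the
# analytic-signal FFTs run batched. Returns [freq x pair].
icoh2_pair_matrix <- function(spec, pairs, denominator = "per_trial",
                              chunk_cols = 20000L) {
  N <- spec$n_trials; nf <- length(spec$freqs); np <- ncol(pairs)
  out <- matrix(0, nf, np)
  g <- max(1L, chunk_cols %/% N)
  for (start in seq(1L, np, by = g)) {
    ks <- start:min(np, start + g - 1L)
    IP <- matrix(0, nf, N * length(ks))
    NUM <- matrix(0, nf, length(ks))
    for (j in seq_along(ks)) {
      k <- ks[j]
      P <- matrix(spec$coeffs[, pairs[1, k], ], N) *
        Conj(matrix(spec$coeffs[, pairs[2, k], ], N))
      ip <- t(Im(P))
      IP[, (j - 1L) * N + seq_len(N)] <- ip
      NUM[, j] <- rowMeans(ip)
    }
    if (denominator == "per_trial") {
      ENV <- Mod(analytic_signal(IP))
      for (j in seq_along(ks)) {
        den <- rowMeans(ENV[, (j - 1L) * N + seq_len(N), drop = FALSE])
        v <- numeric(nf); ok <- den > 0
        v[ok] <- NUM[ok, j] / den[ok]
        out[, ks[j]] <- v
      }
    } else {
      ENV <- Mod(analytic_signal(NUM))
      v <- matrix(0, nf, length(ks)); ok <- ENV > 0
      v[ok] <- NUM[ok] / ENV[ok]
      out[, ks] <- v
    }
  }
  out
}

map_edges <- function(map) {
  nch <- nrow(map)
  idx <- which(upper.tri(map), arr.ind = TRUE)
  data.frame(a = idx[, 1], b = idx[, 2], w = map[upper.tri(map)])
}

#' Percentile-thresholded sparse graphs
#'
#' Sparse edge sets `m = 0..M`: graph `m` keeps the edges whose weight is at
#' least the `(100 m / M)`-th percentile of all edge weights, so `m = 0`
#' keeps every edge and `m = M` keeps none (the top graph is empty by
#' convention; ties at interior thresholds are kept).
#'
#' @param map an `fc_map`.
#' @param M number of percentile steps (default 100).
#' @return List of `M + 1` data frames with columns `a`, `b`, `w` (sensor
#'   index pairs and weights).
#' @export
percentile_graphs <- function(map, M = 100) {
  if (M < 1) stop("M must be >= 1")
  ed <- map_edges(map)
  lapply(0:M, function(m) {
    if (m == M) return(ed[integer(0), ])
    thr <- quantile(ed$w, probs = m / M, names = FALSE)
    ed[ed$w >= thr, ]
  })
}

#' Classify edges as true or false positives against sensor ROIs
#'
#' An edge is a true positive iff its endpoints belong to the K-nearest
#' sensor sets of two *different* ROIs (any ROI pair counts - transitivity
#' is accepted, so an indirect `x -> y -> z` association scored between the
#' `x` and `z` sets is still a TP). Everything else - both endpoints inside
#' one ROI's set, or touching a non-ROI sensor - is a false positive.
#'
#' @param edges data frame with columns `a`, `b` (sensor indices), e.g. one
#'   element of [percentile_graphs()].
#' @param rois a `sensor_rois` set from [kns_rois()].
#' @return Named integer vector `c(TP =, FP =)`.
#' @export
classify_tp_fp <- function(edges, rois) {
  stopifnot(inherits(rois, "sensor_rois"))
  ns <- attr(rois, "n_sensors")
  if (nrow(edges) == 0L) return(c(TP = 0L, FP = 0L))
  if (any(edges$a < 1 | edges$a > ns | edges$b < 1 | edges$b > ns))
    stop("edge endpoint outside the sensor set")
  tp <- edge_tp_flags(edges, rois)
  c(TP = sum(tp), FP = sum(!tp))
}

# vectorised TP test: an edge is TP iff both endpoints belong to some ROI set
# and the union of their ROI memberships spans at least two ROIs
edge_tp_flags <- function(edges, rois) {
  ns <- attr(rois, "n_sensors")
  member <- matrix(FALSE, ns, length(rois))
  for (r in seq_along(rois)) member[rois[[r]], r] <- TRUE
  MA <- member[edges$a, , drop = FALSE]
  MB <- member[edges$b, , drop = FALSE]
  rowSums(MA) > 0 & rowSums(MB) > 0 & rowSums(MA | MB) >= 2
}

#' ROC curve and AUC of an FC map against nearest-sensor ROIs
#'
#' Thresholds the map at `M + 1` percentile levels, counts TP/FP at each,
#' forms `TPR(m) = TP(m)/TP(0)`, `FPR(m) = FP(m)/FP(0)` and integrates the
#' (FPR, TPR) polyline by the trapezoidal rule with endpoints (0,0) and
#' (1,1) appended.
#'
#' @param map an `fc_map`.
#' @param rois a `sensor_rois` set.
#' @param M percentile steps (default 100).
#' @return An object of class `roc_result`: vectors `m`, `TP`, `FP`, `TPR`,
#'   `FPR` and scalar `auc`, plus the `K` used.
#' @export
roc_auc <- function(map, rois, M = 100) {
  if (M < 1) stop("M must be >= 1")
  ed <- map_edges(map)
  flags <- edge_tp_flags(ed, rois)
  thr <- quantile(ed$w, probs = (0:M) / M, names = FALSE)
  TP <- vapply(0:M, function(m) {
    if (m == M) 0L else sum(flags[ed$w >= thr[m + 1]])
  }, integer(1))
  FP <- vapply(0:M, function(m) {
    if (m == M) 0L else sum(!flags[ed$w >= thr[m + 1]])
  }, integer(1))
  if (TP[1] == 0L) stop("degenerate ROI geometry: no potential true-positive edge (TP(0) = 0)")
  if (FP[1] == 0L) stop("degenerate ROI geometry: no potential false-positive edge (FP(0) = 0)")
  TPR <- TP / TP[1]; FPR <- FP / FP[1]
  xs <- c(0, rev(FPR), 1)
  ys <- c(0, rev(TPR), 1)
  ord <- order(xs, ys)
  xs <- xs[ord]; ys <- ys[ord]
  auc <- sum(diff(xs) * (head2(ys) + tail2(ys)) / 2)
  structure(list(m = 0:M, TP = TP, FP = FP, TPR = TPR, FPR = FPR,
                 auc = auc, K = attr(rois, "K")),
            class = "roc_result")
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f over %d thresholds (KNS = %d)\n",
              x$auc, length(x$m), x$K))
  invisible(x)
}

#' Null AUC by random edge-weight permutation
#'
#' Re-assigns the map's edge weights uniformly at random across edges
#' (equivalently, permutes graph labels) and recomputes the AUC: the chance
#' level against which recovered maps are compared.
#'
#' @inheritParams roc_auc
#' @param seed integer seed.
#' @return Scalar null AUC.
#' @export
roc_auc_null <- function(map, rois, M = 100, seed = NULL) {
  nch <- nrow(map)
  w <- map[upper.tri(map)]
  with_seed(seed, {
    perm <- sample(w)
    m2 <- matrix(NA_real_, nch, nch)
    m2[upper.tri(m2)] <- perm
    m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
    attributes(m2) <- c(attributes(m2), attributes(map)[c("measure", "band", "aggregate")])
    class(m2) <- class(map)
    roc_auc(m2, rois, M)$auc
  })
}
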