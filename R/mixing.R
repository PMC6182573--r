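#' Local leadfield mixing coefficients
#'
#' Gains of the two-sensor mixing model `u = a1 x + b1 y + eps_u`,
#' `v = a2 x + b2 y + eps_v`. The determinant `a1 b2 - a2 b1` controls how
#' much of the sources' imaginary cross-spectrum survives in the sensors:
#' the sensor-level `Im S_uv` is exactly that determinant times the source
#' `Im S_xy` (plus sampling error), so a zero determinant kills lag
#' information entirely.
#'
#' @param a1,b1,a2,b2 unitless gains; defaults 0.75, 0.5, 0.5, 0.75
#'   (determinant 0.3125).
#' @param sigma_u,sigma_v sensor-noise standard deviations; `NULL` (default)
#'   means 10% of the noiseless mixed-signal sd, resolved at mixing time.
#' @return A list of class `mixing_coeffs` with a `determinant` element.
#' @export
mixing_coeffs <- function(a1 = 0.75, b1 = 0.5, a2 = 0.5, b2 = 0.75,
                          sigma_u = NULL, sigma_v = NULL) {
  stopifnot(is.finite(a1), is.finite(b1), is.finite(a2), is.finite(b2))
  det <- a1 * b2 - a2 * b1
  if (det == 0)
    warning("mixing determinant a1*b2 - a2*b1 is zero: sensor signals carry no lag information",
            call. = FALSE)
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 sigma_u = sigma_u, sigma_v = sigma_v, determinant = det),
            class = "mixing_coeffs")
}

#' Mix a two-source epoch set into a two-sensor epoch set
#'
#' Applies the local leadfield model per sample: `u = a1 x + b1 y + eps_u`,
#' `v = a2 x + b2 y + eps_v`, with iid Gaussian sensor noise.
#'
#' @param src an [epoched_signals] holding the source pair.
#' @param coeffs a [mixing_coeffs] set.
#' @param ch_x,ch_y the source channels to mix (default the first two).
#' @param seed integer seed for the sensor noise.
#' @return An [epoched_signals] with channels `u`, `v`.
#' @export
mix_two_sensors <- function(src, coeffs = mixing_coeffs(),
                            ch_x = 1, ch_y = 2, seed = NULL) {
  stopifnot(inherits(src, "epoched_signals"), inherits(coeffs, "mixing_coeffs"))
  ix <- channel_index(src, ch_x); iy <- channel_index(src, ch_y)
  x <- src$data[, ix, , drop = FALSE]
  y <- src$data[, iy, , drop = FALSE]
  u0 <- coeffs$a1 * x + coeffs$b1 * y
  v0 <- coeffs$a2 * x + coeffs$b2 * y
  su <- if (is.null(coeffs$sigma_u)) 0.1 * sd(u0) else coeffs$sigma_u
  sv <- if (is.null(coeffs$sigma_v)) 0.1 * sd(v0) else coeffs$sigma_v
  with_seed(seed, {
    dat <- array(0, c(dim(src$data)[1], 2L, dim(src$data)[3]))
    dat[, 1L, ] <- u0 + if (su > 0) rnorm(length(u0), sd = su) else 0
    dat[, 2L, ] <- v0 + if (sv > 0) rnorm(length(v0), sd = sv) else 0
    epoched_signals(dat, fs = src$fs, channel_ids = c("u", "v"))
  })
}

#' Synthetic sensor layout and distance-falloff gain matrix
#'
#' Places `n_sensors` quasi-uniformly (Fibonacci lattice) on an upper
#' hemispheric cap of unit radius, scatters `n_background` background sources
#' and accepts user ROI source positions strictly inside the cap. The gain
#' from source `q` to sensor `s` is `1 / (d(s, q)^2 + eps0)` with
#' `eps0 = 0.02` (2% of the squared cap radius), and every source's gain
#' column is scaled to unit norm so that the signal-to-background ratio is
#' controlled by the mixing weights alone. This is a deliberately simple
#' stand-in for an anatomical leadfield: the nearest-sensor ROI heuristic
#' only requires gains that decay monotonically with distance.
#'
#' @param n_sensors number of sensors on the cap (default 102).
#' @param n_background number of background sources (default 500).
#' @param roi_positions matrix `[n_roi x 3]` of ROI source positions with
#'   norm < 1, or an integer ROI count to use [default_roi_positions()].
#' @param seed integer seed (background source placement).
#' @return A list of class `sensor_layout`: `sensors`, `roi`, `background`
#'   position matrices and the `gain` matrix
#'   `[n_sensors x (n_roi + n_background)]` (ROI columns first).
#' @export
synth_layout <- function(n_sensors = 102, n_background = 500,
                         roi_positions = 3, seed = NULL) {
  stopifnot(n_sensors >= 2, n_background >= 0)
  if (is.numeric(roi_positions) && length(roi_positions) == 1L)
    roi_positions <- default_roi_positions(roi_positions)
  roi_positions <- as.matrix(roi_positions)
  stopifnot(ncol(roi_positions) == 3L)
  rr <- sqrt(rowSums(roi_positions^2))
  if (any(rr >= 1)) stop("ROI positions must lie strictly inside the unit sensor cap")
  sensors <- fibonacci_cap(n_sensors)
  bg <- with_seed(seed, random_interior_points(n_background))
  src <- rbind(roi_positions, bg)
  d2 <- outer(rowSums(sensors^2), rowSums(src^2), "+") -
    2 * sensors %*% t(src)
  gain <- 1 / (pmax(d2, 0) + 0.02)
  gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
  structure(list(sensors = sensors, roi = roi_positions, background = bg,
                 gain = gain, n_roi = nrow(roi_positions)),
            class = "sensor_layout")
}

# quasi-uniform points on the upper unit hemisphere (z in [0.15, 1])
fibonacci_cap <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 0.85 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# random points inside the cap volume (radius in [0.4, 0.8], z > 0.1)
random_interior_points <- function(n) {
  if (n == 0L) return(matrix(numeric(), 0L, 3L))
  pts <- matrix(rnorm(3L * n), n, 3L)
  pts[, 3] <- abs(pts[, 3]) + 0.3
  pts <- pts / sqrt(rowSums(pts^2))
  pts * stats::runif(n, 0.4, 0.8)
}

#' Default ROI source positions
#'
#' Fixed, well-separated interior positions (radius 0.7) for up to 6 ROIs;
#' all but the last sit on the "left" half of the cap, mirroring a
#' predominantly unilateral source configuration.
#'
#' @param n_roi number of ROIs (1..6).
#' @return Matrix `[n_roi x 3]`.
#' @export
default_roi_positions <- function(n_roi) {
  stopifnot(n_roi >= 1, n_roi <= 6)
  base <- rbind(
    c(-0.45,  0.35, 0.42),
    c(-0.50, -0.30, 0.40),
    c(-0.10,  0.05, 0.69),
    c(-0.15, -0.55, 0.40),
    c( 0.50,  0.25, 0.42),
    c( 0.25,  0.55, 0.35))
  base[seq_len(n_roi), , drop = FALSE]
}

#' Project ROI sources to sensors with background and measurement noise
#'
#' Two Frobenius-normalised convex mixtures per trial: first the ROI signal
#' projection is blended with projected iid Gaussian background activity,
#' `Yb = alpha * Yrois/||Yrois|| + (1 - alpha) * Ybg/||Ybg||`
#' (alpha of 0.1, 0.5, 0.9 emulates roughly -20, 0, +20 dB), then iid sensor
#' noise is added the same way with weight `beta` (default 0.9). Background
#' source time courses are redrawn fresh for every trial.
#'
#' @param roi_epochs an [epoched_signals] with one channel per ROI.
#' @param layout a [synth_layout()] whose ROI count matches.
#' @param alpha signal-to-background weight in `[0, 1]`.
#' @param beta measurement-noise weight in `[0, 1]` (default 0.9).
#' @param seed integer seed (background + sensor noise).
#' @return An [epoched_signals] with one channel per sensor.
#' @export
project_with_background <- function(roi_epochs, layout, alpha, beta = 0.9,
                                    seed = NULL) {
  stopifnot(inherits(roi_epochs, "epoched_signals"),
            inherits(layout, "sensor_layout"))
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  k <- layout$n_roi
  if (n_channels(roi_epochs) != k)
    stop("roi_epochs has ", n_channels(roi_epochs), " channels but layout has ",
         k, " ROIs")
  G_roi <- layout$gain[, seq_len(k), drop = FALSE]
  G_bg <- layout$gain[, -seq_len(k), drop = FALSE]
  ns <- nrow(layout$sensors)
  ntr <- n_trials(roi_epochs); nt <- n_samples(roi_epochs)
  nbg <- ncol(G_bg)
  with_seed(seed, {
    out <- array(0, c(ntr, ns, nt))
    for (tr in seq_len(ntr)) {
      Yrois <- G_roi %*% matrix(roi_epochs$data[tr, , ], nrow = k)
      Yb <- alpha * Yrois / frobenius(Yrois)
      if (nbg > 0L && alpha < 1) {
        Ybg <- G_bg %*% matrix(rnorm(nbg * nt), nbg)
        Yb <- Yb + (1 - alpha) * Ybg / frobenius(Ybg)
      }
      if (beta < 1) {
        U <- matrix(rnorm(ns * nt), ns)
        Yb <- beta * Yb / frobenius(Yb) + (1 - beta) * U / frobenius(U)
      }
      out[tr, , ] <- Yb
    }
    epoched_signals(out, fs = roi_epochs$fs,
                    channel_ids = sprintf("S%03d", seq_len(ns)))
  })
}

#' K-nearest-sensor regions of interest
#'
#' For each ROI source in the layout, the `K` sensors with smallest
#' Euclidean distance (ties broken by sensor index). Overlapping sets are
#' allowed but flagged with a warning.
#'
#' @param layout a [synth_layout()].
#' @param K sensors per ROI (default 6).
#' @return A list of class `sensor_rois`: integer vectors of sensor indices,
#'   one per ROI, plus attribute `K`.
#' @export
kns_rois <- function(layout, K = 6) {
  stopifnot(inherits(layout, "sensor_layout"), K >= 1)
  ns <- nrow(layout$sensors)
  if (K > ns) stop("K exceeds the number of sensors (", ns, ")")
  sets <- lapply(seq_len(layout$n_roi), function(r) {
    d <- sqrt(colSums((t(layout$sensors) - layout$roi[r, ])^2))
    order(d, seq_len(ns))[seq_len(K)]
  })
  if (layout$n_roi > 1L) {
    all_s <- unlist(sets)
    if (anyDuplicated(all_s))
      warning("KNS sensor sets overlap for this geometry/K", call. = FALSE)
  }
  structure(sets, class = "sensor_rois", K = as.integer(K), n_sensors = ns)
}
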