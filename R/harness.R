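#' Define a sensor-space evaluation scenario
#'
#' Bundles everything one Monte-Carlo configuration needs: the ground-truth
#' network and generative model, the sensor geometry, and the noise mixing
#' weights.
#'
#' @param network an [fc_network] (its `kind` selects the generator).
#' @param alpha signal-to-background weight (0.1/0.5/0.9 ~ -20/0/+20 dB).
#' @param beta measurement-noise weight (default 0.9).
#' @param n_trials,epoch_s,fs epoch geometry.
#' @param n_sensors,n_background layout size (defaults 102 sensors, 500
#'   background sources).
#' @param band aggregation band in Hz; `NULL` picks the generator's rhythm
#'   +/- 2 Hz (18-22 for MVAR, 8.87-12.87 for the neural-mass model).
#' @param label optional scenario name.
#' @return A list of class `roc_scenario`.
#' @export
roc_scenario <- function(network, alpha = 0.5, beta = 0.9,
                         n_trials = 100, epoch_s = 1, fs = 250,
                         n_sensors = 102, n_background = 500,
                         band = NULL, label = NULL) {
  stopifnot(inherits(network, "fc_network"))
  if (is.null(band)) {
    band <- if (network$kind == "mvar") c(18, 22) else 10.87 + c(-2, 2)
  }
  if (is.null(label)) {
    label <- sprintf("%s_%droi_a%s", network$kind, network$n_roi, alpha)
  }
  structure(list(network = network, alpha = alpha, beta = beta,
                 n_trials = n_trials, epoch_s = epoch_s, fs = fs,
                 n_sensors = n_sensors, n_background = n_background,
                 band = band, label = label),
            class = "roc_scenario")
}

#' Monte-Carlo comparison harness for FC measures
#'
#' Runs `R` independent realizations of each scenario: fresh source signals
#' (MVAR; neural-mass source signals are simulated once per scenario and
#' reused across realizations, which only redraw background and measurement
#' noise - a standard cost-saving device since the SDDE integration
#' dominates runtime), fresh background and sensor noise, projection to the
#' synthetic layout, one FC map per measure, and the AUC averaged over the
#' requested KNS range.
#'
#' @param scenarios list of [roc_scenario()] objects (a single scenario may
#'   be passed bare).
#' @param measures character vector of measure ids.
#' @param R realizations per scenario (>= 2).
#' @param kns_range integer vector of KNS values to average over (default
#'   `6:10`).
#' @param M percentile steps for the ROC (default 100).
#' @param seed root seed; per-realization seeds are derived deterministically.
#' @param reuse_nmm reuse one SDDE source simulation across realizations
#'   (default `TRUE`).
#' @return An object of class `mc_comparison`: data frame `auc` with columns
#'   `scenario`, `measure`, `realization`, `auc`, plus the call parameters.
#' @export
mc_harness <- function(scenarios, measures = c("LCOH", "ICOH1", "PLI", "WPLI", "EIC2"),
                       R = 20, kns_range = 6:10, M = 100, seed = 1,
                       reuse_nmm = TRUE) {
  if (inherits(scenarios, "roc_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L) stop("empty scenario list")
  if (R < 2) stop("need R >= 2 realizations for any comparison")
  measures <- vapply(measures, match_measure, character(1))
  rows <- list()
  for (sc in scenarios) {
    layout <- synth_layout(sc$n_sensors, sc$n_background,
                           roi_positions = sc$network$n_roi,
                           seed = derive_seed(seed, paste0("layout/", sc$label)))
    rois <- lapply(kns_range, function(K) kns_rois(layout, K))
    nmm_src <- NULL
    if (sc$network$kind == "nmm" && reuse_nmm) {
      nmm_src <- simulate_nmm_sdde(sc$network, sc$n_trials, sc$epoch_s,
                                   fs_out = sc$fs,
                                   seed = derive_seed(seed, paste0("nmm/", sc$label)))
    }
    for (r in seq_len(R)) {
      sseed <- derive_seed(seed, sprintf("real/%s/%d", sc$label, r))
      src <- if (!is.null(nmm_src)) nmm_src
             else if (sc$network$kind == "mvar")
               simulate_mvar(sc$network, sc$n_trials,
                             n_samples = round(sc$epoch_s * sc$fs),
                             fs = sc$fs, seed = sseed)
             else simulate_nmm_sdde(sc$network, sc$n_trials, sc$epoch_s,
                                    fs_out = sc$fs, seed = sseed)
      sens <- project_with_background(src, layout, sc$alpha, sc$beta,
                                      seed = derive_seed(seed, sprintf("noise/%s/%d", sc$label, r)))
      spec <- epoch_fft(center_epochs(sens))
      for (msr in measures) {
        map <- full_fc_map(spec, msr, band = sc$band)
        aucs <- vapply(rois, function(ro) roc_auc(map, ro, M)$auc, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          scenario = sc$label, measure = msr, realization = r,
          auc = mean(aucs))
      }
    }
  }
  structure(list(auc = do.call(rbind, rows), measures = measures,
                 R = R, kns_range = kns_range, M = M, seed = seed),
            class = "mc_comparison")
}

#' @export
print.mc_comparison <- function(x, ...) {
  cat(sprintf("<mc_comparison> %d realization(s) x %d measure(s) x %d scenario(s)\n",
              x$R, length(x$measures), length(unique(x$auc$scenario))))
  print(stats::aggregate(auc ~ scenario + measure, x$auc, median))
  invisible(x)
}

#' Paired rank tests between FC measures
#'
#' Two-sided Wilcoxon signed-rank tests between every pair of measures,
#' within each scenario, on AUC samples matched by realization (the samples
#' are paired because each pair comes from the same simulated data).
#' Bonferroni correction uses the total pair count unless `bonferroni_n`
#' overrides it.
#'
#' @param mc an `mc_comparison`.
#' @param bonferroni_n correction factor; default = number of tests run.
#' @return Data frame with columns `scenario`, `measure_a`, `measure_b`,
#'   `median_a`, `median_b`, `p`, `p_bonf`, `winner` (`"draw"` when not
#'   significant at 0.05 after correction).
#' @export
compare_measures_paired <- function(mc, bonferroni_n = NULL) {
  stopifnot(inherits(mc, "mc_comparison"))
  out <- list()
  for (scn in unique(mc$auc$scenario)) {
    d <- mc$auc[mc$auc$scenario == scn, ]
    ms <- unique(d$measure)
    if (length(ms) < 2L) next
    for (pr in utils::combn(ms, 2, simplify = FALSE)) {
      a <- d$auc[d$measure == pr[1]][order(d$realization[d$measure == pr[1]])]
      b <- d$auc[d$measure == pr[2]][order(d$realization[d$measure == pr[2]])]
      p <- if (all(a == b)) 1
           else suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
      out[[length(out) + 1L]] <- data.frame(
        scenario = scn, measure_a = pr[1], measure_b = pr[2],
        median_a = median(a), median_b = median(b), p = p)
    }
  }
  res <- do.call(rbind, out)
  n <- if (is.null(bonferroni_n)) nrow(res) else bonferroni_n
  res$p_bonf <- pmin(1, res$p * n)
  res$winner <- ifelse(res$p_bonf < 0.05,
                       ifelse(res$median_a > res$median_b, res$measure_a, res$measure_b),
                       "draw")
  attr(res, "bonferroni_n") <- n
  res
}

#' Unpaired rank test between two AUC samples
#'
#' Two-sided Mann-Whitney U test (equal medians null) for comparisons whose
#' samples come from different simulated data, e.g. across SNR levels,
#' generative models, or ROI counts.
#'
#' @param auc_a,auc_b numeric AUC samples.
#' @param alternative passed to [stats::wilcox.test()].
#' @return The `htest` object.
#' @export
compare_auc_unpaired <- function(auc_a, auc_b, alternative = "two.sided") {
  suppressWarnings(wilcox.test(auc_a, auc_b, alternative = alternative,
                               exact = FALSE))
}

#' Win/loss/draw bookkeeping for measure tournaments
#'
#' Scores a set of pairwise outcomes under two systems: "league" (win 3,
#' draw 1, loss 0) and "chess" (win 1, draw 0.5, loss 0).
#'
#' @param outcomes data frame with columns `measure_a`, `measure_b`,
#'   `winner` (one of the two measures, or `"draw"`).
#' @return Data frame per measure: `wins`, `losses`, `draws`,
#'   `points_league`, `points_chess`.
#' @export
score_winloss <- function(outcomes) {
  stopifnot(all(c("measure_a", "measure_b", "winner") %in% names(outcomes)))
  ms <- sort(unique(c(outcomes$measure_a, outcomes$measure_b)))
  tab <- data.frame(measure = ms, wins = 0L, losses = 0L, draws = 0L)
  for (i in seq_len(nrow(outcomes))) {
    a <- outcomes$measure_a[i]; b <- outcomes$measure_b[i]
    w <- outcomes$winner[i]
    if (w == "draw") {
      tab$draws[tab$measure %in% c(a, b)] <- tab$draws[tab$measure %in% c(a, b)] + 1L
    } else {
      l <- if (w == a) b else a
      tab$wins[tab$measure == w] <- tab$wins[tab$measure == w] + 1L
      tab$losses[tab$measure == l] <- tab$losses[tab$measure == l] + 1L
    }
  }
  tab$points_league <- 3L * tab$wins + tab$draws
  tab$points_chess <- tab$wins + 0.5 * tab$draws
  tab
}
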