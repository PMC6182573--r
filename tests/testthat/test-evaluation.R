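toy_map <- function(w, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(w))) / 2
  m <- matrix(NA_real_, n, n)
  m[upper.tri(m)] <- w
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  dimnames(m) <- list(labels, labels)
  structure(m, class = c("fc_map", "matrix"), measure = "COH",
            band = c(18, 22), aggregate = "max")
}

toy_rois <- function(sets, n_sensors) {
  structure(sets, class = "sensor_rois", K = lengths(sets)[1],
            n_sensors = as.integer(n_sensors))
}

test_that("full_fc_map agrees with per-pair curve aggregation", {
  x <- white_epochs(6, 4, 64, seed = 1)
  spec <- epoch_fft(center_epochs(x))
  for (m in c("COH", "ICOH1", "EIC2")) {
    map <- full_fc_map(spec, m, band = c(10, 20))
    sel <- spec$freqs >= 10 & spec$freqs <= 20
    for (pr in list(c(1, 2), c(2, 4), c(3, 4))) {
      cv <- measure_curve(spec, pr[1], pr[2], m, warn = FALSE)
      expect_equal(unname(map[pr[1], pr[2]]), max(abs(cv$values[sel])),
                   tolerance = 1e-12)
    }
    expect_true(isSymmetric(unclass(map)))
  }
  # 2 sensors -> 1 edge
  two <- epoch_fft(center_epochs(white_epochs(3, 2, 32, seed = 2)))
  map2 <- full_fc_map(two, "COH", band = c(4, 12))
  expect_equal(nrow(eiconn:::map_edges(map2)), 1)
})

test_that("duplicated sensors get coherence weight 1", {
  x <- white_epochs(4, 2, 32, seed = 3)
  x$data[, 2, ] <- x$data[, 1, ]
  map <- full_fc_map(epoch_fft(center_epochs(x)), "COH", band = c(4, 12))
  expect_equal(unname(map[1, 2]), 1, tolerance = 1e-9)
})

test_that("percentile graphs keep all edges at m=0 and none at m=M", {
  map <- toy_map(c(5, 3, 8, 1, 9, 2))
  gs <- percentile_graphs(map, M = 4)
  expect_length(gs, 5)
  expect_equal(nrow(gs[[1]]), 6)       # m = 0: complete graph
  expect_equal(nrow(gs[[5]]), 0)       # m = M: empty by convention
  # nested
  for (i in 1:4) expect_true(all(gs[[i + 1]]$w %in% gs[[i]]$w))
})

test_that("equal-weight ties are kept at the threshold", {
  map <- toy_map(rep(1, 5 * 4 / 2))  # 5 sensors, all weights equal
  gs <- percentile_graphs(map, M = 2)
  # sort-based oracle: threshold equals the common weight, >= keeps all
  expect_equal(nrow(gs[[2]]), 10)
  expect_equal(nrow(gs[[3]]), 0)
})

test_that("classify_tp_fp follows the two-different-ROIs rule", {
  rois <- toy_rois(list(c(1L, 2L, 3L), c(4L, 5L, 6L)), n_sensors = 6)
  # exhaustive oracle over all 15 edges of the 6-sensor toy
  pairs <- t(combn(6, 2))
  in1 <- function(s) s %in% 1:3
  truth <- apply(pairs, 1, function(e) in1(e[1]) != in1(e[2]))
  got <- eiconn:::edge_tp_flags(data.frame(a = pairs[, 1], b = pairs[, 2]), rois)
  expect_equal(got, truth)
  # single-edge checks
  expect_equal(classify_tp_fp(data.frame(a = 1, b = 2), rois), c(TP = 0L, FP = 1L))
  expect_equal(classify_tp_fp(data.frame(a = 1, b = 5), rois), c(TP = 1L, FP = 0L))
  # non-ROI sensor -> FP
  rois2 <- toy_rois(list(c(1L, 2L), c(4L, 5L)), n_sensors = 6)
  expect_equal(classify_tp_fp(data.frame(a = 3, b = 6), rois2), c(TP = 0L, FP = 1L))
  # overlapping membership still allows a distinct ROI pair
  rois3 <- toy_rois(list(c(1L, 2L), c(2L, 3L)), n_sensors = 6)
  expect_equal(classify_tp_fp(data.frame(a = 2, b = 2), rois3), c(TP = 1L, FP = 0L))
})

test_that("perfect separation gives AUC 1 and random weights ~0.5", {
  rois <- toy_rois(list(c(1L, 2L), c(3L, 4L)), n_sensors = 8)
  # enumerate edges in the same (upper-triangle) order the map uses
  idx <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  tp <- eiconn:::edge_tp_flags(data.frame(a = idx[, 1], b = idx[, 2]), rois)
  w <- ifelse(tp, 10 + seq_along(tp), seq_along(tp) / 100)
  roc <- roc_auc(toy_map(w), rois, M = 50)
  expect_equal(roc$auc, 1, tolerance = 1e-9)
  expect_equal(roc$TPR[1], 1); expect_equal(roc$FPR[1], 1)
  expect_true(all(diff(roc$TPR) <= 1e-12) && all(diff(roc$FPR) <= 1e-12))
  expect_true(all(roc$TP + roc$FP ==
                    vapply(percentile_graphs(toy_map(w), 50), nrow, integer(1))))

  aucs <- eiconn:::with_seed(99, {
    replicate(100, roc_auc(toy_map(sample(seq_along(tp))), rois, M = 50)$auc)
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUC is invariant under strictly monotone weight transforms", {
  rois <- toy_rois(list(c(1L, 2L), c(5L, 6L)), n_sensors = 7)
  w <- eiconn:::with_seed(4, runif(21))
  a1 <- roc_auc(toy_map(w), rois, M = 40)$auc
  a2 <- roc_auc(toy_map(exp(3 * w)), rois, M = 40)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("degenerate ROI geometries are refused", {
  # healthy geometry: 4 sensors, singleton ROIs {1}, {2}: edge (1,2) is the
  # lone TP, every edge touching 3 or 4 is an FP
  expect_error(roc_auc(toy_map(c(1, 2, 3, 4, 5, 6)),
                       toy_rois(list(1L, 2L), n_sensors = 4), M = 10),
               NA)
  # all edges TP -> FP(0) = 0
  expect_error(roc_auc(toy_map(1), toy_rois(list(1L, 2L), n_sensors = 2)),
               "FP\\(0\\)")
  # no ROI pair reachable -> TP(0) = 0
  expect_error(roc_auc(toy_map(c(1, 2, 3)),
                       toy_rois(list(1:3), n_sensors = 3)),
               "TP\\(0\\)")
})

test_that("roc_auc_null permutes weights reproducibly", {
  rois <- toy_rois(list(c(1L, 2L), c(4L, 5L)), n_sensors = 6)
  map <- toy_map(eiconn:::with_seed(5, runif(15)))
  n1 <- roc_auc_null(map, rois, seed = 3)
  n2 <- roc_auc_null(map, rois, seed = 3)
  expect_identical(n1, n2)
  expect_true(n1 >= 0 && n1 <= 1)
})

test_that("win/loss bookkeeping reproduces both scoring systems", {
  outcomes <- data.frame(
    measure_a = c("A", "A", "B"),
    measure_b = c("B", "C", "C"),
    winner = c("A", "draw", "C"))
  tab <- score_winloss(outcomes)
  expect_equal(tab$points_league[tab$measure == "A"], 4)  # 1 win + 1 draw
  expect_equal(tab$points_league[tab$measure == "B"], 0)
  expect_equal(tab$points_league[tab$measure == "C"], 4)  # 1 win + 1 draw
  expect_equal(tab$points_chess[tab$measure == "A"], 1.5)
  expect_equal(tab$points_chess[tab$measure == "C"], 1.5)
})

test_that("paired measure comparison detects a dominant measure", {
  mc <- structure(list(
    auc = data.frame(
      scenario = "s", measure = rep(c("A", "B"), each = 12),
      realization = rep(1:12, 2),
      auc = c(seq(0.8, 0.91, 0.01), seq(0.5, 0.61, 0.01))),
    measures = c("A", "B"), R = 12, kns_range = 6, M = 100, seed = 1),
    class = "mc_comparison")
  res <- compare_measures_paired(mc)
  expect_equal(res$winner, "A")
  expect_lt(res$p_bonf, 0.05)
  # identical samples draw
  mc$auc$auc[13:24] <- mc$auc$auc[1:12]
  expect_equal(compare_measures_paired(mc)$winner, "draw")
})

test_that("mc_harness runs end-to-end at toy scale and is deterministic", {
  sc <- roc_scenario(network_mvar_3roi(), alpha = 0.5, n_trials = 20,
                     n_sensors = 24, n_background = 50, label = "toy")
  # 24 sensors for 3 ROIs: overlapping KNS sets are expected and warned about
  mc <- suppressWarnings(mc_harness(sc, measures = c("ICOH1", "COH"), R = 2,
                                    kns_range = 3:4, M = 20, seed = 7))
  expect_s3_class(mc, "mc_comparison")
  expect_equal(nrow(mc$auc), 2 * 2)          # 2 measures x 2 realizations
  expect_true(all(mc$auc$auc >= 0 & mc$auc$auc <= 1))
  mc2 <- suppressWarnings(mc_harness(sc, measures = c("ICOH1", "COH"), R = 2,
                                     kns_range = 3:4, M = 20, seed = 7))
  expect_identical(mc$auc, mc2$auc)
  res <- compare_measures_paired(mc)
  expect_equal(nrow(res), 1)
  expect_error(mc_harness(list(), R = 2), "empty scenario")
  expect_error(mc_harness(sc, R = 1), "R >= 2")
})
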