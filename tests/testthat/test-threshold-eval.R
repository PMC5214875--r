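test_that("threshold assignment splits the Q axis in three", {
  expect_identical(assign_structure_threshold(0.92, 0.90), "PURE_A")
  expect_identical(assign_structure_threshold(0.05, 0.90), "PURE_B")
  expect_identical(assign_structure_threshold(0.50, 0.90), "HYBRID")
  # equality retains the animal
  expect_identical(assign_structure_threshold(0.90, 0.90), "PURE_A")
  expect_error(assign_structure_threshold(0.5, 0.4), "threshold")
})

test_that("efficiency and accuracy follow their definitions", {
  # 500 true F1; 450 assigned F1 correctly, 20 others wrongly assigned F1
  truth <- c(rep("F1", 500), rep("F2", 100))
  assigned <- c(rep("F1", 450), rep("OTHER", 50),
                rep("F1", 20), rep("F2", 80))
  r <- efficiency_accuracy(truth, assigned, "F1")
  expect_equal(r$efficiency, 0.90)
  expect_equal(r$accuracy, 450 / 470, tolerance = 1e-12)
  expect_equal(r$performance, 0.90 * 450 / 470, tolerance = 1e-12)
  # perfect assignment
  r <- efficiency_accuracy(rep("F1", 5), rep("F1", 5), "F1")
  expect_equal(unlist(r[c("efficiency", "accuracy", "performance")]),
               c(efficiency = 1, accuracy = 1, performance = 1))
  # nothing assigned: accuracy 0 by convention
  r <- efficiency_accuracy(rep("F1", 5), rep("OTHER", 5), "F1")
  expect_equal(r$accuracy, 0)
  expect_equal(r$efficiency, 0)
  expect_error(efficiency_accuracy("F1", "F1", "BC_A"), "absent")
})

test_that("performance never exceeds efficiency or accuracy", {
  set.seed(61)
  truth <- sample(c("PURE_A", "PURE_B", "F1", "F2"), 200, replace = TRUE)
  q <- stats::runif(200)
  scan <- threshold_scan(truth, q, method = "structure_q",
                         grid = threshold_grid())
  tab <- scan$table
  expect_true(all(tab$performance <= pmin(tab$efficiency, tab$accuracy) +
                    1e-12))
})

test_that("the efficiency/accuracy trade-off holds across the grid", {
  pools <- calibrated_pair()
  for (s in c(67, 71)) {
    ts <- build_test_set(pools, simulation_design(60), seed = s)
    q <- em_admixture(ts, seed = s + 1)
    q <- align_clusters(list(q), ts$ids[ts$truth == "PURE_A"])[[1]]
    scan <- threshold_scan(ts$truth, q, method = "structure_q",
                           grid = threshold_grid())
    tab <- scan$table[scan$table$subset == "all", ]
    for (cat in c("PURE_A", "PURE_B")) {
      sub <- tab[tab$category == cat, ]
      sub <- sub[order(sub$threshold), ]
      # efficiency shrinks with the threshold (set inclusion, exact)
      expect_true(all(diff(sub$efficiency) <= 1e-12))
      # accuracy is maximized toward the high end of the grid: over
      # thresholds that still assign someone, the top end beats the bottom
      nz <- sub[sub$n_assigned > 0, ]
      expect_gte(nz$accuracy[nrow(nz)], nz$accuracy[1])
    }
    hyb <- tab[tab$category == "HYBRID", ]
    hyb <- hyb[order(hyb$threshold), ]
    expect_true(all(diff(hyb$efficiency) >= -1e-12))
    # hybrid accuracy is maximized at low thresholds; small count-ratio
    # jitter aside, it never rises with the threshold
    expect_true(all(diff(hyb$accuracy) <= 0.01))
    expect_gte(hyb$accuracy[1], hyb$accuracy[nrow(hyb)])
  }
})

test_that("excluding double backcrosses never hurts hybrid efficiency", {
  pools <- calibrated_pair()
  ts <- build_test_set(pools, simulation_design(100), seed = 73)
  q <- em_admixture(ts, seed = 74)
  q <- align_clusters(list(q), ts$ids[ts$truth == "PURE_A"])[[1]]
  scan <- threshold_scan(ts$truth, q, method = "structure_q",
                         grid = threshold_grid())
  tab <- scan$table[scan$table$category == "HYBRID", ]
  wide <- merge(tab[tab$subset == "all", c("threshold", "efficiency")],
                tab[tab$subset == "no_bc2", c("threshold", "efficiency")],
                by = "threshold", suffixes = c("_all", "_nobc2"))
  expect_true(all(wide$efficiency_nobc2 >= wide$efficiency_all - 1e-12))
})

test_that("removal curves match brute-force filtering exactly", {
  set.seed(79)
  truth <- sample(hybrid_class_labels(), 300, replace = TRUE)
  q <- stats::runif(300)
  grid <- threshold_grid()
  rc <- removal_curve(truth, q, grid)
  for (Tq in sample(grid, 4)) {
    removed <- !(q >= Tq)                      # brute-force culling rule
    row <- rc$overall[rc$overall$threshold == Tq, ]
    expect_equal(row$overall_removed, mean(removed))
    expect_equal(row$pure_A_removed, mean(removed[truth == "PURE_A"]))
    hyb <- !(truth %in% c("PURE_A", "PURE_B"))
    expect_equal(row$hybrid_not_removed, mean(!removed[hyb]))
  }
  # monotonicity: removal never decreases as the threshold rises
  expect_true(all(diff(rc$overall$overall_removed) >= -1e-12))
  expect_true(all(diff(rc$overall$pure_A_removed) >= -1e-12))
  # all-pure sample below the minimum Q: nothing removed
  rc0 <- removal_curve(rep("PURE_A", 5), rep(0.995, 5), grid = 0.99)
  expect_equal(rc0$overall$overall_removed, 0)
})

test_that("hybrid-class removal difficulty follows expected ancestry", {
  pools <- calibrated_pair()
  ts <- build_test_set(pools, simulation_design(250), seed = 83)
  q <- em_admixture(ts, seed = 84)
  q <- align_clusters(list(q), ts$ids[ts$truth == "PURE_A"])[[1]]
  rc <- removal_curve(ts$truth, q, grid = 0.90)
  pc <- rc$per_class
  frac <- stats::setNames(pc$removed_fraction, pc$class)
  # the double backcross to A escapes removal most often
  expect_lt(frac["BC2_A"], frac["BC_A"])
  expect_lt(frac["BC_A"], frac["F1"])
})

test_that("per-location composition respects the minimum-size rule", {
  labels <- c(rep("PURE_A", 7), rep("HYBRID", 3),  # loc1: n = 10
              rep("PURE_A", 9),                    # loc2: n = 9, dropped
              rep("PURE_A", 10))                   # loc3: all pure
  locations <- c(rep("loc1", 10), rep("loc2", 9), rep("loc3", 10))
  lc <- location_composition(labels, locations)
  expect_identical(nrow(lc$table), 2L)
  l1 <- lc$table[lc$table$location == "loc1", ]
  expect_equal(l1$frac_hybrid, 0.3)
  expect_equal(rowSums(lc$table[, c("frac_pure_A", "frac_pure_B",
                                    "frac_hybrid")]),
               rep(1, 2), ignore_attr = TRUE)
  expect_identical(lc$n_all_pure_A, 1L)
})

test_that("method comparison is a symmetric count of label differences", {
  a <- c(rep("PURE_A", 98), "HYBRID", "PURE_B")
  b <- c(rep("PURE_A", 98), "PURE_A", "HYBRID")
  cmp <- compare_methods(a, b)
  expect_identical(cmp$n_differ, 2L)
  expect_equal(cmp$fraction_differ, 0.02)
  expect_identical(compare_methods(a, a)$n_differ, 0L)
  expect_identical(compare_methods(b, a)$n_differ, cmp$n_differ)
})
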