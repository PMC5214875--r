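test_that("run presets carry the standard lengths", {
  p <- run_preset("short")
  expect_equal(p$total, 1e5); expect_equal(p$burnin, 1e4)
  p <- run_preset("long")
  expect_equal(p$total, 1.2e6); expect_equal(p$burnin, 2e5)
  p <- run_preset("very_long")
  expect_equal(p$total, 2.4e6); expect_equal(p$burnin, 4e5)
  expect_error(run_preset("custom", total = 100, burnin = 200), "burn-in")
  # thinning auto-raised to bound retained samples
  expect_gte(run_preset("very_long")$thin, (2.4e6 - 4e5) / 20000)
})

test_that("supervised EM recovers boundary and symmetric ancestries", {
  pools <- diagnostic_pools(12)
  a <- sample_population(pools$pool_A, 5, group = "A", seed = 1)
  f1 <- cross(a, sample_population(pools$pool_B, 5, group = "B", seed = 2),
              10, group = "F1", seed = 3)
  qa <- em_admixture(a, pools = pools)
  expect_true(all(qa$Q > 1 - 1e-6))
  qf <- em_admixture(f1, pools = pools)
  expect_equal(qf$Q, rep(0.5, 10), tolerance = 1e-9)
})

test_that("EM log-likelihood is non-decreasing every iteration", {
  pools <- calibrated_pair()
  ts <- build_test_set(pools, simulation_design(15), seed = 4)
  for (sup in c(TRUE, FALSE)) {
    q <- em_admixture(ts, pools = if (sup) pools, seed = 6)
    trace <- attr(q, "loglik_trace")
    expect_true(all(diff(trace) > -1e-6))
    expect_true(attr(q, "converged"))
  }
})

test_that("alleles absent from both pools never crash supervised EM", {
  pools <- diagnostic_pools(3)
  geno <- matrix(c(999L, 999L, 230L, 230L, 260L, 260L), 1)
  d <- genotype_dataset("x", "g", pools$pool_A$loci, geno)
  expect_silent(q <- em_admixture(d, pools = pools))
  expect_true(is.finite(q$Q))
})

test_that("Gibbs Q matches the likelihood limit on diagnostic pools", {
  pools <- diagnostic_pools(12)
  a <- sample_population(pools$pool_A, 20, group = "A", seed = 1)
  b <- sample_population(pools$pool_B, 20, group = "B", seed = 2)
  f1 <- cross(a, b, 20, group = "F1", seed = 3)
  d <- bind_datasets(a, b, f1)
  q <- gibbs_admixture(d, preset = run_preset("custom", total = 4000,
                                              burnin = 1000),
                       reference_A = a$ids, seed = 5)
  expect_true(all(q$Q[1:20] >= 0.95))
  expect_true(all(q$Q[21:40] <= 0.05))
  # F1 posterior mean near 0.5 (EM oracle gives exactly 0.5)
  expect_true(all(abs(q$Q[41:60] - 0.5) <= 0.05))
  # credible bounds bracket the posterior mean, Q within [0,1]
  expect_true(all(q$ci_low <= q$Q & q$Q <= q$ci_high))
  expect_true(all(q$Q >= 0 & q$Q <= 1))
})

test_that("the correlated-frequency model runs and separates clusters", {
  pools <- diagnostic_pools(8)
  a <- sample_population(pools$pool_A, 15, group = "A", seed = 1)
  b <- sample_population(pools$pool_B, 15, group = "B", seed = 2)
  d <- bind_datasets(a, b)
  q <- gibbs_admixture(d, admixture_config(frequency_model = "correlated"),
                       preset = run_preset("custom", total = 4000,
                                           burnin = 1000),
                       reference_A = a$ids, seed = 9)
  expect_true(all(q$Q[1:15] > 0.9))
  expect_true(all(q$Q[16:30] < 0.1))
  expect_true(all(attr(q, "F") > 0 & attr(q, "F") < 1))
})

test_that("cluster alignment flips labels and is idempotent", {
  run <- data.frame(id = c("a", "b", "c"), Q = c(0.1, 0.2, 0.9),
                    ci_low = c(0.05, 0.1, 0.8),
                    ci_high = c(0.15, 0.3, 0.95))
  al <- align_clusters(list(run), reference_A = c("a", "b"))[[1]]
  expect_equal(al$Q, c(0.9, 0.8, 0.1))
  expect_equal(al$ci_low, c(0.85, 0.7, 0.05))
  expect_equal(al$ci_high, c(0.95, 0.9, 0.2))
  # already aligned: unchanged; aligning twice equals aligning once
  expect_identical(align_clusters(list(al), c("a", "b"))[[1]], al)
  tie <- data.frame(id = c("a", "b"), Q = c(0.4, 0.6))
  expect_error(align_clusters(list(tie), c("a", "b")), "tie")
})

test_that("run consistency counts strict exceedances of delta", {
  r1 <- data.frame(id = c("a", "b"), Q = c(0.90, 0.50))
  expect_identical(run_consistency(list(r1, r1))$n_changed, 0L)
  r2 <- data.frame(id = c("a", "b"), Q = c(0.96, 0.50))
  expect_identical(run_consistency(list(r1, r2))$n_changed, 1L)
  r3 <- data.frame(id = c("a", "b"), Q = c(0.95, 0.50))
  expect_identical(run_consistency(list(r1, r3))$n_changed, 0L)
  expect_error(run_consistency(list(r1)), "at least 2")
  expect_error(run_consistency(list(r1, data.frame(id = "z", Q = 0.5))),
               "different individual sets")
})

test_that("independent short chains agree closely on simulated data", {
  pools <- calibrated_pair()
  ts <- build_test_set(pools, simulation_design(30), seed = 11)
  refA <- ts$ids[ts$truth == "PURE_A"]
  preset <- run_preset("custom", total = 6000, burnin = 2000)
  runs <- lapply(c(21, 22), function(s)
    gibbs_admixture(ts, preset = preset, reference_A = refA, seed = s))
  cons <- run_consistency(runs, delta = 0.05)
  # replicate stability: almost no individual moves by more than 0.05
  expect_lte(cons$n_changed, ceiling(0.05 * length(ts$ids)))
})
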