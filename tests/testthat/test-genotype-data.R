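test_that("genotype_dataset validates its invariants", {
  d <- toy_dataset()
  expect_s3_class(d, "genotype_dataset")
  expect_identical(length(d$ids), 3L)
  # one call slot per locus per individual
  expect_identical(dim(d$alleles), c(3L, 4L))
  # positive allele sizes enforced
  expect_error(genotype_dataset("a", "g", "L1", matrix(c(-1L, 5L), 1)),
               "positive")
  # half-missing calls rejected
  expect_error(genotype_dataset("a", "g", "L1", matrix(c(NA, 5L), 1)),
               "fully")
  expect_error(genotype_dataset(c("a", "a"), "g", "L1",
                                matrix(c(1L, 1L, 2L, 2L), 2)),
               "unique")
})

test_that("GenePop round trip preserves calls, groups and missing data", {
  d <- toy_dataset()
  d$alleles[2, 3:4] <- NA_integer_
  d <- genotype_dataset(d$ids, d$group, d$loci, d$alleles)
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(d, path)
  d2 <- read_genepop(path)
  expect_identical(d2$alleles, d$alleles)
  expect_identical(length(unique(d2$group)), 2L)
  expect_identical(d2$loci, d$loci)
})

test_that("GenePop parser handles the missing code and malformed input", {
  path <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("title", "LA", "LB", "pop",
               "ind1 , 100100 000000",
               "ind2 , 100104 200202"), path)
  d <- read_genepop(path)
  expect_identical(unname(d$alleles[1, 3:4]), c(NA_integer_, NA_integer_))
  expect_identical(unname(d$alleles[2, ]), c(100L, 104L, 200L, 202L))

  writeLines(c("title", "LA", "LB",
               "ind1 , 100100 200200"), path)
  expect_error(read_genepop(path), "pop")

  writeLines(c("title", "LA", "LB", "pop",
               "ind1 , 100100 0202"), path)
  expect_error(read_genepop(path), "width")
})

test_that("STRUCTURE table round trip is the identity", {
  set.seed(31)
  pools <- toy_pools()
  d <- sample_population(pools$pool_B, 12, group = "farm_9")
  d <- inject_missingness(d, 0.15)
  path <- withr::local_tempfile(fileext = ".str")
  write_structure_table(d, path)
  d2 <- read_structure_table(path)
  expect_identical(unname(d2$alleles), unname(d$alleles))
  expect_identical(d2$ids, d$ids)
  expect_identical(d2$group, d$group)

  # -9 entries decode to missing
  expect_identical(is.na(d2$alleles), is.na(d$alleles))
  expect_identical(d2$loci, d$loci)
  # row pairs carrying different ids are rejected
  path2 <- withr::local_tempfile(fileext = ".str")
  writeLines(c("x\t1\t100\t102", "y\t1\t100\t102"), path2)
  expect_error(read_structure_table(path2), "pairs")
  # odd row counts are rejected
  writeLines(c("x\t1\t100\t102"), path2)
  expect_error(read_structure_table(path2), "odd")
})

test_that("allele frequencies count gene copies and exclude missing", {
  geno <- rbind(c(100L, 100L), c(100L, 104L))
  d <- genotype_dataset(c("a", "b"), "g", "L1", geno)
  f <- allele_frequencies(d, "g")
  expect_equal(unname(f$freqs[["L1"]]), c(0.75, 0.25))

  geno <- rbind(c(100L, 100L), c(NA_integer_, NA_integer_))
  d <- genotype_dataset(c("a", "b"), "g", "L1", geno)
  f <- allele_frequencies(d, "g")
  expect_equal(unname(f$freqs[["L1"]]), 1)

  geno <- matrix(NA_integer_, 2, 2)
  d <- genotype_dataset(c("a", "b"), "g", "L1", geno)
  expect_error(allele_frequencies(d, "g"), "L1")
})

test_that("pool frequencies always sum to one per locus", {
  set.seed(5)
  for (rep in 1:5) {
    pools <- calibrated_pair()
    d <- sample_population(pools$pool_B, 20, group = "g")
    f <- allele_frequencies(d, "g")
    sums <- vapply(f$freqs, sum, 0)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("diversity statistics match hand calculations", {
  # {100/104, 100/100}: Ho = 1/2; p = (3/4, 1/4); n = 2
  # plain He = 1 - (9/16 + 1/16) = 0.375; unbiased = 4/3 * 0.375 = 0.5
  geno <- rbind(c(100L, 104L), c(100L, 100L))
  d <- genotype_dataset(c("a", "b"), "g", "L1", geno)
  s <- diversity_stats(d, "g")
  expect_equal(s$per_locus$Ho, 0.5)
  expect_equal(s$per_locus$He, 0.5)
  expect_equal(diversity_stats(d, "g", unbiased = FALSE)$per_locus$He, 0.375)

  # monomorphic locus
  geno <- rbind(c(100L, 100L), c(100L, 100L))
  d <- genotype_dataset(c("a", "b"), "g", "L1", geno)
  s <- diversity_stats(d, "g")
  expect_equal(s$per_locus$A, 1)
  expect_equal(s$per_locus$Ho, 0)
  expect_equal(s$per_locus$He, 0)
})

test_that("He is invariant under allele relabeling", {
  set.seed(11)
  pools <- toy_pools()
  d <- sample_population(pools$pool_A, 40, group = "g")
  s1 <- diversity_stats(d, "g")
  shifted <- genotype_dataset(d$ids, d$group, d$loci, d$alleles + 50L)
  s2 <- diversity_stats(shifted, "g")
  expect_equal(s1$per_locus$He, s2$per_locus$He)
  expect_equal(s1$per_locus$Ho, s2$per_locus$Ho)
})

test_that("PCA separates fixed groups and places F1s midway", {
  pools <- diagnostic_pools(4)
  set.seed(21)
  a <- sample_population(pools$pool_A, 10, group = "A")
  b <- sample_population(pools$pool_B, 10, group = "B")
  f1 <- cross(a, b, 10, group = "F1")
  pc <- pca_individuals(bind_datasets(a, b, f1))
  g <- c(rep("A", 10), rep("B", 10), rep("F1", 10))
  centers <- tapply(pc$scores[, 1], g, mean)
  spread <- tapply(pc$scores[, 1], g, stats::sd)
  # parental clusters are points (zero within-group spread on PC1)
  expect_lt(max(spread[c("A", "B")]), 1e-8)
  # F1s sit exactly midway between the parental clusters
  expect_equal(unname(centers["F1"]),
               unname((centers["A"] + centers["B"]) / 2), tolerance = 1e-8)
  # explained variance fractions non-increasing and bounded
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-12)
})

test_that("duplicate individuals receive identical PCA coordinates", {
  d <- toy_dataset()
  d2 <- bind_datasets(d, genotype_dataset(paste0(d$ids, "_dup"), d$group,
                                          d$loci, d$alleles))
  pc <- pca_individuals(d2)
  expect_equal(unname(pc$scores[1:3, ]), unname(pc$scores[4:6, ]))
})

test_that("all-identical individuals are flagged as zero-variance", {
  geno <- matrix(rep(c(100L, 100L, 200L, 200L), 3), 3, byrow = TRUE)
  d <- genotype_dataset(c("a", "b", "c"), "g", c("LA", "LB"), geno)
  expect_warning(pc <- pca_individuals(d), "zero-variance")
  expect_true(pc$zero_variance)
})
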