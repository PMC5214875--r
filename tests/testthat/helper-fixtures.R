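# Shared fixtures: small pools and datasets built in code.

# fully diagnostic pools: disjoint fixed alleles at every locus
diagnostic_pools <- function(n_loci = 12L) {
  loci <- sprintf("L%02d", seq_len(n_loci))
  freqs_A <- lapply(seq_len(n_loci), function(l)
    stats::setNames(1, 100 + 30 * (l - 1)))
  freqs_B <- lapply(seq_len(n_loci), function(l)
    stats::setNames(1, 120 + 30 * (l - 1)))
  list(pool_A = allele_freq_pool(loci, freqs_A),
       pool_B = allele_freq_pool(loci, freqs_B))
}

# small polymorphic pools with partial overlap (2 loci)
toy_pools <- function() {
  loci <- c("LA", "LB")
  pool_A <- allele_freq_pool(loci, list(
    c(`100` = 0.7, `102` = 0.2, `104` = 0.1),
    c(`200` = 0.8, `202` = 0.2)))
  pool_B <- allele_freq_pool(loci, list(
    c(`102` = 0.1, `104` = 0.3, `110` = 0.6),
    c(`202` = 0.5, `208` = 0.5)))
  list(pool_A = pool_A, pool_B = pool_B)
}

# tiny hand-built dataset: 3 individuals, 2 loci
toy_dataset <- function() {
  geno <- rbind(c(100L, 100L, 200L, 202L),
                c(100L, 104L, 200L, 200L),
                c(110L, 110L, 208L, 208L))
  genotype_dataset(c("i1", "i2", "i3"), c("g1", "g1", "g2"),
                   c("LA", "LB"), geno)
}

# default calibrated reference pair, computed once per test run
calibrated_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_pools(calibration_spec(),
                                                  seed = 42)
    cache
  }
})
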