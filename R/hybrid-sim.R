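#' Pedigree hybrid classes
#'
#' The eight pedigree classes simulated by the crossing engine: the two
#' nonadmixed parental taxa, first- and second-generation hybrids, single
#' backcrosses, and double backcrosses. `class_expected_ancestry()` gives the
#' expected proportion of the genome originating from taxon A for each class.
#'
#' @return character vector of class labels / named numeric vector of
#'   expected A-ancestry.
#' @export
hybrid_class_labels <- function() {
  c("PURE_A", "PURE_B", "F1", "F2", "BC_A", "BC_B", "BC2_A", "BC2_B")
}

#' @rdname hybrid_class_labels
#' @export
class_expected_ancestry <- function() {
  c(PURE_A = 1, PURE_B = 0, F1 = 0.5, F2 = 0.5,
    BC_A = 0.75, BC_B = 0.25, BC2_A = 0.875, BC2_B = 0.125)
}

#' Draw a gamete from a diploid genotype
#'
#' At each locus one of the two parental alleles is chosen with probability
#' 1/2, independently across loci (free recombination, the standard model for
#' unlinked microsatellites).
#'
#' @param genotype integer vector of length `2 * L` (the `alleles` row of a
#'   [genotype_dataset()]); no missing calls allowed.
#' @return integer vector of length `L`, one allele per locus.
#' @export
gamete <- function(genotype) {
  if (anyNA(genotype)) stop("cannot draw a gamete from a missing call")
  L <- length(genotype) / 2L
  pick <- stats::runif(L) < 0.5
  a1 <- genotype[seq(1L, 2L * L, by = 2L)]
  a2 <- genotype[seq(2L, 2L * L, by = 2L)]
  ifelse(pick, a1, a2)
}

# vectorized gametes for rows `idx` of a dataset: returns n x L matrix
gametes_of <- function(dataset, idx) {
  L <- length(dataset$loci)
  n <- length(idx)
  a1 <- dataset$alleles[idx, seq(1L, 2L * L, by = 2L), drop = FALSE]
  a2 <- dataset$alleles[idx, seq(2L, 2L * L, by = 2L), drop = FALSE]
  if (anyNA(a1) || anyNA(a2)) stop("cannot draw a gamete from a missing call")
  pick <- matrix(stats::runif(n * L) < 0.5, nrow = n)
  out <- a1
  out[!pick] <- a2[!pick]
  out
}

#' Cross two parent sets
#'
#' Each offspring receives one gamete from a parent drawn uniformly with
#' replacement from each set. Parents must be fully genotyped at the same
#' loci.
#'
#' @param parents_1,parents_2 [genotype_dataset()]s sharing the same loci.
#' @param n number of offspring.
#' @param group group label for the offspring.
#' @param truth optional pedigree class recorded for the offspring.
#' @param seed optional integer seed.
#' @return a [genotype_dataset()] of offspring.
#' @export
cross <- function(parents_1, parents_2, n, group = "cross", truth = NULL,
                  seed = NULL) {
  if (!identical(parents_1$loci, parents_2$loci)) {
    stop("parent sets must share the same loci")
  }
  if (n_ind(parents_1) == 0L || n_ind(parents_2) == 0L) {
    stop("empty parent set")
  }
  if (!is.null(seed)) set.seed(seed)
  i1 <- sample.int(n_ind(parents_1), n, replace = TRUE)
  i2 <- sample.int(n_ind(parents_2), n, replace = TRUE)
  g1 <- gametes_of(parents_1, i1)
  g2 <- gametes_of(parents_2, i2)
  L <- length(parents_1$loci)
  geno <- matrix(NA_integer_, nrow = n, ncol = 2L * L)
  geno[, seq(1L, 2L * L, by = 2L)] <- g1
  geno[, seq(2L, 2L * L, by = 2L)] <- g2
  genotype_dataset(sprintf("%s_%04d", group, seq_len(n)), group,
                   parents_1$loci, geno,
                   truth = if (!is.null(truth)) rep(truth, n))
}

#' Per-class sample counts for the simulated test set
#'
#' @param n_per_class either a single count applied to all eight classes
#'   (default 500, giving the standard 4,000-individual test set) or a named
#'   vector over [hybrid_class_labels()].
#' @param n_parents size of each intermediate parent pool (>= 200); parent
#'   pools are generated fresh and never appear among the study individuals.
#' @return a list of class `simulation_design`.
#' @export
simulation_design <- function(n_per_class = 500L, n_parents = 200L) {
  labels <- hybrid_class_labels()
  if (length(n_per_class) == 1L) {
    counts <- stats::setNames(rep(as.integer(n_per_class), 8L), labels)
  } else {
    counts <- stats::setNames(rep(0L, 8L), labels)
    counts[names(n_per_class)] <- as.integer(n_per_class)
  }
  if (any(counts < 0L) || sum(counts) < 1L) stop("invalid class counts")
  if (n_parents < 2L) stop("n_parents must be >= 2")
  structure(list(counts = counts, n_parents = as.integer(n_parents)),
            class = "simulation_design")
}

#' Build the simulated test set of known-pedigree individuals
#'
#' Generates the hybrid-class test set from a calibrated reference pair:
#' pure classes are sampled from the pools under Hardy-Weinberg proportions;
#' F1 = pure_A x pure_B; F2 = F1 x F1 (intercross); BC = F1 x pure parent;
#' BC2 = BC x fresh pure parent. All crosses use fresh intermediate parent
#' pools that never appear among the returned study individuals. The true
#' pedigree class of every individual is recorded in `truth`.
#'
#' @param pools a `reference_pair` from [calibrate_pools()], or any list with
#'   `pool_A` and `pool_B` [allele_freq_pool()]s.
#' @param design a [simulation_design()].
#' @param seed optional integer seed.
#' @return a [genotype_dataset()] with `truth` labels; groups equal the class
#'   labels.
#' @export
build_test_set <- function(pools, design = simulation_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cnt <- design$counts
  np <- design$n_parents
  pa <- sample_population(pools$pool_A, np, group = "parent_A")
  pb <- sample_population(pools$pool_B, np, group = "parent_B")
  f1p <- cross(pa, pb, np, group = "parent_F1")
  bcap <- cross(f1p, pa, np, group = "parent_BCA")
  bcbp <- cross(f1p, pb, np, group = "parent_BCB")

  parts <- list()
  gen <- function(label) {
    n <- cnt[[label]]
    if (n == 0L) return(NULL)
    switch(label,
      PURE_A = sample_population(pools$pool_A, n, group = label,
                                 id_prefix = label, truth = label),
      PURE_B = sample_population(pools$pool_B, n, group = label,
                                 id_prefix = label, truth = label),
      F1 = cross(pa, pb, n, group = label, truth = label),
      F2 = cross(f1p, f1p, n, group = label, truth = label),
      BC_A = cross(f1p, pa, n, group = label, truth = label),
      BC_B = cross(f1p, pb, n, group = label, truth = label),
      BC2_A = cross(bcap, pa, n, group = label, truth = label),
      BC2_B = cross(bcbp, pb, n, group = label, truth = label))
  }
  for (label in hybrid_class_labels()) {
    d <- gen(label)
    if (!is.null(d)) parts[[label]] <- d
  }
  bind_datasets(parts)
}

#' Write the truth sidecar table of a simulated dataset
#'
#' @param dataset a [genotype_dataset()] with `truth` labels.
#' @param path output path (tab-separated `id`, `class`).
#' @return invisibly, `path`.
#' @export
write_truth_table <- function(dataset, path) {
  if (is.null(dataset$truth)) stop("dataset carries no truth labels")
  utils::write.table(data.frame(id = dataset$ids, class = dataset$truth),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
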