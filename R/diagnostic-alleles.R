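#' Find species-specific (private, diagnostic) alleles
#'
#' An allele of the target taxon is diagnostic when it is (a) at appreciable
#' frequency in the target pool (strictly above `f_min`), (b) absent or
#' nearly so from the other pool (strictly below `f_max`), and (c) at least
#' `min_dist_bp` base pairs from every allele "known" in the other pool,
#' where known means at frequency at least `f_max` (present above the noise
#' floor). A locus with no known other-pool allele imposes no distance
#' constraint.
#'
#' @param pool_target,pool_other [allele_freq_pool()]s over the same loci.
#' @param f_min minimum target-pool frequency (default 0.05, strict).
#' @param f_max other-pool frequency ceiling / noise floor (default 0.005).
#' @param min_dist_bp minimum distance to a known other-pool allele
#'   (default 3).
#' @return data frame `locus`, `allele`, `freq_target`, `freq_other`,
#'   `min_dist_bp_observed` — one row per qualifying allele.
#' @export
find_species_specific <- function(pool_target, pool_other, f_min = 0.05,
                                  f_max = 0.005, min_dist_bp = 3) {
  if (!identical(pool_target$loci, pool_other$loci)) {
    stop("pools must share the same loci")
  }
  rows <- list()
  for (l in seq_along(pool_target$loci)) {
    ft <- pool_target$freqs[[l]]
    fo <- pool_other$freqs[[l]]
    known <- as.integer(names(fo)[fo >= f_max])
    for (a in as.integer(names(ft))) {
      fa <- ft[[as.character(a)]]
      if (fa <= f_min) next
      oa <- fo[as.character(a)]
      if (!is.na(oa) && oa >= f_max) next
      d <- if (length(known) == 0L) Inf else min(abs(a - known))
      if (d < min_dist_bp) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus = pool_target$loci[l], allele = a, freq_target = fa,
        freq_other = if (is.na(oa)) 0 else unname(oa),
        min_dist_bp_observed = d)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus = character(0), allele = integer(0),
                      freq_target = numeric(0), freq_other = numeric(0),
                      min_dist_bp_observed = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Find alleles fixed in one taxon and absent from the other
#'
#' An allele qualifies when its target-pool frequency is at least `fix_min`
#' (near fixation; "frequency ~ 1" is read as approximately fixed, hence the
#' 0.995 default rather than exactly 1) and its other-pool frequency is at
#' most `absent_max`.
#'
#' @param pool_target,pool_other [allele_freq_pool()]s over the same loci.
#' @param fix_min fixation floor in the target pool (default 0.995).
#' @param absent_max frequency ceiling in the other pool (default 0).
#' @return data frame `locus`, `allele`, `freq_target`, `freq_other`.
#' @export
find_fixed_alleles <- function(pool_target, pool_other, fix_min = 0.995,
                               absent_max = 0) {
  if (!identical(pool_target$loci, pool_other$loci)) {
    stop("pools must share the same loci")
  }
  rows <- list()
  for (l in seq_along(pool_target$loci)) {
    ft <- pool_target$freqs[[l]]
    fo <- pool_other$freqs[[l]]
    for (a in as.integer(names(ft))) {
      fa <- ft[[as.character(a)]]
      if (fa < fix_min) next
      oa <- fo[as.character(a)]
      oa <- if (is.na(oa)) 0 else unname(oa)
      if (oa > absent_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus = pool_target$loci[l], allele = a,
        freq_target = unname(fa), freq_other = oa)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus = character(0), allele = integer(0),
                      freq_target = numeric(0), freq_other = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Assemble the diagnostic-allele set for a reference pair
#'
#' Convenience wrapper running [find_species_specific()] in both directions
#' and [find_fixed_alleles()] for taxon A against a calibrated (or
#' empirically estimated) pair of pools.
#'
#' @param pools a `reference_pair` or list with `pool_A`, `pool_B`.
#' @param f_min,f_max,min_dist_bp diagnostic-rule parameters.
#' @param fix_min,absent_max fixation-rule parameters.
#' @return a list of class `diagnostic_allele_set`: data frames
#'   `specific_B`, `specific_A`, `fixed_A`, plus the rule parameters.
#' @export
diagnostic_allele_set <- function(pools, f_min = 0.05, f_max = 0.005,
                                  min_dist_bp = 3, fix_min = 0.995,
                                  absent_max = 0) {
  out <- list(
    specific_B = find_species_specific(pools$pool_B, pools$pool_A,
                                       f_min, f_max, min_dist_bp),
    specific_A = find_species_specific(pools$pool_A, pools$pool_B,
                                       f_min, f_max, min_dist_bp),
    fixed_A = find_fixed_alleles(pools$pool_A, pools$pool_B,
                                 fix_min, absent_max),
    params = list(f_min = f_min, f_max = f_max, min_dist_bp = min_dist_bp,
                  fix_min = fix_min, absent_max = absent_max))
  both <- merge(out$specific_A[c("locus", "allele")],
                out$specific_B[c("locus", "allele")])
  if (nrow(both) > 0L) {
    stop("internal inconsistency: allele diagnostic for both taxa")
  }
  class(out) <- "diagnostic_allele_set"
  out
}

#' Classify individuals by diagnostic-allele carriage
#'
#' The non-model-based hybrid detector: flags each individual for (i)
#' carrying at least one taxon-B-private allele (evidence of B introgression)
#' and (ii) carrying the near-fixed taxon-A allele at every fixed locus with
#' a non-missing call. Missing calls are skipped — they neither provide the
#' flag nor disqualify it — unless `strict = TRUE`, in which case a missing
#' call at a fixed locus breaks the all-fixed condition.
#'
#' @param dataset a [genotype_dataset()] whose loci include all diagnostic
#'   loci.
#' @param diag a [diagnostic_allele_set()].
#' @param strict treat a missing call at a fixed locus as failing the
#'   all-fixed condition (default FALSE).
#' @return data frame `id`, `has_B_specific`, `has_all_A_fixed`,
#'   `n_B_specific` (count of B-private alleles carried).
#' @export
classify_by_alleles <- function(dataset, diag, strict = FALSE) {
  need <- unique(c(diag$specific_B$locus, diag$fixed_A$locus))
  unknown <- setdiff(need, dataset$loci)
  if (length(unknown) > 0L) {
    stop("diagnostic set references unknown locus: ",
         paste(unknown, collapse = ", "))
  }
  n <- n_ind(dataset)
  n_spec <- integer(n)
  for (r in seq_len(nrow(diag$specific_B))) {
    l <- match(diag$specific_B$locus[r], dataset$loci)
    a <- diag$specific_B$allele[r]
    x <- dataset$alleles[, 2L * l - 1L]
    y <- dataset$alleles[, 2L * l]
    hit <- (!is.na(x) & x == a) + (!is.na(y) & y == a)
    n_spec <- n_spec + hit
  }
  all_fixed <- rep(TRUE, n)
  for (r in seq_len(nrow(diag$fixed_A))) {
    l <- match(diag$fixed_A$locus[r], dataset$loci)
    a <- diag$fixed_A$allele[r]
    x <- dataset$alleles[, 2L * l - 1L]
    y <- dataset$alleles[, 2L * l]
    has <- (x == a | y == a)
    has[is.na(has)] <- !strict
    all_fixed <- all_fixed & has
  }
  if (nrow(diag$fixed_A) == 0L) all_fixed <- rep(NA, n)
  data.frame(id = dataset$ids, has_B_specific = n_spec > 0L,
             has_all_A_fixed = all_fixed, n_B_specific = n_spec,
             stringsAsFactors = FALSE)
}
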