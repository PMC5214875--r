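#' Calibration targets for a synthetic pair of parental reference pools
#'
#' Describes the summary structure the synthetic parental populations must
#' reproduce: number of loci, mean expected heterozygosity of each taxon,
#' number of taxon-B-private (diagnostic) alleles and the number of loci they
#' occupy, near-fixed taxon-A alleles, and the allele-size lattice. Defaults
#' describe a low-diversity taxon A (bontebok-like, mean He 0.321) and a more
#' variable taxon B (blesbok-like, mean He 0.543) typed at 12 dinucleotide
#' microsatellites, with 17 B-private alleles across 8 loci and near-fixed A
#' alleles at 2 loci.
#'
#' @param n_loci number of microsatellite loci.
#' @param target_he_A,target_he_B mean expected heterozygosity targets.
#' @param n_private_B number of planted B-private diagnostic alleles.
#' @param n_private_loci_B number of loci carrying the private alleles.
#' @param n_fixed_alleles_A number of A-restricted alleles at the fixed loci
#'   (two per fixed locus: a near-fixed major and a trace minor).
#' @param n_fixed_loci_A number of loci carrying a near-fixed A allele.
#' @param n_low_div_loci_A number of taxon-A near-homozygous loci. The
#'   reference low-diversity taxon owes most of its reduced He to a few
#'   near-monomorphic markers; the fixed loci are a subset of these, and any
#'   remainder are near-homozygous for an allele shared with taxon B.
#' @param lattice_step allele-size spacing in base pairs (dinucleotide = 2).
#' @param he_tol tolerance on the achieved mean He.
#' @param n_shared_alleles number of lattice alleles shared by both taxa at
#'   each non-fixed locus.
#' @param private_freq planted frequency of each B-private allele (must
#'   exceed the 0.05 diagnostic cutoff).
#' @return a list of class `calibration_spec`.
#' @export
calibration_spec <- function(n_loci = 12L,
                             target_he_A = 0.321, target_he_B = 0.543,
                             n_private_B = 17L, n_private_loci_B = 8L,
                             n_fixed_alleles_A = 4L, n_fixed_loci_A = 2L,
                             n_low_div_loci_A = 3L,
                             lattice_step = 2L, he_tol = 0.02,
                             n_shared_alleles = 6L, private_freq = 0.08) {
  stopifnot(n_loci >= 1L, target_he_A >= 0, target_he_A < 1,
            target_he_B >= 0, target_he_B < 1, he_tol > 0,
            n_low_div_loci_A >= n_fixed_loci_A,
            n_private_loci_B <= n_loci - n_low_div_loci_A,
            n_private_B >= n_private_loci_B,
            n_fixed_loci_A >= 0L, n_low_div_loci_A < n_loci,
            lattice_step >= 1L, n_shared_alleles >= 2L,
            private_freq > 0.05)
  structure(as.list(environment()), class = "calibration_spec")
}

#' Calibrate a pair of divergent parental allele-frequency pools
#'
#' Builds two allele-frequency pools whose mean expected heterozygosities hit
#' the spec targets and which carry, by construction, the requested number of
#' B-private diagnostic alleles (each at appreciable frequency in B, absent
#' from A, and at least 3 bp from any appreciable A allele) and near-fixed
#' A alleles absent from B.
#'
#' Per-locus base frequencies are drawn from a flat Dirichlet and then
#' "tempered" (`p^t`, renormalized) with a single exponent per pool found by
#' bisection so the post-planting mean He matches its target: `t -> 0` gives
#' even frequencies (maximal He), `t -> Inf` fixation. Shared alleles that
#' are common in B (frequency above the diagnostic cutoff) are kept at
#' frequency >= 0.006 in A so that only the planted alleles satisfy the
#' diagnostic rule; when a near-zero He target forces A to full fixation this
#' guard is dropped and additional B alleles become genuinely diagnostic
#' (a monomorphic taxon makes every foreign allele diagnostic).
#'
#' @param spec a [calibration_spec()].
#' @param seed optional integer seed.
#' @param max_iter bisection iterations before declaring the spec infeasible.
#' @return a list of class `reference_pair`: `pool_A`, `pool_B`
#'   ([allele_freq_pool()]s), `ledger` (data frames `private_B`, `fixed_A`
#'   of planted alleles), `achieved_he_A`, `achieved_he_B`, `spec`.
#' @export
calibrate_pools <- function(spec = calibration_spec(), seed = NULL,
                            max_iter = 60L) {
  stopifnot(inherits(spec, "calibration_spec"))
  if (!is.null(seed)) set.seed(seed)
  L <- spec$n_loci
  step <- spec$lattice_step
  m <- spec$n_shared_alleles
  low_loci <- if (spec$n_low_div_loci_A > 0L)
    seq(L - spec$n_low_div_loci_A + 1L, L) else integer(0)
  fixed_loci <- if (spec$n_fixed_loci_A > 0L)
    seq(L - spec$n_fixed_loci_A + 1L, L) else integer(0)
  # near-homozygous A loci whose major allele is shared with taxon B
  lowshared_loci <- setdiff(low_loci, fixed_loci)
  open_loci <- setdiff(seq_len(L), low_loci)
  private_loci <- open_loci[seq_len(spec$n_private_loci_B)]
  loci <- sprintf("L%02d", seq_len(L))

  # allele-size scaffold: shared lattice block per locus, B-private alleles
  # one lattice gap (>= 3 bp for step 2) beyond the block
  base <- 100L + 30L * (seq_len(L) - 1L)
  shared_sizes <- lapply(seq_len(L), function(l)
    base[l] + step * (seq_len(m) - 1L))
  n_priv <- integer(L)
  n_priv[private_loci] <- diff(floor(seq(0, spec$n_private_B,
                                         length.out = spec$n_private_loci_B + 1L)))
  priv_sizes <- lapply(seq_len(L), function(l) {
    if (n_priv[l] == 0L) return(integer(0))
    top <- base[l] + step * (m - 1L)
    top + 2L * step + step * (seq_len(n_priv[l]) - 1L)
  })

  # base Dirichlet(1) draws, tempered later
  rdirich <- function(k) { g <- stats::rgamma(k, 1); g / sum(g) }
  base_A <- lapply(seq_len(L), function(l)
    if (l %in% fixed_loci) NULL else rdirich(m))
  base_B <- lapply(seq_len(L), function(l)
    if (l %in% fixed_loci) rdirich(3L) else rdirich(m))

  temper <- function(p, t) {
    if (is.infinite(t)) { q <- rep(0, length(p)); q[which.max(p)] <- 1; return(q) }
    w <- exp(t * log(p)); w / sum(w)
  }

  # fixed-locus design: A = major (>=0.995) + trace minor, both absent from
  # B; B = three lattice alleles, each within 2 bp of an A allele so none can
  # pass the 3-bp diagnostic-distance rule
  fix_major <- 0.995
  fixed_A_freqs <- function(l) {
    f <- c(fix_major, 1 - fix_major)
    names(f) <- c(base[l], base[l] + 2L * step)
    f
  }
  fixed_B_sizes <- function(l) base[l] + step * c(1L, 2L, 3L)

  lowshared_A_freqs <- function(l) {
    p <- c(0.99, rep(0.01 / (m - 1), m - 1L))
    names(p) <- shared_sizes[[l]]
    p
  }
  build_A <- function(t) {
    freqs <- vector("list", L)
    for (l in seq_len(L)) {
      if (l %in% fixed_loci) { freqs[[l]] <- fixed_A_freqs(l); next }
      if (l %in% lowshared_loci) { freqs[[l]] <- lowshared_A_freqs(l); next }
      p <- temper(base_A[[l]], t)
      names(p) <- shared_sizes[[l]]
      freqs[[l]] <- p
    }
    freqs
  }
  build_B <- function(t) {
    freqs <- vector("list", L)
    for (l in seq_len(L)) {
      if (l %in% fixed_loci) {
        p <- temper(base_B[[l]], t)
        names(p) <- fixed_B_sizes(l)
        freqs[[l]] <- p
        next
      }
      pm <- spec$private_freq * n_priv[l]
      p <- temper(base_B[[l]], t) * (1 - pm)
      names(p) <- shared_sizes[[l]]
      if (n_priv[l] > 0L) {
        pv <- rep(spec$private_freq, n_priv[l])
        names(pv) <- priv_sizes[[l]]
        p <- c(p, pv)
      }
      freqs[[l]] <- p
    }
    freqs
  }
  # guard: shared alleles common in B stay at appreciable frequency in A, so
  # no unplanned allele passes the "absent from A" diagnostic criterion
  guard_A <- function(freqs_A, freqs_B) {
    for (l in c(open_loci, lowshared_loci)) {
      fa <- freqs_A[[l]]
      if (max(fa) >= 1 - 1e-12) next  # hard fixation: guard dropped
      fb <- freqs_B[[l]][names(fa)]
      need <- !is.na(fb) & fb > 0.05 & fa < 0.006
      if (any(need)) {
        fa[need] <- 0.006
        fa <- fa / sum(fa)
        freqs_A[[l]] <- fa
      }
    }
    freqs_A
  }
  mean_he <- function(freqs) mean(vapply(freqs, function(f) 1 - sum(f^2), 0))

  # pool B first (independent of A), then A (guard depends on B)
  he_B <- function(t) mean_he(build_B(t))
  t_B <- bisect_temper(he_B, spec$target_he_B, spec$he_tol, max_iter, "B")
  freqs_B <- build_B(t_B)
  he_A <- function(t) mean_he(guard_A(build_A(t), freqs_B))
  t_A <- bisect_temper(he_A, spec$target_he_A, spec$he_tol, max_iter, "A")
  freqs_A <- guard_A(build_A(t_A), freqs_B)

  pool_A <- allele_freq_pool(loci, freqs_A)
  pool_B <- allele_freq_pool(loci, freqs_B)
  ledger <- list(
    private_B = data.frame(
      locus = rep(loci, n_priv),
      allele = unlist(priv_sizes),
      freq_B = rep(spec$private_freq, sum(n_priv))),
    fixed_A = data.frame(
      locus = loci[fixed_loci],
      allele = vapply(fixed_loci, function(l) base[l], 0L),
      freq_A = rep(fix_major, length(fixed_loci))),
    trace_A = data.frame(
      locus = loci[fixed_loci],
      allele = vapply(fixed_loci, function(l) base[l] + 2L * step, 0L),
      freq_A = rep(1 - fix_major, length(fixed_loci))))
  structure(list(pool_A = pool_A, pool_B = pool_B, ledger = ledger,
                 achieved_he_A = mean(pool_he(pool_A)),
                 achieved_he_B = mean(pool_he(pool_B)),
                 spec = spec),
            class = "reference_pair")
}

# monotone-decreasing He(t); bisection on log t, Inf = hard fixation
bisect_temper <- function(he_fun, target, tol, max_iter, label) {
  if (target <= 1e-12) {              # zero target: exact fixation
    he_inf <- he_fun(Inf)
    if (he_inf <= tol) return(Inf)
    stop("calibration failure for pool ", label, ": target He 0 ",
         "unreachable (locus structure forces He ", round(he_inf, 3), ")")
  }
  lo <- 1e-3; hi <- 40
  he_lo <- he_fun(lo)            # maximal He (near-even frequencies)
  he_hi <- he_fun(hi)
  if (target > he_lo + tol) {
    stop("calibration failure for pool ", label, ": target He ", target,
         " exceeds attainable maximum ", round(he_lo, 3))
  }
  if (target < he_hi - tol) {
    he_inf <- he_fun(Inf)
    if (target >= he_inf - tol) return(Inf)
    stop("calibration failure for pool ", label, ": target He ", target,
         " below attainable minimum ", round(he_inf, 3))
  }
  for (i in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    he <- he_fun(mid)
    if (abs(he - target) <= tol * 0.5) return(mid)
    if (he > target) lo <- mid else hi <- mid
  }
  mid <- sqrt(lo * hi)
  if (abs(he_fun(mid) - target) <= tol) return(mid)
  stop("calibration failure for pool ", label,
       ": bisection did not reach tolerance ", tol)
}

#' @export
print.reference_pair <- function(x, ...) {
  cat("reference_pair:", length(x$pool_A$loci), "loci\n")
  cat(sprintf("  mean He: pool_A %.3f, pool_B %.3f\n",
              x$achieved_he_A, x$achieved_he_B))
  cat("  planted:", nrow(x$ledger$private_B), "B-private alleles across",
      length(unique(x$ledger$private_B$locus)), "loci;",
      nrow(x$ledger$fixed_A), "near-fixed A alleles\n")
  invisible(x)
}

#' Sample a population from an allele-frequency pool
#'
#' Each individual's genotype at each locus is two gene copies drawn i.i.d.
#' from the pool frequencies (Hardy-Weinberg proportions, unlinked loci).
#' No missing data are produced; see [inject_missingness()].
#'
#' @param pool an [allele_freq_pool()].
#' @param n number of individuals (>= 1).
#' @param group group label for the sampled individuals.
#' @param id_prefix prefix for generated ids.
#' @param truth optional pedigree class recorded for every individual.
#' @param seed optional integer seed.
#' @return a [genotype_dataset()].
#' @export
sample_population <- function(pool, n, group = "pop", id_prefix = group,
                              truth = NULL, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  L <- length(pool$loci)
  geno <- matrix(NA_integer_, nrow = n, ncol = 2L * L)
  for (l in seq_len(L)) {
    f <- pool$freqs[[l]]
    sizes <- as.integer(names(f))
    draws <- sizes[sample.int(length(sizes), 2L * n, replace = TRUE,
                              prob = f)]
    geno[, 2L * l - 1L] <- draws[seq_len(n)]
    geno[, 2L * l] <- draws[n + seq_len(n)]
  }
  genotype_dataset(sprintf("%s_%04d", id_prefix, seq_len(n)), group,
                   pool$loci, geno,
                   truth = if (!is.null(truth)) rep(truth, n))
}

#' Set calls to missing at random
#'
#' Each call (locus genotype) is independently replaced by a missing value
#' with the given probability, emulating amplification failure.
#'
#' @param dataset a [genotype_dataset()].
#' @param rate missing probability per call, in `[0, 1)`.
#' @param seed optional integer seed.
#' @return a [genotype_dataset()] with the masked calls.
#' @export
inject_missingness <- function(dataset, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(dataset)
  if (!is.null(seed)) set.seed(seed)
  n <- n_ind(dataset); L <- length(dataset$loci)
  mask <- matrix(stats::runif(n * L) < rate, nrow = n)
  geno <- dataset$alleles
  for (l in seq_len(L)) {
    geno[mask[, l], c(2L * l - 1L, 2L * l)] <- NA_integer_
  }
  genotype_dataset(dataset$ids, dataset$group, dataset$loci, geno,
                   truth = dataset$truth)
}
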