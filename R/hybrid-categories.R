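#' Pedigree categories and their genotype-frequency classes
#'
#' Each pedigree category determines, at every locus, the probability that an
#' individual's two gene copies derive both from taxon A, one from each, or
#' both from taxon B. These per-category proportions (phi_AA, phi_AB, phi_BB)
#' are exact consequences of the pedigree and drive the category likelihood.
#'
#' The default set holds the six categories identifiable over two
#' generations: the two nonadmixed taxa, F1, F2 (intercross), and the two
#' single backcrosses. `extended = TRUE` adds the two double backcrosses —
#' off by default because the six-category model is the standard analysis
#' and double backcrosses are not separable from it.
#'
#' @param extended include BC2_A and BC2_B rows.
#' @return matrix with one row per category and columns `AA`, `AB`, `BB`.
#' @export
category_set <- function(extended = FALSE) {
  cats <- c("PURE_A", "PURE_B", "F1", "F2", "BC_A", "BC_B")
  if (extended) cats <- c(cats, "BC2_A", "BC2_B")
  t(vapply(cats, category_class_proportions, numeric(3)))
}

# pedigree: parents of each non-founder category
.pedigree <- list(
  F1 = c("PURE_A", "PURE_B"), F2 = c("F1", "F1"),
  BC_A = c("F1", "PURE_A"), BC_B = c("F1", "PURE_B"),
  BC2_A = c("BC_A", "PURE_A"), BC2_B = c("BC_B", "PURE_B"))

# probability a random gamete of this category carries an A-origin copy
.gamete_prob_A <- function(category) {
  phi <- category_class_proportions(category)
  phi[["AA"]] + phi[["AB"]] / 2
}

#' Genotype-frequency-class proportions of one category
#'
#' Derived by pedigree enumeration: a category's (phi_AA, phi_AB, phi_BB) is
#' the product distribution of its two parents' gamete-origin probabilities,
#' recursively down to the nonadmixed founders.
#'
#' @param category a category label (see [category_set()]).
#' @return named numeric vector `(AA, AB, BB)` summing to 1.
#' @export
category_class_proportions <- function(category) {
  if (category == "PURE_A") return(c(AA = 1, AB = 0, BB = 0))
  if (category == "PURE_B") return(c(AA = 0, AB = 0, BB = 1))
  par <- .pedigree[[category]]
  if (is.null(par)) stop("unknown category: ", category)
  g1 <- .gamete_prob_A(par[1])
  g2 <- .gamete_prob_A(par[2])
  c(AA = g1 * g2, AB = g1 * (1 - g2) + g2 * (1 - g1),
    BB = (1 - g1) * (1 - g2))
}

#' Likelihood of a genotype under one pedigree category
#'
#' For an unordered genotype `{x, y}` with taxon allele frequencies `pA`,
#' `pB` at the locus:
#' `phi_AA * HW(pA) + phi_BB * HW(pB) + phi_AB * mix`, where
#' `HW(p) = p(x)^2` for homozygotes and `2 p(x) p(y)` otherwise, and
#' `mix = p_A(x) p_B(x)` for homozygotes, `p_A(x) p_B(y) + p_A(y) p_B(x)`
#' otherwise. Zero is a valid likelihood.
#'
#' @param x,y allele sizes (integers).
#' @param freq_A,freq_B named frequency vectors at the locus (allele size ->
#'   frequency); absent alleles have frequency 0.
#' @param category category label, or a numeric `(AA, AB, BB)` vector.
#' @return the likelihood (a single probability).
#' @export
genotype_category_likelihood <- function(x, y, freq_A, freq_B, category) {
  phi <- if (is.character(category)) category_class_proportions(category)
         else category
  gA <- function(a) { f <- freq_A[as.character(a)]; if (is.na(f)) 0 else f }
  gB <- function(a) { f <- freq_B[as.character(a)]; if (is.na(f)) 0 else f }
  if (x == y) {
    hwA <- gA(x)^2; hwB <- gB(x)^2; mix <- gA(x) * gB(x)
  } else {
    hwA <- 2 * gA(x) * gA(y); hwB <- 2 * gB(x) * gB(y)
    mix <- gA(x) * gB(y) + gA(y) * gB(x)
  }
  unname(phi[[1]] * hwA + phi[[2]] * mix + phi[[3]] * hwB)
}

#' Direct-Bayes category posterior with known allele frequencies
#'
#' The closed-form posterior over pedigree categories when the parental
#' allele frequencies are known (e.g. the generating pools of a simulation):
#' per-category likelihood = product of [genotype_category_likelihood()]
#' over non-missing loci; posterior = likelihood times a uniform category
#' prior, normalized. This is the deterministic oracle against which the
#' MCMC classifier is validated.
#'
#' @param dataset a [genotype_dataset()].
#' @param pools a `reference_pair` (or list with `pool_A`, `pool_B`).
#' @param extended use the eight-category set.
#' @return a `data.frame` (class `category_posterior`): `id`, then one
#'   probability column per category (rows sum to 1).
#' @export
category_posterior_direct <- function(dataset, pools, extended = FALSE) {
  phi <- category_set(extended)
  C <- nrow(phi)
  L <- length(dataset$loci)
  n <- n_ind(dataset)
  ll <- matrix(0, n, C)
  for (l in seq_len(L)) {
    fA <- pools$pool_A$freqs[[l]]
    fB <- pools$pool_B$freqs[[l]]
    x <- dataset$alleles[, 2L * l - 1L]
    y <- dataset$alleles[, 2L * l]
    gax <- fA[as.character(x)]; gax[is.na(gax)] <- 0
    gay <- fA[as.character(y)]; gay[is.na(gay)] <- 0
    gbx <- fB[as.character(x)]; gbx[is.na(gbx)] <- 0
    gby <- fB[as.character(y)]; gby[is.na(gby)] <- 0
    hom <- !is.na(x) & x == y
    hwA <- ifelse(hom, gax^2, 2 * gax * gay)
    hwB <- ifelse(hom, gbx^2, 2 * gbx * gby)
    mix <- ifelse(hom, gax * gbx, gax * gby + gay * gbx)
    for (cc in seq_len(C)) {
      lc <- phi[cc, 1] * hwA + phi[cc, 2] * mix + phi[cc, 3] * hwB
      contrib <- ifelse(is.na(x), 0, ifelse(lc > 0, log(lc), -Inf))
      ll[, cc] <- ll[, cc] + contrib
    }
  }
  post <- exp(ll - apply(ll, 1L, max))
  post[!is.finite(post)] <- 0
  zero <- rowSums(post) == 0        # genotype impossible under every category
  post[zero, ] <- 1 / C
  post <- post / rowSums(post)
  out <- data.frame(id = dataset$ids, post, stringsAsFactors = FALSE)
  names(out) <- c("id", rownames(phi))
  class(out) <- c("category_posterior", "data.frame")
  out
}

#' MCMC category classifier (no reference ancestry)
#'
#' Gibbs sampler over latent per-individual pedigree categories, per-locus
#' gene-copy origins, the two taxa's allele frequencies (Dirichlet prior:
#' uniform lambda = 1 or Jeffreys lambda = 0.5), and category mixing
#' proportions (flat Dirichlet). No prior population information is used;
#' the two clusters are discovered from the data, as in the standard
#' category-classification analysis.
#'
#' The two clusters are exchangeable, so the species orientation of the
#' output is resolved after sampling: by `reference_A` ids when given,
#' otherwise by expected heterozygosity of the inferred cluster frequencies
#' (taxon A is taken to be the less variable cluster, this package's
#' convention for the low-diversity native taxon). The orientation used is
#' recorded in the `orientation` attribute.
#'
#' @param dataset a [genotype_dataset()] with >= 2 individuals.
#' @param prior `"jeffreys"` (default) or `"uniform"` allele-frequency
#'   prior.
#' @param preset a [run_preset()]; the standard choices are `moderate` and
#'   `long`.
#' @param extended use the eight-category set.
#' @param reference_A optional ids of known taxon-A individuals for
#'   orientation.
#' @param seed optional integer seed.
#' @return a `data.frame` (class `category_posterior`): `id`, one column per
#'   category; attributes `orientation`, `cluster_he` (He of the two
#'   inferred clusters), `preset`, `prior`.
#' @export
category_posterior_mcmc <- function(dataset,
                                    prior = c("jeffreys", "uniform"),
                                    preset = run_preset("moderate"),
                                    extended = FALSE, reference_A = NULL,
                                    seed = NULL) {
  prior <- match.arg(prior)
  if (n_ind(dataset) < 2L) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  lambda <- if (prior == "jeffreys") 0.5 else 1.0
  phi <- category_set(extended)
  enc <- encode_alleles(dataset)
  fit <- .category_gibbs_cpp(enc$geno, enc$n_alleles, unname(phi), lambda,
                             as.integer(preset$total),
                             as.integer(preset$burnin),
                             as.integer(preset$thin))
  if (fit$n_kept < 1L) stop("no post-burn-in samples retained")
  post <- fit$cat_counts / fit$n_kept
  colnames(post) <- rownames(phi)

  off <- c(0L, cumsum(enc$n_alleles))
  he_of <- function(p) {
    mean(vapply(seq_along(enc$n_alleles), function(l) {
      f <- p[(off[l] + 1L):off[l + 1L]]
      1 - sum(f^2)
    }, 0))
  }
  cluster_he <- c(A = he_of(fit$p0_mean), B = he_of(fit$p1_mean))

  swapped <- FALSE
  if (!is.null(reference_A)) {
    i <- match(reference_A, dataset$ids)
    if (anyNA(i)) stop("reference ids missing from dataset")
    swapped <- mean(post[i, "PURE_A"]) < mean(post[i, "PURE_B"])
    orientation <- "reference"
  } else {
    swapped <- cluster_he[["A"]] > cluster_he[["B"]]
    orientation <- "cluster_he"
  }
  if (swapped) {
    swap <- c(PURE_A = "PURE_B", PURE_B = "PURE_A", F1 = "F1", F2 = "F2",
              BC_A = "BC_B", BC_B = "BC_A", BC2_A = "BC2_B",
              BC2_B = "BC2_A")
    post <- post[, swap[colnames(post)], drop = FALSE]
    colnames(post) <- names(swap)[seq_len(ncol(post))]
    cluster_he <- rev(cluster_he)
    names(cluster_he) <- c("A", "B")
  }
  out <- data.frame(id = dataset$ids, post, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out) <- c("id", rownames(phi))
  class(out) <- c("category_posterior", "data.frame")
  attr(out, "orientation") <- orientation
  attr(out, "swapped") <- swapped
  attr(out, "cluster_he") <- cluster_he
  attr(out, "preset") <- preset
  attr(out, "prior") <- prior
  out
}

#' Threshold assignment from category posteriors
#'
#' `six_way`: the argmax category when its posterior exceeds the threshold
#' (strictly), otherwise `"OTHER"`; a tie at the argmax is conservative and
#' yields `"OTHER"`. `three_way`: `"PURE_A"` if its posterior is at least
#' the threshold, `"PURE_B"` likewise, otherwise `"HYBRID"` — the scheme
#' that mirrors a two-cluster ancestry threshold.
#'
#' @param posterior a `category_posterior` data frame.
#' @param threshold assignment threshold in `[0.5, 1)`.
#' @param scheme `"six_way"` or `"three_way"`.
#' @return character vector of labels, one per row of `posterior`.
#' @export
map_category_assignment <- function(posterior, threshold,
                                    scheme = c("six_way", "three_way")) {
  scheme <- match.arg(scheme)
  if (threshold < 0.5 || threshold >= 1) stop("threshold must be in [0.5, 1)")
  p <- as.matrix(posterior[, setdiff(names(posterior), "id"), drop = FALSE])
  if (scheme == "three_way") {
    out <- rep("HYBRID", nrow(p))
    out[p[, "PURE_B"] >= threshold] <- "PURE_B"
    out[p[, "PURE_A"] >= threshold] <- "PURE_A"   # A takes precedence
    return(out)
  }
  vapply(seq_len(nrow(p)), function(i) {
    mx <- max(p[i, ])
    if (mx <= threshold) return("OTHER")
    hit <- which(p[i, ] == mx)
    if (length(hit) > 1L) return("OTHER")
    colnames(p)[hit]
  }, "")
}
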