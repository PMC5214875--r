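#' MCMC run-length presets
#'
#' Named presets for chain length and burn-in: `short` (1e5 total, 1e4
#' burn-in), `long` (1.2e6, 2e5), `very_long` (2.4e6, 4e5), and `moderate`
#' (1e5, 1e4; the category-model naming of the short preset). A `custom`
#' preset takes explicit lengths — the package's tests and examples use short
#' custom chains.
#'
#' @param name one of `"short"`, `"moderate"`, `"long"`, `"very_long"`,
#'   `"custom"`.
#' @param total,burnin chain length and burn-in (required for `"custom"`,
#'   override the preset otherwise).
#' @param thin thinning interval for retained samples (default 10). The
#'   effective interval is raised automatically if the retained sample count
#'   would exceed 20,000, to bound memory on very long chains.
#' @return a list of class `run_preset`.
#' @export
run_preset <- function(name = c("short", "moderate", "long", "very_long",
                                "custom"),
                       total = NULL, burnin = NULL, thin = 10L) {
  name <- match.arg(name)
  std <- list(short = c(1e5, 1e4), moderate = c(1e5, 1e4),
              long = c(1.2e6, 2e5), very_long = c(2.4e6, 4e5))
  if (name == "custom") {
    if (is.null(total) || is.null(burnin)) {
      stop("custom preset needs total and burnin")
    }
  } else {
    if (is.null(total)) total <- std[[name]][1]
    if (is.null(burnin)) burnin <- std[[name]][2]
  }
  total <- as.numeric(total); burnin <- as.numeric(burnin)
  if (burnin >= total) stop("burn-in must be smaller than total length")
  if (thin < 1L) stop("thinning interval must be >= 1")
  thin <- max(as.integer(thin), as.integer(ceiling((total - burnin) / 20000)))
  structure(list(name = name, total = total, burnin = burnin, thin = thin),
            class = "run_preset")
}

#' Configuration of the two-cluster admixture model
#'
#' @param frequency_model `"uncorrelated"` (independent Dirichlet prior per
#'   cluster) or `"correlated"` (hierarchical F-model: cluster frequencies
#'   drift from shared ancestral frequencies, one drift parameter per
#'   cluster with a uniform prior on (0,1)).
#' @param lambda Dirichlet allele-frequency prior parameter (default 1.0,
#'   i.e. uniform).
#' @param alpha_init,alpha_max,alpha_step initial value, upper bound of the
#'   uniform prior, and Metropolis step of the admixture parameter alpha
#'   (single alpha shared by both clusters, inferred during sampling).
#' @param ci_level credible-interval level for reported Q bounds (default
#'   0.90).
#' @return a list of class `admixture_config`.
#' @export
admixture_config <- function(frequency_model = c("uncorrelated",
                                                 "correlated"),
                             lambda = 1.0, alpha_init = 1.0,
                             alpha_max = 10.0, alpha_step = 0.05,
                             ci_level = 0.90) {
  frequency_model <- match.arg(frequency_model)
  stopifnot(lambda > 0, alpha_init > 0, alpha_init <= alpha_max,
            alpha_step > 0, ci_level > 0, ci_level < 1)
  structure(list(frequency_model = frequency_model, lambda = lambda,
                 alpha_init = alpha_init, alpha_max = alpha_max,
                 alpha_step = alpha_step, ci_level = ci_level),
            class = "admixture_config")
}

# encode allele sizes as 0-based per-locus indices over the union of the
# dataset's observed alleles and (optionally) pool alleles; -1 = missing
encode_alleles <- function(dataset, pools = NULL) {
  L <- length(dataset$loci)
  sizes <- vector("list", L)
  for (l in seq_len(L)) {
    s <- unique(c(dataset$alleles[, 2L * l - 1L], dataset$alleles[, 2L * l]))
    if (!is.null(pools)) {
      s <- unique(c(s, as.integer(names(pools$pool_A$freqs[[l]])),
                    as.integer(names(pools$pool_B$freqs[[l]]))))
    }
    sizes[[l]] <- sort(s[!is.na(s)])
  }
  geno <- matrix(-1L, nrow = n_ind(dataset), ncol = 2L * L)
  for (l in seq_len(L)) {
    for (cc in c(2L * l - 1L, 2L * l)) {
      idx <- match(dataset$alleles[, cc], sizes[[l]]) - 1L
      idx[is.na(idx)] <- -1L
      geno[, cc] <- idx
    }
  }
  list(geno = geno, sizes = sizes,
       n_alleles = vapply(sizes, length, 1L))
}

#' Gibbs sampler for the K=2 admixture model
#'
#' Re-implementation of the standard two-cluster admixture model for
#' unlinked multiallelic loci: each individual has an ancestry proportion
#' `q` for cluster A; each gene copy originates from a cluster with
#' probability proportional to `q_k * p_k(allele)`; cluster allele
#' frequencies carry a Dirichlet prior (independent per cluster, or a
#' correlated hierarchical F-model); the admixture parameter alpha is
#' inferred by random-walk Metropolis under a uniform prior. Missing calls
#' contribute nothing to the likelihood. Reported Q is the posterior mean of
#' `q` after burn-in (thinned), with a central credible interval.
#'
#' Cluster labels are arbitrary in the posterior; when `reference_A` ids are
#' given the output is aligned so that their mean Q is >= 0.5 (see
#' [align_clusters()]).
#'
#' @param dataset a [genotype_dataset()] with >= 2 individuals.
#' @param config an [admixture_config()].
#' @param preset a [run_preset()].
#' @param reference_A optional ids of known cluster-A individuals used to
#'   orient the labels.
#' @param seed optional integer seed.
#' @return a `data.frame` (class `q_estimate`) with columns `id`, `group`,
#'   `Q`, `ci_low`, `ci_high`; attributes `alpha` (posterior mean),
#'   `alpha_accept_rate`, `F` (correlated model), `preset`, `config`.
#' @export
gibbs_admixture <- function(dataset, config = admixture_config(),
                            preset = run_preset("short"),
                            reference_A = NULL, seed = NULL) {
  if (n_ind(dataset) < 2L) stop("need at least 2 individuals")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_alleles(dataset)
  fit <- .gibbs_admixture_cpp(enc$geno, enc$n_alleles, config$lambda,
                              as.integer(config$frequency_model ==
                                           "correlated"),
                              config$alpha_init, config$alpha_max,
                              config$alpha_step,
                              as.integer(preset$total),
                              as.integer(preset$burnin),
                              as.integer(preset$thin))
  if (fit$n_kept < 1L) stop("no post-burn-in samples retained")
  qs <- fit$q_samples
  Q <- colMeans(qs)
  half <- (1 - config$ci_level) / 2
  ci <- apply(qs, 2L, stats::quantile, probs = c(half, 1 - half),
              names = FALSE)
  out <- data.frame(id = dataset$ids, group = dataset$group, Q = Q,
                    ci_low = ci[1, ], ci_high = ci[2, ],
                    stringsAsFactors = FALSE)
  class(out) <- c("q_estimate", "data.frame")
  attr(out, "alpha") <- mean(fit$alpha_trace)
  attr(out, "alpha_accept_rate") <- fit$alpha_accept_rate
  attr(out, "F") <- fit$F
  attr(out, "preset") <- preset
  attr(out, "config") <- config
  if (!is.null(reference_A)) out <- align_clusters(list(out),
                                                   reference_A)[[1]]
  out
}

#' EM estimation of individual ancestry proportions
#'
#' Deterministic maximum-likelihood counterpart of [gibbs_admixture()]. In
#' supervised mode (reference `pools` supplied) cluster allele frequencies
#' are fixed and each individual's `q` is maximized independently — a
#' one-dimensional concave problem solved by EM. In unsupervised mode
#' frequencies and `q` are estimated jointly by block EM from a seeded random
#' start. The log-likelihood is non-decreasing every iteration; convergence
#' is declared when no `q` moves by more than `tol`.
#'
#' Alleles observed in the data but absent from both pools (supervised mode)
#' receive a tiny pseudo-frequency in both clusters so that the likelihood
#' stays finite; alleles absent from only one pool remain fully informative.
#'
#' @param dataset a [genotype_dataset()].
#' @param pools optional `reference_pair` (or list with `pool_A`, `pool_B`)
#'   switching on supervised mode.
#' @param max_iter,tol iteration cap and convergence tolerance on `max |dq|`.
#' @param seed optional integer seed (unsupervised initialization only).
#' @return a `data.frame` (class `q_estimate`) with columns `id`, `group`,
#'   `Q`; attribute `loglik_trace` (one value per iteration), `converged`.
#' @export
em_admixture <- function(dataset, pools = NULL, max_iter = 2000L,
                         tol = 1e-6, seed = NULL) {
  n <- n_ind(dataset)
  L <- length(dataset$loci)
  supervised <- !is.null(pools)
  enc <- encode_alleles(dataset, pools = if (supervised) pools)
  A <- sum(enc$n_alleles)
  off <- c(0L, cumsum(enc$n_alleles))
  # per-copy flattened allele index matrix (n x 2L), NA missing
  flat <- matrix(NA_integer_, n, 2L * L)
  for (l in seq_len(L)) {
    for (cc in c(2L * l - 1L, 2L * l)) {
      v <- enc$geno[, cc]
      flat[, cc] <- ifelse(v < 0L, NA_integer_, off[l] + v + 1L)
    }
  }
  obs <- !is.na(flat)
  flat0 <- flat; flat0[!obs] <- 1L   # placeholder index, masked later

  pool_vec <- function(pool) {
    v <- numeric(A)
    for (l in seq_len(L)) {
      f <- pool$freqs[[l]]
      hit <- match(as.integer(names(f)), enc$sizes[[l]])
      v[off[l] + hit] <- f
    }
    v
  }
  if (supervised) {
    pA <- pool_vec(pools$pool_A); pB <- pool_vec(pools$pool_B)
    orphan <- pA == 0 & pB == 0
    pA[orphan] <- 1e-6; pB[orphan] <- 1e-6
  } else {
    if (!is.null(seed)) set.seed(seed)
    g <- matrix(stats::rgamma(2L * A, 1), ncol = 2L)
    pA <- numeric(A); pB <- numeric(A)
    for (l in seq_len(L)) {
      rng <- (off[l] + 1L):off[l + 1L]
      pA[rng] <- g[rng, 1] / sum(g[rng, 1])
      pB[rng] <- g[rng, 2] / sum(g[rng, 2])
    }
  }

  q <- rep(0.5, n)
  n_obs <- rowSums(obs)
  if (any(n_obs == 0L)) warning("individual(s) with no observed calls: q = 0.5")
  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    PA <- matrix(pA[flat0], n, 2L * L); PA[!obs] <- NA
    PB <- matrix(pB[flat0], n, 2L * L); PB[!obs] <- NA
    num <- q * PA
    den <- num + (1 - q) * PB
    ll <- sum(log(den[obs]))
    loglik <- c(loglik, ll)
    r <- num / den                       # responsibility: copy from cluster A
    r[den == 0] <- 0.5
    q_new <- rowMeans(r, na.rm = TRUE)
    q_new[n_obs == 0L] <- 0.5
    if (!supervised) {
      idx <- flat[obs]
      cA <- numeric(A); cB <- numeric(A)
      tmpA <- rowsum(r[obs], idx)
      tmpB <- rowsum(1 - r[obs], idx)
      cA[as.integer(rownames(tmpA))] <- tmpA[, 1]
      cB[as.integer(rownames(tmpB))] <- tmpB[, 1]
      cA <- cA + 1e-9; cB <- cB + 1e-9
      for (l in seq_len(L)) {
        rng <- (off[l] + 1L):off[l + 1L]
        pA[rng] <- cA[rng] / sum(cA[rng])
        pB[rng] <- cB[rng] / sum(cB[rng])
      }
    }
    delta <- max(abs(q_new - q))
    q <- q_new
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- data.frame(id = dataset$ids, group = dataset$group, Q = q,
                    stringsAsFactors = FALSE)
  class(out) <- c("q_estimate", "data.frame")
  attr(out, "loglik_trace") <- loglik
  attr(out, "converged") <- converged
  attr(out, "supervised") <- supervised
  out
}

#' Resolve label switching across admixture runs
#'
#' Cluster labels are exchangeable in the admixture posterior: independent
#' runs may report Q for opposite clusters. Each run is permuted (Q -> 1-Q,
#' credible bounds swapped) so that the mean Q over the reference cluster-A
#' individuals is >= 0.5. Alignment is idempotent.
#'
#' @param q_runs a list of `q_estimate` data frames (or plain data frames
#'   with `id` and `Q`) covering the same individuals.
#' @param reference_A non-empty character vector of ids of known cluster-A
#'   individuals.
#' @return the list with every run aligned.
#' @export
align_clusters <- function(q_runs, reference_A) {
  if (length(reference_A) == 0L) stop("reference_A must be non-empty")
  lapply(q_runs, function(run) {
    i <- match(reference_A, run$id)
    if (anyNA(i)) stop("reference ids missing from run")
    m <- mean(run$Q[i])
    if (m == 0.5) stop("cluster orientation tie (mean reference Q exactly ",
                       "0.5): manual review required")
    if (m < 0.5) {
      run$Q <- 1 - run$Q
      if (all(c("ci_low", "ci_high") %in% names(run))) {
        lo <- 1 - run$ci_high
        run$ci_high <- 1 - run$ci_low
        run$ci_low <- lo
      }
    }
    run
  })
}

#' Count individuals whose Q changes between runs
#'
#' The replicate-stability metric: for aligned runs, how many individuals
#' have Q values differing by more than `delta` (strict) in at least one
#' pair of runs, plus the mean count over run pairs.
#'
#' @param q_runs list (length >= 2) of aligned `q_estimate` data frames over
#'   the same individuals.
#' @param delta change threshold (default 0.05).
#' @return a list: `n_changed` (union over pairs), `mean_pairwise` (mean
#'   per-pair count), `per_pair` data frame.
#' @export
run_consistency <- function(q_runs, delta = 0.05) {
  if (length(q_runs) < 2L) stop("need at least 2 runs")
  ids <- q_runs[[1]]$id
  qm <- vapply(q_runs, function(run) {
    i <- match(ids, run$id)
    if (anyNA(i)) stop("runs cover different individual sets")
    run$Q[i]
  }, numeric(length(ids)))
  pairs <- utils::combn(length(q_runs), 2L)
  changed_any <- rep(FALSE, length(ids))
  per_pair <- data.frame(run_1 = integer(0), run_2 = integer(0),
                         n_changed = integer(0))
  for (p in seq_len(ncol(pairs))) {
    d <- abs(qm[, pairs[1, p]] - qm[, pairs[2, p]]) > delta
    changed_any <- changed_any | d
    per_pair <- rbind(per_pair,
                      data.frame(run_1 = pairs[1, p], run_2 = pairs[2, p],
                                 n_changed = sum(d)))
  }
  list(n_changed = sum(changed_any),
       mean_pairwise = mean(per_pair$n_changed),
       per_pair = per_pair)
}
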