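---
title: "Models and design choices behind hybriq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind hybriq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriq)
```

## The management problem

hybriq addresses a recurring conservation situation: a rare, genetically
depauperate native taxon (here called taxon A, modelled on the bontebok)
hybridizes with an abundant, more variable relative (taxon B, blesbok-like)
after human-mediated contact. Managers must decide, animal by animal, who is
nonadmixed and may be certified and translocated, and who is a hybrid to be
isolated or culled. The molecular instrument is a panel of microsatellite
loci; the decision instrument is a threshold on the admixture coefficient
*Q* — the estimated proportion of an individual's genome deriving from the
taxon-A gene pool under a two-cluster admixture model. Because hybrids
beyond the first generation carry ever more taxon-A genome, any threshold
trades false-negative hybrids against wrongly condemned pure animals. The
package quantifies that trade-off on simulated individuals of known
pedigree and reports the consequences of candidate thresholds.

## The admixture model

`gibbs_admixture()` implements the standard Bayesian admixture model for
unlinked multiallelic loci with K = 2 clusters. Each individual *i* has an
ancestry proportion $q_i \in [0,1]$ for cluster A. Each gene copy carries a
latent origin: cluster A with probability $\propto q_i\,p_A(a)$, cluster B
with probability $\propto (1-q_i)\,p_B(a)$, where $p_k(a)$ is the frequency
of allele $a$ in cluster $k$. A Gibbs sweep (i) samples every copy's origin,
(ii) samples cluster allele frequencies from their Dirichlet full
conditional, (iii) samples each $q_i$ from
$\mathrm{Beta}(\alpha + n_{iA}, \alpha + n_{iB})$, and (iv) updates the
admixture concentration $\alpha$ by random-walk Metropolis. Missing calls
are simply skipped: they contribute nothing to the likelihood.

Tunable parameters, with defaults and reasons:

* `lambda = 1` — uniform Dirichlet prior on cluster allele frequencies
  (the conventional uninformative choice for the uncorrelated model). It
  also guarantees that an allele seen only in unknowns can never acquire
  zero probability in a cluster.
* `alpha` — inferred, single value shared by the two clusters, uniform
  prior on (0, 10], Metropolis step 0.05 (acceptance around 1/3 on the
  simulated sets). Fixing alpha small would sharpen pure individuals'
  posteriors; inferring it lets the data decide how admixed the sample is.
* `frequency_model` — `"uncorrelated"` (independent priors per cluster) or
  `"correlated"`, a hierarchical F-model in which cluster frequencies are
  Dirichlet-distributed around shared ancestral frequencies with
  per-cluster drift parameters on a uniform (0,1) prior, updated by
  Metropolis. Both are provided because the choice is a known source of
  run-to-run variability; the uncorrelated model is the default and the
  more stable of the two on well-separated taxa.
* `run_preset()` — `short` (1e5 sweeps, 1e4 burn-in), `long` (1.2e6/2e5),
  `very_long` (2.4e6/4e5), or custom lengths. The package's own tests and
  the bundled acceptance analysis use custom 2e4-sweep chains: with 12
  loci and thousands of individuals the posterior mean of *q* is stable
  well before that (replicate chains move essentially no individual by
  more than 0.05; see `run_consistency()`). Thinning (default 10) bounds
  retained samples; the interval is raised automatically if a very long
  chain would retain more than 20,000 samples.
* Credible intervals are central 90% posterior intervals, the customary
  reporting level for admixture coefficients.

Cluster labels are exchangeable, so outputs are oriented afterwards:
`align_clusters()` flips runs so that designated reference individuals
average Q at or above 0.5, and errors on an exact tie rather than guessing.

`em_admixture()` is the deterministic counterpart used for cross-checking:
block EM over (frequencies, q), or per-individual concave maximization when
reference pools fix the frequencies. Its log-likelihood is non-decreasing
by construction and convergence is declared when no ancestry moves by more
than 1e-6. An allele absent from both reference pools (possible with
empirical data) receives a pseudo-frequency of 1e-6 in both clusters —
effectively uninformative, never a crash. Because EM reports the
maximum-likelihood point, pure individuals sit exactly at the boundary
(q = 1) where the Gibbs posterior mean cannot reach; the two estimators are
expected to agree within 0.05 for the vast majority of individuals, not
all, and that is what the tests assert.

## The pedigree-category model

`category_posterior_mcmc()` classifies individuals into pedigree categories
(nonadmixed A, nonadmixed B, F1, F2 intercross, backcross to A, backcross
to B; optionally the two double backcrosses) using genotype-frequency
classes: each category fixes the per-locus probability that an individual's
two gene copies are both A-derived, one from each, or both B-derived
($\varphi_{AA}, \varphi_{AB}, \varphi_{BB}$ — computed exactly by pedigree
enumeration in `category_class_proportions()`). The sampler alternates
latent categories, per-locus copy origins, cluster frequencies (Dirichlet
prior: uniform $\lambda = 1$ or Jeffreys $\lambda = 0.5$ — the standard
multinomial reading of a Jeffreys prior), and category mixing proportions
(flat Dirichlet). No reference ancestry is supplied; the clusters are
discovered from the sample, and the species orientation is resolved after
sampling either by reference ids or, failing that, by cluster
heterozygosity (taxon A is the less variable cluster by this package's
convention). The eight-category mode is off by default: the six-category
model is the standard analysis, and the default setting reproduces its
known blind spot for double backcrosses rather than papering over it.

`category_posterior_direct()` computes the closed-form posterior when the
generating pools are known. It is the oracle for the sampler and makes the
double-backcross problem transparent: a BC2-to-A individual is mostly
homozygous-A with a sprinkling of mixed loci, which the six-category model
can only explain as "pure A" or "backcross to A" — its posterior splits
between the two and rarely exceeds 0.9 for either.

`map_category_assignment()` offers the two thresholding schemes in common
use: six-way argmax-above-threshold (ties and sub-threshold maxima yield
OTHER, the conservative choice), and a three-way scheme (pure A / pure B /
hybrid) that mirrors the two-cluster Q threshold; in the three-way scheme
OTHER-type individuals count as hybrids, matching how mixed low-confidence
assignments are tallied in practice.

## Diagnostic alleles

`find_species_specific()` encodes the three-part private-allele rule: a
taxon-B diagnostic allele must exceed frequency 0.05 in B (strictly), be
below 0.005 in A (strictly), and lie at least 3 bp from any allele "known"
in A. "Known" is read as "present above the 0.005 noise floor", which keeps
the absence criterion and the distance criterion mutually consistent; the
floor is a parameter for users who prefer the distance check against every
recorded allele. `find_fixed_alleles()` screens for near-fixed alleles
(frequency at least 0.995 — "approximately 1" is read as approximate on
purpose) absent from the other taxon. `classify_by_alleles()` is the
non-model-based detector: a missing call at a fixed locus neither grants
nor revokes the all-fixed flag (a strict mode is available), because
individuals with a percent or two of missing data are routinely classified
in practice.

## The synthetic reference pair

No genotypes are distributed with the package, so `calibrate_pools()`
constructs a synthetic pair of parental allele-frequency pools reproducing
the summary structure of the reference populations the package's analyses
emulate:

* 12 dinucleotide microsatellites (2-bp allele lattice — the spacing that
  makes a 3-bp distance rule meaningful);
* mean expected heterozygosity 0.321 in taxon A versus 0.543 in taxon B;
* three near-homozygous taxon-A loci carrying most of A's diversity
  deficit: excluding them, the remaining nine loci average He ≈ 0.42 in A
  and ≈ 0.53–0.58 in B — both decompositions emerge from one calibration;
* 17 taxon-B private alleles across 8 loci, each planted at frequency 0.08
  (comfortably above the 0.05 rule) and one lattice gap (4 bp) away from
  every appreciable A allele;
* near-fixed A alleles at 2 of the three near-homozygous loci. A locus
  cannot hold two alleles both at frequency ~1, so "four fixed alleles at
  two loci" is realized as, per locus, a near-fixed major (0.995) plus a
  trace minor (0.005), both restricted to taxon A — four A-restricted
  alleles, of which the two majors pass the strict 0.995 fixation screen.

Per-locus frequencies start from flat Dirichlet draws and are "tempered"
($p^t$, renormalized) with one exponent per pool, found by bisection so the
planted-and-tempered pools hit their He targets within 0.02; a zero He
target short-circuits to exact fixation. Shared alleles that are common in
B are kept at frequency at least 0.006 in A so that no unplanned allele
slips through the diagnostic rule — except under forced fixation, where
additional B alleles become genuinely diagnostic, as they should when one
taxon is monomorphic.

`sample_population()` draws genotypes under Hardy–Weinberg proportions with
free recombination between loci; `build_test_set()` generates the
known-pedigree test set (default 500 per class, 4,000 individuals): pure
classes from the pools, F1 = A×B, F2 = F1×F1 (the intercross definition),
BC = F1×pure, BC2 = BC×pure, with every intermediate parent pool (size 200)
generated fresh and never reused as study individuals. Parents are drawn
with replacement and no inbreeding avoidance is applied; at pool size 200
the effect on class allele-frequency distributions is negligible.

What the generator deliberately does **not** emulate: mutation, linkage
and linkage disequilibrium, null alleles and scoring error, population
structure within taxa, and — most importantly — the exact cross-taxon
overlap of common alleles, which the published summary statistics do not
determine. Shared-allele frequencies are drawn independently for the two
pools at matched heterozygosity. Consequently, statistics driven by hybrid
ancestry (the fraction of hybrids or double backcrosses below a threshold)
are robustly reproduced, while statistics driven by how sharply the pure
native taxon concentrates near Q = 1 — the fraction of pure A falling
below high thresholds — are sensitive to that unconstrained overlap and
should be read as order-of-magnitude reproductions, not point estimates.
Passing tests demonstrate internal correctness of the estimators and the
evaluation machinery under the stated conditions; they do not certify
removal percentages for any particular real population.

## Threshold evaluation

`assign_structure_threshold()` applies the management rule: pure A when
$Q \ge T$, pure B when $1 - Q \ge T$, hybrid otherwise. Equality retains
the animal — with a 0.99 threshold an animal at exactly 0.99 is kept; the
rule is a one-liner to flip for agencies that read "above" strictly.
Efficiency (of those truly in a category, the fraction assigned to it),
accuracy (of those assigned, the fraction truly there; zero when nothing is
assigned), and performance (their product) follow the standard definitions;
the merged HYBRID truth category pools F1, F2, BC and BC2, and any non-pure
assignment counts as a hybrid assignment. `threshold_scan()` evaluates the
0.86–0.99 grid at 0.01 steps (endpoints included) on the full test set and
on the subset without double backcrosses, whose removal quantifies how much
that hardest class costs. `removal_curve()` applies the culling rule
(everything not assigned pure A is removed — taxon B included, since the
management goal retains only nonadmixed natives) and reports per-class and
overall removal fractions. Efficiency is exactly monotone in the threshold
by set inclusion; accuracy is a ratio of shrinking counts, so it trends —
rising toward high thresholds for the pure categories until the assigned
set empties, falling for hybrids — without being step-wise monotone at
finite sample size. The tests assert the exact part exactly and the trend
as a trend.

`location_composition()` reports per-location composition for locations
with at least 10 sampled individuals, and `compare_methods()` counts
three-way label disagreements between two estimators.

## Numerical choices

* Gibbs `q` draws are clamped to [1e-9, 1 − 1e-9] so the alpha update's
  log terms stay finite; Dirichlet draws floor their gamma components at
  1e-300.
* EM uses a 1e-9 pseudocount in unsupervised M-steps (keeps frequencies
  positive; the log-likelihood remains non-decreasing to well below test
  tolerance) and declares convergence at max |Δq| < 1e-6.
* Calibration bisection runs on a logarithmic temper grid with 60
  iterations and targets half the He tolerance, erroring out — naming the
  pool — when a target is unattainable for the locus structure.
* Stage seeds in the pipeline are derived from (master seed, stage name)
  and stay below 2^31; identical configurations give byte-identical output
  tables, verified by checksum in the tests.
* Problem sizes in the tests: 500 per class for pedigree-mean and
  diagnostic-rate checks, 250 per class × 3 replicates for the
  threshold-removal reproduction, 4,000 individuals at 2e4 sweeps for the
  Gibbs/EM agreement check — sizes at which every asserted quantity's
  Monte-Carlo error is far below its test tolerance.

## Known limitations

* K is fixed at 2; no model-choice machinery (and none is needed for a
  two-taxon management question).
* The category model covers two generations plus the double-backcross
  extension; deeper or mixed pedigrees (e.g. F1 × BC) are not separable
  with 12 microsatellites and are not modelled.
* The correlated-frequency model updates ancestral frequencies and drift
  by simple Metropolis moves; it mixes adequately on the package's problem
  sizes but is the less polished of the two frequency models, mirroring
  its role as a robustness check.
* Pure-taxon removal fractions at high thresholds depend on cross-taxon
  allele sharing that summary calibration targets cannot pin down (see
  above); conclusions about those fractions should be drawn from pools
  estimated on real reference data whenever such data exist.
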