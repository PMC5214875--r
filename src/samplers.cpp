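// Gibbs samplers for the two-cluster admixture model and the
// genotype-frequency-class (pedigree category) model.
//
// Genotypes arrive as an n x 2L integer matrix of 0-based per-locus allele
// indices (-1 = missing). All random draws go through R's RNG, so set.seed()
// in R governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

static inline double rbeta_safe(double a, double b) {
  double x = R::rbeta(a, b);
  if (x < 1e-9) x = 1e-9;
  if (x > 1.0 - 1e-9) x = 1.0 - 1e-9;
  return x;
}

// Dirichlet draw into out[from..from+k) given shape[from..from+k)
static void rdirichlet_into(std::vector<double>& out,
                            const std::vector<double>& shape,
                            int from, int k) {
  double s = 0.0;
  for (int a = 0; a < k; ++a) {
    double g = R::rgamma(shape[from + a], 1.0);
    if (g < 1e-300) g = 1e-300;
    out[from + a] = g;
    s += g;
  }
  for (int a = 0; a < k; ++a) out[from + a] /= s;
}

// log Dirichlet(p; shape) density over k components
static double ldirichlet(const std::vector<double>& p,
                         const std::vector<double>& shape,
                         int from, int k) {
  double lp = 0.0, ssum = 0.0;
  for (int a = 0; a < k; ++a) {
    double s = shape[from + a];
    ssum += s;
    lp += (s - 1.0) * std::log(p[from + a]) - R::lgammafn(s);
  }
  return lp + R::lgammafn(ssum);
}

// [[Rcpp::export(name = ".gibbs_admixture_cpp")]]
List gibbs_admixture_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                         double lambda, int correlated,
                         double alpha_init, double alpha_max,
                         double alpha_step, int total, int burnin, int thin) {
  const int n = geno.nrow();
  const int twoL = geno.ncol();
  const int L = twoL / 2;
  if (burnin >= total) stop("burn-in must be smaller than the total length");

  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int A = off[L];

  RNGScope scope;

  // state
  std::vector<double> p0(A), p1(A), anc(A), shape(A);
  std::vector<double> q0(n, 0.5);
  std::vector<double> c0(A), c1(A), ctot(A);
  double alpha = alpha_init;
  double F0 = 0.05, F1v = 0.05;          // per-cluster drift (correlated)
  const double f_step = 0.05, anc_step = 0.02;

  // initialize frequencies from flat Dirichlet; ancestral from pooled counts
  for (int l = 0; l < L; ++l) {
    std::fill(shape.begin() + off[l], shape.begin() + off[l + 1], 1.0);
    rdirichlet_into(p0, shape, off[l], n_alleles[l]);
    rdirichlet_into(p1, shape, off[l], n_alleles[l]);
    rdirichlet_into(anc, shape, off[l], n_alleles[l]);
  }
  for (int i = 0; i < n; ++i) q0[i] = rbeta_safe(1.0, 1.0);

  const int n_kept = (total - burnin + thin - 1) / thin;
  NumericMatrix q_samples(n_kept, n);
  NumericVector alpha_trace(n_kept);
  int kept = 0, alpha_acc = 0, alpha_try = 0;
  std::vector<double> m0(n), m1(n);

  for (int sweep = 0; sweep < total; ++sweep) {
    std::fill(c0.begin(), c0.end(), 0.0);
    std::fill(c1.begin(), c1.end(), 0.0);
    std::fill(m0.begin(), m0.end(), 0.0);
    std::fill(m1.begin(), m1.end(), 0.0);

    // (i) origin of each gene copy
    for (int i = 0; i < n; ++i) {
      const double qi = q0[i], qj = 1.0 - qi;
      for (int j = 0; j < twoL; ++j) {
        const int a = geno(i, j);
        if (a < 0) continue;
        const int idx = off[j >> 1] + a;
        const double w0 = qi * p0[idx];
        const double w1 = qj * p1[idx];
        if (unif_rand() * (w0 + w1) < w0) { c0[idx] += 1.0; m0[i] += 1.0; }
        else                              { c1[idx] += 1.0; m1[i] += 1.0; }
      }
    }

    // (ii) cluster allele frequencies
    if (!correlated) {
      for (int l = 0; l < L; ++l) {
        for (int a = off[l]; a < off[l + 1]; ++a) shape[a] = lambda + c0[a];
        rdirichlet_into(p0, shape, off[l], n_alleles[l]);
        for (int a = off[l]; a < off[l + 1]; ++a) shape[a] = lambda + c1[a];
        rdirichlet_into(p1, shape, off[l], n_alleles[l]);
      }
    } else {
      // hierarchical F-model: p_k | anc, F_k ~ Dirichlet(anc (1-F)/F)
      const double g0 = (1.0 - F0) / F0, g1 = (1.0 - F1v) / F1v;
      for (int l = 0; l < L; ++l) {
        for (int a = off[l]; a < off[l + 1]; ++a)
          shape[a] = anc[a] * g0 + c0[a];
        rdirichlet_into(p0, shape, off[l], n_alleles[l]);
        for (int a = off[l]; a < off[l + 1]; ++a)
          shape[a] = anc[a] * g1 + c1[a];
        rdirichlet_into(p1, shape, off[l], n_alleles[l]);
      }
      // F_k updates (random-walk Metropolis, uniform(0,1) prior)
      for (int k = 0; k < 2; ++k) {
        double& F = (k == 0) ? F0 : F1v;
        const std::vector<double>& pk = (k == 0) ? p0 : p1;
        double Fp = F + norm_rand() * f_step;
        if (Fp > 1e-4 && Fp < 1.0 - 1e-4) {
          double lr = 0.0;
          for (int l = 0; l < L; ++l) {
            for (int a = off[l]; a < off[l + 1]; ++a)
              shape[a] = anc[a] * (1.0 - Fp) / Fp;
            lr += ldirichlet(pk, shape, off[l], n_alleles[l]);
            for (int a = off[l]; a < off[l + 1]; ++a)
              shape[a] = anc[a] * (1.0 - F) / F;
            lr -= ldirichlet(pk, shape, off[l], n_alleles[l]);
          }
          if (std::log(unif_rand()) < lr) F = Fp;
        }
      }
      // ancestral frequencies: symmetric mass-transfer proposal per locus
      for (int l = 0; l < L; ++l) {
        const int k = n_alleles[l];
        if (k < 2) continue;
        int a1 = (int)(unif_rand() * k), a2 = (int)(unif_rand() * k);
        if (a1 == a2 || a1 >= k || a2 >= k) continue;
        double d = norm_rand() * anc_step;
        int i1 = off[l] + a1, i2 = off[l] + a2;
        double n1 = anc[i1] + d, n2 = anc[i2] - d;
        if (n1 <= 1e-6 || n2 <= 1e-6) continue;
        double lr = 0.0;
        // Dirichlet(lambda) prior on anc is flat for lambda = 1; include the
        // general term anyway
        lr += (lambda - 1.0) * (std::log(n1) - std::log(anc[i1]) +
                                std::log(n2) - std::log(anc[i2]));
        double old1 = anc[i1], old2 = anc[i2];
        anc[i1] = n1; anc[i2] = n2;
        for (int a = off[l]; a < off[l + 1]; ++a)
          shape[a] = anc[a] * (1.0 - F0) / F0;
        lr += ldirichlet(p0, shape, off[l], k);
        for (int a = off[l]; a < off[l + 1]; ++a)
          shape[a] = anc[a] * (1.0 - F1v) / F1v;
        lr += ldirichlet(p1, shape, off[l], k);
        anc[i1] = old1; anc[i2] = old2;
        for (int a = off[l]; a < off[l + 1]; ++a)
          shape[a] = anc[a] * (1.0 - F0) / F0;
        lr -= ldirichlet(p0, shape, off[l], k);
        for (int a = off[l]; a < off[l + 1]; ++a)
          shape[a] = anc[a] * (1.0 - F1v) / F1v;
        lr -= ldirichlet(p1, shape, off[l], k);
        if (std::log(unif_rand()) < lr) { anc[i1] = n1; anc[i2] = n2; }
      }
    }

    // (iii) individual ancestry proportions
    double sumlog = 0.0;
    for (int i = 0; i < n; ++i) {
      q0[i] = rbeta_safe(alpha + m0[i], alpha + m1[i]);
      sumlog += std::log(q0[i]) + std::log(1.0 - q0[i]);
    }

    // (iv) admixture parameter alpha, random-walk Metropolis,
    // uniform prior on (0, alpha_max]
    {
      ++alpha_try;
      double ap = alpha + norm_rand() * alpha_step;
      if (ap > 0.0 && ap <= alpha_max) {
        double lr = n * (R::lgammafn(2.0 * ap) - 2.0 * R::lgammafn(ap)) -
                    n * (R::lgammafn(2.0 * alpha) - 2.0 * R::lgammafn(alpha)) +
                    (ap - alpha) * sumlog;
        if (std::log(unif_rand()) < lr) { alpha = ap; ++alpha_acc; }
      }
    }

    if (sweep >= burnin && (sweep - burnin) % thin == 0) {
      for (int i = 0; i < n; ++i) q_samples(kept, i) = q0[i];
      alpha_trace[kept] = alpha;
      ++kept;
    }
  }

  return List::create(
    _["q_samples"] = q_samples,
    _["alpha_trace"] = alpha_trace,
    _["alpha_accept_rate"] = (double)alpha_acc / (double)alpha_try,
    _["F"] = NumericVector::create(F0, F1v),
    _["n_kept"] = kept);
}

// [[Rcpp::export(name = ".category_gibbs_cpp")]]
List category_gibbs_cpp(IntegerMatrix geno, IntegerVector n_alleles,
                        NumericMatrix phi, double lambda,
                        int total, int burnin, int thin) {
  const int n = geno.nrow();
  const int twoL = geno.ncol();
  const int L = twoL / 2;
  const int C = phi.nrow();
  if (burnin >= total) stop("burn-in must be smaller than the total length");

  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int A = off[L];

  RNGScope scope;

  std::vector<double> p0(A), p1(A), shape(A);
  std::vector<double> c0(A), c1(A);
  std::vector<double> pi(C, 1.0 / C), loglik(C), w(C);
  std::vector<int> z(n, 0), nc(C, 0);
  for (int l = 0; l < L; ++l) {
    std::fill(shape.begin() + off[l], shape.begin() + off[l + 1], 1.0);
    rdirichlet_into(p0, shape, off[l], n_alleles[l]);
    rdirichlet_into(p1, shape, off[l], n_alleles[l]);
  }

  IntegerMatrix cat_counts(n, C);
  NumericVector p0_mean(A), p1_mean(A);
  int kept = 0;

  for (int sweep = 0; sweep < total; ++sweep) {
    // (i) latent category per individual, given frequencies and pi
    std::fill(nc.begin(), nc.end(), 0);
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < C; ++c) loglik[c] = std::log(pi[c]);
      for (int l = 0; l < L; ++l) {
        const int x = geno(i, 2 * l), y = geno(i, 2 * l + 1);
        if (x < 0) continue;
        const double pax = p0[off[l] + x], pay = p0[off[l] + y];
        const double pbx = p1[off[l] + x], pby = p1[off[l] + y];
        const double hwA = (x == y) ? pax * pax : 2.0 * pax * pay;
        const double hwB = (x == y) ? pbx * pbx : 2.0 * pbx * pby;
        const double mix = (x == y) ? pax * pbx : pax * pby + pay * pbx;
        for (int c = 0; c < C; ++c) {
          double lc = phi(c, 0) * hwA + phi(c, 1) * mix + phi(c, 2) * hwB;
          loglik[c] += (lc > 0.0) ? std::log(lc) : -1e300;
        }
      }
      double mx = loglik[0];
      for (int c = 1; c < C; ++c) if (loglik[c] > mx) mx = loglik[c];
      double s = 0.0;
      for (int c = 0; c < C; ++c) { w[c] = std::exp(loglik[c] - mx); s += w[c]; }
      double u = unif_rand() * s;
      int zi = C - 1;
      for (int c = 0; c < C; ++c) { u -= w[c]; if (u <= 0.0) { zi = c; break; } }
      z[i] = zi;
      ++nc[zi];
    }

    // (ii) gene-copy origins given categories; accumulate cluster counts
    std::fill(c0.begin(), c0.end(), 0.0);
    std::fill(c1.begin(), c1.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const int c = z[i];
      for (int l = 0; l < L; ++l) {
        const int x = geno(i, 2 * l), y = geno(i, 2 * l + 1);
        if (x < 0) continue;
        const double pax = p0[off[l] + x], pay = p0[off[l] + y];
        const double pbx = p1[off[l] + x], pby = p1[off[l] + y];
        const double hwA = (x == y) ? pax * pax : 2.0 * pax * pay;
        const double hwB = (x == y) ? pbx * pbx : 2.0 * pbx * pby;
        const double mix = (x == y) ? pax * pbx : pax * pby + pay * pbx;
        const double wAA = phi(c, 0) * hwA;
        const double wAB = phi(c, 1) * mix;
        const double wBB = phi(c, 2) * hwB;
        double u = unif_rand() * (wAA + wAB + wBB);
        if (u < wAA) {
          c0[off[l] + x] += 1.0; c0[off[l] + y] += 1.0;
        } else if (u < wAA + wAB) {
          if (x == y) {
            c0[off[l] + x] += 1.0; c1[off[l] + x] += 1.0;
          } else {
            const double wxy = pax * pby;    // copy x from A, y from B
            if (unif_rand() * (pax * pby + pay * pbx) < wxy) {
              c0[off[l] + x] += 1.0; c1[off[l] + y] += 1.0;
            } else {
              c0[off[l] + y] += 1.0; c1[off[l] + x] += 1.0;
            }
          }
        } else {
          c1[off[l] + x] += 1.0; c1[off[l] + y] += 1.0;
        }
      }
    }

    // (iii) cluster allele frequencies (lambda = 1 uniform, 0.5 Jeffreys)
    for (int l = 0; l < L; ++l) {
      for (int a = off[l]; a < off[l + 1]; ++a) shape[a] = lambda + c0[a];
      rdirichlet_into(p0, shape, off[l], n_alleles[l]);
      for (int a = off[l]; a < off[l + 1]; ++a) shape[a] = lambda + c1[a];
      rdirichlet_into(p1, shape, off[l], n_alleles[l]);
    }

    // (iv) category mixing proportions, flat Dirichlet(1) prior
    {
      double s = 0.0;
      for (int c = 0; c < C; ++c) {
        double g = R::rgamma(1.0 + nc[c], 1.0);
        if (g < 1e-300) g = 1e-300;
        pi[c] = g; s += g;
      }
      for (int c = 0; c < C; ++c) pi[c] /= s;
    }

    if (sweep >= burnin && (sweep - burnin) % thin == 0) {
      for (int i = 0; i < n; ++i) cat_counts(i, z[i]) += 1;
      for (int a = 0; a < A; ++a) { p0_mean[a] += p0[a]; p1_mean[a] += p1[a]; }
      ++kept;
    }
  }
  if (kept > 0) {
    for (int a = 0; a < A; ++a) { p0_mean[a] /= kept; p1_mean[a] /= kept; }
  }

  return List::create(
    _["cat_counts"] = cat_counts,
    _["p0_mean"] = p0_mean,
    _["p1_mean"] = p1_mean,
    _["n_kept"] = kept);
}
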