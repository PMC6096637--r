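// EM machinery for the binomial admixture likelihood
//   L = prod_ij Binom(g_ij | 2, p_ij),  p_ij = sum_k Q_ik F_jk.
// Used for (1) joint estimation of Q and F (classic multiplicative EM),
// (2) per-SNP maximum-likelihood ancestral frequencies with Q fixed, and
// (3) the bootstrap loop over individual resamples. Missing genotypes are
// encoded as negative values and skipped. Both EM loops use SQUAREM-style
// extrapolation (with a plain-EM fallback whenever the extrapolated step
// does not improve the likelihood), which preserves EM's monotone
// convergence while cutting the iteration count near boundaries.

#include <Rcpp.h>
using namespace Rcpp;

static const double PMIN = 1e-9;

static inline double clamp01(double x) {
  if (x < PMIN) return PMIN;
  if (x > 1.0 - PMIN) return 1.0 - PMIN;
  return x;
}

// ---------- fixed-Q, single SNP ----------

static double snp_loglik(const std::vector<double>& g,
                         const NumericMatrix& Q,
                         const std::vector<double>& f,
                         const std::vector<int>& idx) {
  double ll = 0.0;
  int K = f.size();
  for (size_t t = 0; t < idx.size(); ++t) {
    int i = idx[t];
    double gi = g[i];
    double p = 0.0;
    for (int k = 0; k < K; ++k) p += Q(i, k) * f[k];
    p = clamp01(p);
    ll += gi * std::log(p) + (2.0 - gi) * std::log1p(-p);
  }
  return ll;
}

// one EM update of f with Q fixed
static std::vector<double> em_f_step(const std::vector<double>& g,
                                     const NumericMatrix& Q,
                                     const std::vector<int>& idx,
                                     const std::vector<double>& f) {
  int K = f.size();
  std::vector<double> A(K, 0.0), B(K, 0.0), out(f);
  for (size_t t = 0; t < idx.size(); ++t) {
    int i = idx[t];
    double gi = g[i];
    double p = 0.0;
    for (int k = 0; k < K; ++k) p += Q(i, k) * f[k];
    p = clamp01(p);
    for (int k = 0; k < K; ++k) {
      double qk = Q(i, k);
      if (qk <= 0) continue;
      A[k] += gi * qk * f[k] / p;                        // effect alleles
      B[k] += (2.0 - gi) * qk * (1.0 - f[k]) / (1.0 - p);
    }
  }
  for (int k = 0; k < K; ++k) {
    double tot = A[k] + B[k];
    if (tot > 0) out[k] = clamp01(A[k] / tot);
  }
  return out;
}

// SQUAREM-accelerated EM for f
static std::vector<double> em_f(const std::vector<double>& g,
                                const NumericMatrix& Q,
                                const std::vector<int>& idx,
                                std::vector<double> f,
                                double tol, int max_iter,
                                double* ll_out, int* iter_out,
                                bool* conv_out) {
  int K = f.size();
  double ll = snp_loglik(g, Q, f, idx);
  bool converged = false;
  int it;
  for (it = 0; it < max_iter; ++it) {
    std::vector<double> f1 = em_f_step(g, Q, idx, f);
    std::vector<double> f2 = em_f_step(g, Q, idx, f1);
    double rr = 0.0, vv = 0.0;
    std::vector<double> r(K), v(K);
    for (int k = 0; k < K; ++k) {
      r[k] = f1[k] - f[k];
      v[k] = (f2[k] - f1[k]) - r[k];
      rr += r[k] * r[k];
      vv += v[k] * v[k];
    }
    std::vector<double> cand = f2;
    if (vv > 0) {
      double alpha = -std::sqrt(rr / vv);
      if (alpha > -1.0) alpha = -1.0;
      std::vector<double> fs(K);
      for (int k = 0; k < K; ++k)
        fs[k] = clamp01(f[k] - 2.0 * alpha * r[k] + alpha * alpha * v[k]);
      std::vector<double> fstab = em_f_step(g, Q, idx, fs);
      if (snp_loglik(g, Q, fstab, idx) >= snp_loglik(g, Q, f2, idx))
        cand = fstab;
    }
    double ll_new = snp_loglik(g, Q, cand, idx);
    f = cand;
    if (ll_new - ll < tol) { ll = ll_new; converged = true; break; }
    ll = ll_new;
  }
  *ll_out = ll;
  *iter_out = it + 1;
  *conv_out = converged;
  return f;
}

static std::vector<double> f_init(const std::vector<double>& g,
                                  const std::vector<int>& idx, int K) {
  double num = 0.0, den = 0.0;
  for (size_t t = 0; t < idx.size(); ++t) { num += g[idx[t]]; den += 2.0; }
  return std::vector<double>(K, den > 0 ? clamp01(num / den) : 0.5);
}

// [[Rcpp::export(name = ".em_fixed_q")]]
List em_fixed_q_cpp(NumericVector g, NumericMatrix Q,
                    double tol = 1e-8, int max_iter = 10000) {
  int n = g.size();
  std::vector<double> gv(n);
  for (int i = 0; i < n; ++i) gv[i] = NumericVector::is_na(g[i]) ? -1.0 : g[i];
  std::vector<int> idx;
  for (int i = 0; i < n; ++i) if (gv[i] >= 0) idx.push_back(i);
  double ll; int iters; bool conv;
  std::vector<double> f = em_f(gv, Q, idx, f_init(gv, idx, Q.ncol()),
                               tol, max_iter, &ll, &iters, &conv);
  return List::create(_["f"] = NumericVector(f.begin(), f.end()),
                      _["loglik"] = ll, _["iterations"] = iters,
                      _["converged"] = conv);
}

// [[Rcpp::export(name = ".bootstrap_fixed_q")]]
NumericMatrix bootstrap_fixed_q_cpp(NumericVector g, NumericMatrix Q,
                                    IntegerMatrix idx1,  // B x n, 1-based
                                    NumericVector f_start,
                                    double mass_min = 1.0,
                                    double tol = 1e-8,
                                    int max_iter = 10000) {
  int B = idx1.nrow(), nb = idx1.ncol(), K = Q.ncol();
  int n = g.size();
  std::vector<double> gv(n);
  for (int i = 0; i < n; ++i) gv[i] = NumericVector::is_na(g[i]) ? -1.0 : g[i];
  std::vector<double> f0(f_start.begin(), f_start.end());
  for (int k = 0; k < K; ++k)
    if (!R_finite(f0[k])) f0[k] = 0.5;
  NumericMatrix out(B, K);
  for (int b = 0; b < B; ++b) {
    std::vector<int> idx;
    idx.reserve(nb);
    for (int t = 0; t < nb; ++t) {
      int i = idx1(b, t) - 1;
      if (gv[i] >= 0) idx.push_back(i);
    }
    if (idx.empty()) {
      for (int k = 0; k < K; ++k) out(b, k) = NA_REAL;
      continue;
    }
    // component identifiability: total ancestry mass among resampled
    // non-missing individuals must reach mass_min individual-equivalents
    std::vector<double> mass(K, 0.0);
    for (size_t t = 0; t < idx.size(); ++t)
      for (int k = 0; k < K; ++k) mass[k] += Q(idx[t], k);
    double ll; int iters; bool conv;
    // warm start at the full-sample estimate
    std::vector<double> f = em_f(gv, Q, idx, f0, tol, max_iter,
                                 &ll, &iters, &conv);
    for (int k = 0; k < K; ++k)
      out(b, k) = mass[k] < mass_min ? NA_REAL : f[k];
  }
  return out;
}

// ---------- joint admixture EM ----------

struct AdmixData {
  const IntegerMatrix& G;
  const LogicalVector& anchored;
  int n, m, K;
};

static double admix_loglik(const AdmixData& D, const NumericMatrix& Q,
                           const NumericMatrix& F) {
  double ll = 0.0;
  for (int j = 0; j < D.m; ++j)
    for (int i = 0; i < D.n; ++i) {
      int gij = D.G(i, j);
      if (gij < 0) continue;
      double p = 0.0;
      for (int k = 0; k < D.K; ++k) p += Q(i, k) * F(j, k);
      p = clamp01(p);
      ll += gij * std::log(p) + (2 - gij) * std::log1p(-p);
    }
  return ll;
}

// one joint EM update (multiplicative updates of F then Q)
static void admix_step(const AdmixData& D, const NumericMatrix& Q,
                       const NumericMatrix& F, NumericMatrix& Qn,
                       NumericMatrix& Fn) {
  int n = D.n, m = D.m, K = D.K;
  std::vector<double> Fa(m * K, 0.0), Fb(m * K, 0.0),
    Aq(n * K, 0.0), denom(n, 0.0);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      int gij = D.G(i, j);
      if (gij < 0) continue;
      double p = 0.0;
      for (int k = 0; k < K; ++k) p += Q(i, k) * F(j, k);
      p = clamp01(p);
      for (int k = 0; k < K; ++k) {
        double a = gij * Q(i, k) * F(j, k) / p;
        double b = (2 - gij) * Q(i, k) * (1.0 - F(j, k)) / (1.0 - p);
        Fa[j + m * k] += a;
        Fb[j + m * k] += b;
        Aq[i + n * k] += a + b;
        denom[i] += a + b;
      }
    }
  }
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < K; ++k) {
      double tot = Fa[j + m * k] + Fb[j + m * k];
      Fn(j, k) = tot > 0 ? clamp01(Fa[j + m * k] / tot) : F(j, k);
    }
  for (int i = 0; i < n; ++i) {
    if (D.anchored[i] || denom[i] <= 0) {
      for (int k = 0; k < K; ++k) Qn(i, k) = Q(i, k);
    } else {
      for (int k = 0; k < K; ++k) Qn(i, k) = Aq[i + n * k] / denom[i];
    }
  }
}

// project extrapolated parameters back to the feasible set
static void admix_project(const AdmixData& D, NumericMatrix& Q,
                          NumericMatrix& F) {
  for (int j = 0; j < D.m; ++j)
    for (int k = 0; k < D.K; ++k) F(j, k) = clamp01(F(j, k));
  for (int i = 0; i < D.n; ++i) {
    double s = 0.0;
    for (int k = 0; k < D.K; ++k) {
      if (Q(i, k) < 0) Q(i, k) = 0;
      s += Q(i, k);
    }
    if (s <= 0) { for (int k = 0; k < D.K; ++k) Q(i, k) = 1.0 / D.K; }
    else for (int k = 0; k < D.K; ++k) Q(i, k) /= s;
  }
}

// [[Rcpp::export(name = ".em_admixture")]]
List em_admixture_cpp(IntegerMatrix G, NumericMatrix Q0, NumericMatrix F0,
                      LogicalVector anchored, double tol = 1e-4,
                      int max_iter = 2000) {
  AdmixData D{G, anchored, G.nrow(), G.ncol(), Q0.ncol()};
  NumericMatrix Q(clone(Q0)), F(clone(F0));
  NumericMatrix Q1(D.n, D.K), F1(D.m, D.K), Q2(D.n, D.K), F2(D.m, D.K),
    Qs(D.n, D.K), Fs(D.m, D.K), Qc(D.n, D.K), Fc(D.m, D.K);
  std::vector<double> ll_trace;
  double ll = admix_loglik(D, Q, F);
  ll_trace.push_back(ll);
  bool converged = false;
  int it;
  for (it = 0; it < max_iter; ++it) {
    admix_step(D, Q, F, Q1, F1);
    admix_step(D, Q1, F1, Q2, F2);
    double rr = 0.0, vv = 0.0;
    for (int i = 0; i < D.n * D.K; ++i) {
      double r = Q1[i] - Q[i], v = (Q2[i] - Q1[i]) - r;
      rr += r * r; vv += v * v;
    }
    for (int i = 0; i < D.m * D.K; ++i) {
      double r = F1[i] - F[i], v = (F2[i] - F1[i]) - r;
      rr += r * r; vv += v * v;
    }
    double ll2 = admix_loglik(D, Q2, F2);
    double ll_new = ll2;
    NumericMatrix *Qbest = &Q2, *Fbest = &F2;
    if (vv > 0) {
      double alpha = -std::sqrt(rr / vv);
      if (alpha > -1.0) alpha = -1.0;
      for (int i = 0; i < D.n * D.K; ++i) {
        double r = Q1[i] - Q[i], v = (Q2[i] - Q1[i]) - r;
        Qs[i] = Q[i] - 2.0 * alpha * r + alpha * alpha * v;
      }
      for (int i = 0; i < D.m * D.K; ++i) {
        double r = F1[i] - F[i], v = (F2[i] - F1[i]) - r;
        Fs[i] = F[i] - 2.0 * alpha * r + alpha * alpha * v;
      }
      admix_project(D, Qs, Fs);
      admix_step(D, Qs, Fs, Qc, Fc);   // stabilizing EM step
      double llc = admix_loglik(D, Qc, Fc);
      if (llc >= ll2) { ll_new = llc; Qbest = &Qc; Fbest = &Fc; }
    }
    for (int i = 0; i < D.n * D.K; ++i) Q[i] = (*Qbest)[i];
    for (int i = 0; i < D.m * D.K; ++i) F[i] = (*Fbest)[i];
    ll_trace.push_back(ll_new);
    if (ll_new - ll < tol) { ll = ll_new; converged = true; break; }
    ll = ll_new;
  }
  return List::create(_["Q"] = Q, _["F"] = F, _["loglik"] = ll,
                      _["loglik_trace"] = NumericVector(ll_trace.begin(),
                                                        ll_trace.end()),
                      _["iterations"] = it + 1,
                      _["converged"] = converged);
}
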