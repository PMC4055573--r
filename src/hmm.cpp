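// Scaled HMM recursions. The forward/backward passes exploit the structure
// of the parental-class transition matrix
//   T[i,j] = D_i                          (i == j)
//          = (1-gamma) * s_i * pt_j       (same class, i != j)
//          = gammap * pt_j                (different class)
// with pt_j the class-normalized topology probability of state j's
// genealogy, so one step costs O(n_states) instead of O(n_states^2).
// Emissions arrive as likelihoods rescaled per site pattern (E[j,p] =
// exp(logE[j,p] - logEmax[p])), which keeps the linear-space recursion in
// range for arbitrarily unlikely columns.

#include <Rcpp.h>
using namespace Rcpp;

// one structured transition step: out_j = sum_i a_i T[i,j]
// (S, A are caller-provided scratch buffers of length K)
static inline void step_forward(const double* a, double* out, int ns,
                                const int* cls, const double* ptil,
                                const double* svec, const double* D,
                                double gamma, double gammap, int K,
                                double* S, double* A) {
  double Atot = 0.0;
  for (int c = 0; c < K; ++c) { S[c] = 0.0; A[c] = 0.0; }
  for (int i = 0; i < ns; ++i) {
    S[cls[i]] += a[i] * svec[i];
    A[cls[i]] += a[i];
    Atot += a[i];
  }
  for (int j = 0; j < ns; ++j) {
    int c = cls[j];
    out[j] = D[j] * a[j] +
      (1.0 - gamma) * ptil[j] * (S[c] - svec[j] * a[j]) +
      gammap * ptil[j] * (Atot - A[c]);
  }
}

// [[Rcpp::export]]
List hmm_forward_cpp(NumericVector pi0, IntegerVector cls, NumericVector ptil,
                     NumericVector svec, NumericVector D, double gamma,
                     double gammap, int K, NumericMatrix E,
                     NumericVector logEmax, IntegerVector pidx,
                     bool keep_alpha) {
  int ns = pi0.size(), L = pidx.size();
  std::vector<double> a(ns), nxt(ns), S(K), A(K);
  NumericMatrix alpha(keep_alpha ? ns : 1, keep_alpha ? L : 1);
  const double* Ep = E.begin();
  double loglik = 0.0;
  int p = pidx[0];
  double c0 = 0.0;
  for (int i = 0; i < ns; ++i) { a[i] = pi0[i] * Ep[p * ns + i]; c0 += a[i]; }
  if (c0 <= 0.0) stop("impossible observation: all-zero likelihood at column 1");
  for (int i = 0; i < ns; ++i) a[i] /= c0;
  loglik += std::log(c0) + logEmax[p];
  if (keep_alpha) for (int i = 0; i < ns; ++i) alpha(i, 0) = a[i];
  for (int t = 1; t < L; ++t) {
    step_forward(a.data(), nxt.data(), ns, cls.begin(), ptil.begin(),
                 svec.begin(), D.begin(), gamma, gammap, K,
                 S.data(), A.data());
    p = pidx[t];
    const double* e = Ep + (size_t)p * ns;
    double ct = 0.0;
    for (int i = 0; i < ns; ++i) { nxt[i] *= e[i]; ct += nxt[i]; }
    if (ct <= 0.0)
      stop("impossible observation: all-zero likelihood at column %d", t + 1);
    for (int i = 0; i < ns; ++i) a[i] = nxt[i] / ct;
    loglik += std::log(ct) + logEmax[p];
    if (keep_alpha) for (int i = 0; i < ns; ++i) alpha(i, t) = a[i];
  }
  return List::create(_["loglik"] = loglik, _["alpha"] = alpha);
}

// backward pass with its own scaling; also returns an independently
// accumulated total log-likelihood for the forward/backward identity check
// [[Rcpp::export]]
List hmm_backward_cpp(NumericVector pi0, IntegerVector cls, NumericVector ptil,
                      NumericVector svec, NumericVector D, double gamma,
                      double gammap, int K, NumericMatrix E,
                      NumericVector logEmax, IntegerVector pidx,
                      bool keep_beta) {
  int ns = pi0.size(), L = pidx.size();
  std::vector<double> b(ns, 1.0), x(ns), nxt(ns), W(K);
  NumericMatrix beta(keep_beta ? ns : 1, keep_beta ? L : 1);
  const double* Ep = E.begin();
  double logscale = 0.0;
  if (keep_beta) for (int i = 0; i < ns; ++i) beta(i, L - 1) = 1.0;
  for (int t = L - 2; t >= 0; --t) {
    int p = pidx[t + 1];
    const double* e = Ep + (size_t)p * ns;
    double Wtot = 0.0;
    for (int c = 0; c < K; ++c) W[c] = 0.0;
    for (int j = 0; j < ns; ++j) {
      x[j] = e[j] * b[j];
      W[cls[j]] += ptil[j] * x[j];
      Wtot += ptil[j] * x[j];
    }
    double ct = 0.0;
    for (int i = 0; i < ns; ++i) {
      int c = cls[i];
      nxt[i] = D[i] * x[i] +
        (1.0 - gamma) * svec[i] * (W[c] - ptil[i] * x[i]) +
        gammap * (Wtot - W[c]);
      ct += nxt[i];
    }
    if (ct <= 0.0)
      stop("impossible observation: all-zero likelihood at column %d", t + 2);
    for (int i = 0; i < ns; ++i) b[i] = nxt[i] / ct;
    logscale += std::log(ct) + logEmax[p];
    if (keep_beta) for (int i = 0; i < ns; ++i) beta(i, t) = b[i];
  }
  int p0 = pidx[0];
  double tot = 0.0;
  for (int i = 0; i < ns; ++i) tot += pi0[i] * Ep[(size_t)p0 * ns + i] * b[i];
  double loglik = std::log(tot) + logEmax[p0] + logscale;
  return List::create(_["loglik"] = loglik, _["beta"] = beta);
}

// fused forward-backward posterior: stores the scaled forward variables,
// rolls the backward pass in place, and returns the per-site posterior mass
// of the flagged states (the introgression track) plus per-state total
// posterior mass, without materializing the full posterior matrix
// [[Rcpp::export]]
List hmm_posterior_track_cpp(NumericVector pi0, IntegerVector cls,
                             NumericVector ptil, NumericVector svec,
                             NumericVector D, double gamma, double gammap,
                             int K, NumericMatrix E, NumericVector logEmax,
                             IntegerVector pidx, LogicalVector flagged) {
  int ns = pi0.size(), L = pidx.size();
  const double* Ep = E.begin();
  std::vector<double> a(ns), nxt(ns), S(K), A(K);
  std::vector<double> alpha((size_t)ns * L);
  double loglik = 0.0;
  {
    int p = pidx[0];
    double c0 = 0.0;
    for (int i = 0; i < ns; ++i) { a[i] = pi0[i] * Ep[(size_t)p * ns + i]; c0 += a[i]; }
    if (c0 <= 0.0) stop("impossible observation: all-zero likelihood at column 1");
    for (int i = 0; i < ns; ++i) { a[i] /= c0; alpha[i] = a[i]; }
    loglik += std::log(c0) + logEmax[p];
  }
  for (int t = 1; t < L; ++t) {
    step_forward(a.data(), nxt.data(), ns, cls.begin(), ptil.begin(),
                 svec.begin(), D.begin(), gamma, gammap, K,
                 S.data(), A.data());
    int p = pidx[t];
    const double* e = Ep + (size_t)p * ns;
    double ct = 0.0;
    for (int i = 0; i < ns; ++i) { nxt[i] *= e[i]; ct += nxt[i]; }
    if (ct <= 0.0)
      stop("impossible observation: all-zero likelihood at column %d", t + 1);
    double* at = alpha.data() + (size_t)t * ns;
    for (int i = 0; i < ns; ++i) { a[i] = nxt[i] / ct; at[i] = a[i]; }
    loglik += std::log(ct) + logEmax[p];
  }
  // backward pass, combining on the fly
  NumericVector track(L);
  NumericVector state_mass(ns);
  std::vector<double> b(ns, 1.0), x(ns), W(K);
  double logscale = 0.0;
  for (int t = L - 1; t >= 0; --t) {
    const double* at = alpha.data() + (size_t)t * ns;
    double tot = 0.0, fl = 0.0;
    for (int i = 0; i < ns; ++i) {
      double w = at[i] * b[i];
      x[i] = w;                      // reuse x as scratch for weights
      tot += w;
      if (flagged[i]) fl += w;
    }
    track[t] = fl / tot;
    for (int i = 0; i < ns; ++i) state_mass[i] += x[i] / tot;
    if (t == 0) break;
    int p = pidx[t];
    const double* e = Ep + (size_t)p * ns;
    double Wtot = 0.0;
    for (int c = 0; c < K; ++c) W[c] = 0.0;
    for (int j = 0; j < ns; ++j) {
      x[j] = e[j] * b[j];
      W[cls[j]] += ptil[j] * x[j];
      Wtot += ptil[j] * x[j];
    }
    double ct = 0.0;
    for (int i = 0; i < ns; ++i) {
      int c = cls[i];
      nxt[i] = D[i] * x[i] +
        (1.0 - gamma) * svec[i] * (W[c] - ptil[i] * x[i]) +
        gammap * (Wtot - W[c]);
      ct += nxt[i];
    }
    if (ct <= 0.0)
      stop("impossible observation: all-zero likelihood at column %d", t + 1);
    for (int i = 0; i < ns; ++i) b[i] = nxt[i] / ct;
    logscale += std::log(ct) + logEmax[p];
  }
  // independent backward total log-likelihood
  double tot0 = 0.0;
  int p0 = pidx[0];
  for (int i = 0; i < ns; ++i) tot0 += pi0[i] * Ep[(size_t)p0 * ns + i] * b[i];
  double loglik_b = std::log(tot0) + logEmax[p0] + logscale;
  return List::create(_["loglik"] = loglik, _["loglik_backward"] = loglik_b,
                      _["track"] = track, _["state_mass"] = state_mass);
}

// dense log-space Viterbi; ties broken toward the lowest state index
// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericVector logpi0, NumericMatrix logT,
                     NumericMatrix logE, IntegerVector pidx) {
  int ns = logpi0.size(), L = pidx.size();
  NumericMatrix delta(ns, L);
  IntegerMatrix psi(ns, L);
  for (int i = 0; i < ns; ++i) delta(i, 0) = logpi0[i] + logE(i, pidx[0]);
  for (int t = 1; t < L; ++t) {
    int p = pidx[t];
    for (int j = 0; j < ns; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < ns; ++i) {
        double v = delta(i, t - 1) + logT(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(j, t) = best + logE(j, p);
      psi(j, t) = arg;
    }
  }
  double best = R_NegInf;
  int arg = 0;
  for (int i = 0; i < ns; ++i)
    if (delta(i, L - 1) > best) { best = delta(i, L - 1); arg = i; }
  IntegerVector path(L);
  path[L - 1] = arg;
  for (int t = L - 1; t > 0; --t) path[t - 1] = psi(path[t], t);
  for (int t = 0; t < L; ++t) path[t] += 1;  // 1-based state indices
  return List::create(_["path"] = path, _["logprob"] = best);
}
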