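#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the binary-band admixture mixture:
//   theta_kl ~ Beta(1,1); q_i ~ Dirichlet(1,...,1);
//   z_il ~ Cat(q_i); band_il ~ Bernoulli(theta[z_il, l]).
// Uses R's RNG so set.seed() in R makes runs reproducible. Allocation
// counts for the conjugate theta/q updates are accumulated while z is
// resampled, and the mixture log-likelihood of the current state falls out
// of the same pass.
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix X, int K, int burnin, int nsamp) {
  const int n = X.nrow(), L = X.ncol();
  std::vector<int> z(static_cast<size_t>(n) * L);
  std::vector<double> theta(static_cast<size_t>(K) * L);     // theta[k + K*l]
  std::vector<double> q(static_cast<size_t>(K) * n);         // q[k + K*i]
  std::vector<double> n1(static_cast<size_t>(K) * L), n0(static_cast<size_t>(K) * L);
  std::vector<double> cnt(static_cast<size_t>(K) * n);
  std::vector<double> Qsum(static_cast<size_t>(K) * n, 0.0);
  std::vector<double> Tsum(static_cast<size_t>(K) * L, 0.0);
  std::vector<double> theta_ref(static_cast<size_t>(K) * L);
  std::vector<int> Xt(static_cast<size_t>(n) * L);           // Xt[i + n*l]
  for (int l = 0; l < L; l++)
    for (int i = 0; i < n; i++) Xt[i + static_cast<size_t>(n) * l] = X(i, l);
  std::vector<int> perm(K), used(K);
  std::vector<double> w(K);
  double ll_sum = 0.0;

  // random initial allocations -> initial counts
  std::fill(n1.begin(), n1.end(), 0.0);
  std::fill(n0.begin(), n0.end(), 0.0);
  std::fill(cnt.begin(), cnt.end(), 0.0);
  for (int l = 0; l < L; l++)
    for (int i = 0; i < n; i++) {
      int k = (int)(unif_rand() * K);
      if (k >= K) k = K - 1;
      z[i + static_cast<size_t>(n) * l] = k;
      if (Xt[i + static_cast<size_t>(n) * l] == 1) n1[k + static_cast<size_t>(K) * l] += 1.0;
      else n0[k + static_cast<size_t>(K) * l] += 1.0;
      cnt[k + static_cast<size_t>(K) * i] += 1.0;
    }

  const int total = burnin + nsamp;
  for (int sweep = 0; sweep < total; sweep++) {
    // theta | z
    for (size_t kl = 0; kl < theta.size(); kl++)
      theta[kl] = R::rbeta(1.0 + n1[kl], 1.0 + n0[kl]);
    // q | z (Dirichlet via gamma draws)
    for (int i = 0; i < n; i++) {
      double s = 0.0;
      double *qi = &q[static_cast<size_t>(K) * i];
      const double *ci = &cnt[static_cast<size_t>(K) * i];
      for (int k = 0; k < K; k++) { qi[k] = R::rgamma(1.0 + ci[k], 1.0); s += qi[k]; }
      for (int k = 0; k < K; k++) qi[k] /= s;
    }
    // z | theta, q, accumulating counts for the next sweep
    std::fill(n1.begin(), n1.end(), 0.0);
    std::fill(n0.begin(), n0.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    const bool record = sweep >= burnin;
    double ll = 0.0;
    for (int l = 0; l < L; l++) {
      const double *tl = &theta[static_cast<size_t>(K) * l];
      double *n1l = &n1[static_cast<size_t>(K) * l];
      double *n0l = &n0[static_cast<size_t>(K) * l];
      const int *xl = &Xt[static_cast<size_t>(n) * l];
      int *zl = &z[static_cast<size_t>(n) * l];
      for (int i = 0; i < n; i++) {
        const double *qi = &q[static_cast<size_t>(K) * i];
        double tot = 0.0;
        if (xl[i] == 1) {
          for (int k = 0; k < K; k++) { w[k] = qi[k] * tl[k]; tot += w[k]; }
        } else {
          for (int k = 0; k < K; k++) { w[k] = qi[k] * (1.0 - tl[k]); tot += w[k]; }
        }
        double u = unif_rand() * tot, acc = 0.0;
        int knew = K - 1;
        for (int k = 0; k < K; k++) { acc += w[k]; if (u <= acc) { knew = k; break; } }
        zl[i] = knew;
        if (xl[i] == 1) n1l[knew] += 1.0; else n0l[knew] += 1.0;
        cnt[knew + static_cast<size_t>(K) * i] += 1.0;
        if (record) ll += std::log(tot);
      }
    }
    if (record) {
      ll_sum += ll;
      // align labels to the first recorded sample's theta (greedy matching)
      if (sweep == burnin) theta_ref = theta;
      std::fill(used.begin(), used.end(), 0);
      for (int k = 0; k < K; k++) {
        int best = -1; double bestc = R_PosInf;
        for (int j = 0; j < K; j++) {
          if (used[j]) continue;
          double c = 0.0;
          for (int l = 0; l < L; l++)
            c += std::fabs(theta[k + static_cast<size_t>(K) * l] -
                           theta_ref[j + static_cast<size_t>(K) * l]);
          if (c < bestc) { bestc = c; best = j; }
        }
        perm[k] = best; used[best] = 1;
      }
      for (int i = 0; i < n; i++)
        for (int k = 0; k < K; k++)
          Qsum[perm[k] + static_cast<size_t>(K) * i] += q[k + static_cast<size_t>(K) * i];
      for (int l = 0; l < L; l++)
        for (int k = 0; k < K; k++)
          Tsum[perm[k] + static_cast<size_t>(K) * l] += theta[k + static_cast<size_t>(K) * l];
    }
  }
  NumericMatrix Q(n, K), Tm(K, L);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++) Q(i, k) = Qsum[k + static_cast<size_t>(K) * i] / nsamp;
  for (int k = 0; k < K; k++)
    for (int l = 0; l < L; l++) Tm(k, l) = Tsum[k + static_cast<size_t>(K) * l] / nsamp;
  return List::create(_["loglik"] = ll_sum / nsamp, _["Q"] = Q, _["theta"] = Tm);
}

// Permutation distribution of the AMOVA Phi-statistic: permutes individuals
// among populations with fixed sizes and recomputes Phi from the fixed
// distance matrix. d2 holds squared Euclidean (= Hamming) distances.
// [[Rcpp::export]]
NumericVector amova_perm_cpp(NumericMatrix d2, IntegerVector sizes,
                             int nperm, double n0) {
  const int n = d2.nrow();
  const int G = sizes.size();
  const int dfa = G - 1, dfw = n - G;
  const double *D = d2.begin();
  double sstot = 0.0;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) sstot += D[i + static_cast<size_t>(n) * j];
  sstot /= n;
  std::vector<int> idx(n);
  for (int i = 0; i < n; i++) idx[i] = i;
  NumericVector phi(nperm);
  for (int b = 0; b < nperm; b++) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = n - 1; i > 0; i--) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double ssw = 0.0;
    int off = 0;
    for (int g = 0; g < G; g++) {
      const int ng = sizes[g];
      double s = 0.0;
      for (int a = 0; a < ng; a++) {
        const double *row = D + static_cast<size_t>(n) * idx[off + a];
        for (int c = a + 1; c < ng; c++) s += row[idx[off + c]];
      }
      ssw += s / ng;
      off += ng;
    }
    double msw = ssw / dfw;
    double msa = (sstot - ssw) / dfa;
    double s2a = (msa - msw) / n0;
    phi[b] = s2a / (s2a + msw);
  }
  return phi;
}
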