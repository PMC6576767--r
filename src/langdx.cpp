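#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA.
// doc, word are 0-based token-instance vectors; topic-count matrices are
// K-major so the inner loop over topics walks contiguous memory.
// Uses R's RNG: reproducible under set.seed() in the caller.
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector word,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double eta, int n_sweeps) {
  const int N = doc.size();
  const int K = n_topics;
  std::vector<int> nkd((size_t)K * n_docs, 0);   // topic x doc
  std::vector<int> nkw((size_t)K * n_vocab, 0);  // topic x word
  std::vector<int> nk(K, 0);
  std::vector<int> z(N);
  std::vector<double> cum(K);
  const double Veta = n_vocab * eta;

  for (int i = 0; i < N; ++i) {
    int k = (int)(unif_rand() * K);
    if (k >= K) k = K - 1;
    z[i] = k;
    ++nkd[(size_t)doc[i] * K + k];
    ++nkw[(size_t)word[i] * K + k];
    ++nk[k];
  }
  std::vector<double> inv_nk(K);
  for (int t = 0; t < K; ++t) inv_nk[t] = 1.0 / (nk[t] + Veta);

  for (int it = 0; it < n_sweeps; ++it) {
    for (int i = 0; i < N; ++i) {
      const int d = doc[i], w = word[i];
      int k = z[i];
      int* cd = &nkd[(size_t)d * K];
      int* cw = &nkw[(size_t)w * K];
      --cd[k]; --cw[k]; --nk[k];
      inv_nk[k] = 1.0 / (nk[k] + Veta);
      double tot = 0.0;
      for (int t = 0; t < K; ++t) {
        tot += (cd[t] + alpha) * (cw[t] + eta) * inv_nk[t];
        cum[t] = tot;
      }
      const double u = unif_rand() * tot;
      int knew = 0;
      while (knew < K - 1 && cum[knew] < u) ++knew;
      z[i] = knew;
      ++cd[knew]; ++cw[knew]; ++nk[knew];
      inv_nk[knew] = 1.0 / (nk[knew] + Veta);
    }
    if ((it & 31) == 0) Rcpp::checkUserInterrupt();
  }

  IntegerMatrix topic_word(K, n_vocab);
  for (int w = 0; w < n_vocab; ++w)
    for (int t = 0; t < K; ++t)
      topic_word(t, w) = nkw[(size_t)w * K + t];
  IntegerVector topic_tot(K);
  for (int t = 0; t < K; ++t) topic_tot[t] = nk[t];
  return List::create(_["topic_word"] = topic_word,
                      _["topic_totals"] = topic_tot);
}

// Rank-based AUC with average ranks for ties; y is 0/1.
static double auc_ranked(const std::vector<double>& s, const IntegerVector& y,
                         std::vector<int>& ord) {
  const int n = (int)s.size();
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&s](int a, int b) { return s[a] < s[b]; });
  double sum_pos = 0.0;
  int n1 = 0;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s[ord[j + 1]] == s[ord[i]]) ++j;
    const double r = 0.5 * (i + j) + 1.0;  // average rank of the tie block
    for (int t = i; t <= j; ++t)
      if (y[ord[t]] == 1) { sum_pos += r; ++n1; }
    i = j + 1;
  }
  const int n0 = n - n1;
  return (sum_pos - n1 * (n1 + 1.0) / 2.0) / ((double)n1 * n0);
}

// Paired sign-flip permutation null for the difference of two AUCs:
// each iteration independently swaps (a_i, b_i) with probability 1/2.
// Returns the count of |delta_perm| >= |delta_obs| (small tolerance for
// floating-point equality at the observed value).
// [[Rcpp::export]]
int perm_auc_diff_count_cpp(NumericVector a, NumericVector b,
                            IntegerVector y, double delta_obs, int n_iter) {
  const int n = a.size();
  std::vector<double> a2(n), b2(n);
  std::vector<int> ord(n);
  const double thr = std::fabs(delta_obs) - 1e-12;
  int count = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      if (unif_rand() < 0.5) { a2[i] = b[i]; b2[i] = a[i]; }
      else                   { a2[i] = a[i]; b2[i] = b[i]; }
    }
    const double d = auc_ranked(a2, y, ord) - auc_ranked(b2, y, ord);
    if (std::fabs(d) >= thr) ++count;
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return count;
}
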