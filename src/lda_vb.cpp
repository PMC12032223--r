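// Batch variational Bayes for latent Dirichlet allocation over sparse
// gene-count documents, with support for holding a leading block of topics
// fixed at given log-probabilities (the two-stage singlet/doublet fit).
//
// Documents are cells (columns of a genes x cells dgCMatrix), words are
// genes, word counts are the integer expression counts. The E-step works in
// linear space on exp(Elog*) tables; with V in the thousands the products
// stay far from the double underflow range.

#include <Rcpp.h>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".lda_vb_cpp")]]
List lda_vb_cpp(IntegerVector mi, IntegerVector mp, NumericVector mx,
                int V, int D, int K, int n_fixed,
                NumericMatrix log_beta_fixed,
                double alpha, double eta,
                int max_iter, double tol, int inner_iter,
                bool update_beta, NumericMatrix lambda_init) {
  const int n_free = K - n_fixed;

  // lambda (free-topic variational word weights): either supplied (V x
  // n_free, e.g. document-seeded for the doublet stage) or a
  // Gamma(100, 0.01)-style random init drawn from R's RNG so a set.seed()
  // upstream fixes it.
  std::vector<double> lambda((size_t)std::max(n_free, 0) * V, 0.0);
  if (lambda_init.ncol() == n_free && n_free > 0) {
    for (int k = 0; k < n_free; ++k)
      for (int w = 0; w < V; ++w)
        lambda[(size_t)k * V + w] = lambda_init(w, k);
  } else {
    for (size_t t = 0; t < lambda.size(); ++t)
      lambda[t] = R::rgamma(100.0, 0.01);
  }

  std::vector<double> expElogbeta((size_t)K * V, 0.0);  // [k*V + w]
  std::vector<double> beta_hat((size_t)K * V, 0.0);     // expected word probs
  for (int k = 0; k < n_fixed; ++k)
    for (int w = 0; w < V; ++w) {
      expElogbeta[(size_t)k * V + w] = std::exp(log_beta_fixed(w, k));
      beta_hat[(size_t)k * V + w] = std::exp(log_beta_fixed(w, k));
    }

  NumericMatrix gamma_out(D, K);
  std::vector<double> gamma_d(K), expEltheta(K), gnew(K), phik(K);
  std::vector<double> sstats;
  std::vector<double> scores;
  double total_tokens = 0.0;
  for (int t = 0; t < mx.size(); ++t) total_tokens += mx[t];
  if (total_tokens <= 0) stop("LDA input has no counts");

  double prev_score = R_NegInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // refresh free-topic expectations
    for (int k = 0; k < n_free; ++k) {
      double s = 0.0;
      for (int w = 0; w < V; ++w) s += lambda[(size_t)k * V + w];
      double dg = R::digamma(s);
      int kk = n_fixed + k;
      for (int w = 0; w < V; ++w) {
        expElogbeta[(size_t)kk * V + w] =
          std::exp(R::digamma(lambda[(size_t)k * V + w]) - dg);
        beta_hat[(size_t)kk * V + w] = lambda[(size_t)k * V + w] / s;
      }
    }
    if (update_beta) sstats.assign((size_t)std::max(n_free, 0) * V, 0.0);

    double score = 0.0;
    for (int d = 0; d < D; ++d) {
      int from = mp[d], to = mp[d + 1];
      if (from == to) {
        for (int k = 0; k < K; ++k) gamma_out(d, k) = alpha;
        continue;
      }
      double nd = 0.0;
      for (int t = from; t < to; ++t) nd += mx[t];
      for (int k = 0; k < K; ++k) gamma_d[k] = alpha + nd / K;

      for (int it = 0; it < inner_iter; ++it) {
        double gs = std::accumulate(gamma_d.begin(), gamma_d.end(), 0.0);
        double dgs = R::digamma(gs);
        for (int k = 0; k < K; ++k)
          expEltheta[k] = std::exp(R::digamma(gamma_d[k]) - dgs);
        std::fill(gnew.begin(), gnew.end(), alpha);
        for (int t = from; t < to; ++t) {
          const double* eb = &expElogbeta[(size_t)mi[t]];
          double norm = 0.0;
          for (int k = 0; k < K; ++k) {
            phik[k] = expEltheta[k] * eb[(size_t)k * V];
            norm += phik[k];
          }
          double scale = mx[t] / std::max(norm, 1e-300);
          for (int k = 0; k < K; ++k) gnew[k] += scale * phik[k];
        }
        double diff = 0.0;
        for (int k = 0; k < K; ++k) diff += std::fabs(gnew[k] - gamma_d[k]);
        std::swap(gamma_d, gnew);
        if (diff / K < 1e-3) break;
      }

      // accumulate sufficient statistics and the score with converged gamma
      double gs = std::accumulate(gamma_d.begin(), gamma_d.end(), 0.0);
      double dgs = R::digamma(gs);
      for (int k = 0; k < K; ++k)
        expEltheta[k] = std::exp(R::digamma(gamma_d[k]) - dgs);
      for (int t = from; t < to; ++t) {
        int w = mi[t];
        double norm = 0.0, lik = 0.0;
        for (int k = 0; k < K; ++k) {
          phik[k] = expEltheta[k] * expElogbeta[(size_t)k * V + w];
          norm += phik[k];
          lik += (gamma_d[k] / gs) * beta_hat[(size_t)k * V + w];
        }
        if (update_beta) {
          double scale = mx[t] / std::max(norm, 1e-300);
          for (int k = n_fixed; k < K; ++k)
            sstats[(size_t)(k - n_fixed) * V + w] += scale * phik[k];
        }
        score += mx[t] * std::log(std::max(lik, 1e-300));
      }
      for (int k = 0; k < K; ++k) gamma_out(d, k) = gamma_d[k];
    }

    if (update_beta)
      for (size_t t = 0; t < lambda.size(); ++t)
        lambda[t] = eta + sstats[t];

    scores.push_back(score);
    double rel = std::fabs(score - prev_score) /
      std::max(std::fabs(prev_score), 1e-12);
    if (iter > 1 && rel < tol) break;
    prev_score = score;
    if (!update_beta) break;  // pure transform: one outer pass suffices
  }

  // final expected beta for free topics
  NumericMatrix beta_out(V, K);
  for (int k = 0; k < K; ++k)
    for (int w = 0; w < V; ++w)
      beta_out(w, k) = beta_hat[(size_t)k * V + w];
  for (int k = 0; k < n_free; ++k) {
    double s = 0.0;
    for (int w = 0; w < V; ++w) s += lambda[(size_t)k * V + w];
    for (int w = 0; w < V; ++w)
      beta_out(w, n_fixed + k) = lambda[(size_t)k * V + w] / s;
  }

  double last = scores.empty() ? R_NegInf : scores.back();
  return List::create(
    _["gamma"] = gamma_out, _["beta"] = beta_out,
    _["scores"] = NumericVector(scores.begin(), scores.end()),
    _["n_iter"] = (double)std::min(iter, max_iter),
    _["perplexity"] = std::exp(-last / total_tokens),
    _["tokens"] = total_tokens);
}
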