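// Gibbs sampler for the spatially-aware clustering model:
//   y_i | z_i = k, w_i ~ N(mu_k, Sigma / w_i),  w_i ~ Gamma(nu/2, nu/2)
//   p(z_i = k | z_N(i)) proportional to exp(gamma * #{j in N(i): z_j = k})
// Conjugate updates for mu_k and the shared precision Lambda = Sigma^{-1}
// (normal / Wishart), Gamma update for the t-scale weights, and single-site
// Gibbs updates for z from the exact full conditional (the same conditional
// the enumeration oracle checks). Uses R's RNG throughout so a fixed R seed
// reproduces the chain exactly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::vec site_probs_core(const arma::vec& loglik,
                                 const arma::ivec& nbrLabels,
                                 double gamma, int q) {
  arma::vec lp = loglik;
  for (arma::uword j = 0; j < nbrLabels.n_elem; ++j) {
    int l = nbrLabels[j];
    if (l >= 0 && l < q) lp[l] += gamma;
  }
  lp -= lp.max();
  arma::vec p = arma::exp(lp);
  return p / arma::accu(p);
}

// Exposed for the enumeration oracle: normalized single-site conditional
// p(z_i = k | neighbours, likelihood) with log-likelihood row `loglik`
// (length q) and 0-based neighbour labels.
// [[Rcpp::export(name = ".pottsSiteProbs")]]
arma::vec potts_site_probs(const arma::vec& loglik,
                           const arma::ivec& nbrLabels, double gamma) {
  return site_probs_core(loglik, nbrLabels, gamma, loglik.n_elem);
}

static int sample_cat(const arma::vec& p) {
  double u = R::runif(0.0, 1.0), c = 0.0;
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    c += p[k];
    if (u <= c) return k;
  }
  return p.n_elem - 1;
}

// Wishart(df, S) via Bartlett decomposition; S passed as its lower
// Cholesky factor L (S = L L').
static arma::mat rwishart_chol(double df, const arma::mat& L) {
  int d = L.n_rows;
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export(name = ".mrfGibbs")]]
List mrf_gibbs(const arma::mat& Y, const List& nbr, int q, double gamma,
               double nu, int nIter, int burnIn, double tau2,
               const arma::ivec& zInit) {
  const int n = Y.n_rows, d = Y.n_cols;
  const bool tErrors = arma::is_finite(nu);

  std::vector<arma::ivec> N(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbr[i];
    arma::ivec vi(v.size());
    for (int j = 0; j < v.size(); ++j) vi[j] = v[j] - 1;  // to 0-based
    N[i] = vi;
  }

  arma::ivec z = zInit;  // 0-based
  arma::vec w(n, arma::fill::ones);
  arma::rowvec m0 = arma::mean(Y, 0);

  // vague conjugate priors: mu_k ~ N(m0, tau2 I);
  // Lambda ~ Wishart(d + 2, S0) with E[Lambda] = inv(cov(Y))
  double df0 = d + 2.0;
  arma::mat covY = arma::cov(Y);
  covY.diag() += 1e-8 * arma::trace(covY) / d;
  arma::mat S0inv = df0 * covY;
  arma::mat Lambda = arma::inv_sympd(covY);

  arma::mat Mu(q, d);
  for (int k = 0; k < q; ++k) {
    arma::uvec idx = arma::find(z == k);
    Mu.row(k) = idx.n_elem ? arma::mean(Y.rows(idx), 0) : m0;
  }

  arma::mat labelCounts(n, q, arma::fill::zeros);
  arma::vec negPLL(nIter);
  arma::vec flipRate(nIter);
  long labelSwitches = 0;
  int emptyReseeds = 0;

  for (int it = 0; it < nIter; ++it) {
    // --- mu_k | z, w, Lambda ---
    for (int k = 0; k < q; ++k) {
      arma::uvec idx = arma::find(z == k);
      double sw = 0.0;
      arma::rowvec sy(d, arma::fill::zeros);
      for (arma::uword a = 0; a < idx.n_elem; ++a) {
        sw += w[idx[a]];
        sy += w[idx[a]] * Y.row(idx[a]);
      }
      arma::mat A = sw * Lambda;
      A.diag() += 1.0 / tau2;
      arma::vec b = Lambda * sy.t() + m0.t() / tau2;
      arma::mat Ainv = arma::inv_sympd(A);
      arma::vec mean = Ainv * b;
      arma::mat Lc = arma::chol(Ainv, "lower");
      arma::vec zdraw(d);
      for (int j = 0; j < d; ++j) zdraw[j] = R::norm_rand();
      Mu.row(k) = (mean + Lc * zdraw).t();
    }

    // --- Lambda | z, w, mu ---
    arma::mat SS(d, d, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      arma::rowvec r = Y.row(i) - Mu.row(z[i]);
      SS += w[i] * (r.t() * r);
    }
    arma::mat scale = arma::inv_sympd(S0inv + SS);
    Lambda = rwishart_chol(df0 + n, arma::chol(scale, "lower"));

    // --- squared Mahalanobis distances to each cluster mean ---
    arma::mat U = arma::chol(Lambda);          // Lambda = U' U
    arma::mat Yt = Y * U.t();
    arma::mat Mt = Mu * U.t();
    arma::mat D2(n, q);
    for (int k = 0; k < q; ++k) {
      arma::mat diff = Yt.each_row() - Mt.row(k);
      D2.col(k) = arma::sum(diff % diff, 1);
    }

    // --- w_i | z, mu, Lambda (t-scale weights) ---
    if (tErrors) {
      for (int i = 0; i < n; ++i)
        w[i] = R::rgamma((nu + d) / 2.0, 2.0 / (nu + D2(i, z[i])));
      // D2 used for z below is unchanged (depends on mu, Lambda only)
    }

    // --- z sweep: single-site Gibbs from the exact conditional ---
    int flips = 0;
    for (int i = 0; i < n; ++i) {
      arma::vec loglik = -0.5 * w[i] * D2.row(i).t();
      arma::ivec nbl(N[i].n_elem);
      for (arma::uword j = 0; j < N[i].n_elem; ++j) nbl[j] = z[N[i][j]];
      arma::vec p = site_probs_core(loglik, nbl, gamma, q);
      int znew = sample_cat(p);
      if (znew != z[i]) ++flips;
      z[i] = znew;
    }
    labelSwitches += flips;
    flipRate[it] = (double)flips / n;

    // --- negative pseudo-log-likelihood (Besag): data term under the
    // marginal multivariate-t (or Gaussian) density plus the Potts
    // single-site label conditional, at the current state ---
    double logDetSigma = 0.0;  // |Sigma| = 1/|Lambda|; U'U = Lambda
    for (int j = 0; j < d; ++j) logDetSigma -= 2.0 * std::log(U(j, j));
    double npll = 0.0;
    for (int i = 0; i < n; ++i) {
      double d2 = D2(i, z[i]);
      double logf;
      if (tErrors)
        logf = R::lgammafn((nu + d) / 2.0) - R::lgammafn(nu / 2.0)
             - 0.5 * d * std::log(nu * M_PI) - 0.5 * logDetSigma
             - 0.5 * (nu + d) * std::log1p(d2 / nu);
      else
        logf = -0.5 * d * std::log(2.0 * M_PI) - 0.5 * logDetSigma - 0.5 * d2;
      arma::vec pott(q, arma::fill::zeros);
      for (arma::uword j = 0; j < N[i].n_elem; ++j) pott[z[N[i][j]]] += gamma;
      pott -= pott.max();
      double logPrior = pott[z[i]] - std::log(arma::accu(arma::exp(pott)));
      npll -= logf + logPrior;
    }
    negPLL[it] = npll;

    // --- empty-cluster rescue: re-seed from the worst-fitting pixel ---
    for (int k = 0; k < q; ++k) {
      if (!arma::any(z == k)) {
        arma::vec fit(n);
        for (int i = 0; i < n; ++i) fit[i] = -0.5 * w[i] * D2(i, z[i]);
        arma::uword worst = fit.index_min();
        z[worst] = k;
        ++emptyReseeds;
      }
    }

    if (it >= burnIn)
      for (int i = 0; i < n; ++i) labelCounts(i, z[i]) += 1.0;
  }

  // posterior mode over post-burn-in samples
  arma::ivec zMode(n);
  for (int i = 0; i < n; ++i) zMode[i] = labelCounts.row(i).index_max();

  return List::create(
    _["labels"] = IntegerVector(zMode.begin(), zMode.end()),
    _["negPseudoLogLik"] = NumericVector(negPLL.begin(), negPLL.end()),
    _["flipRate"] = NumericVector(flipRate.begin(), flipRate.end()),
    _["labelSwitches"] = (double)labelSwitches,
    _["emptyReseeds"] = emptyReseeds);
}
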