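#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs cores for the simplified (rotated-frame)
// and full Ball-and-Stick models. Parameters with uniform priors are updated
// by symmetric Gaussian random-walk Metropolis steps; out-of-support
// proposals carry zero prior mass and are rejected. The noise precision is
// updated by an exact conditional draw (conjugate Gamma prior) or by a
// slice-sampling step on log(sigma^2) (inverse-gamma prior on the precision,
// whose conditional is generalized-inverse-Gaussian).

static double loglik_gauss(const std::vector<double> &resid, double sigma) {
  double ssr = 0.0;
  for (double r : resid) ssr += r * r;
  double n = (double)resid.size();
  return -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
         ssr / (2.0 * sigma * sigma);
}

// proposal-scale adaptation: multiply or divide by delta depending on the
// batch acceptance rate; delta = exp(min(0.01, 1/sqrt(batch))) shrinks to 1
static double adapt_delta(int batch_index) {
  double c = std::sqrt((double)batch_index);
  double e = std::min(0.01, 1.0 / c);
  return std::exp(e);
}

struct PrecisionPrior {
  int type;        // 0 = conjugate Gamma on precision, 1 = IG on precision
  double shape;    // alpha
  double rate;     // beta (rate for Gamma, scale of the IG density)
};

// log conditional density of t = log(sigma^2) up to a constant.
// IG(alpha, beta) prior on precision => sigma^2 ~ Gamma(alpha, rate beta);
// with the Gaussian likelihood the conditional of y = sigma^2 is
// GIG(lambda = alpha - n/2, chi = SSR, psi = 2 beta): strictly log-concave
// in t, which makes the slice sampler robust.
static double log_cond_t(double t, double lambda, double beta, double ssr) {
  return lambda * t - beta * std::exp(t) - 0.5 * ssr * std::exp(-t);
}

static double slice_sample_logvar(double t0, double lambda, double beta,
                                  double ssr) {
  double ly = log_cond_t(t0, lambda, beta, ssr) - R::rexp(1.0);
  double w = 0.5;
  double L = t0 - w * R::runif(0.0, 1.0);
  double R_ = L + w;
  while (log_cond_t(L, lambda, beta, ssr) > ly) L -= w;
  while (log_cond_t(R_, lambda, beta, ssr) > ly) R_ += w;
  for (int it = 0; it < 1000; ++it) {
    double t1 = R::runif(L, R_);
    if (log_cond_t(t1, lambda, beta, ssr) > ly) return t1;
    if (t1 < t0) L = t1; else R_ = t1;
  }
  return t0;
}

static double draw_sigma(double sigma, double ssr, int n,
                         const PrecisionPrior &pp) {
  if (pp.type == 0) {
    double tau = R::rgamma(pp.shape + 0.5 * n, 1.0 / (pp.rate + 0.5 * ssr));
    return 1.0 / std::sqrt(tau);
  }
  double lambda = pp.shape - 0.5 * n;
  double t = slice_sample_logvar(2.0 * std::log(sigma), lambda, pp.rate, ssr);
  return std::exp(0.5 * t);
}

// ---- simplified model ------------------------------------------------------

// signal for the simplified rotated-frame model at all acquisitions
static void simplified_predict(const NumericVector &bd,
                               const NumericVector &rx, const NumericVector &ry,
                               double S0, double Ftot, double d_unused,
                               double f1, double p1, double p2,
                               std::vector<double> &mu) {
  double c1 = std::cos(p1), s1 = std::sin(p1);
  double c2 = std::cos(p2), s2 = std::sin(p2);
  int n = bd.size();
  for (int i = 0; i < n; ++i) {
    double a1 = rx[i] * c1 + ry[i] * s1;
    double a2 = rx[i] * c2 + ry[i] * s2;
    mu[i] = S0 * ((1.0 - Ftot) * std::exp(-bd[i]) +
                  f1 * std::exp(-bd[i] * a1 * a1) +
                  (Ftot - f1) * std::exp(-bd[i] * a2 * a2));
  }
}

// [[Rcpp::export(name = ".cpp_run_simplified")]]
List cpp_run_simplified(NumericVector y, NumericVector rx, NumericVector ry,
                        NumericVector bd, double S0, double Ftot,
                        NumericVector init, NumericVector eps,
                        int nIter, int adaptInterval, double targetAccept,
                        int precType, double priorShape, double priorRate,
                        int batchOffset) {
  int n = y.size();
  PrecisionPrior pp{precType, priorShape, priorRate};
  double f1 = init[0], p1 = init[1], p2 = init[2], sigma = init[3];
  std::vector<double> eps_(eps.begin(), eps.end());
  std::vector<double> mu(n), mu_prop(n), resid(n);

  NumericMatrix samples(nIter, 4);
  std::vector<long> accTot(3, 0);
  std::vector<int> accBatch(3, 0);

  simplified_predict(bd, rx, ry, S0, Ftot, 0.0, f1, p1, p2, mu);
  for (int i = 0; i < n; ++i) resid[i] = y[i] - mu[i];
  double ll = loglik_gauss(resid, sigma);

  for (int t = 0; t < nIter; ++t) {
    double cur[3] = {f1, p1, p2};
    for (int p = 0; p < 3; ++p) {
      double cand = cur[p] + eps_[p] * R::norm_rand();
      bool ok = (p == 0) ? (cand >= 0.0 && cand <= Ftot)
                         : (cand >= 0.0 && cand < M_PI);
      if (ok) {
        double nf1 = (p == 0) ? cand : cur[0];
        double np1 = (p == 1) ? cand : cur[1];
        double np2 = (p == 2) ? cand : cur[2];
        simplified_predict(bd, rx, ry, S0, Ftot, 0.0, nf1, np1, np2, mu_prop);
        double ssr = 0.0;
        for (int i = 0; i < n; ++i) {
          double r = y[i] - mu_prop[i];
          ssr += r * r;
        }
        double ll_new = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
                        ssr / (2.0 * sigma * sigma);
        if (std::log(R::unif_rand()) < ll_new - ll) {
          cur[p] = cand;
          ll = ll_new;
          std::swap(mu, mu_prop);
          accTot[p]++; accBatch[p]++;
        }
      }
    }
    f1 = cur[0]; p1 = cur[1]; p2 = cur[2];

    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - mu[i];
      ssr += r * r;
    }
    sigma = draw_sigma(sigma, ssr, n, pp);
    ll = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
         ssr / (2.0 * sigma * sigma);

    samples(t, 0) = f1; samples(t, 1) = p1; samples(t, 2) = p2;
    samples(t, 3) = sigma;

    if ((t + 1) % adaptInterval == 0) {
      int batch = batchOffset + (t + 1) / adaptInterval;
      double delta = adapt_delta(batch);
      for (int p = 0; p < 3; ++p) {
        double rate = (double)accBatch[p] / adaptInterval;
        if (rate > targetAccept) eps_[p] *= delta;
        else if (rate < targetAccept) eps_[p] /= delta;
        accBatch[p] = 0;
      }
    }
  }

  return List::create(
      _["samples"] = samples,
      _["eps"] = NumericVector(eps_.begin(), eps_.end()),
      _["accept"] = NumericVector::create((double)accTot[0] / nIter,
                                          (double)accTot[1] / nIter,
                                          (double)accTot[2] / nIter));
}

// ---- full nine-parameter model ---------------------------------------------

// full Ball-and-Stick prediction; angles are elevation/azimuth in radians
static void full_predict(const NumericVector &b, const NumericMatrix &U,
                         double S0, double d, double f1, double f2,
                         double th1, double ph1, double th2, double ph2,
                         std::vector<double> &mu) {
  double t1x = std::cos(th1) * std::cos(ph1), t1y = std::cos(th1) * std::sin(ph1),
         t1z = std::sin(th1);
  double t2x = std::cos(th2) * std::cos(ph2), t2y = std::cos(th2) * std::sin(ph2),
         t2z = std::sin(th2);
  int n = b.size();
  for (int i = 0; i < n; ++i) {
    double c1 = U(0, i) * t1x + U(1, i) * t1y + U(2, i) * t1z;
    double c2 = U(0, i) * t2x + U(1, i) * t2y + U(2, i) * t2z;
    double bd = b[i] * d;
    mu[i] = S0 * ((1.0 - f1 - f2) * std::exp(-bd) +
                  f1 * std::exp(-bd * c1 * c1) + f2 * std::exp(-bd * c2 * c2));
  }
}

// [[Rcpp::export(name = ".cpp_run_full")]]
List cpp_run_full(NumericVector y, NumericMatrix U, NumericVector b,
                  NumericVector init, NumericVector eps,
                  NumericVector lower, NumericVector upper,
                  int nIter, int adaptInterval, double targetAccept,
                  int precType, double priorShape, double priorRate,
                  int batchOffset) {
  // parameter order: S0, d, f1, f2, th1, ph1, th2, ph2 (then sigma by Gibbs)
  const int NP = 8;
  int n = y.size();
  PrecisionPrior pp{precType, priorShape, priorRate};
  std::vector<double> cur(init.begin(), init.begin() + NP);
  double sigma = init[NP];
  std::vector<double> eps_(eps.begin(), eps.end());
  std::vector<double> mu(n), mu_prop(n);

  NumericMatrix samples(nIter, NP + 1);
  std::vector<long> accTot(NP, 0);
  std::vector<int> accBatch(NP, 0);

  full_predict(b, U, cur[0], cur[1], cur[2], cur[3], cur[4], cur[5], cur[6],
               cur[7], mu);
  double ssr0 = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = y[i] - mu[i];
    ssr0 += r * r;
  }
  double ll = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
              ssr0 / (2.0 * sigma * sigma);

  for (int t = 0; t < nIter; ++t) {
    for (int p = 0; p < NP; ++p) {
      double cand = cur[p] + eps_[p] * R::norm_rand();
      bool ok = cand >= lower[p] && cand <= upper[p];
      if (ok && p == 2) ok = cand + cur[3] <= 1.0;   // f1 + f2 <= 1
      if (ok && p == 3) ok = cur[2] + cand <= 1.0;
      if (ok) {
        std::vector<double> prop(cur);
        prop[p] = cand;
        full_predict(b, U, prop[0], prop[1], prop[2], prop[3], prop[4],
                     prop[5], prop[6], prop[7], mu_prop);
        double ssr = 0.0;
        for (int i = 0; i < n; ++i) {
          double r = y[i] - mu_prop[i];
          ssr += r * r;
        }
        double ll_new = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
                        ssr / (2.0 * sigma * sigma);
        double lpr = 0.0;
        // area-uniform orientation prior: density proportional to
        // cos(elevation)
        if (p == 4 || p == 6)
          lpr = std::log(std::max(std::cos(cand), 1e-300)) -
                std::log(std::max(std::cos(cur[p]), 1e-300));
        if (std::log(R::unif_rand()) < ll_new - ll + lpr) {
          cur[p] = cand;
          ll = ll_new;
          std::swap(mu, mu_prop);
          accTot[p]++; accBatch[p]++;
        }
      }
    }

    double ssr = 0.0;
    for (int i = 0; i < n; ++i) {
      double r = y[i] - mu[i];
      ssr += r * r;
    }
    sigma = draw_sigma(sigma, ssr, n, pp);
    ll = -0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
         ssr / (2.0 * sigma * sigma);

    for (int p = 0; p < NP; ++p) samples(t, p) = cur[p];
    samples(t, NP) = sigma;

    if ((t + 1) % adaptInterval == 0) {
      int batch = batchOffset + (t + 1) / adaptInterval;
      double delta = adapt_delta(batch);
      for (int p = 0; p < NP; ++p) {
        double rate = (double)accBatch[p] / adaptInterval;
        if (rate > targetAccept) eps_[p] *= delta;
        else if (rate < targetAccept) eps_[p] /= delta;
        accBatch[p] = 0;
      }
    }
  }

  NumericVector acc(NP);
  for (int p = 0; p < NP; ++p) acc[p] = (double)accTot[p] / nIter;
  return List::create(_["samples"] = samples,
                      _["eps"] = NumericVector(eps_.begin(), eps_.end()),
                      _["accept"] = acc);
}
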