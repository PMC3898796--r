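// Fast ideal-observer likelihood kernels.
//
// These mirror the exported analytic R functions (log_familiarity_likelihoods,
// log_ooo_likelihoods, softmax_lapse) and are used inside the MCMC sampler and
// posterior-averaged prediction, where the same quantities are evaluated tens
// of thousands of times. A unit test asserts bitwise-level agreement (1e-10)
// between the two paths.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG_FLOOR = -745.0;
static const double LOG2PI = std::log(2.0 * M_PI);

// Per-component constants of the mixture with covariances inflated by
// `inflate * I`: quadratic-form coefficients of the inverse and the log
// normalizer (including the log weight). covs is K x 3:
// (var_x, cov_xy, var_y).
struct MixConsts {
  std::vector<double> mx, my, ia, ib, id, lognorm;
  int K;
  MixConsts(const arma::vec& logw, const arma::mat& mu, const arma::mat& covs,
            double inflate) {
    K = mu.n_rows;
    if (K > 16) Rcpp::stop("at most 16 mixture components supported");
    mx.resize(K); my.resize(K);
    ia.resize(K); ib.resize(K); id.resize(K); lognorm.resize(K);
    for (int k = 0; k < K; ++k) {
      const double a = covs(k, 0) + inflate;
      const double b = covs(k, 1);
      const double d = covs(k, 2) + inflate;
      const double det = a * d - b * b;
      mx[k] = mu(k, 0);
      my[k] = mu(k, 1);
      ia[k] = d / det;
      ib[k] = b / det;
      id[k] = a / det;
      lognorm[k] = logw(k) - LOG2PI - 0.5 * std::log(det);
    }
  }
  inline double logpdf(double x, double y) const {
    double m = -arma::datum::inf;
    double lp[16];
    for (int k = 0; k < K; ++k) {
      const double dx = x - mx[k];
      const double dy = y - my[k];
      const double q =
          ia[k] * dx * dx - 2.0 * ib[k] * dx * dy + id[k] * dy * dy;
      lp[k] = lognorm[k] - 0.5 * q;
      if (lp[k] > m) m = lp[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += std::exp(lp[k] - m);
    return m + std::log(s);
  }
};

// Row-wise softmax with temperature and lapse, in place on logv.
static inline void softmax_lapse_row(arma::rowvec& logv, double temperature,
                                     double lapse) {
  const int n = logv.n_elem;
  logv *= temperature;
  const double m = logv.max();
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    logv(j) = std::exp(logv(j) - m);
    s += logv(j);
  }
  for (int j = 0; j < n; ++j) {
    logv(j) = (1.0 - lapse) * logv(j) / s + lapse / n;
  }
}

static arma::mat resp_prob_fam(const arma::mat& S, const arma::vec& logw,
                               const arma::mat& mu, const arma::mat& covs,
                               double sigma_p, double temperature,
                               double lapse, double log_u) {
  const int n = S.n_rows;
  const double s2 = sigma_p * sigma_p;
  const MixConsts mc(logw, mu, covs, s2);
  arma::mat out(n, 2);
  for (int i = 0; i < n; ++i) {
    arma::rowvec logv(2);
    logv(0) = log_u + mc.logpdf(S(i, 0), S(i, 1));
    logv(1) = log_u + mc.logpdf(S(i, 2), S(i, 3));
    logv(0) = std::max(logv(0), LOG_FLOOR);
    logv(1) = std::max(logv(1), LOG_FLOOR);
    softmax_lapse_row(logv, temperature, lapse);
    out.row(i) = logv;
  }
  return out;
}

static arma::mat resp_prob_ooo(const arma::mat& S, const arma::vec& logw,
                               const arma::mat& mu, const arma::mat& covs,
                               double sigma_p, double temperature,
                               double lapse) {
  const int n = S.n_rows;
  const double s2 = sigma_p * sigma_p;
  const MixConsts mc_single(logw, mu, covs, s2);
  const MixConsts mc_pair(logw, mu, covs, s2 / 2.0);
  const double lpair_const = -LOG2PI - std::log(2.0 * s2);
  const int pi_[3] = {1, 0, 0}; // pair indices (0-based) per hypothesis
  const int pj_[3] = {2, 2, 1};
  arma::mat out(n, 3);
  for (int i = 0; i < n; ++i) {
    double sx[3], sy[3], lsingle[3];
    for (int a = 0; a < 3; ++a) {
      sx[a] = S(i, 2 * a);
      sy[a] = S(i, 2 * a + 1);
      lsingle[a] = mc_single.logpdf(sx[a], sy[a]);
    }
    arma::rowvec logv(3);
    for (int k = 0; k < 3; ++k) {
      const int a = pi_[k], b = pj_[k];
      const double dx = sx[a] - sx[b];
      const double dy = sy[a] - sy[b];
      const double lpair_noise =
          lpair_const - (dx * dx + dy * dy) / (4.0 * s2);
      const double lpair_prior =
          mc_pair.logpdf((sx[a] + sx[b]) / 2.0, (sy[a] + sy[b]) / 2.0);
      logv(k) = std::max(lpair_noise + lpair_prior + lsingle[k], LOG_FLOOR);
    }
    softmax_lapse_row(logv, temperature, lapse);
    out.row(i) = logv;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_response_prob(const arma::mat& S, int task,
                            const arma::vec& w, const arma::mat& mu,
                            const arma::mat& covs, double sigma_p,
                            double temperature, double lapse, double log_u) {
  arma::vec logw = arma::log(w);
  if (task == 2) {
    return resp_prob_fam(S, logw, mu, covs, sigma_p, temperature, lapse,
                         log_u);
  }
  return resp_prob_ooo(S, logw, mu, covs, sigma_p, temperature, lapse);
}

// Total log-likelihood of the observed 0-based choices.
// [[Rcpp::export]]
double cpp_loglik(const arma::mat& S, const arma::ivec& choice, int task,
                  const arma::vec& w, const arma::mat& mu,
                  const arma::mat& covs, double sigma_p, double temperature,
                  double lapse, double log_u) {
  arma::mat p = cpp_response_prob(S, task, w, mu, covs, sigma_p, temperature,
                                  lapse, log_u);
  double ll = 0.0;
  for (arma::uword i = 0; i < p.n_rows; ++i) {
    ll += std::log(p(i, choice(i)));
  }
  return ll;
}
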