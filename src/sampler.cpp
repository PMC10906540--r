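// Adaptive random-walk Metropolis-within-Gibbs sampler for the arm-based
// binomial-logit network meta-analysis model.
//
// Likelihood: r_ik ~ Binomial(n_ik, p_ik)
//   fixed effects:  logit(p_ik) = mu_i + x_ik' theta
//   random effects: logit(p_ik) = mu_i + delta_ik,
//                   delta_i ~ MVN(X_i theta, tau^2 * (0.5 I + 0.5 J))
// where x_ik is the arm's row of the effect design matrix (zero for the
// study's baseline arm). Under the consistency parametrisation theta holds
// the basic parameters d_k (log-OR vs reference); under the unrelated-mean-
// effects parametrisation theta holds one free effect per observed design
// pair. The multi-arm covariance (correlation 0.5 between effects sharing a
// study) is the standard homogeneous-variance structure; for two-arm studies
// it reduces to independent N(d, tau^2) effects.
//
// Priors: theta_j ~ N(0, sd_d^2), mu_i ~ N(0, sd_mu^2), tau ~ U(0, upper).
//
// Each scalar parameter is updated by a random-walk Metropolis step whose
// proposal scale is tuned during burn-in by Robbins-Monro adaptation toward
// a 0.44 acceptance rate, then frozen. Chain c uses an independent
// mt19937_64 stream seeded with seed + c, so runs are bit-reproducible.

#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

// log(1 + exp(x)) without overflow
inline double log1pexp(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}

struct NmaData {
  std::vector<int> arm_study;       // 0-based
  std::vector<double> n, r;
  std::vector<std::vector<double>> X;  // A x P
  std::vector<int> delta_index;     // per arm: index into delta, -1 = baseline
  std::vector<std::vector<int>> study_arms; // non-baseline arm ids per study
  int A = 0, S = 0, P = 0, n_delta = 0;
  bool random_effects = false;
  double sd_d = 100.0, sd_mu = 100.0, tau_upper = 2.0;
};

struct NmaState {
  std::vector<double> theta, mu, delta;
  double tau = 0.1;
};

double log_posterior(const NmaData& d, const NmaState& s) {
  double lp = 0.0;
  // binomial likelihood (constants dropped)
  for (int a = 0; a < d.A; ++a) {
    double eta = s.mu[d.arm_study[a]];
    if (d.random_effects) {
      if (d.delta_index[a] >= 0) eta += s.delta[d.delta_index[a]];
    } else {
      const std::vector<double>& x = d.X[a];
      for (int j = 0; j < d.P; ++j) if (x[j] != 0.0) eta += x[j] * s.theta[j];
    }
    lp += d.r[a] * eta - d.n[a] * log1pexp(eta);
  }
  // priors on theta and mu
  for (int j = 0; j < d.P; ++j) {
    double z = s.theta[j] / d.sd_d;
    lp -= 0.5 * z * z;
  }
  for (int i = 0; i < d.S; ++i) {
    double z = s.mu[i] / d.sd_mu;
    lp -= 0.5 * z * z;
  }
  if (d.random_effects) {
    if (s.tau <= 0.0 || s.tau > d.tau_upper) return -INFINITY;
    double tau2 = s.tau * s.tau;
    // per-study MVN(X theta, tau^2 (0.5 I + 0.5 J)):
    //   Sigma^-1 = (1/tau^2) (2 I - 2/(m+1) J)
    //   log|Sigma| = 2 m log tau + (m-1) log 0.5 + log(0.5 (m+1))
    for (int i = 0; i < d.S; ++i) {
      const std::vector<int>& arms = d.study_arms[i];
      int m = (int)arms.size();
      if (m == 0) continue;
      double ss = 0.0, sum = 0.0;
      for (int a : arms) {
        double mean = 0.0;
        const std::vector<double>& x = d.X[a];
        for (int j = 0; j < d.P; ++j) if (x[j] != 0.0) mean += x[j] * s.theta[j];
        double e = s.delta[d.delta_index[a]] - mean;
        ss += e * e; sum += e;
      }
      double quad = (2.0 * ss - 2.0 / (m + 1.0) * sum * sum) / tau2;
      double logdet = 2.0 * m * std::log(s.tau) + (m - 1) * std::log(0.5)
                      + std::log(0.5 * (m + 1));
      lp += -0.5 * quad - 0.5 * logdet;
    }
  }
  return lp;
}

NmaData build_data(const IntegerVector& arm_study, const NumericVector& n,
                   const NumericVector& r, const NumericMatrix& X,
                   int n_studies, bool random_effects, double sd_d,
                   double sd_mu, double tau_upper) {
  NmaData d;
  d.A = arm_study.size();
  d.S = n_studies;
  d.P = X.ncol();
  d.random_effects = random_effects;
  d.sd_d = sd_d; d.sd_mu = sd_mu; d.tau_upper = tau_upper;
  d.arm_study.assign(arm_study.begin(), arm_study.end());
  d.n.assign(n.begin(), n.end());
  d.r.assign(r.begin(), r.end());
  d.X.assign(d.A, std::vector<double>(d.P, 0.0));
  d.delta_index.assign(d.A, -1);
  d.study_arms.assign(d.S, std::vector<int>());
  for (int a = 0; a < d.A; ++a) {
    bool any = false;
    for (int j = 0; j < d.P; ++j) {
      d.X[a][j] = X(a, j);
      if (X(a, j) != 0.0) any = true;
    }
    if (any) {  // non-baseline arm carries a trial-specific effect
      d.delta_index[a] = d.n_delta++;
      d.study_arms[d.arm_study[a]].push_back(a);
    }
  }
  return d;
}

} // namespace

// [[Rcpp::export]]
List nma_mcmc(IntegerVector arm_study, NumericVector n, NumericVector r,
              NumericMatrix X, int n_studies, bool random_effects,
              double sd_d, double sd_mu, double tau_upper,
              int n_chains, int burn_in, int iterations, int seed,
              NumericVector mu_init) {
  NmaData dat = build_data(arm_study, n, r, X, n_studies, random_effects,
                           sd_d, sd_mu, tau_upper);
  const int P = dat.P, S = dat.S, D = dat.n_delta;
  // scalar updates for every parameter, plus one joint move per effect
  // parameter along the posterior's dominant ridge: for random effects it
  // shifts theta_j together with the deltas centred on it (without this
  // the theta/delta coupling mixes arbitrarily slowly as tau -> 0); for
  // fixed effects it shifts theta_j while compensating the baselines of
  // the studies it loads on (theta_j and mu_i are strongly anticorrelated
  // within a study)
  const int n_scalar = P + S + (random_effects ? D + 1 : 0);
  const int n_par = n_scalar + P;

  // studies loading on each effect parameter (for the FE joint move)
  std::vector<std::vector<int>> param_studies(P);
  for (int j = 0; j < P; ++j) {
    std::vector<bool> seen(n_studies, false);
    for (int a = 0; a < dat.A; ++a)
      if (dat.X[a][j] != 0.0 && !seen[dat.arm_study[a]]) {
        seen[dat.arm_study[a]] = true;
        param_studies[j].push_back(dat.arm_study[a]);
      }
  }
  const int total = n_chains * iterations;

  NumericMatrix theta_draws(total, P), mu_draws(total, S);
  NumericMatrix delta_draws(random_effects ? total : 0,
                            random_effects ? D : 0);
  NumericVector tau_draws(random_effects ? total : 0);
  IntegerVector chain_ids(total);
  NumericVector accept(n_par * n_chains);

  for (int c = 0; c < n_chains; ++c) {
    std::mt19937_64 rng(static_cast<unsigned long long>(seed) + c);
    std::normal_distribution<double> rnorm01(0.0, 1.0);
    std::uniform_real_distribution<double> runif01(0.0, 1.0);

    NmaState st;
    st.theta.assign(P, 0.0);
    st.mu.assign(S, 0.0);
    // overdispersed starts around the empirical baseline logits
    for (int j = 0; j < P; ++j) st.theta[j] = 0.5 * rnorm01(rng);
    for (int i = 0; i < S; ++i) st.mu[i] = mu_init[i] + 0.5 * rnorm01(rng);
    if (random_effects) {
      st.delta.assign(D, 0.0);
      for (int a = 0; a < dat.A; ++a)
        if (dat.delta_index[a] >= 0) {
          double mean = 0.0;
          for (int j = 0; j < P; ++j) mean += dat.X[a][j] * st.theta[j];
          st.delta[dat.delta_index[a]] = mean + 0.1 * rnorm01(rng);
        }
      st.tau = tau_upper * (0.05 + 0.45 * runif01(rng));
    }

    std::vector<double> lsd(n_par, std::log(0.5));  // log proposal sd
    if (random_effects) lsd[P + S + D] = std::log(0.1 * tau_upper);
    std::vector<long> acc(n_par, 0), att(n_par, 0);
    double lp = log_posterior(dat, st);
    std::vector<double> delta_old;

    for (int it = 0; it < burn_in + iterations; ++it) {
      for (int p = 0; p < n_par; ++p) {
        double* target = nullptr;
        int joint_j = -1;
        double eps = std::exp(lsd[p]) * rnorm01(rng);
        double old = 0.0;
        if (p < P) target = &st.theta[p];
        else if (p < P + S) target = &st.mu[p - P];
        else if (random_effects && p < P + S + D)
          target = &st.delta[p - P - S];
        else if (random_effects && p == P + S + D) target = &st.tau;
        else joint_j = p - n_scalar;
        if (target) {
          old = *target;
          *target = old + eps;
        } else if (random_effects) {
          // joint move: theta_j and every delta whose prior mean loads on it
          delta_old = st.delta;
          st.theta[joint_j] += eps;
          for (int a = 0; a < dat.A; ++a)
            if (dat.delta_index[a] >= 0 && dat.X[a][joint_j] != 0.0)
              st.delta[dat.delta_index[a]] += dat.X[a][joint_j] * eps;
        } else {
          // joint move: theta_j up, its studies' baselines down
          st.theta[joint_j] += eps;
          for (int i : param_studies[joint_j]) st.mu[i] -= eps;
        }
        double lp_new = log_posterior(dat, st);
        bool ok = std::isfinite(lp_new) &&
                  std::log(runif01(rng)) < lp_new - lp;
        if (ok) {
          lp = lp_new; ++acc[p];
        } else if (target) {
          *target = old;
        } else if (random_effects) {
          st.theta[joint_j] -= eps;
          st.delta = delta_old;
        } else {
          st.theta[joint_j] -= eps;
          for (int i : param_studies[joint_j]) st.mu[i] += eps;
        }
        ++att[p];
        if (it < burn_in) {  // Robbins-Monro toward 0.44 acceptance
          double gamma = std::min(0.25, 5.0 / std::sqrt(it + 1.0));
          lsd[p] += gamma * ((ok ? 1.0 : 0.0) - 0.44);
          lsd[p] = std::min(5.0, std::max(-8.0, lsd[p]));
        }
      }
      if (it >= burn_in) {
        int row = c * iterations + (it - burn_in);
        for (int j = 0; j < P; ++j) theta_draws(row, j) = st.theta[j];
        for (int i = 0; i < S; ++i) mu_draws(row, i) = st.mu[i];
        if (random_effects) {
          for (int k = 0; k < D; ++k) delta_draws(row, k) = st.delta[k];
          tau_draws[row] = st.tau;
        }
        chain_ids[row] = c + 1;
      }
    }
    for (int p = 0; p < n_par; ++p)
      accept[c * n_par + p] = att[p] ? (double)acc[p] / att[p] : 0.0;
  }

  return List::create(
    _["theta"] = theta_draws, _["mu"] = mu_draws,
    _["delta"] = delta_draws, _["tau"] = tau_draws,
    _["chain"] = chain_ids, _["accept"] = accept);
}

// Unnormalised joint log density used by the sampler, exposed so the R-level
// reference density can be checked against it (they must agree up to an
// additive constant).
// [[Rcpp::export]]
double nma_logpost_cpp(NumericVector theta, NumericVector mu,
                       NumericVector delta, double tau,
                       IntegerVector arm_study, NumericVector n,
                       NumericVector r, NumericMatrix X, int n_studies,
                       bool random_effects, double sd_d, double sd_mu,
                       double tau_upper) {
  NmaData dat = build_data(arm_study, n, r, X, n_studies, random_effects,
                           sd_d, sd_mu, tau_upper);
  NmaState st;
  st.theta.assign(theta.begin(), theta.end());
  st.mu.assign(mu.begin(), mu.end());
  if (random_effects) {
    st.delta.assign(delta.begin(), delta.end());
    st.tau = tau;
  }
  return log_posterior(dat, st);
}
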