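#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Model variant codes: 0 = single learning rate, 1 = dual (alpha+ / alpha-),
// 2 = variable (alpha tracks recent |prediction error| at rate eta).
// Parameter column order inside `vals` (K cells x P params):
//   single:   alpha, beta
//   dual:     alpha_pos, alpha_neg, beta
//   variable: alpha, eta, beta

namespace {

// log softmax probability of the chosen machine: -log(1 + exp(-d)) with
// d = beta * (q_chosen - q_other); |d| <= 10 under the parameter bounds,
// so the single exponential is safe
inline double log_choice_prob(double beta, double qa, double qb, int choice) {
  double d = choice == 0 ? beta * (qa - qb) : beta * (qb - qa);
  return -std::log1p(std::exp(-d));
}

struct AgentState {
  double Q[2][2];
  double acur[2];
  bool ainit[2];
  int curblock;
  void reset_block(int b) {
    Q[0][0] = Q[0][1] = Q[1][0] = Q[1][1] = 0.0;
    ainit[0] = ainit[1] = false;
    curblock = b;
  }
};

// one observed trial: accumulate log-lik of the observed choice and update
// state; missing choices (choice < 0) contribute nothing and leave Q alone
inline double observe_trial(AgentState& st, int e, int k, int choice, int reward,
                            const double* vals, int K, int lr_kind) {
  double beta = vals[k + K * (lr_kind == 0 ? 1 : 2)];
  double lp = log_choice_prob(beta, st.Q[e][0], st.Q[e][1], choice);
  double a;
  if (lr_kind == 0) {
    a = vals[k];
  } else if (lr_kind == 1) {
    a = (reward == 1) ? vals[k] : vals[k + K];
  } else {
    if (!st.ainit[e]) { st.acur[e] = vals[k]; st.ainit[e] = true; }
    a = st.acur[e];
  }
  double q = st.Q[e][choice];
  double pe = (double)reward - q;
  st.Q[e][choice] = q + a * pe;
  if (lr_kind == 2) {
    double eta = vals[k + K];
    st.acur[e] = eta * std::fabs(pe) + (1.0 - eta) * st.acur[e];
  }
  return lp;
}

// summed log-likelihood of one participant's trial sequence; optionally
// writes per-trial values into pw (NA_REAL where choice is missing)
double ppt_loglik(const int* env, const int* block, const int* cell,
                  const int* choice, const int* reward, int T,
                  const double* vals, int K, int lr_kind, double* pw) {
  AgentState st;
  st.curblock = INT_MIN;
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    if (block[t] != st.curblock) st.reset_block(block[t]);
    if (choice[t] < 0) { if (pw) pw[t] = NA_REAL; continue; }
    double lp = observe_trial(st, env[t], cell[t], choice[t], reward[t],
                              vals, K, lr_kind);
    if (pw) pw[t] = lp;
    ll += lp;
  }
  return ll;
}

// simulate choices/rewards against a winning-machine schedule (R RNG)
void ppt_simulate(const int* env, const int* block, const int* cell,
                  const int* winning, int T, const double* vals, int K,
                  int lr_kind, int* choice_out, int* reward_out) {
  AgentState st;
  st.curblock = INT_MIN;
  for (int t = 0; t < T; ++t) {
    if (block[t] != st.curblock) st.reset_block(block[t]);
    int e = env[t], k = cell[t];
    double beta = vals[k + K * (lr_kind == 0 ? 1 : 2)];
    double p1 = 1.0 / (1.0 + std::exp(beta * (st.Q[e][0] - st.Q[e][1])));
    int c = (unif_rand() < p1) ? 1 : 0;
    int r = (c == winning[t]) ? 1 : 0;
    choice_out[t] = c;
    reward_out[t] = r;
    observe_trial(st, e, k, c, r, vals, K, lr_kind);
  }
}

inline double Phi(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// half-Cauchy(0, 5) log-density on sigma > 0
inline double lp_half_cauchy(double sigma) {
  const double scale = 5.0;
  return std::log(2.0 / (M_PI * scale)) - std::log1p((sigma / scale) * (sigma / scale));
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik(IntegerVector env, IntegerVector block,
                                   IntegerVector cell, IntegerVector choice,
                                   IntegerVector reward, NumericMatrix vals,
                                   int lr_kind) {
  int T = env.size();
  NumericVector pw(T);
  ppt_loglik(env.begin(), block.begin(), cell.begin(), choice.begin(),
             reward.begin(), T, vals.begin(), vals.nrow(), lr_kind, pw.begin());
  return pw;
}

// [[Rcpp::export]]
List cpp_simulate(IntegerVector env, IntegerVector block, IntegerVector cell,
                  IntegerVector winning, NumericMatrix vals, int lr_kind) {
  int T = env.size();
  IntegerVector choice(T), reward(T);
  RNGScope scope;
  ppt_simulate(env.begin(), block.begin(), cell.begin(), winning.begin(), T,
               vals.begin(), vals.nrow(), lr_kind, choice.begin(), reward.begin());
  return List::create(_["choice"] = choice, _["reward"] = reward);
}

// ---------------------------------------------------------------------------
// Hierarchical model machinery.
//
// Parameter rows r = k + K * p for env-cell k (0..K-1) and model parameter p
// (0..P-1). Each row has bounds [lower[r], upper[r]], a group mean on the raw
// (probit) scale, a group SD, and one standard-normal deviate z per
// participant. Bounded individual value:
//   lower + (upper - lower) * Phi(mu_raw + sigma * z).
// Priors: mu_raw ~ N(0,1) (equivalent to a uniform prior on the bounded
// group mean through the probit change of variables), sigma ~ half-Cauchy(0,5),
// z ~ N(0,1).
// ---------------------------------------------------------------------------

namespace {

struct HierData {
  const int *env, *block, *cell, *choice, *reward;
  const int* offs; // participant start offsets, length N+1 (0-based)
  int N, K, P, lr_kind;
  const double *lower, *upper;
};

// resolve the K x P bounded value matrix for participant i
void resolve_vals(const HierData& d, const double* mu, const double* sigma,
                  const double* z /*N x R, column-major [i + N*r]*/, int i,
                  double* vals /*K x P*/) {
  int R = d.K * d.P;
  for (int r = 0; r < R; ++r) {
    double raw = mu[r] + sigma[r] * z[i + d.N * r];
    vals[r] = d.lower[r] + (d.upper[r] - d.lower[r]) * Phi(raw);
  }
}

double lik_i(const HierData& d, int i, const double* vals, double* pw = nullptr) {
  int s = d.offs[i], T = d.offs[i + 1] - s;
  return ppt_loglik(d.env + s, d.block + s, d.cell + s, d.choice + s,
                    d.reward + s, T, vals, d.K, d.lr_kind,
                    pw ? pw + s : nullptr);
}

HierData unpack(IntegerVector env, IntegerVector block, IntegerVector cell,
                IntegerVector choice, IntegerVector reward, IntegerVector offs,
                NumericVector lower, NumericVector upper, int K, int P,
                int lr_kind) {
  HierData d;
  d.env = env.begin(); d.block = block.begin(); d.cell = cell.begin();
  d.choice = choice.begin(); d.reward = reward.begin(); d.offs = offs.begin();
  d.N = offs.size() - 1; d.K = K; d.P = P; d.lr_kind = lr_kind;
  d.lower = lower.begin(); d.upper = upper.begin();
  return d;
}

} // namespace

// joint log-density (priors + likelihood) at one point, sigma on natural scale
// [[Rcpp::export]]
double cpp_joint_logdensity(IntegerVector env, IntegerVector block,
                            IntegerVector cell, IntegerVector choice,
                            IntegerVector reward, IntegerVector offs,
                            NumericVector lower, NumericVector upper,
                            int K, int P, int lr_kind,
                            NumericVector mu, NumericVector sigma,
                            NumericMatrix z) {
  HierData d = unpack(env, block, cell, choice, reward, offs, lower, upper,
                      K, P, lr_kind);
  int R = K * P;
  double lp = 0.0;
  for (int r = 0; r < R; ++r) {
    lp += R::dnorm(mu[r], 0.0, 1.0, 1);
    lp += lp_half_cauchy(sigma[r]);
    for (int i = 0; i < d.N; ++i) lp += R::dnorm(z(i, r), 0.0, 1.0, 1);
  }
  std::vector<double> vals(R);
  for (int i = 0; i < d.N; ++i) {
    resolve_vals(d, mu.begin(), sigma.begin(), z.begin(), i, vals.data());
    lp += lik_i(d, i, vals.data());
  }
  return lp;
}

// One chain of adaptive Metropolis-within-Gibbs over (mu_raw, log sigma, z).
// Scalar random-walk proposals, scales adapted toward 0.44 acceptance in
// batches of 50 during burn-in only. Uses the R RNG (seed via set.seed()).
// [[Rcpp::export]]
List cpp_hier_sample(IntegerVector env, IntegerVector block, IntegerVector cell,
                     IntegerVector choice, IntegerVector reward,
                     IntegerVector offs, NumericVector lower,
                     NumericVector upper, int K, int P, int lr_kind,
                     int n_iter, int n_burn) {
  HierData d = unpack(env, block, cell, choice, reward, offs, lower, upper,
                      K, P, lr_kind);
  int R = K * P, N = d.N;
  int n_keep = n_iter - n_burn;
  RNGScope scope;

  std::vector<double> mu(R), ls(R), sigma(R), z(N * R);
  for (int r = 0; r < R; ++r) {
    mu[r] = 0.2 * norm_rand();
    ls[r] = std::log(0.5) + 0.2 * norm_rand();
    sigma[r] = std::exp(ls[r]);
    for (int i = 0; i < N; ++i) z[i + N * r] = 0.2 * norm_rand();
  }

  std::vector<double> ll(N), vals(R);
  for (int i = 0; i < N; ++i) {
    resolve_vals(d, mu.data(), sigma.data(), z.data(), i, vals.data());
    ll[i] = lik_i(d, i, vals.data());
  }

  // proposal scales and batch acceptance counters
  std::vector<double> s_mu(R, 0.2), s_ls(R, 0.3), s_z(N * R, 0.5);
  std::vector<double> s_tr(R, 0.3), s_sc(R, 0.3);
  std::vector<int> a_mu(R, 0), a_z(N * R, 0), a_tr(R, 0), a_sc(R, 0);
  double acc_tr = 0, try_tr = 0;
  int batch = 0, batch_len = 50;

  NumericMatrix out_mu(n_keep, R), out_ls(n_keep, R), out_z(n_keep, N * R);
  std::vector<double> ll_prop(N), vals_prop(R);
  double acc_group = 0, try_group = 0, acc_ind = 0, try_ind = 0;

  for (int it = 0; it < n_iter; ++it) {
    // ---- group-level parameters: joint (mu, log sigma) proposal per cell ----
    for (int r = 0; r < R; ++r) {
      double mu_new = mu[r] + s_mu[r] * norm_rand();
      double ls_new = ls[r] + s_ls[r] * norm_rand();
      double sig_new = std::exp(ls_new);
      // N(0,1) prior on mu_raw; half-Cauchy on sigma plus log-scale Jacobian
      double lp_delta = -0.5 * (mu_new * mu_new - mu[r] * mu[r])
                      + lp_half_cauchy(sig_new) + ls_new
                      - (lp_half_cauchy(sigma[r]) + ls[r]);
      std::vector<double> mu_v(mu), sig_v(sigma);
      mu_v[r] = mu_new; sig_v[r] = sig_new;
      double dll = 0.0;
      for (int i = 0; i < N; ++i) {
        resolve_vals(d, mu_v.data(), sig_v.data(), z.data(), i, vals_prop.data());
        ll_prop[i] = lik_i(d, i, vals_prop.data());
        dll += ll_prop[i] - ll[i];
      }
      try_group += 1;
      if (std::log(unif_rand()) < dll + lp_delta) {
        mu[r] = mu_new;
        ls[r] = ls_new;
        sigma[r] = sig_new;
        a_mu[r]++;
        ll = ll_prop;
        acc_group += 1;
      }
    }
    // ---- individual deviates ----
    for (int i = 0; i < N; ++i) {
      for (int r = 0; r < R; ++r) {
        double cur = z[i + N * r];
        double prop = cur + s_z[i + N * r] * norm_rand();
        z[i + N * r] = prop;
        resolve_vals(d, mu.data(), sigma.data(), z.data(), i, vals_prop.data());
        double ll_new = lik_i(d, i, vals_prop.data());
        double lp_delta = -0.5 * (prop * prop - cur * cur) + ll_new - ll[i];
        try_ind += 1;
        if (std::log(unif_rand()) < lp_delta) {
          ll[i] = ll_new;
          a_z[i + N * r]++;
          acc_ind += 1;
        } else {
          z[i + N * r] = cur;
        }
      }
    }
    // ---- ancillarity-sufficiency interweaving moves ----
    // translation: mu -> mu + delta, z_i -> z_i - delta/sigma leaves every
    // bounded individual parameter (hence the likelihood) unchanged; only
    // the prior ratio enters. Scale: sigma -> c*sigma, z -> z/c likewise,
    // with the log-scale change of variables. Both repair the strong
    // posterior coupling between group and individual levels at no
    // likelihood cost. They are iterated several times per sweep: each
    // repetition is nearly free compared with one likelihood evaluation.
    for (int asis_rep = 0; asis_rep < 10; ++asis_rep)
    for (int r = 0; r < R; ++r) {
      double delta = s_tr[r] * norm_rand();
      double lp = -0.5 * ((mu[r] + delta) * (mu[r] + delta) - mu[r] * mu[r]);
      double shift = delta / sigma[r];
      for (int i = 0; i < N; ++i) {
        double zo = z[i + N * r], zn = zo - shift;
        lp += -0.5 * (zn * zn - zo * zo);
      }
      try_tr += 1;
      if (std::log(unif_rand()) < lp) {
        mu[r] += delta;
        for (int i = 0; i < N; ++i) z[i + N * r] -= shift;
        a_tr[r]++;
        acc_tr += 1;
      }
      double eps = s_sc[r] * norm_rand();
      double ls_new = ls[r] + eps, sig_new = std::exp(ls_new);
      double c = std::exp(-eps);
      lp = lp_half_cauchy(sig_new) + ls_new - (lp_half_cauchy(sigma[r]) + ls[r])
         - (double)N * eps; // Jacobian of z -> z * exp(-eps)
      for (int i = 0; i < N; ++i) {
        double zo = z[i + N * r], zn = zo * c;
        lp += -0.5 * (zn * zn - zo * zo);
      }
      try_tr += 1;
      if (std::log(unif_rand()) < lp) {
        ls[r] = ls_new;
        sigma[r] = sig_new;
        for (int i = 0; i < N; ++i) z[i + N * r] *= c;
        a_sc[r]++;
        acc_tr += 1;
      }
    }
    // ---- adaptation (burn-in only) ----
    if (it < n_burn && (it + 1) % batch_len == 0) {
      batch++;
      double delta = std::min(0.1, 1.0 / std::sqrt((double)batch));
      for (int r = 0; r < R; ++r) {
        // 2-d joint proposal: aim for ~0.3 acceptance
        double f = std::exp(((double)a_mu[r] / batch_len > 0.30 ? 1 : -1) * delta);
        s_mu[r] *= f;
        s_ls[r] *= f;
        a_mu[r] = 0;
      }
      for (int j = 0; j < N * R; ++j) {
        s_z[j] *= std::exp(((double)a_z[j] / batch_len > 0.44 ? 1 : -1) * delta);
        a_z[j] = 0;
      }
      for (int r = 0; r < R; ++r) {
        s_tr[r] *= std::exp(((double)a_tr[r] / batch_len > 0.44 ? 1 : -1) * delta);
        s_sc[r] *= std::exp(((double)a_sc[r] / batch_len > 0.44 ? 1 : -1) * delta);
        a_tr[r] = a_sc[r] = 0;
      }
    }
    if (it >= n_burn) {
      int row = it - n_burn;
      for (int r = 0; r < R; ++r) {
        out_mu(row, r) = mu[r];
        out_ls(row, r) = ls[r];
      }
      for (int j = 0; j < N * R; ++j) out_z(row, j) = z[j];
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["mu_raw"] = out_mu, _["log_sigma"] = out_ls,
                      _["z"] = out_z,
                      _["accept_group"] = acc_group / try_group,
                      _["accept_individual"] = acc_ind / try_ind);
}

// per-draw pointwise log-likelihoods of all observed choices
// (columns ordered by participant then trial, missing-choice trials skipped)
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_matrix(IntegerVector env, IntegerVector block,
                                   IntegerVector cell, IntegerVector choice,
                                   IntegerVector reward, IntegerVector offs,
                                   NumericVector lower, NumericVector upper,
                                   int K, int P, int lr_kind,
                                   NumericMatrix mu_draws,
                                   NumericMatrix ls_draws,
                                   NumericMatrix z_draws) {
  HierData d = unpack(env, block, cell, choice, reward, offs, lower, upper,
                      K, P, lr_kind);
  int S = mu_draws.nrow(), R = K * P, N = d.N;
  int Ttot = env.size();
  int n_obs = 0;
  for (int t = 0; t < Ttot; ++t) if (choice[t] >= 0) n_obs++;
  NumericMatrix out(S, n_obs);
  std::vector<double> vals(R), pw(Ttot), mu(R), sigma(R), zz(N * R);
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < R; ++r) {
      mu[r] = mu_draws(s, r);
      sigma[r] = std::exp(ls_draws(s, r));
    }
    for (int j = 0; j < N * R; ++j) zz[j] = z_draws(s, j);
    for (int i = 0; i < N; ++i) {
      resolve_vals(d, mu.data(), sigma.data(), zz.data(), i, vals.data());
      lik_i(d, i, vals.data(), pw.data());
    }
    int c = 0;
    for (int t = 0; t < Ttot; ++t) if (choice[t] >= 0) out(s, c++) = pw[t];
    if (s % 100 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// posterior predictive simulation: for every draw, simulate each participant's
// choices against their realized winning-machine schedule and accumulate the
// reward rate per Q-environment (env index 0/1); returns N x 2 matrices of
// draw-averaged simulated reward rates and the within-env trial counts
// [[Rcpp::export]]
List cpp_ppc(IntegerVector env, IntegerVector block, IntegerVector cell,
             IntegerVector winning, IntegerVector offs, NumericVector lower,
             NumericVector upper, int K, int P, int lr_kind,
             NumericMatrix mu_draws, NumericMatrix ls_draws,
             NumericMatrix z_draws) {
  HierData d = unpack(env, block, cell, winning, winning, offs, lower, upper,
                      K, P, lr_kind);
  int S = mu_draws.nrow(), R = K * P, N = d.N;
  RNGScope scope;
  NumericMatrix rate(N, 2);
  NumericMatrix draw_rate(S, N); // per-draw overall reward rate
  IntegerMatrix count(N, 2);
  std::vector<double> vals(R), mu(R), sigma(R), zz(N * R);
  int Tmax = 0;
  for (int i = 0; i < N; ++i) Tmax = std::max(Tmax, offs[i + 1] - offs[i]);
  std::vector<int> ch(Tmax), rw(Tmax);
  for (int i = 0; i < N; ++i)
    for (int t = offs[i]; t < offs[i + 1]; ++t) count(i, env[t])++;
  for (int s = 0; s < S; ++s) {
    for (int r = 0; r < R; ++r) {
      mu[r] = mu_draws(s, r);
      sigma[r] = std::exp(ls_draws(s, r));
    }
    for (int j = 0; j < N * R; ++j) zz[j] = z_draws(s, j);
    for (int i = 0; i < N; ++i) {
      resolve_vals(d, mu.data(), sigma.data(), zz.data(), i, vals.data());
      int st = offs[i], T = offs[i + 1] - st;
      ppt_simulate(env.begin() + st, block.begin() + st, cell.begin() + st,
                   winning.begin() + st, T, vals.data(), K, lr_kind,
                   ch.data(), rw.data());
      double tot = 0.0;
      for (int t = 0; t < T; ++t) {
        rate(i, env[st + t]) += rw[t];
        tot += rw[t];
      }
      draw_rate(s, i) = tot / T;
    }
    if (s % 100 == 0) Rcpp::checkUserInterrupt();
  }
  for (int i = 0; i < N; ++i)
    for (int e = 0; e < 2; ++e)
      if (count(i, e) > 0) rate(i, e) /= (double)S * count(i, e);
  return List::create(_["rate"] = rate, _["count"] = count,
                      _["draw_rate"] = draw_rate);
}

// ---------------------------------------------------------------------------
// Pareto-smoothed importance sampling (per-observation LOO contributions).
// Generalised Pareto tail fit by the Zhang-Stephens profile posterior mean
// with the usual mild regularisation of the shape toward 0.5.
// ---------------------------------------------------------------------------

namespace {

bool gpd_fit_cpp(const std::vector<double>& x, double& k_out, double& sig_out) {
  int n = x.size();
  const double prior_bs = 3.0;
  int m = 30 + (int)std::floor(std::sqrt((double)n));
  int istar = std::max(0, (int)std::floor(n / 4.0 + 0.5) - 1);
  double xstar = x[istar], xmax = x[n - 1];
  if (xstar <= 0.0 || xmax <= 0.0) return false;
  std::vector<double> theta(m), l(m);
  double lmax = -HUGE_VAL;
  for (int j = 0; j < m; ++j) {
    double jj = j + 1.0;
    theta[j] = 1.0 / xmax + (1.0 - std::sqrt(m / (jj - 0.5))) / prior_bs / xstar;
    double k = 0.0;
    for (int i = 0; i < n; ++i) k += std::log1p(-theta[j] * x[i]);
    k = -k / n;
    l[j] = n * (std::log(theta[j] / k) + k - 1.0);
    if (l[j] > lmax) lmax = l[j];
  }
  double wsum = 0.0, theta_hat = 0.0;
  for (int j = 0; j < m; ++j) {
    double w = std::exp(l[j] - lmax);
    wsum += w;
    theta_hat += theta[j] * w;
  }
  theta_hat /= wsum;
  double k = 0.0;
  for (int i = 0; i < n; ++i) k += std::log1p(-theta_hat * x[i]);
  k = -k / n;
  double sigma = k / theta_hat;
  k = (n * k + 10.0 * 0.5) / (n + 10.0);
  if (!std::isfinite(k) || !std::isfinite(sigma) || sigma <= 0.0) return false;
  k_out = k;
  sig_out = sigma;
  return true;
}

inline double qgpd_cpp(double p, double k, double sigma) {
  if (std::fabs(k) < 1e-12) return -sigma * std::log1p(-p);
  return sigma * std::expm1(-k * std::log1p(-p)) / k;
}

} // namespace

// per-observation PSIS elpd contributions and Pareto shapes for a
// draws x observations log-likelihood matrix
// [[Rcpp::export]]
List cpp_psis_elpd(NumericMatrix ll) {
  int S = ll.nrow(), n = ll.ncol();
  NumericVector pointwise(n), pareto_k(n, NA_REAL);
  int M = (int)std::ceil(std::min(0.2 * S, 3.0 * std::sqrt((double)S)));
  std::vector<double> lw(S);
  std::vector<int> idx(S);
  std::vector<double> x(M > 0 ? M : 1);
  for (int obs = 0; obs < n; ++obs) {
    double mx = -HUGE_VAL;
    for (int s = 0; s < S; ++s) { lw[s] = -ll(s, obs); if (lw[s] > mx) mx = lw[s]; }
    for (int s = 0; s < S; ++s) lw[s] -= mx;
    if (M >= 5) {
      for (int s = 0; s < S; ++s) idx[s] = s;
      std::sort(idx.begin(), idx.end(),
                [&](int a, int b) { return lw[a] < lw[b]; });
      double cutoff = lw[idx[S - M - 1]];
      double ecut = std::exp(cutoff);
      for (int j = 0; j < M; ++j) {
        double v = std::exp(lw[idx[S - M + j]]) - ecut;
        x[j] = v > 0.0 ? v : 0.0;
      }
      double k, sigma;
      if (gpd_fit_cpp(x, k, sigma)) {
        pareto_k[obs] = k;
        for (int j = 0; j < M; ++j) {
          double p = (j + 0.5) / M;
          double sm = std::log(qgpd_cpp(p, k, sigma) + ecut);
          if (sm > 0.0) sm = 0.0; // cap at the raw maximum (lw is max-shifted)
          lw[idx[S - M + j]] = sm;
        }
      }
    }
    // normalise and accumulate elpd = log sum w * lik
    double lse = -HUGE_VAL;
    for (int s = 0; s < S; ++s) lse = std::max(lse, lw[s]);
    double tot = 0.0;
    for (int s = 0; s < S; ++s) tot += std::exp(lw[s] - lse);
    double lnorm = lse + std::log(tot);
    double m2 = -HUGE_VAL;
    for (int s = 0; s < S; ++s) m2 = std::max(m2, lw[s] - lnorm + ll(s, obs));
    double tot2 = 0.0;
    for (int s = 0; s < S; ++s) tot2 += std::exp(lw[s] - lnorm + ll(s, obs) - m2);
    pointwise[obs] = m2 + std::log(tot2);
  }
  return List::create(_["pointwise"] = pointwise, _["pareto_k"] = pareto_k);
}

// mean reward rate per parameter-grid cell over a pool of schedule
// realizations (single environment; cell index 0 throughout)
// [[Rcpp::export]]
NumericVector cpp_reward_rate_grid(IntegerVector block, IntegerVector winning,
                                   IntegerVector offs, NumericMatrix grid,
                                   int lr_kind) {
  int n_rep = offs.size() - 1, n_cell = grid.nrow(), P = grid.ncol();
  RNGScope scope;
  NumericVector out(n_cell);
  int Tmax = 0;
  for (int i = 0; i < n_rep; ++i) Tmax = std::max(Tmax, offs[i + 1] - offs[i]);
  std::vector<int> env(Tmax, 0), cellv(Tmax, 0), ch(Tmax), rw(Tmax);
  std::vector<double> vals(P);
  long n_tr_tot = 0;
  for (int i = 0; i < n_rep; ++i) n_tr_tot += offs[i + 1] - offs[i];
  for (int c = 0; c < n_cell; ++c) {
    for (int p = 0; p < P; ++p) vals[p] = grid(c, p);
    double tot = 0;
    for (int i = 0; i < n_rep; ++i) {
      int st = offs[i], T = offs[i + 1] - st;
      ppt_simulate(env.data(), block.begin() + st, cellv.data(),
                   winning.begin() + st, T, vals.data(), 1, lr_kind,
                   ch.data(), rw.data());
      for (int t = 0; t < T; ++t) tot += rw[t];
    }
    out[c] = tot / (double)n_tr_tot;
    if (c % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
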