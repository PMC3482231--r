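// Sampler core for the Dirichlet linking model.
//
// Parameter vector layout (length P = 7 + 2D):
//   [0..4] per-AOI baselines, [5] beta_object, [6] beta_cue,
//   [7..6+D] association polynomial, [7+D..6+2D] habituation polynomial.
// Coefficient shrinkage scales tau have length 2 + 2D and cover everything
// except the baselines, which get a fixed normal prior.
//
// All randomness comes from R's RNG (RNGScope), so chains are reproducible
// from set.seed() on the R side.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Infant {
  arma::mat logx, obj, cue, Hs, Hbar; // all T x 5
};

struct ModelCfg {
  int D;
  bool use_cue, use_assoc, use_habit;
  double bl_sd, tau_min, tau_max;
  int P() const { return 7 + 2 * D; }
  int ntau() const { return 2 + 2 * D; }
  // tau index for a theta coefficient index (>= 5), -1 for baselines
  int tau_of(int j) const { return j - 5; }
};

// Conditional draw of a local shrinkage scale tau given its coefficient:
// w | tau ~ N(0, tau) with the Jeffreys-type hyperprior p(tau) ~ 1/tau
// truncated to [tau_min, tau_max].  In x = 1/tau the conditional is
// Gamma(1/2, rate w^2/2) truncated to [1/tau_max, 1/tau_min]; sampled by
// inverse-CDF.  The 1/tau spike pins coefficients the data do not need.
static double draw_tau(double w, const ModelCfg& mc) {
  double lo = 1.0 / mc.tau_max, hi = 1.0 / mc.tau_min;
  double w2 = w * w;
  double x;
  if (w2 < 1e-16) {
    // flat-rate limit: density of x is proportional to x^(-1/2)
    double a = std::sqrt(lo), b = std::sqrt(hi);
    double r = a + unif_rand() * (b - a);
    x = r * r;
  } else {
    double scale = 2.0 / w2;
    double plo = R::pgamma(lo, 0.5, scale, 1, 0);
    double phi = R::pgamma(hi, 0.5, scale, 1, 0);
    if (phi - plo < 1e-14) {
      x = (plo > 0.5) ? lo : hi;
    } else {
      double u = plo + unif_rand() * (phi - plo);
      x = R::qgamma(u, 0.5, scale, 1, 0);
    }
    x = std::min(hi, std::max(lo, x));
  }
  return 1.0 / x;
}

static Infant unpack_infant(const List& p) {
  Infant inf;
  inf.logx = as<arma::mat>(p["logx"]);
  inf.obj  = as<arma::mat>(p["obj"]);
  inf.cue  = as<arma::mat>(p["cue"]);
  inf.Hs   = as<arma::mat>(p["Hs"]);
  inf.Hbar = as<arma::mat>(p["Hbar"]);
  return inf;
}

static std::vector<Infant> unpack_infants(const List& pre) {
  std::vector<Infant> v;
  v.reserve(pre.size());
  for (int i = 0; i < pre.size(); ++i) v.push_back(unpack_infant(pre[i]));
  return v;
}

static double infant_ll(const Infant& inf, const arma::vec& th,
                        const ModelCfg& mc) {
  const int T = inf.logx.n_rows;
  double total = 0.0;
  for (int t = 0; t < T; ++t) {
    double asum = 0.0, ll = 0.0;
    for (int i = 0; i < 5; ++i) {
      double eta = th[i];
      if (i < 4) {
        eta += th[5] * inf.obj(t, i);
        if (mc.use_cue) eta += th[6] * inf.cue(t, i);
        if (mc.use_assoc) {
          double h = inf.Hs(t, i), hp = h;
          for (int d = 0; d < mc.D; ++d) { eta += th[7 + d] * hp; hp *= h; }
        }
        if (mc.use_habit) {
          double h = inf.Hbar(t, i), hp = h;
          for (int d = 0; d < mc.D; ++d) { eta += th[7 + mc.D + d] * hp; hp *= h; }
        }
      }
      if (eta > 700.0 || eta < -700.0)
        return -std::numeric_limits<double>::infinity();
      double a = std::exp(eta);
      asum += a;
      ll += -std::lgamma(a) + (a - 1.0) * inf.logx(t, i);
    }
    total += ll + std::lgamma(asum);
  }
  return total;
}

// Parameter blocks for Metropolis updates: 0 baselines, 1 beta_object,
// 2 beta_cue, 3 association, 4 habituation (skipped when inactive).
static std::vector<std::vector<int>> make_blocks(const ModelCfg& mc) {
  std::vector<std::vector<int>> blocks(5);
  blocks[0] = {0, 1, 2, 3, 4};
  blocks[1] = {5};
  if (mc.use_cue) blocks[2] = {6};
  if (mc.use_assoc)
    for (int d = 0; d < mc.D; ++d) blocks[3].push_back(7 + d);
  if (mc.use_habit)
    for (int d = 0; d < mc.D; ++d) blocks[4].push_back(7 + mc.D + d);
  return blocks;
}

// Exchange move between the association and habituation families: the two
// history covariates are strongly collinear (the sound-independent history
// is the sum of the per-sound histories), so the posterior has curved
// ridges that axis-aligned blocks traverse poorly.  Per degree, propose a
// correlated transfer (a_d + t, h_d - r t) with a random ratio r spanning
// the ridge slopes; the proposal density is symmetric under negation, so
// plain Metropolis acceptance is valid.
static bool exchange_move(arma::vec& th, double& cur, const arma::rowvec& tau,
                          const ModelCfg& mc, double scale,
                          const std::function<double(const arma::vec&)>& ll_fn) {
  bool any = false;
  for (int d = 0; d < mc.D; ++d) {
    int ja = 7 + d, jh = 7 + mc.D + d;
    double sdx = std::min(scale, 3.0 * std::sqrt(std::max(tau[mc.tau_of(ja)],
                                                          tau[mc.tau_of(jh)])));
    double t = sdx * norm_rand();
    double r = 0.3 + 0.9 * unif_rand();
    arma::vec prop = th;
    prop[ja] += t;
    prop[jh] -= r * t;
    double lp0 = R::dnorm(th[ja], 0.0, std::sqrt(tau[mc.tau_of(ja)]), 1) +
                 R::dnorm(th[jh], 0.0, std::sqrt(tau[mc.tau_of(jh)]), 1);
    double lp1 = R::dnorm(prop[ja], 0.0, std::sqrt(tau[mc.tau_of(ja)]), 1) +
                 R::dnorm(prop[jh], 0.0, std::sqrt(tau[mc.tau_of(jh)]), 1);
    double llp = ll_fn(prop);
    if (std::log(unif_rand()) < llp + lp1 - cur - lp0) {
      th = prop;
      cur = llp;
      any = true;
    }
  }
  return any;
}

static double block_log_prior(const arma::vec& th, const std::vector<int>& idx,
                              const arma::rowvec& tau, const ModelCfg& mc) {
  double lp = 0.0;
  for (int j : idx) {
    double sd = (j < 5) ? mc.bl_sd : std::sqrt(tau[mc.tau_of(j)]);
    lp += R::dnorm(th[j], 0.0, sd, 1);
  }
  return lp;
}

// Joint prior draw of a fresh table: local scales log-uniform on their
// truncated range, then coefficients given the scales (baselines from
// their fixed normal).  Inactive terms stay at zero.
static void draw_prior_table(arma::vec& th, arma::rowvec& tau,
                             const ModelCfg& mc) {
  th.zeros(mc.P());
  tau.set_size(mc.ntau());
  double llo = std::log(mc.tau_min), lhi = std::log(mc.tau_max);
  for (int t = 0; t < mc.ntau(); ++t)
    tau[t] = std::exp(llo + unif_rand() * (lhi - llo));
  for (int i = 0; i < 5; ++i) th[i] = R::rnorm(0.0, mc.bl_sd);
  th[5] = R::rnorm(0.0, std::sqrt(tau[0]));
  if (mc.use_cue) th[6] = R::rnorm(0.0, std::sqrt(tau[1]));
  if (mc.use_assoc)
    for (int d = 0; d < mc.D; ++d) th[7 + d] = R::rnorm(0.0, std::sqrt(tau[2 + d]));
  if (mc.use_habit)
    for (int d = 0; d < mc.D; ++d)
      th[7 + mc.D + d] = R::rnorm(0.0, std::sqrt(tau[2 + mc.D + d]));
}

static int sample_log_weights(const std::vector<double>& lw) {
  double m = -std::numeric_limits<double>::infinity();
  for (double w : lw) m = std::max(m, w);
  std::vector<double> cum(lw.size());
  double tot = 0.0;
  for (size_t k = 0; k < lw.size(); ++k) {
    tot += std::exp(lw[k] - m);
    cum[k] = tot;
  }
  double u = unif_rand() * tot;
  for (size_t k = 0; k < lw.size(); ++k)
    if (u <= cum[k]) return (int)k;
  return (int)lw.size() - 1;
}

static ModelCfg cfg_from_list(const List& cfg) {
  ModelCfg mc;
  mc.D = as<int>(cfg["D"]);
  mc.use_cue = as<bool>(cfg["use_cue"]);
  mc.use_assoc = as<bool>(cfg["use_assoc"]);
  mc.use_habit = as<bool>(cfg["use_habit"]);
  mc.bl_sd = as<double>(cfg["bl_sd"]);
  mc.tau_min = as<double>(cfg["tau_min"]);
  mc.tau_max = as<double>(cfg["tau_max"]);
  return mc;
}

// [[Rcpp::export]]
double cpp_infant_loglik(List pre, NumericVector theta, int D,
                         bool use_cue, bool use_assoc, bool use_habit) {
  ModelCfg mc;
  mc.D = D; mc.use_cue = use_cue; mc.use_assoc = use_assoc;
  mc.use_habit = use_habit; mc.bl_sd = 1; mc.tau_min = 1; mc.tau_max = 1;
  Infant inf = unpack_infant(pre);
  return infant_ll(inf, as<arma::vec>(theta), mc);
}

// Log-likelihood of one infant under each row of a parameter matrix.
// [[Rcpp::export]]
NumericVector cpp_loglik_rows(List pre, NumericMatrix Theta, int D,
                              bool use_cue, bool use_assoc, bool use_habit) {
  ModelCfg mc;
  mc.D = D; mc.use_cue = use_cue; mc.use_assoc = use_assoc;
  mc.use_habit = use_habit; mc.bl_sd = 1; mc.tau_min = 1; mc.tau_max = 1;
  Infant inf = unpack_infant(pre);
  NumericVector out(Theta.nrow());
  for (int k = 0; k < Theta.nrow(); ++k) {
    arma::vec th = as<arma::vec>(NumericVector(Theta(k, _)));
    out[k] = infant_ll(inf, th, mc);
  }
  return out;
}

// Random-walk Metropolis chain for a single infant with fixed prior
// scales (stage-1 initialization chains).  Proposal scales adapt toward
// ~30% acceptance over the first half of the chain, then freeze.
// [[Rcpp::export]]
List cpp_individual_chain(List pre, NumericVector theta0, int n_samples,
                          List cfg, NumericVector scales0, double coef_sd) {
  ModelCfg mc = cfg_from_list(cfg);
  Infant inf = unpack_infant(pre);
  arma::rowvec tau(mc.ntau());
  tau.fill(coef_sd * coef_sd);
  std::vector<std::vector<int>> blocks = make_blocks(mc);
  arma::vec th = as<arma::vec>(theta0);
  arma::vec scales = as<arma::vec>(scales0);
  arma::mat samples(n_samples, mc.P());
  arma::vec acc(5, arma::fill::zeros), att(5, arma::fill::zeros);
  arma::vec acc_w(5, arma::fill::zeros), att_w(5, arma::fill::zeros);
  double cur = infant_ll(inf, th, mc);
  int adapt_until = n_samples / 2, interval = 25;
  for (int s = 0; s < n_samples; ++s) {
    for (int b = 0; b < 5; ++b) {
      if (blocks[b].empty()) continue;
      arma::vec prop = th;
      for (int j : blocks[b]) prop[j] += scales[b] * norm_rand();
      double lp0 = block_log_prior(th, blocks[b], tau, mc);
      double lp1 = block_log_prior(prop, blocks[b], tau, mc);
      double llp = infant_ll(inf, prop, mc);
      att[b] += 1; att_w[b] += 1;
      if (std::log(unif_rand()) < llp + lp1 - cur - lp0) {
        th = prop; cur = llp; acc[b] += 1; acc_w[b] += 1;
      }
    }
    if (mc.use_assoc && mc.use_habit)
      exchange_move(th, cur, tau, mc, scales[3],
                    [&](const arma::vec& p) { return infant_ll(inf, p, mc); });
    if (s < adapt_until && (s + 1) % interval == 0) {
      for (int b = 0; b < 5; ++b) {
        if (att_w[b] > 0) {
          double r = acc_w[b] / att_w[b];
          scales[b] = std::min(10.0, std::max(1e-4, scales[b] * std::exp(0.5 * (r - 0.3))));
        }
        acc_w[b] = 0; att_w[b] = 0;
      }
    }
    samples.row(s) = th.t();
  }
  return List::create(_["samples"] = samples,
                      _["accept"] = acc / arma::clamp(att, 1.0, arma::datum::inf),
                      _["scales"] = scales);
}

// --- group chain -----------------------------------------------------------

struct GroupState {
  std::vector<arma::vec> tables;
  std::vector<arma::rowvec> tau;   // local shrinkage scales, one row per table
  std::vector<int> z;              // 0-based table index per infant
  double kappa;
};

static std::vector<int> table_counts(const GroupState& st) {
  std::vector<int> cnt(st.tables.size(), 0);
  for (int zi : st.z) cnt[zi]++;
  return cnt;
}

static void reassign_infant(GroupState& st, int i,
                            const std::vector<Infant>& infants,
                            const ModelCfg& mc, int m_aux) {
  std::vector<int> cnt = table_counts(st);
  int old = st.z[i];
  cnt[old]--;
  bool freed = false;
  arma::vec freed_params;
  arma::rowvec freed_tau;
  if (cnt[old] == 0) {
    freed = true;
    freed_params = st.tables[old];
    freed_tau = st.tau[old];
    st.tables.erase(st.tables.begin() + old);
    st.tau.erase(st.tau.begin() + old);
    cnt.erase(cnt.begin() + old);
    for (int& zj : st.z) if (zj > old) zj--;
  }
  int K = (int)st.tables.size();
  std::vector<arma::vec> aux(m_aux);
  std::vector<arma::rowvec> aux_tau(m_aux);
  for (int j = 0; j < m_aux; ++j) {
    if (j == 0 && freed) {
      aux[j] = freed_params;
      aux_tau[j] = freed_tau;
    } else {
      draw_prior_table(aux[j], aux_tau[j], mc);
    }
  }
  std::vector<double> lw(K + m_aux);
  for (int k = 0; k < K; ++k)
    lw[k] = std::log((double)cnt[k]) + infant_ll(infants[i], st.tables[k], mc);
  double lnew = std::log(st.kappa / m_aux);
  for (int j = 0; j < m_aux; ++j)
    lw[K + j] = lnew + infant_ll(infants[i], aux[j], mc);
  int pick = sample_log_weights(lw);
  if (pick < K) {
    st.z[i] = pick;
  } else {
    st.tables.push_back(aux[pick - K]);
    st.tau.push_back(aux_tau[pick - K]);
    st.z[i] = K;
  }
}

static double members_ll(const GroupState& st, int k,
                         const std::vector<Infant>& infants,
                         const arma::vec& th, const ModelCfg& mc) {
  double ll = 0.0;
  for (size_t i = 0; i < st.z.size(); ++i)
    if (st.z[i] == k) ll += infant_ll(infants[i], th, mc);
  return ll;
}

static void update_table(GroupState& st, int k,
                         const std::vector<Infant>& infants,
                         const ModelCfg& mc,
                         const std::vector<std::vector<int>>& blocks,
                         const arma::vec& scales,
                         arma::vec& acc, arma::vec& att) {
  double cur = members_ll(st, k, infants, st.tables[k], mc);
  for (int b = 0; b < 5; ++b) {
    if (blocks[b].empty()) continue;
    arma::vec prop = st.tables[k];
    for (int j : blocks[b]) {
      double sd = scales[b];
      if (j >= 5) sd = std::min(sd, 3.0 * std::sqrt(st.tau[k][mc.tau_of(j)]));
      prop[j] += sd * norm_rand();
    }
    double lp0 = block_log_prior(st.tables[k], blocks[b], st.tau[k], mc);
    double lp1 = block_log_prior(prop, blocks[b], st.tau[k], mc);
    double llp = members_ll(st, k, infants, prop, mc);
    att[b] += 1;
    if (std::log(unif_rand()) < llp + lp1 - cur - lp0) {
      st.tables[k] = prop; cur = llp; acc[b] += 1;
    }
  }
  if (mc.use_assoc && mc.use_habit)
    exchange_move(st.tables[k], cur, st.tau[k], mc, scales[3],
                  [&](const arma::vec& p) {
                    return members_ll(st, k, infants, p, mc);
                  });
}

static void update_hypers(GroupState& st, const ModelCfg& mc,
                          double kappa_a, double kappa_b, int n_infants) {
  // Local shrinkage scales: conjugate truncated update given each
  // table's coefficient values (adaptive-sparseness construction).
  int K = (int)st.tables.size();
  std::vector<int> active;
  active.push_back(5);
  if (mc.use_cue) active.push_back(6);
  if (mc.use_assoc) for (int d = 0; d < mc.D; ++d) active.push_back(7 + d);
  if (mc.use_habit) for (int d = 0; d < mc.D; ++d) active.push_back(7 + mc.D + d);
  for (int k = 0; k < K; ++k)
    for (int j : active)
      st.tau[k][mc.tau_of(j)] = draw_tau(st.tables[k][j], mc);
  // CRP concentration: Escobar & West auxiliary-variable update.
  double N = (double)n_infants;
  double eta = R::rbeta(st.kappa + 1.0, N);
  double c = kappa_b - std::log(eta);
  double w = (kappa_a + K - 1.0) / (N * c);
  double pi = w / (1.0 + w);
  double kap = (unif_rand() < pi) ? R::rgamma(kappa_a + K, 1.0 / c)
                                  : R::rgamma(kappa_a + K - 1.0, 1.0 / c);
  st.kappa = std::min(1e4, std::max(1e-4, kap));
}

// Full Metropolis-within-Gibbs group chain: per sweep, CRP reassignment of
// every infant (Neal algorithm 8 with m auxiliary tables), random-walk
// Metropolis updates of every table's parameter blocks, then hyperparameter
// updates.  Proposal scales adapt during burn-in and freeze afterwards.
// [[Rcpp::export]]
List cpp_group_chain(List pre, IntegerVector z0, NumericMatrix tables0,
                     double kappa0, NumericMatrix tau0, List cfg) {
  ModelCfg mc = cfg_from_list(cfg);
  int n_sweeps = as<int>(cfg["n_sweeps"]);
  int burn_in = as<int>(cfg["burn_in"]);
  int m_aux = as<int>(cfg["m_aux"]);
  double kappa_a = as<double>(cfg["kappa_a"]);
  double kappa_b = as<double>(cfg["kappa_b"]);
  int adapt_interval = as<int>(cfg["adapt_interval"]);
  arma::vec scales = as<arma::vec>(cfg["scales"]);

  std::vector<Infant> infants = unpack_infants(pre);
  int n = (int)infants.size();
  GroupState st;
  st.z.assign(z0.begin(), z0.end());
  for (int& zi : st.z) zi -= 1;
  for (int k = 0; k < tables0.nrow(); ++k) {
    st.tables.push_back(as<arma::vec>(NumericVector(tables0(k, _))));
    st.tau.push_back(as<arma::rowvec>(NumericVector(tau0(k, _))));
  }
  st.kappa = kappa0;

  std::vector<std::vector<int>> blocks = make_blocks(mc);
  int n_keep = n_sweeps - burn_in;
  IntegerMatrix z_out(n_keep, n);
  List tables_out(n_keep);
  NumericVector kappa_out(n_keep);
  IntegerVector ntab_out(n_keep);
  arma::vec acc(5, arma::fill::zeros), att(5, arma::fill::zeros);
  arma::vec acc_w(5, arma::fill::zeros), att_w(5, arma::fill::zeros);

  for (int s = 0; s < n_sweeps; ++s) {
    if (s % 256 == 0) Rcpp::checkUserInterrupt();
    for (int i = 0; i < n; ++i) reassign_infant(st, i, infants, mc, m_aux);
    arma::vec acc_s(5, arma::fill::zeros), att_s(5, arma::fill::zeros);
    for (int k = 0; k < (int)st.tables.size(); ++k)
      update_table(st, k, infants, mc, blocks, scales, acc_s, att_s);
    update_hypers(st, mc, kappa_a, kappa_b, n);
    if (s < burn_in) {
      acc_w += acc_s; att_w += att_s;
      if ((s + 1) % adapt_interval == 0) {
        for (int b = 0; b < 5; ++b) {
          if (att_w[b] > 0) {
            double r = acc_w[b] / att_w[b];
            scales[b] = std::min(10.0, std::max(1e-4, scales[b] * std::exp(0.5 * (r - 0.3))));
          }
        }
        acc_w.zeros(); att_w.zeros();
      }
    } else {
      acc += acc_s; att += att_s;
      int idx = s - burn_in;
      for (int i = 0; i < n; ++i) z_out(idx, i) = st.z[i] + 1;
      int K = (int)st.tables.size();
      NumericMatrix tab(K, mc.P());
      for (int k = 0; k < K; ++k)
        for (int j = 0; j < mc.P(); ++j) tab(k, j) = st.tables[k][j];
      tables_out[idx] = tab;
      kappa_out[idx] = st.kappa;
      ntab_out[idx] = K;
    }
  }
  return List::create(_["z"] = z_out, _["tables"] = tables_out,
                      _["kappa"] = kappa_out, _["n_tables"] = ntab_out,
                      _["accept"] = acc / arma::clamp(att, 1.0, arma::datum::inf),
                      _["scales"] = scales);
}
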