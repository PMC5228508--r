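// Metropolis-within-Gibbs sampler for the individual state-space CJS model
// with spike-and-slab indicator variable selection.
//
// Latent alive trajectories are monotone (alive, then dead), so each fish's
// trajectory is summarized by its death period d in [first+1, last+1]
// (d = last+1 means alive throughout the record) and updated by an exact
// categorical Gibbs draw. Unobserved spawning states are Bernoulli Gibbs
// draws. Coefficients use adaptive random-walk Metropolis (adaptation only
// during burn-in) plus an independence proposal from the conditional prior,
// which lets a coefficient jump between spike and slab scales in one move.
// Indicators are conjugate Bernoulli Gibbs draws.

#include <Rcpp.h>
using namespace Rcpp;

static inline double log_ilogit(double x) {
  // log(1/(1+exp(-x))) without overflow
  return x < 0 ? x - log1p(std::exp(x)) : -log1p(std::exp(-x));
}
static inline double ilogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double ldnorm(double b, double sd) {
  return -0.5 * (b / sd) * (b / sd) - std::log(sd) -
         0.918938533204672741780329736406;  // log(sqrt(2*pi))
}
// log of the spike-and-slab mixture density with the indicator summed out
static inline double ldmix(double b, double slab_sd, double spike_sd,
                           double pind) {
  double l1 = std::log(pind) + ldnorm(b, slab_sd);
  double l0 = std::log(1 - pind) + ldnorm(b, spike_sd);
  double hi = l1 > l0 ? l1 : l0;
  return hi + log1p(std::exp((l1 > l0 ? l0 : l1) - hi));
}

// coefficient layout:
// 0 beta_phi0  1 beta_phix  2 beta_phiY
// 3 beta_rho0  4 beta_rhoY
// 5 beta_delta0 6 beta_deltaS 7 beta_deltaY
// 8 beta_kappa0 9 beta_kappaL 10 beta_kappaY
// indicator -> coefficient: {1, 2, 4, 6, 7, 9, 10}

struct CjsState {
  int n, K;
  const IntegerVector &first, &last;
  const IntegerMatrix &y, &m, &Tm, &S, &xobs;
  const NumericMatrix &L, &Y;
  std::vector<int> d;       // first dead period, 1-based
  IntegerMatrix x;          // current spawning states
  std::vector<double> beta;
  std::vector<int> gamma;

  CjsState(const IntegerVector &first_, const IntegerVector &last_,
           const IntegerMatrix &y_, const IntegerMatrix &m_,
           const IntegerMatrix &Tm_, const IntegerMatrix &S_,
           const IntegerMatrix &xobs_, const NumericMatrix &L_,
           const NumericMatrix &Y_)
    : n(first_.size()), K(y_.ncol()), first(first_), last(last_), y(y_),
      m(m_), Tm(Tm_), S(S_), xobs(xobs_), L(L_), Y(Y_),
      d(n), x(n, y_.ncol()), beta(11), gamma(7) {
    for (int i = 0; i < n; ++i) {
      d[i] = last[i] + 1;  // all alive through last observation
      for (int t = 0; t < K; ++t)
        x(i, t) = (t + 1 > first[i] && S(i, t) == 1 && xobs(i, t) == 1)
                    ? 1 : 0;
    }
  }

  double lphi(int i, int t) const {  // t 1-based
    return beta[0] + beta[1] * x(i, t - 1) + beta[2] * Y(i, t - 1);
  }
  double lrho(int i, int t) const {
    return beta[3] + beta[4] * Y(i, t - 1);
  }
  double ldelta(int i, int t) const {
    return beta[5] + beta[6] * S(i, t - 1) + beta[7] * Y(i, t - 1);
  }
  double lkappa(int i, int t) const {
    return beta[8] + beta[9] * L(i, t - 1) + beta[10] * Y(i, t - 1);
  }

  // transition (survival) component of the complete-data log likelihood
  double ll_phi() const {
    double ll = 0;
    for (int i = 0; i < n; ++i) {
      int hi = std::min(d[i] - 1, last[i] - 1);
      for (int t = first[i]; t <= hi; ++t) {
        double lp = lphi(i, t);
        ll += (t + 1 < d[i]) ? log_ilogit(lp) : log_ilogit(-lp);
      }
    }
    return ll;
  }
  double ll_rho() const {
    double ll = 0;
    for (int i = 0; i < n; ++i)
      for (int t = first[i] + 1; t <= last[i] && t < d[i]; ++t) {
        double lp = lrho(i, t);
        ll += y(i, t - 1) == 1 ? log_ilogit(lp) : log_ilogit(-lp);
      }
    return ll;
  }
  double ll_delta() const {
    double ll = 0;
    for (int i = 0; i < n; ++i)
      for (int t = first[i] + 1; t <= last[i] && t < d[i]; ++t) {
        if (Tm(i, t - 1) != 1 || m(i, t - 1) < 0) continue;
        double lp = ldelta(i, t);
        ll += m(i, t - 1) == 1 ? log_ilogit(lp) : log_ilogit(-lp);
      }
    return ll;
  }
  double ll_kappa() const {
    double ll = 0;
    for (int i = 0; i < n; ++i)
      for (int t = first[i] + 1; t <= last[i] && t < d[i]; ++t) {
        if (S(i, t - 1) != 1) continue;
        double lp = lkappa(i, t);
        ll += x(i, t - 1) == 1 ? log_ilogit(lp) : log_ilogit(-lp);
      }
    return ll;
  }

  // exact Gibbs draw of each fish's death period given beta and x
  void update_d() {
    std::vector<double> logp(K + 2), obs1(K + 2);
    for (int i = 0; i < n; ++i) {
      int f = first[i], l = last[i];
      // alive-observation log likelihood per period, and forced-alive limit
      int tforce = f;  // z at f is 1 by definition
      obs1[f] = 0;       // release period carries no observation terms
      for (int t = f + 1; t <= l; ++t) {
        double o = 0;
        o += y(i, t - 1) == 1 ? log_ilogit(lrho(i, t))
                              : log_ilogit(-lrho(i, t));
        if (Tm(i, t - 1) == 1 && m(i, t - 1) >= 0)
          o += m(i, t - 1) == 1 ? log_ilogit(ldelta(i, t))
                                : log_ilogit(-ldelta(i, t));
        if (S(i, t - 1) == 1)
          o += x(i, t - 1) == 1 ? log_ilogit(lkappa(i, t))
                                : log_ilogit(-lkappa(i, t));
        obs1[t] = o;
        bool forced = y(i, t - 1) == 1 ||
          (Tm(i, t - 1) == 1 && m(i, t - 1) == 1) ||
          (S(i, t - 1) == 1 && x(i, t - 1) == 1);
        if (forced) tforce = t;
      }
      int dmin = std::max(f + 1, tforce + 1);
      double cumphi = 0, cumobs = 0, best = R_NegInf;
      // accumulate log p(d) for d = f+1 .. l+1
      for (int t = f; t < dmin; ++t) cumobs += obs1[t];
      for (int t = f; t <= dmin - 2; ++t) cumphi += log_ilogit(lphi(i, t));
      for (int dd = dmin; dd <= l + 1; ++dd) {
        double lp = cumphi + cumobs;
        if (dd <= l) lp += log_ilogit(-lphi(i, dd - 1));
        logp[dd] = lp;
        if (lp > best) best = lp;
        // extend cumulative sums for the next candidate
        cumphi += log_ilogit(lphi(i, dd - 1));
        cumobs += (dd <= l) ? obs1[dd] : 0;
      }
      double tot = 0;
      for (int dd = dmin; dd <= l + 1; ++dd)
        tot += std::exp(logp[dd] - best);
      double u = R::runif(0, 1) * tot, acc = 0;
      int dnew = l + 1;
      for (int dd = dmin; dd <= l + 1; ++dd) {
        acc += std::exp(logp[dd] - best);
        if (u <= acc) { dnew = dd; break; }
      }
      d[i] = dnew;
      // dead fish cannot spawn: zero latent states past death
      for (int t = dnew; t <= l; ++t)
        if (S(i, t - 1) == 1 && xobs(i, t - 1) < 0) x(i, t - 1) = 0;
    }
  }

  // Bernoulli Gibbs draw of each unobserved spawning state
  void update_x() {
    for (int i = 0; i < n; ++i) {
      int f = first[i], l = last[i];
      for (int t = f + 1; t <= l; ++t) {
        if (S(i, t - 1) != 1 || xobs(i, t - 1) >= 0) continue;
        if (t >= d[i]) { x(i, t - 1) = 0; continue; }
        double lk = lkappa(i, t);
        double lw1 = log_ilogit(lk), lw0 = log_ilogit(-lk);
        if (t < l) {  // survival from t depends on the spawning state
          double base = beta[0] + beta[2] * Y(i, t - 1);
          bool alive_next = (t + 1) < d[i];
          lw1 += alive_next ? log_ilogit(base + beta[1])
                            : log_ilogit(-(base + beta[1]));
          lw0 += alive_next ? log_ilogit(base) : log_ilogit(-base);
        }
        double p1 = 1.0 / (1.0 + std::exp(lw0 - lw1));
        x(i, t - 1) = R::runif(0, 1) < p1 ? 1 : 0;
      }
    }
  }
};

// [[Rcpp::export]]
List cjs_run_chain(IntegerVector first, IntegerVector last,
                   IntegerMatrix y, IntegerMatrix m, IntegerMatrix Tm,
                   IntegerMatrix S, IntegerMatrix xobs,
                   NumericMatrix L, NumericMatrix Y,
                   double slab_sd, double spike_sd, double indicator_prob,
                   int n_iter, int n_burn, int thin, int n_keep,
                   NumericVector beta_init, IntegerVector gamma_init) {
  CjsState st(first, last, y, m, Tm, S, xobs, L, Y);
  for (int j = 0; j < 11; ++j) st.beta[j] = beta_init[j];
  for (int g = 0; g < 7; ++g) st.gamma[g] = gamma_init[g];

  const int imap[7] = {1, 2, 4, 6, 7, 9, 10};
  const bool is_intercept[11] = {true, false, false, true, false,
                                 true, false, false, true, false, false};
  int coef_gamma[11];  // indicator index per coefficient, -1 for intercepts
  for (int j = 0; j < 11; ++j) coef_gamma[j] = -1;
  for (int g = 0; g < 7; ++g) coef_gamma[imap[g]] = g;
  // component of the likelihood each coefficient touches
  const int comp_of[11] = {0, 0, 0, 1, 1, 2, 2, 2, 3, 3, 3};

  std::vector<double> lscale(11, std::log(0.1));
  std::vector<double> acc_ct(11, 0), prop_ct(11, 0);
  NumericMatrix draws(n_keep, 19);
  int saved = 0;
  const double target = 0.35;  // mid 20-50% acceptance band

  for (int iter = 0; iter < n_iter; ++iter) {
    st.update_d();
    st.update_x();

    double comp_ll[4] = {st.ll_phi(), st.ll_rho(), st.ll_delta(),
                         st.ll_kappa()};
    // coefficient updates work in the collapsed space (indicators summed
    // out of the prior), so a coefficient can cross between spike and slab
    // scales without waiting for a rare indicator flip
    for (int j = 0; j < 11; ++j) {
      int c = comp_of[j];
      double old = st.beta[j];
      double prop = old + std::exp(lscale[j]) * R::rnorm(0, 1);
      st.beta[j] = prop;
      double newll;
      switch (c) {
        case 0: newll = st.ll_phi(); break;
        case 1: newll = st.ll_rho(); break;
        case 2: newll = st.ll_delta(); break;
        default: newll = st.ll_kappa(); break;
      }
      double lr = newll - comp_ll[c] + (is_intercept[j]
        ? ldnorm(prop, slab_sd) - ldnorm(old, slab_sd)
        : ldmix(prop, slab_sd, spike_sd, indicator_prob) -
          ldmix(old, slab_sd, spike_sd, indicator_prob));
      double alpha = lr >= 0 ? 1.0 : std::exp(lr);
      if (R::runif(0, 1) < alpha) {
        comp_ll[c] = newll;
        if (iter >= n_burn) acc_ct[j] += 1;
      } else {
        st.beta[j] = old;
      }
      if (iter >= n_burn) prop_ct[j] += 1;
      if (iter < n_burn)  // Robbins-Monro adaptation, frozen after burn-in
        lscale[j] += (alpha - target) * 2.0 / std::sqrt((double)(iter + 1));
    }

    // independence proposals from the collapsed mixture prior: prior and
    // proposal densities cancel, so the acceptance ratio is the likelihood
    // ratio, and spike <-> slab jumps happen in a single move
    for (int g = 0; g < 7; ++g) {
      int j = imap[g], c = comp_of[j];
      double old = st.beta[j];
      double sd_prop = R::runif(0, 1) < indicator_prob ? slab_sd : spike_sd;
      st.beta[j] = R::rnorm(0, sd_prop);
      double newll;
      switch (c) {
        case 0: newll = st.ll_phi(); break;
        case 1: newll = st.ll_rho(); break;
        case 2: newll = st.ll_delta(); break;
        default: newll = st.ll_kappa(); break;
      }
      if (std::log(R::runif(0, 1)) < newll - comp_ll[c]) comp_ll[c] = newll;
      else st.beta[j] = old;
    }

    // conjugate Gibbs for the indicators
    for (int g = 0; g < 7; ++g) {
      double b = st.beta[imap[g]];
      double l1 = std::log(indicator_prob) + ldnorm(b, slab_sd);
      double l0 = std::log(1 - indicator_prob) + ldnorm(b, spike_sd);
      double p1 = 1.0 / (1.0 + std::exp(l0 - l1));
      st.gamma[g] = R::runif(0, 1) < p1 ? 1 : 0;
    }

    if (iter >= n_burn && (iter - n_burn) % thin == 0 && saved < n_keep) {
      for (int j = 0; j < 11; ++j) draws(saved, j) = st.beta[j];
      for (int g = 0; g < 7; ++g) draws(saved, 11 + g) = st.gamma[g];
      draws(saved, 18) = comp_ll[0] + comp_ll[1] + comp_ll[2] + comp_ll[3];
      ++saved;
    }
  }
  NumericVector accept(11);
  for (int j = 0; j < 11; ++j)
    accept[j] = prop_ct[j] > 0 ? acc_ct[j] / prop_ct[j] : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = accept,
                      _["n_saved"] = saved);
}
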