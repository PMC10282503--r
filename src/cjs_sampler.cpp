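// Compiled hot path of the hierarchical two-age-class CJS model:
// m-array multinomial log-likelihood (without multinomial constants),
// decomposed log-prior, and a componentwise adaptive random-walk
// Metropolis sampler with cached linear predictors, rates and log-rates
// per species (updates touch only the slice a parameter affects).
//
// Parameter layout matches cjs_param_map() on the R side exactly.
// Kinds: 1 hyper-mean, 2 hyper-SD, 3 trait slope, 4 species intercept,
// 5 species slope, 6 residual SD, 7 temporal residual.
// Ages: 1 juvenile survival, 2 adult survival, 3 recapture.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double SLOPE_VAR = 10.0;  // slope prior variance (precision 0.1)
static const double SD_UPPER = 10.0;   // Uniform(0, SD_UPPER) on all SDs
static const double LOG_FLOOR = -690.775527898214; // log(1e-300)

struct CjsModel {
  int S, T, Tm1, P;
  bool literal;
  bool ncp = false;   // sampler uses eps = sigma * z internally
  std::vector<int> has_juv;
  // data
  std::vector<NumericMatrix> m_juv, m_ad;
  std::vector<NumericVector> never_juv, never_ad, R_juv, R_ad;
  std::vector<int> any_juv_rel, any_ad_rel;
  NumericMatrix X;          // 4 x (T-1): year, temp, precip, enso (standardized)
  NumericVector effort2;    // length T-1, standardized effort at occasions 2..T
  NumericVector MB, BSz;
  // parameters
  double mu[3], sigma_mu[3];
  double btrait[2][2];                  // [age][MB/BS]
  std::vector<double> alpha[3];         // [age][s]
  std::vector<double> beta_surv[2];     // [age][4*S], 4 slopes per species
  std::vector<double> beff;             // [s]
  std::vector<double> sigma_res[3];     // [age][s]
  std::vector<double> eps[3];           // [age][t + Tm1*s]
  // caches, all [age][t + Tm1*s]: linear predictor, rate, log rate,
  // and log(1 - p) for the recapture vector
  std::vector<double> eta[3], rate[3], lrate[3], l1mp;
  // parameter map
  IntegerVector kind, psp, pt, page;

  CjsModel(List data, IntegerVector kind_, IntegerVector sp_, IntegerVector t_,
           IntegerVector age_, bool literal_)
      : kind(kind_), psp(sp_), pt(t_), page(age_) {
    S = as<int>(data["S"]);
    T = as<int>(data["T"]);
    Tm1 = T - 1;
    literal = literal_;
    P = kind.size();
    IntegerVector hj = data["has_juv"];
    has_juv.assign(hj.begin(), hj.end());
    List marr = data["marrays"];
    for (int s = 0; s < S; s++) {
      List ms = marr[s];
      m_juv.push_back(as<NumericMatrix>(ms["juv_m"]));
      m_ad.push_back(as<NumericMatrix>(ms["ad_m"]));
      never_juv.push_back(as<NumericVector>(ms["juv_never"]));
      never_ad.push_back(as<NumericVector>(ms["ad_never"]));
      R_juv.push_back(as<NumericVector>(ms["juv_R"]));
      R_ad.push_back(as<NumericVector>(ms["ad_R"]));
      double tj = 0, ta = 0;
      for (int i = 0; i < Tm1; i++) { tj += R_juv[s][i]; ta += R_ad[s][i]; }
      any_juv_rel.push_back(tj > 0);
      any_ad_rel.push_back(ta > 0);
    }
    X = as<NumericMatrix>(data["X"]);
    effort2 = as<NumericVector>(data["effort2"]);
    MB = as<NumericVector>(data["MB"]);
    BSz = as<NumericVector>(data["BSz"]);
    for (int a = 0; a < 3; a++) {
      alpha[a].assign(S, 0.0);
      sigma_res[a].assign(S, 1.0);
      eps[a].assign(Tm1 * S, 0.0);
      eta[a].assign(Tm1 * S, 0.0);
      rate[a].assign(Tm1 * S, 0.5);
      lrate[a].assign(Tm1 * S, 0.0);
    }
    l1mp.assign(Tm1 * S, 0.0);
    beta_surv[0].assign(4 * S, 0.0);
    beta_surv[1].assign(4 * S, 0.0);
    beff.assign(S, 0.0);
  }

  // pointer into the parameter state for flat parameter j
  double* ptr(int j) {
    int k = kind[j], s = psp[j] - 1, t = pt[j] - 1, a = page[j] - 1;
    switch (k) {
      case 1: return &mu[a];
      case 2: return &sigma_mu[a];
      case 3: return &btrait[a][t];
      case 4: return &alpha[a][s];
      case 5: return (a == 2) ? &beff[s] : &beta_surv[a][4 * s + t];
      case 6: return &sigma_res[a][s];
      default: return &eps[a][t + Tm1 * s];
    }
  }

  static double dnorm_log(double x, double m, double s) {
    double z = (x - m) / s;
    return -0.918938533204672741780329736406 - std::log(s) - 0.5 * z * z;
  }
  static double dlogis_log(double x) {
    double ax = std::fabs(x);
    return -ax - 2.0 * std::log1p(std::exp(-ax));
  }
  static double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

  // refresh cached rate/log-rate entries t0..t1 of vector a for species s
  // from the cached linear predictor
  void refresh_rates(int a, int s, int t0, int t1) {
    for (int t = t0; t <= t1; t++) {
      int i = t + Tm1 * s;
      double r = invlogit(eta[a][i]);
      rate[a][i] = r;
      lrate[a][i] = r > 0 ? std::log(r) : LOG_FLOOR;
      if (a == 2) {
        double q = 1.0 - r;
        l1mp[i] = q > 0 ? std::log(q) : LOG_FLOOR;
      }
    }
  }

  // rebuild the linear predictor and rate caches of vector a, species s
  void rebuild_eta(int a, int s) {
    double base = literal ? mu[a] : alpha[a][s];
    double sc = ncp ? sigma_res[a][s] : 1.0;
    for (int t = 0; t < Tm1; t++) {
      double e = base + sc * eps[a][t + Tm1 * s];
      if (a < 2) {
        const double* b = &beta_surv[a][4 * s];
        for (int k = 0; k < 4; k++) e += b[k] * X(k, t);
      } else {
        e += beff[s] * effort2[t];
      }
      eta[a][t + Tm1 * s] = e;
    }
    refresh_rates(a, s, 0, Tm1 - 1);
  }

  // recompute a single eta entry exactly from the parameters
  void rebuild_eta_entry(int a, int s, int t) {
    double e = (literal ? mu[a] : alpha[a][s]) +
      (ncp ? sigma_res[a][s] : 1.0) * eps[a][t + Tm1 * s];
    if (a < 2) {
      const double* b = &beta_surv[a][4 * s];
      for (int k = 0; k < 4; k++) e += b[k] * X(k, t);
    } else {
      e += beff[s] * effort2[t];
    }
    eta[a][t + Tm1 * s] = e;
    refresh_rates(a, s, t, t);
  }

  void rebuild_all() {
    for (int s = 0; s < S; s++)
      for (int a = 0; a < 3; a++) rebuild_eta(a, s);
  }

  void set_theta(const NumericVector& theta) {
    for (int j = 0; j < P; j++) *ptr(j) = theta[j];
    rebuild_all();
  }

  double trait_mean(int a, int s) const {
    return mu[a] + btrait[a][0] * MB[s] + btrait[a][1] * BSz[s];
  }

  // full log-prior (used at initialization and for kept-draw records)
  double logprior() {
    for (int a = 0; a < 3; a++) {
      if (!literal && (sigma_mu[a] <= 0 || sigma_mu[a] >= SD_UPPER)) return R_NegInf;
      for (int s = 0; s < S; s++) {
        if (a == 0 && !has_juv[s]) continue;
        if (sigma_res[a][s] <= 0 || sigma_res[a][s] >= SD_UPPER) return R_NegInf;
      }
    }
    double lp = 0;
    double ssd = std::sqrt(SLOPE_VAR);
    for (int a = 0; a < 3; a++) lp += dlogis_log(mu[a]);
    if (!literal) {
      lp += 3.0 * std::log(1.0 / SD_UPPER);
      for (int a = 0; a < 2; a++)
        for (int t = 0; t < 2; t++) lp += dnorm_log(btrait[a][t], 0.0, ssd);
      for (int s = 0; s < S; s++) {
        if (has_juv[s]) lp += dnorm_log(alpha[0][s], trait_mean(0, s), sigma_mu[0]);
        lp += dnorm_log(alpha[1][s], trait_mean(1, s), sigma_mu[1]);
        lp += dnorm_log(alpha[2][s], mu[2], sigma_mu[2]);
      }
    }
    for (int s = 0; s < S; s++) {
      for (int a = 0; a < 2; a++) {
        if (a == 0 && !has_juv[s]) continue;
        for (int k = 0; k < 4; k++) lp += dnorm_log(beta_surv[a][4 * s + k], 0.0, ssd);
      }
      lp += dnorm_log(beff[s], 0.0, ssd);
      for (int a = 0; a < 3; a++) {
        if (a == 0 && !has_juv[s]) continue;
        double sg = ncp ? 1.0 : sigma_res[a][s];
        for (int t = 0; t < Tm1; t++)
          lp += dnorm_log(eps[a][t + Tm1 * s], 0.0, sg);
      }
    }
    return lp;
  }

  // prior terms involving flat parameter j only (delta evaluation)
  double logprior_terms(int j) {
    int k = kind[j], s = psp[j] - 1, a = page[j] - 1;
    double ssd = std::sqrt(SLOPE_VAR);
    double lp = 0;
    switch (k) {
      case 1: {
        lp += dlogis_log(mu[a]);
        if (!literal) {
          for (int sq = 0; sq < S; sq++) {
            if (a == 0 && !has_juv[sq]) continue;
            if (a < 2) lp += dnorm_log(alpha[a][sq], trait_mean(a, sq), sigma_mu[a]);
            else lp += dnorm_log(alpha[2][sq], mu[2], sigma_mu[2]);
          }
        }
        return lp;
      }
      case 2: {
        if (sigma_mu[a] <= 0 || sigma_mu[a] >= SD_UPPER) return R_NegInf;
        for (int sq = 0; sq < S; sq++) {
          if (a == 0 && !has_juv[sq]) continue;
          if (a < 2) lp += dnorm_log(alpha[a][sq], trait_mean(a, sq), sigma_mu[a]);
          else lp += dnorm_log(alpha[2][sq], mu[2], sigma_mu[2]);
        }
        return lp;
      }
      case 3: {
        lp += dnorm_log(btrait[a][pt[j] - 1], 0.0, ssd);
        for (int sq = 0; sq < S; sq++) {
          if (a == 0 && !has_juv[sq]) continue;
          lp += dnorm_log(alpha[a][sq], trait_mean(a, sq), sigma_mu[a]);
        }
        return lp;
      }
      case 4:
        if (a < 2) return dnorm_log(alpha[a][s], trait_mean(a, s), sigma_mu[a]);
        return dnorm_log(alpha[2][s], mu[2], sigma_mu[2]);
      case 5:
        return dnorm_log(*ptr(j), 0.0, ssd);
      case 6: {
        double sg = sigma_res[a][s];
        if (sg <= 0 || sg >= SD_UPPER) return R_NegInf;
        if (ncp) return 0.0;          // z-scores carry the residual prior
        for (int t = 0; t < Tm1; t++) lp += dnorm_log(eps[a][t + Tm1 * s], 0.0, sg);
        return lp;
      }
      default:
        return dnorm_log(*ptr(j), 0.0, ncp ? 1.0 : sigma_res[a][s]);
    }
  }

  // multinomial log-likelihood of one m-array given the cached rates;
  // phi/lphi of the first interval come from age class `first_age`
  double array_ll(int s, int first_age, const NumericMatrix& m,
                  const NumericVector& never, const NumericVector& R) {
    const double* phi_f = &rate[first_age][Tm1 * s];
    const double* lphi_f = &lrate[first_age][Tm1 * s];
    const double* phi_a = &rate[1][Tm1 * s];
    const double* lphi_a = &lrate[1][Tm1 * s];
    const double* pp = &rate[2][Tm1 * s];
    const double* lpp = &lrate[2][Tm1 * s];
    const double* lq = &l1mp[Tm1 * s];
    double ll = 0;
    for (int i = 0; i < Tm1; i++) {
      if (R[i] <= 0) continue;
      double run = phi_f[i], lrun = lphi_f[i];
      double tot = 0;
      for (int j = i; j < Tm1; j++) {
        if (j > i) {
          run *= phi_a[j] * (1.0 - pp[j - 1]);
          lrun += lphi_a[j] + lq[j - 1];
        }
        tot += run * pp[j];
        double cnt = m(i, j);
        if (cnt > 0) ll += cnt * std::max(lrun + lpp[j], LOG_FLOOR);
      }
      double nv = never[i];
      if (nv > 0) {
        double pnever = 1.0 - tot;
        ll += nv * (pnever > 0 ? std::log(pnever) : LOG_FLOOR);
      }
    }
    return ll;
  }

  double species_ll(int s) {
    double ll = 0;
    if (any_juv_rel[s]) ll += array_ll(s, 0, m_juv[s], never_juv[s], R_juv[s]);
    if (any_ad_rel[s]) ll += array_ll(s, 1, m_ad[s], never_ad[s], R_ad[s]);
    return ll;
  }

  double total_ll() {
    double ll = 0;
    for (int s = 0; s < S; s++) ll += species_ll(s);
    return ll;
  }

  // apply the eta/rate cache consequences of changing parameter j by
  // `delta`; returns the affected range for potential revert
  // scope: -1 no likelihood effect, s >= 0 species s, -2 all species
  struct Touch { int a, s, t0, t1; bool all_species; };
  Touch apply_delta(int j, double delta) {
    int k = kind[j], s = psp[j] - 1, t = pt[j] - 1, a = page[j] - 1;
    Touch tc{ -1, s, 0, Tm1 - 1, false };
    if (k == 4) {                       // intercept: shift whole vector
      tc.a = a;
      for (int u = 0; u < Tm1; u++) eta[a][u + Tm1 * s] += delta;
      refresh_rates(a, s, 0, Tm1 - 1);
    } else if (k == 5) {
      if (a == 2) {                     // effort slope on recapture
        tc.a = 2;
        for (int u = 0; u < Tm1; u++) eta[2][u + Tm1 * s] += delta * effort2[u];
        refresh_rates(2, s, 0, Tm1 - 1);
      } else {                          // survival slope t = covariate index
        tc.a = a;
        for (int u = 0; u < Tm1; u++) eta[a][u + Tm1 * s] += delta * X(t, u);
        refresh_rates(a, s, 0, Tm1 - 1);
      }
    } else if (k == 7) {                // temporal residual: one entry
      tc.a = a; tc.t0 = tc.t1 = t;
      eta[a][t + Tm1 * s] += (ncp ? sigma_res[a][s] : 1.0) * delta;
      refresh_rates(a, s, t, t);
    } else if (k == 6 && ncp) {         // residual SD rescales the whole vector
      tc.a = a;
      for (int u = 0; u < Tm1; u++)
        eta[a][u + Tm1 * s] += delta * eps[a][u + Tm1 * s];
      refresh_rates(a, s, 0, Tm1 - 1);
    } else if (k == 1 && literal) {     // literal form: mu is the intercept
      tc.a = a; tc.all_species = true;
      for (int sq = 0; sq < S; sq++) {
        for (int u = 0; u < Tm1; u++) eta[a][u + Tm1 * sq] += delta;
        refresh_rates(a, sq, 0, Tm1 - 1);
      }
    }
    return tc;
  }
};

// [[Rcpp::export]]
double cjs_logpost_cpp(NumericVector theta, List data, IntegerVector kind,
                       IntegerVector sp, IntegerVector t, IntegerVector age,
                       bool literal) {
  CjsModel mod(data, kind, sp, t, age, literal);
  mod.set_theta(theta);
  double lp = mod.logprior();
  if (!R_finite(lp)) return R_NegInf;
  return lp + mod.total_ll();
}

// [[Rcpp::export]]
List cjs_mcmc_cpp(NumericVector theta0, List data, IntegerVector kind,
                  IntegerVector sp, IntegerVector t, IntegerVector age,
                  bool literal, int n_iter, int n_burn, int thin,
                  double init_step, double target_accept) {
  CjsModel mod(data, kind, sp, t, age, literal);
  mod.set_theta(theta0);          // theta0 arrives on the centered scale
  // switch to the non-centered residual parameterization internally
  for (int a = 0; a < 3; a++)
    for (int s = 0; s < mod.S; s++)
      for (int u = 0; u < mod.Tm1; u++)
        mod.eps[a][u + mod.Tm1 * s] /= mod.sigma_res[a][s];
  mod.ncp = true;
  mod.rebuild_all();
  int P = mod.P, S = mod.S;
  std::vector<double> lstep(P, std::log(init_step));
  std::vector<double> sll(S);
  for (int s = 0; s < S; s++) sll[s] = mod.species_ll(s);
  if (!R_finite(mod.logprior()))
    stop("initial parameter vector outside prior support");
  int n_kept = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_kept, P);
  NumericVector lp_kept(n_kept);
  std::vector<double> acc_sum(P, 0.0);
  RNGScope rng;
  int kept = 0;
  for (int it = 1; it <= n_iter; it++) {
    double eta_rm = 10.0 / (100.0 + it);  // Robbins-Monro rate, frozen after burn-in
    for (int j = 0; j < P; j++) {
      double* th = mod.ptr(j);
      double old = *th;
      double prior_old = mod.logprior_terms(j);
      double delta_prop = std::exp(lstep[j]) * norm_rand();
      double u = unif_rand();
      *th = old + delta_prop;
      double prior_new = mod.logprior_terms(j);
      double dlp = prior_new - prior_old;
      CjsModel::Touch tc{ -1, 0, 0, 0, false };
      double new_sll = 0, old_sll = 0;
      bool touched = false;
      if (R_finite(dlp)) {
        tc = mod.apply_delta(j, delta_prop);
        touched = tc.a >= 0;
        if (touched) {
          if (tc.all_species) {
            for (int s = 0; s < S; s++) { old_sll += sll[s]; }
            new_sll = mod.total_ll();
          } else {
            old_sll = sll[tc.s];
            new_sll = mod.species_ll(tc.s);
          }
          dlp += new_sll - old_sll;
        }
      }
      double aprob = R_finite(dlp) ? std::min(1.0, std::exp(dlp)) : 0.0;
      if (u < aprob) {
        if (touched) {
          if (tc.all_species) for (int s = 0; s < S; s++) sll[s] = mod.species_ll(s);
          else sll[tc.s] = new_sll;
        }
      } else {
        *th = old;
        if (touched) {                  // rebuild caches exactly from parameters
          if (tc.all_species) {
            for (int sq = 0; sq < S; sq++) mod.rebuild_eta(tc.a, sq);
          } else if (tc.t0 == tc.t1) {
            mod.rebuild_eta_entry(tc.a, tc.s, tc.t0);
          } else {
            mod.rebuild_eta(tc.a, tc.s);
          }
        }
      }
      if (it <= n_burn) lstep[j] += eta_rm * (aprob - target_accept);
      else acc_sum[j] += aprob;
    }
    if (it % 100 == 0) {                // bound incremental-update drift
      mod.rebuild_all();
      for (int s = 0; s < S; s++) sll[s] = mod.species_ll(s);
    }
    if (it > n_burn && (it - n_burn) % thin == 0) {
      // kept draws are reported on the centered scale (eps = sigma * z)
      for (int j = 0; j < P; j++) {
        double v = *mod.ptr(j);
        if (kind[j] == 7)
          v *= mod.sigma_res[age[j] - 1][sp[j] - 1];
        draws(kept, j) = v;
      }
      double tll = 0; for (int s = 0; s < S; s++) tll += sll[s];
      lp_kept[kept] = mod.logprior() + tll;
      kept++;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector acc(P);
  for (int j = 0; j < P; j++) acc[j] = acc_sum[j] / std::max(1, n_iter - n_burn);
  return List::create(_["draws"] = draws, _["logpost"] = lp_kept,
                      _["accept"] = acc,
                      _["log_step"] = NumericVector(lstep.begin(), lstep.end()));
}
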