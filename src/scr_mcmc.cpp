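#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Robust-design open-population SCR sampler with data augmentation.
//
// Latent structure, per augmented individual i (i < n_obs are observed):
//   w[i]   ~ Bernoulli(psi)          inclusion in the superpopulation
//   a[i]   in {1..P}                 last primary alive (all individuals
//                                    present from primary 1; monotone death)
//   s[i][p]                          activity-center path: s[.][0] uniform on
//                                    the state space, then a bivariate normal
//                                    random walk with per-axis SD tau
// Observation: while included and alive, detection at board j in one
// secondary occasion is Bernoulli(lam * exp(-d^2 / (2 sigma^2))).
//
// Updates: psi Gibbs (Beta); w Gibbs (random-scan subsample); a Gibbs
// (categorical over death times); s Gibbs from the Gaussian prior where no
// detection term applies, otherwise random-walk Metropolis; phi, sigma,
// lam, tau random-walk Metropolis with adaptive step sizes during burn-in.
// The detection kernel is truncated at kernel_cut * sigma inside the
// sampler (contributions beyond are below ~1e-6 per board-occasion).

struct Det { int j; int n; };

static inline double runif01() { return unif_rand(); }

// truncated standard-normal-style draw on [lo, hi] via inverse CDF
static inline double rtnorm1(double mean, double sd, double lo, double hi) {
  double plo = R::pnorm(lo, mean, sd, 1, 0);
  double phi = R::pnorm(hi, mean, sd, 1, 0);
  double u = plo + runif01() * (phi - plo);
  if (u <= 0.0) u = 1e-300;
  if (u >= 1.0) u = 1 - 1e-16;
  return R::qnorm(u, mean, sd, 1, 0);
}

class ScrModel {
public:
  int M, n_obs, P, J;
  std::vector<int> Ksec;                    // secondaries per primary
  std::vector<double> bx, by;               // board coordinates
  std::vector<double> frac;                 // interval / 365, length P-1
  double xmin, xmax, ymin, ymax;
  double sigma_max, tau_max, kernel_cut;

  // detections[i*P + p] : boards with counts for individual i, primary p
  std::vector< std::vector<Det> > det;
  std::vector<int> lastdet;                 // last primary (1-based) with a
                                            // detection; 0 for augmented
  std::vector<double> cenx, ceny;           // detection centroid per observed
                                            // individual (anchor for the
                                            // sigma interweaving move)
  // latent state
  std::vector<double> sx, sy;               // M*P
  std::vector<int> w, a;                    // inclusion, death time (1-based)
  double phi, sigma, lam, tau, psi;

  inline int sp(int i, int p) const { return i * P + p; }

  // lookup table for exp(z), z in [-ZMAX, 0]; linear interpolation keeps
  // the relative error below ~1e-6, ample for Metropolis ratios
  static const int NEXP = 8192;
  static constexpr double ZMAX = 13.0;
  std::vector<double> exp_tab;
  void build_exp_tab() {
    exp_tab.resize(NEXP + 2);
    for (int i = 0; i <= NEXP + 1; ++i)
      exp_tab[i] = std::exp(-ZMAX * i / (double)NEXP);
  }
  inline double fexp(double z) const {        // z <= 0
    double u = -z * (NEXP / ZMAX);
    if (u >= NEXP) return 0.0;
    int i = (int)u;
    double f = u - i;
    return exp_tab[i] * (1.0 - f) + exp_tab[i + 1] * f;
  }

  // log(1 - p) with a cheap series for the small p typical of detection
  static inline double log1m(double p) {
    if (p < 0.01) return -p * (1.0 + p * (0.5 + p / 3.0));
    return std::log1p(-p);
  }

  // detection log-likelihood for (i, p) at AC (cx, cy), truncated kernel
  double det_ll(int i, int p, double cx, double cy, double sig,
                double lm) const {
    double cut2 = kernel_cut * sig;
    cut2 *= cut2;
    double inv = 1.0 / (2.0 * sig * sig);
    double K = (double)Ksec[p];
    double ll = 0.0;
    for (int j = 0; j < J; ++j) {
      double dx = cx - bx[j], dy = cy - by[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > cut2) continue;
      double pj = lm * fexp(-d2 * inv);
      ll += K * log1m(pj);
    }
    const std::vector<Det>& dd = det[sp(i, p)];
    for (size_t q = 0; q < dd.size(); ++q) {
      double dx = cx - bx[dd[q].j], dy = cy - by[dd[q].j];
      double d2 = dx * dx + dy * dy;
      double pj = lm * std::exp(-d2 * inv);
      if (pj <= 0) return -1e300;
      double base = (d2 > cut2) ? Ksec[p] * log1m(pj) : 0.0;
      ll += base + dd[q].n * (std::log(pj) - log1m(pj));
    }
    return ll;
  }

  // total detection log-likelihood over included, alive (i, p)
  double total_det_ll(double sig, double lm) const {
    double ll = 0.0;
    for (int i = 0; i < M; ++i) {
      if (!w[i]) continue;
      for (int p = 0; p < a[i]; ++p)
        ll += det_ll(i, p, sx[sp(i, p)], sy[sp(i, p)], sig, lm);
    }
    return ll;
  }

  // survival log-likelihood of the included individuals' death times.
  // Death times of excluded (w = 0) individuals are auxiliary draws,
  // refreshed from the prior every sweep, and are marginalized out here so
  // they cannot throttle phi's mixing.
  double surv_ll(double ph) const {
    if (ph <= 0.0 || ph >= 1.0) return -1e300;
    double ll = 0.0;
    for (int q = 0; q < P - 1; ++q) {
      int n_through = 0, n_die = 0;
      for (int i = 0; i < M; ++i) {
        if (!w[i]) continue;
        if (a[i] > q + 1) ++n_through;
        else if (a[i] == q + 1) ++n_die;
      }
      double sq = std::pow(ph, frac[q]);
      ll += n_through * frac[q] * std::log(ph);
      if (n_die > 0) ll += n_die * std::log1p(-sq);
    }
    return ll;
  }

  // random-walk prior log-density contributions touching s[i][p]
  double rw_prior_ll(int i, int p, double cx, double cy) const {
    double ll = 0.0;
    if (p == 0) {
      if (cx < xmin || cx > xmax || cy < ymin || cy > ymax) return -1e300;
    } else {
      ll += R::dnorm(cx - sx[sp(i, p - 1)], 0.0, tau, 1) +
            R::dnorm(cy - sy[sp(i, p - 1)], 0.0, tau, 1);
    }
    if (p < P - 1) {
      ll += R::dnorm(sx[sp(i, p + 1)] - cx, 0.0, tau, 1) +
            R::dnorm(sy[sp(i, p + 1)] - cy, 0.0, tau, 1);
    }
    return ll;
  }

  // Gibbs draw of s[i][p] from the Gaussian/uniform prior alone
  void gibbs_ac_prior(int i, int p) {
    int k = sp(i, p);
    if (P == 1) {
      sx[k] = xmin + runif01() * (xmax - xmin);
      sy[k] = ymin + runif01() * (ymax - ymin);
      return;
    }
    if (p == 0) {
      sx[k] = rtnorm1(sx[sp(i, 1)], tau, xmin, xmax);
      sy[k] = rtnorm1(sy[sp(i, 1)], tau, ymin, ymax);
    } else if (p == P - 1) {
      sx[k] = R::rnorm(sx[sp(i, p - 1)], tau);
      sy[k] = R::rnorm(sy[sp(i, p - 1)], tau);
    } else {
      double mx = 0.5 * (sx[sp(i, p - 1)] + sx[sp(i, p + 1)]);
      double my = 0.5 * (sy[sp(i, p - 1)] + sy[sp(i, p + 1)]);
      double sdp = tau / std::sqrt(2.0);
      sx[k] = R::rnorm(mx, sdp);
      sy[k] = R::rnorm(my, sdp);
    }
  }
};

// [[Rcpp::export]]
List scr_mcmc_cpp(IntegerVector det_i, IntegerVector det_p,
                  IntegerVector det_j, IntegerVector det_n,
                  int M, int n_obs, int P,
                  IntegerVector K_sec,
                  NumericVector board_x, NumericVector board_y,
                  NumericVector intervals,
                  NumericVector state_xlim, NumericVector state_ylim,
                  double sigma_max, double tau_max,
                  int n_iter, int n_burn, int thin,
                  double kernel_cut, double w_frac,
                  NumericVector inits,
                  NumericVector init_sx, NumericVector init_sy) {
  RNGScope scope;
  ScrModel m;
  m.M = M; m.n_obs = n_obs; m.P = P; m.J = board_x.size();
  m.Ksec.assign(K_sec.begin(), K_sec.end());
  m.bx.assign(board_x.begin(), board_x.end());
  m.by.assign(board_y.begin(), board_y.end());
  m.frac.resize(P > 1 ? P - 1 : 0);
  for (int q = 0; q < P - 1; ++q) m.frac[q] = intervals[q] / 365.0;
  m.xmin = state_xlim[0]; m.xmax = state_xlim[1];
  m.ymin = state_ylim[0]; m.ymax = state_ylim[1];
  m.sigma_max = sigma_max; m.tau_max = tau_max; m.kernel_cut = kernel_cut;
  m.build_exp_tab();

  m.det.assign((size_t)M * P, std::vector<Det>());
  m.lastdet.assign(M, 0);
  for (int r = 0; r < det_i.size(); ++r) {
    Det d; d.j = det_j[r]; d.n = det_n[r];
    m.det[m.sp(det_i[r], det_p[r])].push_back(d);
    if (det_p[r] + 1 > m.lastdet[det_i[r]]) m.lastdet[det_i[r]] = det_p[r] + 1;
  }

  m.cenx.assign(n_obs, 0.0); m.ceny.assign(n_obs, 0.0);
  {
    std::vector<double> cnt(n_obs, 0.0);
    for (int r = 0; r < det_i.size(); ++r) {
      if (det_i[r] < n_obs) {
        m.cenx[det_i[r]] += det_n[r] * board_x[det_j[r]];
        m.ceny[det_i[r]] += det_n[r] * board_y[det_j[r]];
        cnt[det_i[r]] += det_n[r];
      }
    }
    for (int i = 0; i < n_obs; ++i) {
      if (cnt[i] > 0) { m.cenx[i] /= cnt[i]; m.ceny[i] /= cnt[i]; }
    }
  }

  m.phi = inits[0]; m.sigma = inits[1]; m.lam = inits[2];
  m.tau = inits[3]; m.psi = inits[4];
  m.sx.assign(init_sx.begin(), init_sx.end());
  m.sy.assign(init_sy.begin(), init_sy.end());
  m.w.assign(M, 0);
  m.a.assign(M, P);
  for (int i = 0; i < M; ++i) m.w[i] = (i < n_obs) ? 1 : (runif01() < 0.5);

  double step_s = std::max(0.5, m.sigma / 3.0);   // ACs without detections
  double step_d = 0.8;                             // ACs with detections
  double step_t = 1.0;                             // whole-path translation
  double step_sigma = 0.05, step_lam = 0.1, step_phi = 0.5, step_tau = 0.1;
  double step_sc = 0.03;
  double acc_s = 0, try_s = 0, acc_sig = 0, try_sig = 0, acc_lam = 0,
         try_lam = 0, acc_phi = 0, try_phi = 0, acc_tau = 0, try_tau = 0,
         acc_sc = 0, try_sc = 0, acc_d = 0, try_d = 0, acc_t = 0, try_t = 0;

  int n_keep = (n_iter - n_burn) / thin;
  NumericVector out_phi(n_keep), out_sigma(n_keep), out_lam(n_keep),
      out_tau(n_keep), out_psi(n_keep), out_density(n_keep),
      out_nsuper(n_keep);
  NumericVector ac_sum_x((size_t)n_obs * P), ac_sum_y((size_t)n_obs * P);
  double area = (m.xmax - m.xmin) * (m.ymax - m.ymin);

  std::vector<double> z0(P);        // zero-detection ll by primary
  std::vector<double> logw(P);

  for (int it = 0; it < n_iter; ++it) {
    // --- activity centers ---
    for (int i = 0; i < M; ++i) {
      bool inc = m.w[i] == 1;
      for (int p = 0; p < P; ++p) {
        bool has_lik = inc && (p < m.a[i]);
        if (!has_lik) {
          m.gibbs_ac_prior(i, p);
          continue;
        }
        int k = m.sp(i, p);
        bool has_det = !m.det[k].empty();
        double stp = has_det ? step_d : step_s;
        double px = m.sx[k] + norm_rand() * stp;
        double py = m.sy[k] + norm_rand() * stp;
        double lr = m.rw_prior_ll(i, p, px, py);
        if (has_det) try_d += 1; else try_s += 1;
        if (lr > -1e299) {
          lr -= m.rw_prior_ll(i, p, m.sx[k], m.sy[k]);
          lr += m.det_ll(i, p, px, py, m.sigma, m.lam) -
                m.det_ll(i, p, m.sx[k], m.sy[k], m.sigma, m.lam);
          if (std::log(runif01()) < lr) {
            m.sx[k] = px; m.sy[k] = py;
            if (has_det) acc_d += 1; else acc_s += 1;
          }
        }
      }
    }

    // --- whole-path translation (included individuals) ---
    // Rigid shift of an individual's entire AC path: the random-walk
    // steps are unchanged, so only the uniform entry bound and the
    // detection likelihood enter the ratio. This decorrelates paths from
    // the detection pattern far faster than per-primary updates alone.
    // Run on even iterations (alternating with the sigma interweave) to
    // halve the cost of the full-likelihood moves.
    if (it % 2 == 0) for (int i = 0; i < n_obs; ++i) {
      if (!m.w[i]) continue;
      double dxs = norm_rand() * step_t, dys = norm_rand() * step_t;
      double e0x = m.sx[m.sp(i, 0)] + dxs, e0y = m.sy[m.sp(i, 0)] + dys;
      try_t += 1;
      if (e0x < m.xmin || e0x > m.xmax || e0y < m.ymin || e0y > m.ymax)
        continue;
      double lr = 0.0;
      for (int p = 0; p < m.a[i]; ++p) {
        lr += m.det_ll(i, p, m.sx[m.sp(i, p)] + dxs,
                       m.sy[m.sp(i, p)] + dys, m.sigma, m.lam) -
              m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)],
                       m.sigma, m.lam);
      }
      if (std::log(runif01()) < lr) {
        for (int p = 0; p < P; ++p) {
          m.sx[m.sp(i, p)] += dxs;
          m.sy[m.sp(i, p)] += dys;
        }
        acc_t += 1;
      }
    }

    // --- death times (Gibbs over categorical support) ---
    for (int i = 0; i < M; ++i) {
      int lo = std::max(m.lastdet[i], 1);          // 1-based lower bound
      if (lo == P) { m.a[i] = P; continue; }
      bool inc = m.w[i] == 1;
      // zero-detection ll for primaries beyond the last detection
      for (int p = lo; p < P; ++p)                 // p 0-based primary index
        z0[p] = inc ? m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)],
                               m.sigma, m.lam)
                    : 0.0;
      double cum_surv = 0.0;                        // survive intervals < lo
      for (int q = 0; q < lo - 1; ++q) cum_surv += m.frac[q] * std::log(m.phi);
      double cum_z0 = 0.0;
      double best = -1e300;
      for (int av = lo; av <= P; ++av) {            // alive through primary av
        if (av > lo) {
          cum_surv += m.frac[av - 2] * std::log(m.phi);
          cum_z0 += z0[av - 1];
        }
        double lw = cum_surv + cum_z0;
        if (av < P) {
          double sq = std::pow(m.phi, m.frac[av - 1]);
          lw += std::log1p(-sq);
        }
        logw[av - lo] = lw;
        if (lw > best) best = lw;
      }
      double tot = 0.0;
      for (int av = lo; av <= P; ++av) {
        logw[av - lo] = std::exp(logw[av - lo] - best);
        tot += logw[av - lo];
      }
      double u = runif01() * tot, c = 0.0;
      m.a[i] = P;
      for (int av = lo; av <= P; ++av) {
        c += logw[av - lo];
        if (u <= c) { m.a[i] = av; break; }
      }
    }

    // --- inclusion w (random-scan Gibbs over augmented individuals) ---
    for (int i = n_obs; i < M; ++i) {
      if (runif01() > w_frac) continue;
      double L0 = 0.0;
      for (int p = 0; p < m.a[i]; ++p)
        L0 += m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)], m.sigma,
                       m.lam);
      double num = m.psi * std::exp(std::min(L0, 0.0));
      double p1 = num / (num + (1.0 - m.psi));
      m.w[i] = (runif01() < p1) ? 1 : 0;
    }

    // --- psi (conjugate Beta) ---
    int nw = 0;
    for (int i = 0; i < M; ++i) nw += m.w[i];
    m.psi = R::rbeta(1.0 + nw, 1.0 + M - nw);

    // --- phi ---
    {
      double cur = m.surv_ll(m.phi);
      double lg = std::log(m.phi / (1.0 - m.phi)) + norm_rand() * step_phi;
      double prop = 1.0 / (1.0 + std::exp(-lg));
      double lr = m.surv_ll(prop) - cur +
                  std::log(prop * (1 - prop)) -
                  std::log(m.phi * (1 - m.phi));   // logit Jacobian
      try_phi += 1;
      if (std::log(runif01()) < lr) { m.phi = prop; acc_phi += 1; }
    }

    // --- tau: non-centered rescale move ---
    // Propose tau' = c * tau and rescale every path around its entry
    // point, s'_p = s_1 + c (s_p - s_1). The random-walk prior terms
    // cancel exactly against the Jacobian, so acceptance is driven by the
    // detection likelihood of the included, alive individuals; this keeps
    // tau mixing data-driven despite the augmented prior-only paths.
    if (P > 1) {
      double c = std::exp(norm_rand() * step_tau);
      double tprop = m.tau * c;
      try_tau += 1;
      if (tprop < tau_max) {
        double d_ll = 0.0;
        for (int i = 0; i < M; ++i) {
          if (!m.w[i]) continue;
          double ox = m.sx[m.sp(i, 0)], oy = m.sy[m.sp(i, 0)];
          for (int p = 1; p < m.a[i]; ++p) {
            double px = ox + c * (m.sx[m.sp(i, p)] - ox);
            double py = oy + c * (m.sy[m.sp(i, p)] - oy);
            d_ll += m.det_ll(i, p, px, py, m.sigma, m.lam) -
                    m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)],
                             m.sigma, m.lam);
          }
        }
        if (std::log(runif01()) < d_ll + std::log(c)) {
          for (int i = 0; i < M; ++i) {
            double ox = m.sx[m.sp(i, 0)], oy = m.sy[m.sp(i, 0)];
            for (int p = 1; p < P; ++p) {
              m.sx[m.sp(i, p)] = ox + c * (m.sx[m.sp(i, p)] - ox);
              m.sy[m.sp(i, p)] = oy + c * (m.sy[m.sp(i, p)] - oy);
            }
          }
          m.tau = tprop;
          acc_tau += 1;
        }
      }
    }

    // --- sigma and lam ---
    {
      double cur = m.total_det_ll(m.sigma, m.lam);
      double prop = m.sigma * std::exp(norm_rand() * step_sigma);
      try_sig += 1;
      if (prop < sigma_max) {
        double ll = m.total_det_ll(prop, m.lam);
        double lr = ll - cur + std::log(prop) - std::log(m.sigma);
        if (std::log(runif01()) < lr) { m.sigma = prop; cur = ll; acc_sig += 1; }
      }
      double lprop = m.lam * std::exp(norm_rand() * step_lam);
      try_lam += 1;
      if (lprop < 1.0) {
        double ll = m.total_det_ll(m.sigma, lprop);
        double lr = ll - cur + std::log(lprop) - std::log(m.lam);
        if (std::log(runif01()) < lr) { m.lam = lprop; acc_lam += 1; }
      }
    }

    // --- sigma interweaving move ---
    // Jointly propose sigma' = c * sigma and rescale each observed
    // individual's AC path around its detection centroid,
    // s' = m_i + c (s - m_i). This traverses the sigma-vs-AC-spread ridge
    // that axis-aligned updates cross only slowly. Deterministic-transform
    // Metropolis: random-walk prior terms and the Jacobian are accounted
    // for explicitly; augmented individuals keep their ACs (their
    // zero-history likelihood still changes with sigma).
    if (it % 2 == 1) {
      double c = std::exp(norm_rand() * step_sc);
      double sprop = m.sigma * c;
      try_sc += 1;
      if (sprop < sigma_max) {
        double lr = std::log(c);                 // sigma proposal Jacobian
        bool ok = true;
        for (int i = 0; i < M && ok; ++i) {
          if (!m.w[i]) continue;
          if (i < n_obs) {
            double ax = m.cenx[i], ay = m.ceny[i];
            double e0x = ax + c * (m.sx[m.sp(i, 0)] - ax);
            double e0y = ay + c * (m.sy[m.sp(i, 0)] - ay);
            if (e0x < m.xmin || e0x > m.xmax || e0y < m.ymin ||
                e0y > m.ymax) { ok = false; break; }
            // per-individual contribution: Jacobian 2P log c for the 2P
            // rescaled coordinates, plus the random-walk prior ratio
            // exp(-(c^2-1) step^2 / (2 tau^2)) per step dimension (tau is
            // unchanged here, so the normal constants cancel exactly)
            double ss = 0.0;
            for (int p = 1; p < P; ++p) {
              double dx = m.sx[m.sp(i, p)] - m.sx[m.sp(i, p - 1)];
              double dy = m.sy[m.sp(i, p)] - m.sy[m.sp(i, p - 1)];
              ss += dx * dx + dy * dy;
            }
            lr += 2.0 * P * std::log(c) -
                  (c * c - 1.0) * ss / (2.0 * m.tau * m.tau);
            for (int p = 0; p < m.a[i]; ++p) {
              double px = ax + c * (m.sx[m.sp(i, p)] - ax);
              double py = ay + c * (m.sy[m.sp(i, p)] - ay);
              lr += m.det_ll(i, p, px, py, sprop, m.lam) -
                    m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)],
                             m.sigma, m.lam);
            }
          } else {
            for (int p = 0; p < m.a[i]; ++p) {
              lr += m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)],
                             sprop, m.lam) -
                    m.det_ll(i, p, m.sx[m.sp(i, p)], m.sy[m.sp(i, p)],
                             m.sigma, m.lam);
            }
          }
        }
        if (ok && std::log(runif01()) < lr) {
          for (int i = 0; i < n_obs; ++i) {
            if (!m.w[i]) continue;
            double ax = m.cenx[i], ay = m.ceny[i];
            for (int p = 0; p < P; ++p) {
              m.sx[m.sp(i, p)] = ax + c * (m.sx[m.sp(i, p)] - ax);
              m.sy[m.sp(i, p)] = ay + c * (m.sy[m.sp(i, p)] - ay);
            }
          }
          m.sigma = sprop;
          acc_sc += 1;
        }
      }
    }

    // --- burn-in adaptation (clamped so steps cannot collapse) ---
    if (it < n_burn && (it + 1) % 50 == 0) {
      auto tune = [](double step, double acc, double tries, double lo,
                     double hi) {
        if (tries <= 0) return step;
        step *= std::exp(acc / tries - 0.3);
        return std::min(hi, std::max(lo, step));
      };
      step_s = tune(step_s, acc_s, try_s, 0.05, 10.0);
      step_sigma = tune(step_sigma, acc_sig, try_sig, 0.005, 1.0);
      step_lam = tune(step_lam, acc_lam, try_lam, 0.005, 1.0);
      step_phi = tune(step_phi, acc_phi, try_phi, 0.05, 5.0);
      step_tau = tune(step_tau, acc_tau, try_tau, 0.01, 1.0);
      step_sc = tune(step_sc, acc_sc, try_sc, 0.005, 0.5);
      step_d = tune(step_d, acc_d, try_d, 0.05, 10.0);
      step_t = tune(step_t, acc_t, try_t, 0.05, 10.0);
      acc_s = try_s = acc_sig = try_sig = acc_lam = try_lam = 0;
      acc_phi = try_phi = acc_tau = try_tau = 0;
      acc_sc = try_sc = 0; acc_d = try_d = 0; acc_t = try_t = 0;
    }

    // --- store ---
    if (it >= n_burn && (it - n_burn) % thin == 0) {
      int k = (it - n_burn) / thin;
      if (k < n_keep) {
        out_phi[k] = m.phi; out_sigma[k] = m.sigma; out_lam[k] = m.lam;
        out_tau[k] = m.tau; out_psi[k] = m.psi;
        double mean_alive = 0.0;
        for (int p = 0; p < P; ++p) {
          int na = 0;
          for (int i = 0; i < M; ++i)
            if (m.w[i] && m.a[i] > p) ++na;
          mean_alive += na;
        }
        mean_alive /= P;
        out_density[k] = mean_alive / area;
        out_nsuper[k] = nw;
        for (int i = 0; i < n_obs; ++i)
          for (int p = 0; p < P; ++p) {
            ac_sum_x[(size_t)i * P + p] += m.sx[m.sp(i, p)];
            ac_sum_y[(size_t)i * P + p] += m.sy[m.sp(i, p)];
          }
      }
    }
  }

  for (size_t q = 0; q < ac_sum_x.size(); ++q) {
    ac_sum_x[q] /= n_keep;
    ac_sum_y[q] /= n_keep;
  }

  return List::create(
      _["phi"] = out_phi, _["sigma"] = out_sigma, _["lam"] = out_lam,
      _["tau"] = out_tau, _["psi"] = out_psi, _["density"] = out_density,
      _["n_super"] = out_nsuper,
      _["ac_mean_x"] = ac_sum_x, _["ac_mean_y"] = ac_sum_y);
}

// Exact detection log-likelihood for one individual-primary, for
// cross-checking the sampler's likelihood against an independent oracle.
// [[Rcpp::export]]
double scr_detect_loglik_cpp(double cx, double cy, IntegerVector y,
                             int K, NumericVector board_x,
                             NumericVector board_y, double sigma,
                             double lam) {
  double inv = 1.0 / (2.0 * sigma * sigma);
  double ll = 0.0;
  for (int j = 0; j < board_x.size(); ++j) {
    double dx = cx - board_x[j], dy = cy - board_y[j];
    double pj = lam * std::exp(-(dx * dx + dy * dy) * inv);
    ll += y[j] * std::log(pj) + (K - y[j]) * std::log1p(-pj);
  }
  return ll;
}
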