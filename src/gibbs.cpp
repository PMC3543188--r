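#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for
//   y = 1*mu + X b + Z u + W a + Q g + e
// with u ~ N(0, A sigma_u2) handled through the sparse A-inverse,
// normal priors a_i ~ N(0, sigma_s2), g_i ~ N(0, sigma_g2) (mixed model)
// or two-component normal mixtures with Bernoulli(pi) indicators (BVS),
// flat priors on mu and b, and flat (or proper scaled-inv-chisq) priors on
// all variances.  Uses R's RNG so set.seed() on the R side makes chains
// bit-reproducible.  The residual vector is maintained incrementally and
// refreshed from scratch every `refresh` cycles to cap floating-point drift.

static inline double draw_var(double ssq, double k, double nu, double s2) {
  if (nu > 0.0) return (ssq + nu * s2) / R::rchisq(k + nu);
  return ssq / R::rchisq(k - 2.0);
}

// N(m, v) full-conditional draw for one coefficient given x'r (r = partial
// residual) computed incrementally as x'e + xtx * current coefficient.
static inline double draw_coef(double xr, double xtx, double sigma_e2,
                               double prior_prec, double *mean_out) {
  double v = sigma_e2 / (xtx + sigma_e2 * prior_prec);
  double m = v * xr / sigma_e2;
  if (mean_out) *mean_out = m;
  return m + sqrt(v) * norm_rand();
}

// [[Rcpp::export]]
List gibbs_core(NumericVector y,
                NumericMatrix X,          // n x p fixed-effect design (0-col ok)
                IntegerVector zmap,       // 0-based pedigree index per row (len 0 = no PED)
                int n_ped,
                IntegerVector Ai_i, IntegerVector Ai_p, NumericVector Ai_x,
                NumericMatrix W,          // n x ma SNP block (0-col ok)
                NumericMatrix Q,          // n x mg expression block (0-col ok)
                bool mix_a, bool mix_g,
                double pi_a, double pi_g,
                int n_iter, int burn_in, int thin,
                double prior_nu, double prior_s2,
                NumericVector fix_var,    // (su2, ss2, sg2, se2); NA = sample
                int refresh = 100,
                int max_reject = 100) {
  const int n = y.size();
  const int p = X.ncol();
  const int ma = W.ncol();
  const int mg = Q.ncol();
  const bool use_ped = zmap.size() > 0;
  if (use_ped && (int)zmap.size() != n) stop("zmap length must match y");

  const double vy = var(y);
  const double tau0_floor = 1e-10 * vy;

  // rows attached to each pedigree member (an incidence Z; 0 or more rows)
  std::vector<std::vector<int> > ped_rows(use_ped ? n_ped : 0);
  if (use_ped) {
    for (int r = 0; r < n; ++r) {
      if (zmap[r] < 0 || zmap[r] >= n_ped) stop("zmap index out of range");
      ped_rows[zmap[r]].push_back(r);
    }
  }

  // precomputed x'x per column
  std::vector<double> xtx_X(p), xtx_W(ma), xtx_Q(mg);
  for (int j = 0; j < p; ++j) {
    double s = 0; for (int r = 0; r < n; ++r) s += X(r, j) * X(r, j);
    xtx_X[j] = s;
  }
  for (int j = 0; j < ma; ++j) {
    double s = 0; for (int r = 0; r < n; ++r) s += W(r, j) * W(r, j);
    xtx_W[j] = s;
  }
  for (int j = 0; j < mg; ++j) {
    double s = 0; for (int r = 0; r < n; ++r) s += Q(r, j) * Q(r, j);
    xtx_Q[j] = s;
  }

  // state
  double mu = mean(y);
  std::vector<double> b(p, 0.0), u(n_ped, 0.0), a(ma, 0.0), g(mg, 0.0);
  std::vector<int> ga(ma, 1), gg(mg, 1);
  double sigma_u2 = 0.5 * vy;
  double sigma_s2 = ma > 0 ? 0.5 * vy / ma : 1.0;
  double sigma_g2 = mg > 0 ? 0.5 * vy / mg : 1.0;
  double sigma_e2 = vy;
  double tau_a1 = ma > 0 ? 0.5 * vy / std::max(1.0, ma * pi_a) : 1.0;
  double tau_a0 = tau_a1 * 0.01;
  double tau_g1 = mg > 0 ? 0.5 * vy / std::max(1.0, mg * pi_g) : 1.0;
  double tau_g0 = tau_g1 * 0.01;
  const bool fix_su = R_finite(fix_var[0]);
  const bool fix_ss = R_finite(fix_var[1]);
  const bool fix_sg = R_finite(fix_var[2]);
  const bool fix_se = R_finite(fix_var[3]);
  if (fix_su) sigma_u2 = fix_var[0];
  if (fix_ss) { sigma_s2 = fix_var[1]; tau_a1 = fix_var[1]; }
  if (fix_sg) { sigma_g2 = fix_var[2]; tau_g1 = fix_var[2]; }
  if (fix_se) sigma_e2 = fix_var[3];

  // residual e = y - fitted (all effects start at 0 except mu)
  std::vector<double> e(n);
  for (int r = 0; r < n; ++r) e[r] = y[r] - mu;

  const int n_keep = (n_iter - burn_in) / thin;
  if (n_keep <= 0) stop("chain settings leave no retained samples");
  NumericVector smu(n_keep);
  NumericMatrix sb(n_keep, p), su(n_keep, use_ped ? n_ped : 0),
      sa(n_keep, ma), sg(n_keep, mg);
  IntegerMatrix sga(mix_a ? n_keep : 0, mix_a ? ma : 0),
      sgg(mix_g ? n_keep : 0, mix_g ? mg : 0);
  NumericMatrix svar(n_keep, 8);  // su2 ss2 sg2 se2 ta1 ta0 tg1 tg0
  int n_reject_a = 0, n_reject_g = 0, n_carry = 0;

  int keep = 0;
  for (int it = 1; it <= n_iter; ++it) {
    // ---- intercept (flat prior)
    {
      double sr = 0; for (int r = 0; r < n; ++r) sr += e[r];
      double m = mu + sr / n;
      double mu_new = m + sqrt(sigma_e2 / n) * norm_rand();
      double d = mu_new - mu;
      for (int r = 0; r < n; ++r) e[r] -= d;
      mu = mu_new;
    }
    // ---- fixed effects (flat prior)
    for (int j = 0; j < p; ++j) {
      double xr = 0; for (int r = 0; r < n; ++r) xr += X(r, j) * e[r];
      xr += xtx_X[j] * b[j];
      double bn = draw_coef(xr, xtx_X[j], sigma_e2, 0.0, 0);
      double d = bn - b[j];
      if (d != 0) for (int r = 0; r < n; ++r) e[r] -= X(r, j) * d;
      b[j] = bn;
    }
    // ---- polygenic effects via sparse A-inverse (single site)
    if (use_ped) {
      double inv_su = 1.0 / sigma_u2;
      for (int i = 0; i < n_ped; ++i) {
        double dii = 0, off = 0;
        for (int k = Ai_p[i]; k < Ai_p[i + 1]; ++k) {
          int row = Ai_i[k];
          if (row == i) dii = Ai_x[k];
          else off += Ai_x[k] * u[row];
        }
        const std::vector<int> &rows = ped_rows[i];
        double c = (double)rows.size(), sr = 0;
        for (size_t k = 0; k < rows.size(); ++k) sr += e[rows[k]];
        double prec = c / sigma_e2 + dii * inv_su;
        double m = ((sr + c * u[i]) / sigma_e2 - off * inv_su) / prec;
        double un = m + sqrt(1.0 / prec) * norm_rand();
        double d = un - u[i];
        if (d != 0) for (size_t k = 0; k < rows.size(); ++k) e[rows[k]] -= d;
        u[i] = un;
      }
    }
    // ---- SNP coefficients (and indicators under the mixture prior)
    for (int j = 0; j < ma; ++j) {
      double pv;
      if (mix_a) {
        double lo = log(pi_a) - log1p(-pi_a) +
          R::dnorm(a[j], 0.0, sqrt(tau_a1), 1) -
          R::dnorm(a[j], 0.0, sqrt(tau_a0), 1);
        double p1 = 1.0 / (1.0 + exp(-lo));
        ga[j] = unif_rand() < p1 ? 1 : 0;
        pv = ga[j] ? tau_a1 : tau_a0;
      } else pv = sigma_s2;
      double xr = 0; const double *wj = &W(0, j);
      for (int r = 0; r < n; ++r) xr += wj[r] * e[r];
      xr += xtx_W[j] * a[j];
      double an = draw_coef(xr, xtx_W[j], sigma_e2, 1.0 / pv, 0);
      double d = an - a[j];
      if (d != 0) for (int r = 0; r < n; ++r) e[r] -= wj[r] * d;
      a[j] = an;
    }
    // ---- expression coefficients
    for (int j = 0; j < mg; ++j) {
      double pv;
      if (mix_g) {
        double lo = log(pi_g) - log1p(-pi_g) +
          R::dnorm(g[j], 0.0, sqrt(tau_g1), 1) -
          R::dnorm(g[j], 0.0, sqrt(tau_g0), 1);
        double p1 = 1.0 / (1.0 + exp(-lo));
        gg[j] = unif_rand() < p1 ? 1 : 0;
        pv = gg[j] ? tau_g1 : tau_g0;
      } else pv = sigma_g2;
      double xr = 0; const double *qj = &Q(0, j);
      for (int r = 0; r < n; ++r) xr += qj[r] * e[r];
      xr += xtx_Q[j] * g[j];
      double gn = draw_coef(xr, xtx_Q[j], sigma_e2, 1.0 / pv, 0);
      double d = gn - g[j];
      if (d != 0) for (int r = 0; r < n; ++r) e[r] -= qj[r] * d;
      g[j] = gn;
    }
    // ---- variances
    if (use_ped && !fix_su) {
      // u' A^-1 u through the sparse structure
      double ssq = 0;
      for (int i = 0; i < n_ped; ++i)
        for (int k = Ai_p[i]; k < Ai_p[i + 1]; ++k)
          ssq += u[Ai_i[k]] * Ai_x[k] * u[i];
      if (ssq > 0) sigma_u2 = draw_var(ssq, n_ped, prior_nu, prior_s2);
    }
    if (ma > 0 && !fix_ss) {
      if (!mix_a) {
        double ssq = 0; for (int j = 0; j < ma; ++j) ssq += a[j] * a[j];
        if (ssq > 0) sigma_s2 = draw_var(ssq, ma, prior_nu, prior_s2);
      } else {
        double ssq1 = 0, ssq0 = 0; int k1 = 0, k0 = 0;
        for (int j = 0; j < ma; ++j) {
          if (ga[j]) { ssq1 += a[j] * a[j]; ++k1; }
          else { ssq0 += a[j] * a[j]; ++k0; }
        }
        bool can1 = k1 >= 3 && ssq1 > 0, can0 = k0 >= 3 && ssq0 > 0;
        if (!can1 || !can0) ++n_carry;
        double t1 = tau_a1, t0 = tau_a0;
        bool ok = false;
        for (int att = 0; att < max_reject; ++att) {
          t1 = can1 ? draw_var(ssq1, k1, prior_nu, prior_s2) : tau_a1;
          t0 = can0 ? std::max(draw_var(ssq0, k0, prior_nu, prior_s2),
                               tau0_floor)
                    : tau_a0;
          if (t1 > t0) { ok = true; break; }
          ++n_reject_a;
          if (!can1 && !can0) break;
        }
        if (ok) { tau_a1 = t1; tau_a0 = t0; }  // else carry previous pair
      }
    }
    if (mg > 0 && !fix_sg) {
      if (!mix_g) {
        double ssq = 0; for (int j = 0; j < mg; ++j) ssq += g[j] * g[j];
        if (ssq > 0) sigma_g2 = draw_var(ssq, mg, prior_nu, prior_s2);
      } else {
        double ssq1 = 0, ssq0 = 0; int k1 = 0, k0 = 0;
        for (int j = 0; j < mg; ++j) {
          if (gg[j]) { ssq1 += g[j] * g[j]; ++k1; }
          else { ssq0 += g[j] * g[j]; ++k0; }
        }
        bool can1 = k1 >= 3 && ssq1 > 0, can0 = k0 >= 3 && ssq0 > 0;
        if (!can1 || !can0) ++n_carry;
        double t1 = tau_g1, t0 = tau_g0;
        bool ok = false;
        for (int att = 0; att < max_reject; ++att) {
          t1 = can1 ? draw_var(ssq1, k1, prior_nu, prior_s2) : tau_g1;
          t0 = can0 ? std::max(draw_var(ssq0, k0, prior_nu, prior_s2),
                               tau0_floor)
                    : tau_g0;
          if (t1 > t0) { ok = true; break; }
          ++n_reject_g;
          if (!can1 && !can0) break;
        }
        if (ok) { tau_g1 = t1; tau_g0 = t0; }
      }
    }
    if (!fix_se) {
      double ssq = 0; for (int r = 0; r < n; ++r) ssq += e[r] * e[r];
      sigma_e2 = draw_var(ssq, n, prior_nu, prior_s2);
    }
    if (!R_finite(sigma_e2) || sigma_e2 > 1e8 * vy) {
      stop("divergent chain: residual variance overflow at cycle %d "
           "(sigma_e2 = %g); check the model/inputs or lengthen burn-in",
           it, sigma_e2);
    }
    // ---- periodic full residual refresh
    if (it % refresh == 0) {
      for (int r = 0; r < n; ++r) {
        double f = mu;
        for (int j = 0; j < p; ++j) f += X(r, j) * b[j];
        if (use_ped) f += u[zmap[r]];
        for (int j = 0; j < ma; ++j) f += W(r, j) * a[j];
        for (int j = 0; j < mg; ++j) f += Q(r, j) * g[j];
        e[r] = y[r] - f;
      }
    }
    // ---- store
    if (it > burn_in && (it - burn_in) % thin == 0) {
      smu[keep] = mu;
      for (int j = 0; j < p; ++j) sb(keep, j) = b[j];
      if (use_ped) for (int i = 0; i < n_ped; ++i) su(keep, i) = u[i];
      for (int j = 0; j < ma; ++j) sa(keep, j) = a[j];
      for (int j = 0; j < mg; ++j) sg(keep, j) = g[j];
      if (mix_a) for (int j = 0; j < ma; ++j) sga(keep, j) = ga[j];
      if (mix_g) for (int j = 0; j < mg; ++j) sgg(keep, j) = gg[j];
      svar(keep, 0) = sigma_u2; svar(keep, 1) = sigma_s2;
      svar(keep, 2) = sigma_g2; svar(keep, 3) = sigma_e2;
      svar(keep, 4) = tau_a1; svar(keep, 5) = tau_a0;
      svar(keep, 6) = tau_g1; svar(keep, 7) = tau_g0;
      ++keep;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["mu"] = smu, _["b"] = sb, _["u"] = su,
                      _["a"] = sa, _["g"] = sg,
                      _["gamma_a"] = sga, _["gamma_g"] = sgg,
                      _["variances"] = svar,
                      _["n_reject_a"] = n_reject_a,
                      _["n_reject_g"] = n_reject_g,
                      _["n_carry"] = n_carry);
}
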