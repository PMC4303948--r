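#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Thermodynamic activation probability for one set of site strengths.
//
// Sites must be sorted by start. Configurations are subsets of mutually
// non-overlapping sites; each bound repressor (alpha < 0) is additionally
// either neutral or "effective". An effective repressor carries weight
// beta = |alpha| and forbids any other binding within d_r of its midpoint
// (short-range repression / quenching). Homotypic cooperativity omega
// applies between consecutively bound same-TF sites whose edge-to-edge gap
// is <= d_coop. The statistical weight towards the numerator additionally
// multiplies alpha for every bound activator; the basal machinery
// contributes q_btm.
//
// The recursion is over the identity (and effectiveness) of the last bound
// site: because sites are position-sorted, the non-overlap constraint and
// the (contiguous) exclusion zone of an effective repressor only need to be
// checked between consecutive bound sites.
static double activation_one(int ns, const int *tf, const double *st,
                             const double *en, const double *mid,
                             const double *alpha, const double *omega,
                             const double *q, double d_r, double d_coop,
                             double q_btm, double *z0, double *z1,
                             double *n0, double *n1) {
  double Z = 1.0, N = 1.0; // empty configuration
  for (int j = 0; j < ns; ++j) {
    double base = q[j];
    if (!(base > 0.0)) { z0[j] = z1[j] = n0[j] = n1[j] = 0.0; continue; }
    bool isrep = alpha[j] < 0.0;
    double aN = alpha[j] > 0.0 ? alpha[j] : 1.0;
    double beta = isrep ? -alpha[j] : 0.0;
    // bind j as the first bound site
    double zj0 = base, nj0 = base * aN;
    double zj1 = isrep ? base * beta : 0.0;
    double nj1 = isrep ? base * beta * aN : 0.0;
    for (int i = 0; i < j; ++i) {
      if (st[j] < en[i]) continue; // overlap with previous bound site
      double gap = st[j] - en[i];
      double co = (tf[j] == tf[i] && gap <= d_coop) ? omega[tf[j]] : 1.0;
      double w = base * co;
      bool far = (mid[j] - mid[i]) > d_r;
      // from (i, neutral)
      zj0 += z0[i] * w;
      nj0 += n0[i] * w * aN;
      if (isrep && far) { zj1 += z0[i] * w * beta; nj1 += n0[i] * w * beta; }
      // from (i, effective repressor): j must lie outside i's zone
      if (far) {
        zj0 += z1[i] * w;
        nj0 += n1[i] * w * aN;
        if (isrep) { zj1 += z1[i] * w * beta; nj1 += n1[i] * w * beta; }
      }
    }
    z0[j] = zj0; z1[j] = zj1; n0[j] = nj0; n1[j] = nj1;
    Z += zj0 + zj1;
    N += nj0 + nj1;
  }
  double num = q_btm * N;
  return num / (num + Z);
}

// [[Rcpp::export]]
NumericVector cpp_activation(NumericMatrix qmat, IntegerVector tf,
                             NumericVector start, NumericVector end,
                             NumericVector mid, NumericVector alpha,
                             NumericVector omega, double d_r, double d_coop,
                             double q_btm) {
  int ns = qmat.nrow(), nc = qmat.ncol();
  NumericVector out(nc);
  std::vector<double> z0(ns), z1(ns), n0(ns), n1(ns), q(ns);
  for (int c = 0; c < nc; ++c) {
    for (int s = 0; s < ns; ++s) q[s] = qmat(s, c);
    double e = activation_one(ns, ns ? &tf[0] : nullptr,
                              ns ? &start[0] : nullptr, ns ? &end[0] : nullptr,
                              ns ? &mid[0] : nullptr, ns ? &alpha[0] : nullptr,
                              omega.size() ? &omega[0] : nullptr,
                              ns ? q.data() : nullptr, d_r, d_coop, q_btm,
                              z0.data(), z1.data(), n0.data(), n1.data());
    if (!std::isfinite(e))
      stop("activation is non-finite (statistical weights overflow)");
    out[c] = e;
  }
  return out;
}

static double interp_knots(const double *times, int nk, const double *vals,
                           double t) {
  if (nk == 1 || t <= times[0]) return vals[0];
  if (t >= times[nk - 1]) return vals[nk - 1];
  int k = 0;
  while (k < nk - 2 && times[k + 1] < t) ++k;
  double w = (t - times[k]) / (times[k + 1] - times[k]);
  return vals[k] * (1.0 - w) + vals[k + 1] * w;
}

// Explicit Euler integration of the two-layer model over cleavage cycles
// 13 and 14A. mRNA u is driven by the thermodynamic activation E recomputed
// every step from current TF fields (simulated gap proteins feed back;
// external TFs are linearly interpolated from supplied profiles); protein v
// is synthesized from u delayed by tau. Nuclei double at t_mit with
// daughters inheriting parental concentrations; diffusion uses no-flux
// boundaries. External profiles are given at cycle-14 nucleus resolution;
// during cycle 13 each nucleus sees the mean of its two daughters.
// [[Rcpp::export]]
List cpp_simulate(List site_tf, List site_start, List site_end, List site_mid,
                  List site_qbase, NumericMatrix Tmat, NumericVector omega,
                  NumericVector d_r, double d_coop, NumericVector q_btm,
                  NumericVector R_u, NumericVector R_v, NumericMatrix D_u,
                  NumericMatrix D_v, NumericVector lambda_u,
                  NumericVector lambda_v, NumericVector tau,
                  IntegerVector tf_source, IntegerVector tf_ext,
                  NumericVector ext, IntegerVector ext_dim,
                  NumericVector ext_times, double t_mit, double t_end,
                  double dt, int n_nuc13, NumericMatrix u_init,
                  NumericMatrix v_init, NumericVector out_times) {
  if (dt <= 0) stop("dt must be positive");
  int ng = Tmat.nrow(), ntf = Tmat.ncol();
  int n14 = 2 * n_nuc13;
  int nsteps = (int)std::llround(t_end / dt);
  int m_step = (int)std::llround(t_mit / dt);
  int n_ext = ext_dim[0], n_knots = ext_dim[1];
  int nk_nuc = ext_dim[2];
  if (n_ext > 0 && nk_nuc != n14)
    stop("external profiles must be given at cycle-14 nucleus resolution");

  // per-gene site tables
  std::vector<std::vector<int>> stf(ng);
  std::vector<std::vector<double>> sst(ng), sen(ng), smid(ng), sqb(ng),
      salpha(ng);
  int max_ns = 1;
  for (int g = 0; g < ng; ++g) {
    IntegerVector tfv = site_tf[g];
    NumericVector stv = site_start[g], env = site_end[g], mdv = site_mid[g],
                  qbv = site_qbase[g];
    int ns = tfv.size();
    if (ns > max_ns) max_ns = ns;
    stf[g].assign(tfv.begin(), tfv.end());
    sst[g].assign(stv.begin(), stv.end());
    sen[g].assign(env.begin(), env.end());
    smid[g].assign(mdv.begin(), mdv.end());
    sqb[g].assign(qbv.begin(), qbv.end());
    salpha[g].resize(ns);
    for (int s = 0; s < ns; ++s) salpha[g][s] = Tmat(g, tfv[s]);
  }
  std::vector<double> z0(max_ns), z1(max_ns), n0b(max_ns), n1b(max_ns),
      qbuf(max_ns);

  // state and history (history always at cycle-14 width)
  std::vector<std::vector<double>> u(ng, std::vector<double>(n14, 0.0));
  std::vector<std::vector<double>> v(ng, std::vector<double>(n14, 0.0));
  for (int g = 0; g < ng; ++g)
    for (int j = 0; j < n_nuc13; ++j) {
      u[g][j] = u_init(g, j);
      v[g][j] = v_init(g, j);
    }
  std::vector<std::vector<double>> hist_u(
      ng, std::vector<double>((size_t)(nsteps + 1) * n14, 0.0));
  std::vector<std::vector<double>> hist_v(
      ng, std::vector<double>((size_t)(nsteps + 1) * n14, 0.0));

  std::vector<double> conc((size_t)ntf * n14);
  std::vector<double> du(n14), dv(n14), Ebuf(n14);
  std::vector<double> ext_knot(n_knots);

  // exponential (ETD1) treatment of the decay term: the linear decay is
  // integrated exactly over the step, production/diffusion/delay are held
  // constant (forward) over the step; exact for constant drive, and
  // identical to forward Euler when lambda = 0
  std::vector<double> eu(ng), pu(ng), ev(ng), pv(ng);
  for (int g = 0; g < ng; ++g) {
    eu[g] = std::exp(-lambda_u[g] * dt);
    pu[g] = lambda_u[g] > 0 ? -std::expm1(-lambda_u[g] * dt) / lambda_u[g]
                            : dt;
    ev[g] = std::exp(-lambda_v[g] * dt);
    pv[g] = lambda_v[g] > 0 ? -std::expm1(-lambda_v[g] * dt) / lambda_v[g]
                            : dt;
  }

  for (int s = 0; s <= nsteps; ++s) {
    double t = s * dt;
    bool c13 = s < m_step;
    if (s == m_step && m_step > 0) {
      // mitosis: each nucleus is replaced by two daughters
      for (int g = 0; g < ng; ++g)
        for (int j = n_nuc13 - 1; j >= 0; --j) {
          u[g][2 * j] = u[g][2 * j + 1] = u[g][j];
          v[g][2 * j] = v[g][2 * j + 1] = v[g][j];
        }
      c13 = false;
    }
    int nn = c13 ? n_nuc13 : n14;
    // record history at cycle-14 width
    for (int g = 0; g < ng; ++g) {
      double *hu = &hist_u[g][(size_t)s * n14];
      double *hv = &hist_v[g][(size_t)s * n14];
      if (c13)
        for (int j = 0; j < n_nuc13; ++j) {
          hu[2 * j] = hu[2 * j + 1] = u[g][j];
          hv[2 * j] = hv[2 * j + 1] = v[g][j];
        }
      else
        for (int j = 0; j < n14; ++j) { hu[j] = u[g][j]; hv[j] = v[g][j]; }
    }
    if (s == nsteps) break;

    // TF concentration fields at time t
    for (int f = 0; f < ntf; ++f) {
      double *cf = &conc[(size_t)f * n14];
      if (tf_source[f] >= 0) {
        const std::vector<double> &vg = v[tf_source[f]];
        for (int j = 0; j < nn; ++j) cf[j] = vg[j];
      } else {
        int e = tf_ext[f];
        for (int j14 = 0; j14 < n14; ++j14) {
          for (int k = 0; k < n_knots; ++k)
            ext_knot[k] = ext[(size_t)e + (size_t)n_ext * (k + (size_t)n_knots * j14)];
          double val = interp_knots(&ext_times[0], n_knots, ext_knot.data(), t);
          if (c13) {
            if (j14 % 2 == 0) cf[j14 / 2] = 0.5 * val;
            else cf[j14 / 2] += 0.5 * val;
          } else {
            cf[j14] = val;
          }
        }
      }
    }

    int cyc = c13 ? 0 : 1;
    for (int g = 0; g < ng; ++g) {
      int ns = (int)stf[g].size();
      // activation per nucleus
      for (int j = 0; j < nn; ++j) {
        for (int ss = 0; ss < ns; ++ss)
          qbuf[ss] = sqb[g][ss] * conc[(size_t)stf[g][ss] * n14 + j];
        Ebuf[j] = ns == 0
                      ? q_btm[g] / (q_btm[g] + 1.0)
                      : activation_one(ns, stf[g].data(), sst[g].data(),
                                       sen[g].data(), smid[g].data(),
                                       salpha[g].data(), &omega[0],
                                       qbuf.data(), d_r[g], d_coop, q_btm[g],
                                       z0.data(), z1.data(), n0b.data(),
                                       n1b.data());
      }
      // delayed mRNA
      double td = t - tau[g];
      int sd = td <= 0 ? 0 : (int)std::llround(td / dt);
      if (sd > s) sd = s;
      const double *hu = &hist_u[g][(size_t)sd * n14];
      for (int j = 0; j < nn; ++j) {
        double diff_u = 0.0, diff_v = 0.0;
        if (j > 0) {
          diff_u += u[g][j - 1] - u[g][j];
          diff_v += v[g][j - 1] - v[g][j];
        }
        if (j < nn - 1) {
          diff_u += u[g][j + 1] - u[g][j];
          diff_v += v[g][j + 1] - v[g][j];
        }
        double u_del = hu[c13 ? 2 * j : j];
        du[j] = R_u[g] * Ebuf[j] + D_u(g, cyc) * diff_u;
        dv[j] = R_v[g] * u_del + D_v(g, cyc) * diff_v;
      }
      for (int j = 0; j < nn; ++j) {
        u[g][j] = u[g][j] * eu[g] + pu[g] * du[j];
        v[g][j] = v[g][j] * ev[g] + pv[g] * dv[j];
        if (!std::isfinite(u[g][j]) || !std::isfinite(v[g][j]))
          stop("simulation unstable: non-finite concentration at t=%.3f "
               "(gene %d, nucleus %d); reduce dt or parameter magnitudes",
               t + dt, g + 1, j + 1);
      }
    }
  }

  int nout = out_times.size();
  NumericVector u_out((size_t)ng * nout * n14), v_out((size_t)ng * nout * n14);
  u_out.attr("dim") = IntegerVector::create(ng, nout, n14);
  v_out.attr("dim") = IntegerVector::create(ng, nout, n14);
  for (int o = 0; o < nout; ++o) {
    int s = (int)std::llround(out_times[o] / dt);
    if (s < 0) s = 0;
    if (s > nsteps) s = nsteps;
    for (int g = 0; g < ng; ++g)
      for (int j = 0; j < n14; ++j) {
        u_out[g + (size_t)ng * (o + (size_t)nout * j)] =
            hist_u[g][(size_t)s * n14 + j];
        v_out[g + (size_t)ng * (o + (size_t)nout * j)] =
            hist_v[g][(size_t)s * n14 + j];
      }
  }
  return List::create(_["u"] = u_out, _["v"] = v_out,
                      _["n_steps"] = nsteps);
}
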