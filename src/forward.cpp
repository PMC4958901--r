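#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Neural state equation with bilinear and activity-gated (non-linear) terms:
//   dz/dt = (A + sum_j u_j B[j] + sum_k z_k D[k]) z + C u
// u is piecewise constant on the microtime grid (one row per bin); states are
// stored at bin-start times; fixed-step RK4 within each bin. B and D are
// almost empty in this model space, so they are carried as sparse triplets.
// ---------------------------------------------------------------------------

struct Triplet { int i, j, k; double v; };   // k = input channel (B) / gating region (D)

struct NeuralSys {
  int n, m;
  std::vector<double> A;        // n x n column-major
  std::vector<double> C;        // n x m column-major
  std::vector<Triplet> B, D;
  std::vector<double> Abar, Cu; // per-bin effective matrix and drive
  void set_bin(const double *u) {
    Abar = A;
    for (const Triplet &t : B) Abar[t.i + n * t.j] += u[t.k] * t.v;
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int c = 0; c < m; ++c) acc += C[i + n * c] * u[c];
      Cu[i] = acc;
    }
  }
  inline void deriv(const double *z, double *dz) const {
    for (int i = 0; i < n; ++i) {
      double acc = Cu[i];
      for (int j = 0; j < n; ++j) acc += Abar[i + n * j] * z[j];
      dz[i] = acc;
    }
    for (const Triplet &t : D) dz[t.i] += t.v * z[t.k] * z[t.j];
  }
};

// integrate neural states over the full grid; returns false on divergence
static bool integrate_neural(NeuralSys &sys, const double *u, int nbin,
                             double dt, const double *z0, double bound,
                             double *zout, int &div_bin) {
  const int n = sys.n, m = sys.m;
  std::vector<double> z(z0, z0 + n), k1(n), k2(n), k3(n), k4(n), tmp(n),
      uc(m);
  for (int t = 0; t < nbin; ++t) {
    for (int i = 0; i < n; ++i) zout[t + (size_t)nbin * i] = z[i];
    for (int c = 0; c < m; ++c) uc[c] = u[t + (size_t)nbin * c];
    sys.set_bin(uc.data());
    sys.deriv(z.data(), k1.data());
    for (int i = 0; i < n; ++i) tmp[i] = z[i] + 0.5 * dt * k1[i];
    sys.deriv(tmp.data(), k2.data());
    for (int i = 0; i < n; ++i) tmp[i] = z[i] + 0.5 * dt * k2[i];
    sys.deriv(tmp.data(), k3.data());
    for (int i = 0; i < n; ++i) tmp[i] = z[i] + dt * k3[i];
    sys.deriv(tmp.data(), k4.data());
    for (int i = 0; i < n; ++i) {
      z[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (!std::isfinite(z[i]) || std::fabs(z[i]) > bound) {
        div_bin = t + 1;
        return false;
      }
    }
  }
  return true;
}

// ---------------------------------------------------------------------------
// Balloon-Windkessel observation model per region, driven by the neural
// series (piecewise constant per bin). States: vasodilatory signal s, inflow
// f, venous volume v, deoxyhaemoglobin q. BOLD is read out at sample_bins
// (1-based bin-start indices) in percent signal change.
// ---------------------------------------------------------------------------

struct BalloonConst {
  double gamma, alpha, E0, V0, theta0, r0, TE;
};

static inline void balloon_deriv(const double *x, double z, double kappa,
                                 double gamma, double itau, double ialpha,
                                 double E0, double log1mE0, double *dx) {
  const double s = x[0], f = x[1], v = x[2], q = x[3];
  const double fv = std::exp(ialpha * std::log(v));   // outflow v^(1/alpha)
  const double Ef = 1.0 - std::exp(log1mE0 / f);      // O2 extraction
  dx[0] = z - kappa * s - gamma * (f - 1.0);
  dx[1] = s;
  dx[2] = (f - fv) * itau;
  dx[3] = (f * Ef / E0 - fv * q / v) * itau;
}

static bool integrate_balloon(const double *z, int nbin, int n, double dt,
                              const double *kappa, const double *tau,
                              const double *epsilon, const BalloonConst &bc,
                              const int *sample_bins, int nvol, double *yout) {
  const double ialpha = 1.0 / bc.alpha;
  const double log1mE0 = std::log(1.0 - bc.E0);
  const double k1 = 4.3 * bc.theta0 * bc.E0 * bc.TE;
  for (int r = 0; r < n; ++r) {
    double x[4] = {0.0, 1.0, 1.0, 1.0};
    double d1[4], d2[4], d3[4], d4[4], tx[4];
    const double kap = kappa[r], itau = 1.0 / tau[r];
    const double k2 = epsilon[r] * bc.r0 * bc.E0 * bc.TE;
    const double k3 = 1.0 - epsilon[r];
    int isamp = 0;
    for (int t = 0; t <= nbin; ++t) {
      while (isamp < nvol && sample_bins[isamp] == t + 1) {
        yout[isamp + (size_t)nvol * r] =
            100.0 * bc.V0 * (k1 * (1.0 - x[3]) + k2 * (1.0 - x[3] / x[2]) +
                             k3 * (1.0 - x[2]));
        ++isamp;
      }
      if (t == nbin) break;
      // neural drive interpolated linearly across the bin (RK4 stage times)
      const double z0c = z[t + (size_t)nbin * r];
      const double z1c = (t + 1 < nbin) ? z[t + 1 + (size_t)nbin * r] : z0c;
      const double zmc = 0.5 * (z0c + z1c);
      balloon_deriv(x, z0c, kap, bc.gamma, itau, ialpha, bc.E0, log1mE0, d1);
      for (int i = 0; i < 4; ++i) tx[i] = x[i] + 0.5 * dt * d1[i];
      balloon_deriv(tx, zmc, kap, bc.gamma, itau, ialpha, bc.E0, log1mE0, d2);
      for (int i = 0; i < 4; ++i) tx[i] = x[i] + 0.5 * dt * d2[i];
      balloon_deriv(tx, zmc, kap, bc.gamma, itau, ialpha, bc.E0, log1mE0, d3);
      for (int i = 0; i < 4; ++i) tx[i] = x[i] + dt * d3[i];
      balloon_deriv(tx, z1c, kap, bc.gamma, itau, ialpha, bc.E0, log1mE0, d4);
      for (int i = 0; i < 4; ++i) {
        x[i] += dt / 6.0 * (d1[i] + 2.0 * d2[i] + 2.0 * d3[i] + d4[i]);
        if (!std::isfinite(x[i])) return false;
      }
      if (x[1] < 1e-6) x[1] = 1e-6;   // inflow and volume must stay positive
      if (x[2] < 1e-6) x[2] = 1e-6;
    }
  }
  return true;
}

// [[Rcpp::export]]
List cpp_simulate_neural(NumericMatrix A, NumericVector Bflat, NumericMatrix C,
                         NumericVector Dflat, NumericMatrix u, double dt,
                         NumericVector z0, double bound) {
  const int n = A.nrow();
  const int m = u.ncol();
  const int nbin = u.nrow();
  NeuralSys sys;
  sys.n = n; sys.m = m;
  sys.A.assign(A.begin(), A.end());
  sys.C.assign(C.begin(), C.end());
  sys.Abar.resize((size_t)n * n);
  sys.Cu.resize(n);
  for (int c = 0; c < m; ++c)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double v = Bflat[(size_t)c * n * n + i + (size_t)n * j];
        if (v != 0.0) sys.B.push_back({i, j, c, v});
      }
  for (int k = 0; k < n; ++k)
    for (int j = 0; j < n; ++j)
      for (int i = 0; i < n; ++i) {
        double v = Dflat[(size_t)k * n * n + i + (size_t)n * j];
        if (v != 0.0) sys.D.push_back({i, j, k, v});
      }
  NumericMatrix z(nbin, n);
  int div_bin = 0;
  bool ok = integrate_neural(sys, REAL(u), nbin, dt, REAL(z0), bound,
                             REAL(z), div_bin);
  return List::create(_["z"] = z, _["diverged"] = !ok, _["bin"] = div_bin);
}

// [[Rcpp::export]]
List cpp_simulate_bold(NumericMatrix z, double dt, NumericVector kappa,
                       double gamma, NumericVector tau, double alpha,
                       double E0, double V0, NumericVector epsilon,
                       double theta0, double r0, double TE,
                       IntegerVector sample_bins) {
  const int nbin = z.nrow();
  const int n = z.ncol();
  const int nvol = sample_bins.size();
  BalloonConst bc{gamma, alpha, E0, V0, theta0, r0, TE};
  NumericMatrix y(nvol, n);
  bool ok = integrate_balloon(REAL(z), nbin, n, dt, REAL(kappa), REAL(tau),
                              REAL(epsilon), bc, INTEGER(sample_bins), nvol,
                              REAL(y));
  return List::create(_["y"] = y, _["diverged"] = !ok);
}

// ---------------------------------------------------------------------------
// Packed-parameter fast path for the inversion: maps the packed vector theta
// onto the model matrices via an index table (block codes: 0 self, 1 A, 2 B,
// 3 C, 4 D, 5 decay, 6 transit, 7 epsilon; i/j/k are 1-based matrix indices)
// and predicts the BOLD series, optionally with the full forward-difference
// Jacobian computed without leaving C++.
// ---------------------------------------------------------------------------

struct PackedModel {
  int n, m, nbin, nvol;
  NeuralSys sys;
  std::vector<double> kappa, tau, epsilon;
  BalloonConst bc;
  const double *u;
  double dt, bound;
  const int *sample_bins;
  std::vector<double> zbuf;

  void apply_theta(const double *theta, const int *block, const int *ii,
                   const int *jj, const int *kk, int p,
                   double decay0, double transit0, double epsilon0) {
    std::fill(sys.A.begin(), sys.A.end(), 0.0);
    std::fill(sys.C.begin(), sys.C.end(), 0.0);
    sys.B.clear();
    sys.D.clear();
    kappa.assign(n, decay0);
    tau.assign(n, transit0);
    epsilon.assign(n, epsilon0);
    for (int q = 0; q < p; ++q) {
      const int i = ii[q] - 1, j = jj[q] - 1, k = kk[q] - 1;
      const double v = theta[q];
      switch (block[q]) {
      case 0: sys.A[i + (size_t)n * j] = -0.5 * std::exp(v); break;
      case 1: sys.A[i + (size_t)n * j] = v; break;
      case 2: if (v != 0.0) sys.B.push_back({i, j, k, v}); break;
      case 3: sys.C[i + (size_t)n * j] = v; break;
      case 4: if (v != 0.0) sys.D.push_back({i, j, k, v}); break;
      case 5: kappa[i] = decay0 * std::exp(v); break;
      case 6: tau[i] = transit0 * std::exp(v); break;
      case 7: epsilon[i] = epsilon0 * std::exp(v); break;
      }
    }
  }

  bool predict(double *yout) {
    int div_bin = 0;
    std::vector<double> z0(n, 0.0);
    if (!integrate_neural(sys, u, nbin, dt, z0.data(), bound, zbuf.data(),
                          div_bin))
      return false;
    return integrate_balloon(zbuf.data(), nbin, n, dt, kappa.data(),
                             tau.data(), epsilon.data(), bc, sample_bins,
                             nvol, yout);
  }
};

static PackedModel make_packed(int n, NumericMatrix u, double dt,
                               IntegerVector sample_bins, List constants,
                               double bound) {
  PackedModel pm;
  pm.n = n;
  pm.m = u.ncol();
  pm.nbin = u.nrow();
  pm.nvol = sample_bins.size();
  pm.sys.n = n; pm.sys.m = pm.m;
  pm.sys.A.assign((size_t)n * n, 0.0);
  pm.sys.C.assign((size_t)n * pm.m, 0.0);
  pm.sys.Abar.resize((size_t)n * n);
  pm.sys.Cu.resize(n);
  pm.bc = BalloonConst{as<double>(constants["gamma"]), as<double>(constants["alpha"]),
                       as<double>(constants["E0"]), as<double>(constants["V0"]),
                       as<double>(constants["theta0"]), as<double>(constants["r0"]),
                       as<double>(constants["TE"])};
  pm.u = REAL(u);
  pm.dt = dt;
  pm.bound = bound;
  pm.sample_bins = INTEGER(sample_bins);
  pm.zbuf.resize((size_t)pm.nbin * n);
  return pm;
}

// [[Rcpp::export]]
List cpp_predict_packed(NumericVector theta, IntegerVector block,
                        IntegerVector ii, IntegerVector jj, IntegerVector kk,
                        int n, NumericMatrix u, double dt,
                        IntegerVector sample_bins, List constants,
                        NumericVector hemo0, double bound) {
  PackedModel pm = make_packed(n, u, dt, sample_bins, constants, bound);
  pm.apply_theta(REAL(theta), INTEGER(block), INTEGER(ii), INTEGER(jj),
                 INTEGER(kk), theta.size(), hemo0[0], hemo0[1], hemo0[2]);
  NumericMatrix y(pm.nvol, n);
  bool ok = pm.predict(REAL(y));
  return List::create(_["y"] = y, _["diverged"] = !ok);
}

// [[Rcpp::export]]
List cpp_jacobian_packed(NumericVector theta, IntegerVector block,
                         IntegerVector ii, IntegerVector jj, IntegerVector kk,
                         int n, NumericMatrix u, double dt,
                         IntegerVector sample_bins, List constants,
                         NumericVector hemo0, double bound, double h) {
  PackedModel pm = make_packed(n, u, dt, sample_bins, constants, bound);
  const int p = theta.size();
  const size_t ny = (size_t)pm.nvol * n;
  std::vector<double> th(theta.begin(), theta.end());
  NumericMatrix y0(pm.nvol, n);
  pm.apply_theta(th.data(), INTEGER(block), INTEGER(ii), INTEGER(jj),
                 INTEGER(kk), p, hemo0[0], hemo0[1], hemo0[2]);
  if (!pm.predict(REAL(y0)))
    return List::create(_["diverged"] = true, _["param"] = -1);
  NumericMatrix J(ny, p);
  std::vector<double> y1(ny);
  std::vector<double> zbase(pm.zbuf);          // neural states at theta
  std::vector<double> kap0(pm.kappa), tau0(pm.tau), eps0(pm.epsilon);
  std::vector<double> yreg(pm.nvol);
  for (int q = 0; q < p; ++q) {
    const int blk = INTEGER(block)[q];
    double saved = th[q];
    if (blk >= 5) {
      // haemodynamic parameter of one region: the neural states are
      // untouched and every other region's sensitivity is exactly zero
      const int r = INTEGER(ii)[q] - 1;
      double kap = kap0[r], tu = tau0[r], ep = eps0[r];
      const double v = saved + h;
      if (blk == 5) kap = hemo0[0] * std::exp(v);
      else if (blk == 6) tu = hemo0[1] * std::exp(v);
      else ep = hemo0[2] * std::exp(v);
      const double *zcol = zbase.data() + (size_t)pm.nbin * r;
      if (!integrate_balloon(zcol, pm.nbin, 1, dt, &kap, &tu, &ep, pm.bc,
                             pm.sample_bins, pm.nvol, yreg.data()))
        return List::create(_["diverged"] = true, _["param"] = q + 1);
      const double *y0r = REAL(y0) + (size_t)pm.nvol * r;
      for (int t = 0; t < pm.nvol; ++t)
        J(t + (size_t)pm.nvol * r, q) = (yreg[t] - y0r[t]) / h;
      continue;
    }
    th[q] = saved + h;
    pm.apply_theta(th.data(), INTEGER(block), INTEGER(ii), INTEGER(jj),
                   INTEGER(kk), p, hemo0[0], hemo0[1], hemo0[2]);
    if (pm.predict(y1.data())) {
      for (size_t r = 0; r < ny; ++r) J(r, q) = (y1[r] - REAL(y0)[r]) / h;
    } else {
      th[q] = saved - h;    // one-sided step into instability: go backwards
      pm.apply_theta(th.data(), INTEGER(block), INTEGER(ii), INTEGER(jj),
                     INTEGER(kk), p, hemo0[0], hemo0[1], hemo0[2]);
      if (!pm.predict(y1.data()))
        return List::create(_["diverged"] = true, _["param"] = q + 1);
      for (size_t r = 0; r < ny; ++r) J(r, q) = (REAL(y0)[r] - y1[r]) / h;
    }
    th[q] = saved;
  }
  return List::create(_["y"] = y0, _["J"] = J, _["diverged"] = false);
}
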