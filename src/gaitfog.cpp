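#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Adaptive Hopf CPG: fixed-step RK4 integrator for the three-pool network.
// State layout (matches cpg_pack() on the R side): for each pool in order
// hip(2), knee1(3), knee2(3): p[n], q[n], omega[n], alpha[n], psi[n], psiG.
// ---------------------------------------------------------------------------

static const int POOL_N[3] = {2, 3, 3};
static const int POOL_OFF[3] = {0, 11, 27};
static const int NSTATE = 43;
// pool constants: xi, mu, eps, tau  (hip; knees)
static const double XI[3] = {8.0, 12.0, 12.0};
static const double MU[3] = {1.0, 1.0, 1.0};
static const double EPS[3] = {0.9, 0.3, 0.3};
static const double TAU[3] = {2.0, 1.0, 1.0};

static inline double iphase(double p, double q) {
  double z = std::sqrt(p * p + q * q);
  double c = -q / z;
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return (p >= 0 ? 1.0 : -1.0) * std::acos(c);
}

// teaching value at time t (periodic linear interpolation), pool j
static inline double teach_at(const double* tab, int T, int j, double t) {
  double s = std::fmod(t, 1.0);
  if (s < 0) s += 1.0;
  s *= T;
  int i0 = (int)std::floor(s);
  double fr = s - i0;
  i0 %= T;
  int i1 = (i0 + 1) % T;
  return (1.0 - fr) * tab[j * T + i0] + fr * tab[j * T + i1];
}

// full-network RHS; tab == NULL -> free run (no forcing)
static void cpg_deriv(double t, const double* y, double* dy,
                      const double* tab, int T, double eta_a,
                      double* Fout /* may be NULL; length 3 */) {
  double ref_phase = 0.0;
  bool have_ref = false;
  for (int j = 0; j < 3; ++j) {
    int n = POOL_N[j], off = POOL_OFF[j];
    const double* p = y + off;
    const double* q = p + n;
    const double* w = q + n;
    const double* a = w + n;
    const double* psi = a + n;
    double psiG = y[off + 5 * n];

    double Q = 0.0;
    for (int i = 0; i < n; ++i) Q += a[i] * p[i];
    double F = 0.0;
    if (tab) F = teach_at(tab, T, j, t) - Q;
    if (Fout) Fout[j] = F;

    double* dp = dy + off;
    double* dq = dp + n;
    double* dw = dq + n;
    double* da = dw + n;
    double* dpsi = da + n;

    double th0_ = iphase(p[0] == 0.0 && q[0] == 0.0 ? 1e-12 : p[0], q[0]);
    double th0 = 0.0;
    for (int i = 0; i < n; ++i) {
      double pi_ = p[i], qi = q[i];
      double z2 = pi_ * pi_ + qi * qi;
      if (z2 < 1e-24) { pi_ += 1e-12; z2 = pi_ * pi_ + qi * qi; }
      double z = std::sqrt(z2);
      double th = iphase(pi_, qi);
      if (i == 0) th0 = th;
      double relax = XI[j] * (MU[j] - z2);
      double coupling;
      if (i == 0) coupling = have_ref
        ? TAU[j] * std::sin(ref_phase - psiG - th) : 0.0;
      else coupling = TAU[j] * std::sin(w[i] / w[0] * th0_ - psi[i] - th);
      dp[i] = relax * pi_ - w[i] * qi + EPS[j] * F + coupling;
      dq[i] = relax * qi + w[i] * pi_;
      dw[i] = -EPS[j] * F * qi / z;
      da[i] = eta_a * pi_ * F;
      dpsi[i] = (i == 0) ? 0.0
        : std::sin(w[i] / w[0] * th0 - th - psi[i]);
    }
    dy[off + 5 * n] = have_ref ? std::sin(ref_phase - th0 - psiG) : 0.0;
    ref_phase = th0;
    have_ref = true;
  }
}

static void rk4_step(double t, double* y, double dt,
                     const double* tab, int T, double eta_a) {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  cpg_deriv(t, y, k1, tab, T, eta_a, NULL);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  cpg_deriv(t + 0.5 * dt, tmp, k2, tab, T, eta_a, NULL);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  cpg_deriv(t + 0.5 * dt, tmp, k3, tab, T, eta_a, NULL);
  for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + dt * k3[i];
  cpg_deriv(t + dt, tmp, k4, tab, T, eta_a, NULL);
  for (int i = 0; i < NSTATE; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// [[Rcpp::export]]
List cpg_train_cpp(NumericVector state0, NumericMatrix teach,
                   int max_cycles, double tolerance, double eta_a, double dt) {
  if (state0.size() != NSTATE) stop("bad state length");
  int T = teach.nrow();
  std::vector<double> tab(3 * T);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < T; ++i) tab[j * T + i] = teach(i, j);
  int steps = (int)std::lround(1.0 / dt);
  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> rms;
  bool converged = false;
  double Fcur[3], dyscratch[NSTATE];
  int cyc = 0;
  for (cyc = 0; cyc < max_cycles; ++cyc) {
    double ss[3] = {0.0, 0.0, 0.0};
    for (int s = 0; s < steps; ++s) {
      double t = (double)s * dt;
      cpg_deriv(t, y.data(), dyscratch, tab.data(), T, eta_a, Fcur);
      for (int j = 0; j < 3; ++j) ss[j] += Fcur[j] * Fcur[j];
      rk4_step(t, y.data(), dt, tab.data(), T, eta_a);
    }
    bool ok = true;
    for (int j = 0; j < 3; ++j) {
      double r = std::sqrt(ss[j] / steps);
      rms.push_back(r);
      if (r >= tolerance) ok = false;
    }
    if (ok) { converged = true; ++cyc; break; }
    if (cyc % 64 == 0) Rcpp::checkUserInterrupt();
  }
  int ncyc = (int)(rms.size() / 3);
  NumericMatrix rms_mat(ncyc, 3);
  for (int c = 0; c < ncyc; ++c)
    for (int j = 0; j < 3; ++j) rms_mat(c, j) = rms[c * 3 + j];
  return List::create(_["state"] = NumericVector(y.begin(), y.end()),
                      _["rms"] = rms_mat,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
List cpg_free_run_cpp(NumericVector state0, int n_steps, double dt) {
  if (state0.size() != NSTATE) stop("bad state length");
  std::vector<double> y(state0.begin(), state0.end());
  NumericMatrix states(n_steps, NSTATE);
  NumericMatrix output(n_steps, 3);
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < NSTATE; ++i) states(s, i) = y[i];
    for (int j = 0; j < 3; ++j) {
      int n = POOL_N[j], off = POOL_OFF[j];
      double Q = 0.0;
      for (int i = 0; i < n; ++i) Q += y[off + 3 * n + i] * y[off + i];
      output(s, j) = Q;
    }
    rk4_step((double)s * dt, y.data(), dt, NULL, 0, 0.0);
  }
  return List::create(_["states"] = states, _["output"] = output,
                      _["final"] = NumericVector(y.begin(), y.end()));
}

// one-cycle integration used to cross-check against the R reference RHS
// [[Rcpp::export]]
NumericMatrix cpg_integrate_cpp(NumericVector state0, NumericMatrix teach,
                                int n_steps, double eta_a, double dt) {
  int T = teach.nrow();
  std::vector<double> tab(3 * T);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < T; ++i) tab[j * T + i] = teach(i, j);
  std::vector<double> y(state0.begin(), state0.end());
  NumericMatrix states(n_steps + 1, NSTATE);
  for (int i = 0; i < NSTATE; ++i) states(0, i) = y[i];
  for (int s = 0; s < n_steps; ++s) {
    rk4_step((double)s * dt, y.data(), dt, tab.data(), T, eta_a);
    for (int i = 0; i < NSTATE; ++i) states(s + 1, i) = y[i];
  }
  return states;
}

// ---------------------------------------------------------------------------
// Doorway-approach episode runner (the fast engine behind train_agent /
// simulate). Semantics replicate the R reference engine run_pass_r(); the
// two are held equal by tests. Uses the R random stream: one uniform for the
// start position, then two uniforms per step for the exploration draw.
// ---------------------------------------------------------------------------

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List run_pass_cpp(NumericVector W, bool learn, List pars, List geom,
                  List loco, int max_steps, int n_sectors, double fov,
                  int orient_mode) {
  // orient_mode: 0 = displacement-following gaze, 1 = door-facing gaze
  const double A_G = pars["A_G"], A_N = pars["A_N"], A_E = pars["A_E"];
  const double lG = pars["lambda_G"], lN = pars["lambda_N"];
  const double sigma = pars["sigma"], gamma = pars["gamma"];
  const double eta = pars["eta"];
  const int mode = pars["mode"];             // 0 control, 1 pd_off, 2 pd_on
  const double dlim = pars["delta_lim"], dmed = pars["delta_med"];
  const bool clamp_sw = pars["clamp_switching"];

  const double x_max = geom["x_max"], y_door = geom["y_door"];
  const double y_start = geom["y_start"], d_pos = geom["d_pos"];
  const double radius = geom["agent_radius"];
  const bool wall_terminal = geom["wall_terminal"];
  const double half = x_max - radius;
  const double slot = d_pos - radius;

  const double e2 = loco["e2"], e3 = loco["e3"], leg = loco["leg"];
  const double A_k = loco["A_k"], c_k = loco["c_k"];
  const bool step_mode = loco["step_mode"];
  const double beps = loco["backward_eps"];
  const bool bhold = loco["backward_hold"];
  const double dx0 = loco["dx0"];

  // sector geometry
  std::vector<double> cth(n_sectors), sth(n_sectors);
  for (int i = 0; i < n_sectors; ++i) {
    double th = (-fov / 2.0 + (i + 0.5) * fov / n_sectors) * M_PI / 180.0;
    cth[i] = std::cos(th);
    sth[i] = std::sin(th);
  }
  std::vector<int> phi(n_sectors), phi2(n_sectors);
  std::vector<double> Wl(W.begin(), W.end());

  RNGScope scope;

  auto view = [&](double x, double y, double ox, double oy,
                  std::vector<int>& out) {
    for (int i = 0; i < n_sectors; ++i) {
      double rx = cth[i] * ox + sth[i] * oy;
      double ry = -sth[i] * ox + cth[i] * oy;
      if (ry <= 0) { out[i] = 0; continue; }
      double xd = (y_door - y) * rx / ry + x;
      out[i] = (xd >= -d_pos && xd <= d_pos) ? 1 : 0;
    }
  };
  auto valueof = [&](const std::vector<int>& ph) {
    double s = 0.0;
    for (int i = 0; i < n_sectors; ++i) if (ph[i]) s += Wl[i];
    return std::tanh(s);
  };

  double u = unif_rand();
  double x = -half + 2.0 * half * u, y = y_start;
  double rox = 0.0 - x, roy = y_door - y;
  double nrm = std::sqrt(rox * rox + roy * roy);
  rox /= nrm; roy /= nrm;
  double dxx = dx0 * rox, dxy = dx0 * roy;

  view(x, y, rox, roy, phi);
  double V = valueof(phi);
  double sw = 0.0;

  NumericMatrix rec(max_steps, 8);
  int outcome = 0;  // 0 max_steps, 1 pass, 2 post, 3 wall(terminal)
  int t;
  for (t = 0; t < max_steps; ++t) {
    double chix = unif_rand() - 0.5;
    double chiy = unif_rand() - 0.5;
    double g = std::exp(-sw * sw / (sigma * sigma));
    double coef = A_G * sigm(lG * sw) - A_N * sigm(lN * sw);
    dxx = coef * dxx + A_E * g * chix;
    dxy = coef * dxy + A_E * g * chiy;
    double nv = std::sqrt(dxx * dxx + dxy * dxy);
    double vhx, vhy, k;
    if (nv < 1e-12) { vhx = rox; vhy = roy; k = 0.0; }
    else { vhx = dxx / nv; vhy = dxy / nv; k = A_k * std::tanh(c_k * nv); }
    double L = leg * std::sin(k * e2 / 2.0);
    if (!step_mode) L += leg * std::sin(k * e3 / 2.0);
    if (dxy < 0) L = bhold ? 0.0 : beps;
    double nx = x + L * vhx, ny = y + L * vhy;

    double r = 0.0;
    bool term = false;
    if (ny >= y_door && y < y_door) {
      double xc = x + (nx - x) * (y_door - y) / (ny - y);
      if (std::fabs(xc) <= slot) { r = 5.0; outcome = 1; }
      else { r = -1.0; outcome = 2; }
      term = true;
    } else if (std::fabs(nx) > half) {
      r = -1.0;
      if (wall_terminal) { term = true; outcome = 3; }
      else nx = (nx > 0 ? half : -half);
    }

    rec(t, 0) = x; rec(t, 1) = y;
    rec(t, 2) = L * vhx; rec(t, 3) = L * vhy;
    rec(t, 4) = L; rec(t, 5) = r; rec(t, 6) = V; rec(t, 7) = sw;

    x = nx; y = ny;
    if (orient_mode == 1) {
      if (y < y_door) {
        rox = 0.0 - x; roy = y_door - y;
        double n2 = std::sqrt(rox * rox + roy * roy);
        rox /= n2; roy /= n2;
      }
    } else if (L > 1e-3) { rox = vhx; roy = vhy; }

    double V2;
    if (term) V2 = 0.0;
    else { view(x, y, rox, roy, phi2); V2 = valueof(phi2); }

    double delta = r + gamma * V2 - V;
    double dc = delta;
    if (mode == 1) dc = std::min(delta, dlim);
    else if (mode == 2) dc = std::min(delta, dlim) + dmed;
    if (learn && eta != 0.0)
      for (int i = 0; i < n_sectors; ++i)
        if (phi[i]) Wl[i] += eta * dc;

    sw = (clamp_sw && mode != 0) ? dc : (V2 - V);
    if (!term) { std::swap(phi, phi2); V = V2; }
    if (term) { ++t; break; }
  }

  NumericMatrix recout(t, 8);
  for (int i = 0; i < t; ++i)
    for (int j = 0; j < 8; ++j) recout(i, j) = rec(i, j);
  colnames(recout) = CharacterVector::create("x", "y", "vx", "vy", "stride",
                                             "reward", "V", "signal");
  return List::create(_["record"] = recout,
                      _["outcome"] = outcome,
                      _["W"] = NumericVector(Wl.begin(), Wl.end()));
}
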