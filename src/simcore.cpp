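// Closed-loop forward-dynamics core: planar serial chain on a horizontally
// translating base, driven by Hill-type muscles under feed-forward +
// delayed-PD-feedback control with first-order activation dynamics.
// Fixed-step classical RK4 on the coupled (theta, theta_dot, a) state;
// controls and delayed sensor reads are held on the step grid (zero-order
// hold across the Runge-Kutta stages).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Curves {
  double gamma_fl, A_f, F_len, k_PE, eps0_PE, c_ecc;
};

inline double f_L(double l, const Curves& cv) {
  double d = l - 1.0;
  return std::exp(-d * d / cv.gamma_fl);
}

inline double f_V(double v, const Curves& cv) {
  if (v <= -1.0) return 0.0;
  if (v <= 0.0) return (1.0 + v) / (1.0 - v / cv.A_f);
  return (cv.F_len * v + cv.c_ecc) / (v + cv.c_ecc);
}

inline double f_PE(double l, const Curves& cv) {
  if (l <= 1.0) return 0.0;
  return (std::exp(cv.k_PE * (l - 1.0) / cv.eps0_PE) - 1.0) /
         (std::exp(cv.k_PE) - 1.0);
}

inline double act_tau(double a, double u, double t_act, double t_deact) {
  return (u > a) ? t_act * (0.5 + 1.5 * a) : t_deact / (0.5 + 1.5 * a);
}

// Solve M x = b (n small) by Gaussian elimination with partial pivoting.
// Returns false on (near-)singularity.
bool solve_small(std::vector<double> M, std::vector<double> b, int n,
                 std::vector<double>& x) {
  for (int c = 0; c < n; ++c) {
    int piv = c;
    double best = std::fabs(M[c * n + c]);
    for (int r = c + 1; r < n; ++r) {
      double v = std::fabs(M[r * n + c]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-12) return false;
    if (piv != c) {
      for (int k = 0; k < n; ++k) std::swap(M[c * n + k], M[piv * n + k]);
      std::swap(b[c], b[piv]);
    }
    for (int r = c + 1; r < n; ++r) {
      double f = M[r * n + c] / M[c * n + c];
      for (int k = c; k < n; ++k) M[r * n + k] -= f * M[c * n + k];
      b[r] -= f * b[c];
    }
  }
  x.assign(n, 0.0);
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < n; ++k) s -= M[r * n + k] * x[k];
    x[r] = s / M[r * n + r];
  }
  return true;
}

struct Plant {
  int n;                       // joints / links
  std::vector<double> m, I, A; // A is n x n chain coefficient matrix
  std::vector<double> damping, mu;
  double g, total_mass;
};

struct Muscles {
  int nm;
  std::vector<double> ma;      // nm x nj, row-major
  std::vector<double> F0, L_opt, L_slack, L_ref, V_max, t_act, t_deact;
};

// Joint accelerations in relative coordinates; false on singular M.
bool chain_accel(const Plant& P, const double* theta, const double* thetad,
                 const double* tau, double base_acc, std::vector<double>& out) {
  int n = P.n;
  std::vector<double> phi(n), phid(n), Q(n), M(n * n), rhs(n);
  double cs = 0.0, cd = 0.0;
  for (int i = 0; i < n; ++i) {
    cs += theta[i]; cd += thetad[i];
    phi[i] = cs; phid[i] = cd;
  }
  for (int i = 0; i < n; ++i)
    Q[i] = tau[i] - (i + 1 < n ? tau[i + 1] : 0.0);
  for (int i = 0; i < n; ++i) {
    double Cv = 0.0;
    for (int j = 0; j < n; ++j) {
      double S = 0.0;
      for (int k = std::max(i, j); k < n; ++k)
        S += P.m[k] * P.A[k * n + i] * P.A[k * n + j];
      M[i * n + j] = S * std::cos(phi[i] - phi[j]) + (i == j ? P.I[i] : 0.0);
      Cv += S * std::sin(phi[i] - phi[j]) * phid[j] * phid[j];
    }
    rhs[i] = Q[i] + P.g * P.mu[i] * std::sin(phi[i]) -
             P.mu[i] * std::cos(phi[i]) * base_acc - Cv;
  }
  std::vector<double> phidd;
  if (!solve_small(M, rhs, n, phidd)) return false;
  out.resize(n);
  double prev = 0.0;
  for (int i = 0; i < n; ++i) { out[i] = phidd[i] - prev; prev = phidd[i]; }
  return true;
}

double com_h(const Plant& P, const double* theta) {
  int n = P.n;
  double cs = 0.0, h = 0.0;
  std::vector<double> phi(n);
  for (int i = 0; i < n; ++i) { cs += theta[i]; phi[i] = cs; }
  for (int k = 0; k < n; ++k) {
    double z = 0.0;
    for (int i = 0; i <= k; ++i) z += P.A[k * n + i] * std::cos(phi[i]);
    h += P.m[k] * z;
  }
  return h / P.total_mass;
}

// Derivative of the coupled state under fixed excitation u_del and given
// base acceleration.  Returns false on singular mass matrix.
bool deriv(const Plant& P, const Muscles& Mu, const Curves& cv,
           const double* theta, const double* thetad, const double* a,
           const double* u_del, double base_acc,
           std::vector<double>& dth, std::vector<double>& dthd,
           std::vector<double>& da) {
  int n = P.n, nm = Mu.nm;
  std::vector<double> tau(n, 0.0);
  for (int i = 0; i < nm; ++i) {
    double L = Mu.L_ref[i], Ld = 0.0;
    for (int j = 0; j < n; ++j) {
      L -= Mu.ma[i * n + j] * theta[j];
      Ld -= Mu.ma[i * n + j] * thetad[j];
    }
    double l = (L - Mu.L_slack[i]) / Mu.L_opt[i];
    double v = Ld / Mu.V_max[i];
    double ac = a[i] < 0.0 ? 0.0 : (a[i] > 1.0 ? 1.0 : a[i]);
    double F = Mu.F0[i] * (ac * f_L(l, cv) * f_V(v, cv) + f_PE(l, cv));
    for (int j = 0; j < n; ++j) tau[j] += F * Mu.ma[i * n + j];
  }
  for (int j = 0; j < n; ++j) tau[j] -= P.damping[j] * thetad[j];
  if (!chain_accel(P, theta, thetad, tau.data(), base_acc, dthd)) return false;
  dth.assign(thetad, thetad + n);
  da.resize(nm);
  for (int i = 0; i < nm; ++i) {
    double ac = a[i] < 0.0 ? 0.0 : (a[i] > 1.0 ? 1.0 : a[i]);
    da[i] = (u_del[i] - a[i]) / act_tau(ac, u_del[i], Mu.t_act[i],
                                        Mu.t_deact[i]);
  }
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector link_m, NumericVector link_l,
                   NumericVector link_d, NumericVector link_I,
                   NumericVector joint_damping, double g,
                   NumericMatrix ma, NumericVector F0, NumericVector L_opt,
                   NumericVector L_slack, NumericVector L_ref,
                   NumericVector V_max, NumericVector t_act,
                   NumericVector t_deact,
                   double gamma_fl, double A_f, double F_len, double k_PE,
                   double eps0_PE,
                   NumericVector u_ff, NumericVector kp, NumericVector kd,
                   NumericVector L0, double Ldot0,
                   double clip_lo, double clip_hi,
                   int fb_steps, int trans_steps,
                   NumericVector theta0, NumericVector thetadot0,
                   NumericVector a0,
                   NumericVector base_acc_half,
                   double dt, int n_steps, double fall_h) {
  int n = link_m.size(), nm = F0.size();

  Plant P;
  P.n = n;
  P.m.assign(link_m.begin(), link_m.end());
  P.I.assign(link_I.begin(), link_I.end());
  P.damping.assign(joint_damping.begin(), joint_damping.end());
  P.g = g;
  P.A.assign(n * n, 0.0);
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < k; ++i) P.A[k * n + i] = link_l[i];
    P.A[k * n + k] = link_d[k];
  }
  P.mu.assign(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int k = i; k < n; ++k) P.mu[i] += P.m[k] * P.A[k * n + i];
  P.total_mass = 0.0;
  for (int k = 0; k < n; ++k) P.total_mass += P.m[k];

  Muscles Mu;
  Mu.nm = nm;
  Mu.ma.assign(nm * n, 0.0);
  for (int i = 0; i < nm; ++i)
    for (int j = 0; j < n; ++j) Mu.ma[i * n + j] = ma(i, j);
  Mu.F0.assign(F0.begin(), F0.end());
  Mu.L_opt.assign(L_opt.begin(), L_opt.end());
  Mu.L_slack.assign(L_slack.begin(), L_slack.end());
  Mu.L_ref.assign(L_ref.begin(), L_ref.end());
  Mu.V_max.assign(V_max.begin(), V_max.end());
  Mu.t_act.assign(t_act.begin(), t_act.end());
  Mu.t_deact.assign(t_deact.begin(), t_deact.end());

  Curves cv;
  cv.gamma_fl = gamma_fl; cv.A_f = A_f; cv.F_len = F_len;
  cv.k_PE = k_PE; cv.eps0_PE = eps0_PE;
  cv.c_ecc = (F_len - 1.0) / (1.0 + 1.0 / A_f);

  int N = n_steps;
  NumericMatrix theta_out(N + 1, n), thetad_out(N + 1, n);
  NumericMatrix a_out(N + 1, nm), u_out(N + 1, nm), uraw_out(N + 1, nm);
  NumericMatrix L_out(N + 1, nm), Ld_out(N + 1, nm);
  NumericVector h_out(N + 1);

  // histories on the step grid for delayed reads
  std::vector<double> L_hist((N + 1) * nm), Ld_hist((N + 1) * nm),
      u_hist((N + 1) * nm);

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> thd(thetadot0.begin(), thetadot0.end());
  std::vector<double> a(a0.begin(), a0.end());

  std::string status = "completed";
  double t_fall_ms = N * dt * 1000.0;
  bool stood = true;
  int last = N;

  std::vector<double> dth1, dthd1, da1, dth2, dthd2, da2, dth3, dthd3, da3,
      dth4, dthd4, da4;
  std::vector<double> th2(n), thd2(n), a2(nm), u_del(nm);

  for (int k = 0; k <= N; ++k) {
    // record state + muscle kinematics
    bool finite = true;
    for (int j = 0; j < n; ++j)
      if (!std::isfinite(th[j]) || !std::isfinite(thd[j])) finite = false;
    if (!finite) {
      status = "diverged";
      stood = false;
      t_fall_ms = k * dt * 1000.0;
      last = k > 0 ? k - 1 : 0;
      break;
    }
    for (int j = 0; j < n; ++j) {
      theta_out(k, j) = th[j];
      thetad_out(k, j) = thd[j];
    }
    for (int i = 0; i < nm; ++i) {
      double L = Mu.L_ref[i], Ld = 0.0;
      for (int j = 0; j < n; ++j) {
        L -= Mu.ma[i * n + j] * th[j];
        Ld -= Mu.ma[i * n + j] * thd[j];
      }
      L_hist[k * nm + i] = L;
      Ld_hist[k * nm + i] = Ld;
      L_out(k, i) = L;
      Ld_out(k, i) = Ld;
      a_out(k, i) = a[i];
    }
    double h = com_h(P, th.data());
    h_out[k] = h;

    // control update (delayed feedback)
    int kfb = k - fb_steps; if (kfb < 0) kfb = 0;
    for (int i = 0; i < nm; ++i) {
      double ufb = kp[i] * (L_hist[kfb * nm + i] - L0[i]) / L0[i] +
                   kd[i] * (Ld_hist[kfb * nm + i] - Ldot0) / Mu.V_max[i];
      double raw = u_ff[i] + ufb;
      double uc = raw < clip_lo ? clip_lo : (raw > clip_hi ? clip_hi : raw);
      u_hist[k * nm + i] = uc;
      u_out(k, i) = uc;
      uraw_out(k, i) = raw;
    }

    if (h < fall_h) {
      status = "fell";
      stood = false;
      t_fall_ms = k * dt * 1000.0;
      last = k;
      break;
    }
    if (k == N) break;

    // excitation for this step: control delayed by the transmission delay
    int ktr = k - trans_steps; if (ktr < 0) ktr = 0;
    for (int i = 0; i < nm; ++i) u_del[i] = u_hist[ktr * nm + i];

    double b1 = base_acc_half[2 * k];
    double b2 = base_acc_half[2 * k + 1];
    double b4 = base_acc_half[2 * k + 2];

    bool ok =
        deriv(P, Mu, cv, th.data(), thd.data(), a.data(), u_del.data(), b1,
              dth1, dthd1, da1);
    if (ok) {
      for (int j = 0; j < n; ++j) {
        th2[j] = th[j] + dt / 2 * dth1[j];
        thd2[j] = thd[j] + dt / 2 * dthd1[j];
      }
      for (int i = 0; i < nm; ++i) a2[i] = a[i] + dt / 2 * da1[i];
      ok = deriv(P, Mu, cv, th2.data(), thd2.data(), a2.data(), u_del.data(),
                 b2, dth2, dthd2, da2);
    }
    if (ok) {
      for (int j = 0; j < n; ++j) {
        th2[j] = th[j] + dt / 2 * dth2[j];
        thd2[j] = thd[j] + dt / 2 * dthd2[j];
      }
      for (int i = 0; i < nm; ++i) a2[i] = a[i] + dt / 2 * da2[i];
      ok = deriv(P, Mu, cv, th2.data(), thd2.data(), a2.data(), u_del.data(),
                 b2, dth3, dthd3, da3);
    }
    if (ok) {
      for (int j = 0; j < n; ++j) {
        th2[j] = th[j] + dt * dth3[j];
        thd2[j] = thd[j] + dt * dthd3[j];
      }
      for (int i = 0; i < nm; ++i) a2[i] = a[i] + dt * da3[i];
      ok = deriv(P, Mu, cv, th2.data(), thd2.data(), a2.data(), u_del.data(),
                 b4, dth4, dthd4, da4);
    }
    if (!ok) {
      status = "diverged";
      stood = false;
      t_fall_ms = k * dt * 1000.0;
      last = k;
      break;
    }
    for (int j = 0; j < n; ++j) {
      th[j] += dt / 6 * (dth1[j] + 2 * dth2[j] + 2 * dth3[j] + dth4[j]);
      thd[j] += dt / 6 * (dthd1[j] + 2 * dthd2[j] + 2 * dthd3[j] + dthd4[j]);
    }
    for (int i = 0; i < nm; ++i) {
      a[i] += dt / 6 * (da1[i] + 2 * da2[i] + 2 * da3[i] + da4[i]);
      if (a[i] < 0.0) a[i] = 0.0;
      if (a[i] > 1.0) a[i] = 1.0;
    }
  }

  return List::create(
      _["theta"] = theta_out, _["theta_dot"] = thetad_out,
      _["a"] = a_out, _["u"] = u_out, _["u_raw"] = uraw_out,
      _["L_MT"] = L_out, _["Ldot_MT"] = Ld_out, _["com_height"] = h_out,
      _["t_fall_ms"] = t_fall_ms, _["stood"] = stood,
      _["status"] = status, _["last_step"] = last);
}
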