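// Reduced 1D pulse-wave solver: chain of linearly tapered segments with a
// linear-elastic tube law p = p_ref + K (A/A_ref(x) - 1), Poiseuille
// friction, a time-varying elastance ventricle with diode valves at the
// inlet, optional lumped side windkessels at internal junctions, and a
// three-element windkessel (or pure resistor) at the distal outlet.
//
// Interior scheme: Richtmyer two-step Lax-Wendroff on the conservative
// form  A_t + (A u)_x = 0,  u_t + (u^2/2 + p/rho)_x = -8 pi nu u / A.
// Boundaries and junctions are coupled through the Riemann invariants
// W+- = u +- 2c of the homogeneous system (c^2 = K A / (rho A_ref), so
// c ~ sqrt(A) and the integral of c/A dA is 2c), with foot-point linear
// interpolation and Newton solves for the boundary states.
//
// All quantities are cgs: cm, g, s, dyn/cm^2. Conversions happen in R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Segment {
  int n;
  double dx;
  double K;
  std::vector<double> Aref, Arefm;  // node and midpoint reference areas
  std::vector<double> A, u;         // state
  std::vector<double> An, un;       // scratch (next state)
  std::vector<double> p;            // node pressures
  std::vector<double> F1h;          // half-step interface mass flux A*u
};

struct Terminal {           // 3-element windkessel; C <= 0 => pure resistor
  double R1, R2, C, p_ven;
  double p_wk;              // state (capacitor pressure)
  bool pure;                // pure resistor to p_ven through R1
};

struct Heart {
  double Emax, Emin, V0, p_fill, Rmv, Rav, t_rise, t_fall;
};

inline double wavespeed(double A, double Aref, double K, double rho) {
  return std::sqrt(K * A / (rho * Aref));
}

inline double activation(double t, const Heart& h) {
  if (t < h.t_rise) return 0.5 * (1.0 - std::cos(M_PI * t / h.t_rise));
  if (t < h.t_fall)
    return 0.5 * (1.0 + std::cos(M_PI * (t - h.t_rise) / (h.t_fall - h.t_rise)));
  return 0.0;
}

// Terminal/outlet Newton: q = A (Wp - 2 c(A)) must equal (p(A) - p_out)/R1.
double solve_outlet(double Wp, double Aref, double K, double rho,
                    double p_ref, double R1, double p_out, double A_init) {
  double A = A_init;
  for (int it = 0; it < 50; ++it) {
    double c = wavespeed(A, Aref, K, rho);
    double u = Wp - 2.0 * c;
    double p = p_ref + K * (A / Aref - 1.0);
    double G = A * u - (p - p_out) / R1;
    double dG = (u - c) - (K / Aref) / R1;
    double step = G / dG;
    double Anew = A - step;
    if (Anew < 0.05 * Aref) Anew = 0.05 * Aref;
    if (Anew > 20.0 * Aref) Anew = 20.0 * Aref;
    if (std::fabs(Anew - A) <= 1e-14 * A) { A = Anew; break; }
    A = Anew;
  }
  return A;
}

} // namespace

// [[Rcpp::export]]
List onedim_simulate_cpp(List segments_in, List junctions_in, List terminal_in,
                         List heart_in, double rho, double mu,
                         double p_ref, double p_init,
                         double dt, double period, int n_cycles_max,
                         double periodicity_tol, int out_every) {
  const int ns = segments_in.size();
  std::vector<Segment> seg(ns);
  for (int s = 0; s < ns; ++s) {
    List L = segments_in[s];
    Segment& S = seg[s];
    S.n = as<int>(L["n"]);
    S.dx = as<double>(L["dx"]);
    S.K = as<double>(L["K"]);
    NumericVector ar = L["Aref"];
    S.Aref.assign(ar.begin(), ar.end());
    S.Arefm.resize(S.n - 1);
    for (int i = 0; i < S.n - 1; ++i)
      S.Arefm[i] = 0.5 * (S.Aref[i] + S.Aref[i + 1]);
    S.A.resize(S.n);                   // start pressurised at p_init
    for (int i = 0; i < S.n; ++i)
      S.A[i] = S.Aref[i] * (1.0 + (p_init - p_ref) / S.K);
    S.u.assign(S.n, 0.0);
    S.An.assign(S.n, 0.0);
    S.un.assign(S.n, 0.0);
    S.p.assign(S.n, p_init);
    S.F1h.assign(S.n - 1, 0.0);
  }

  // Junction side terminals (one per internal junction; may be absent).
  std::vector<bool> has_side(ns - 1, false);
  std::vector<Terminal> side(ns - 1);
  for (int j = 0; j < ns - 1; ++j) {
    if (Rf_isNull(junctions_in[j])) continue;
    List L = junctions_in[j];
    Terminal& T = side[j];
    T.R1 = as<double>(L["R1"]); T.R2 = as<double>(L["R2"]);
    T.C = as<double>(L["C"]);   T.p_ven = as<double>(L["p_ven"]);
    T.pure = (T.C <= 0.0);
    T.p_wk = T.pure ? T.p_ven : p_init;
    has_side[j] = true;
  }

  Terminal term;
  {
    List L = terminal_in;
    term.R1 = as<double>(L["R1"]); term.R2 = as<double>(L["R2"]);
    term.C = as<double>(L["C"]);   term.p_ven = as<double>(L["p_ven"]);
    term.pure = (term.C <= 0.0);
    term.p_wk = term.pure ? term.p_ven : p_init;
  }

  Heart heart;
  {
    List L = heart_in;
    heart.Emax = as<double>(L["Emax"]); heart.Emin = as<double>(L["Emin"]);
    heart.V0 = as<double>(L["V0"]);     heart.p_fill = as<double>(L["p_fill"]);
    heart.Rmv = as<double>(L["Rmv"]);   heart.Rav = as<double>(L["Rav"]);
    heart.t_rise = as<double>(L["t_rise"]); heart.t_fall = as<double>(L["t_fall"]);
  }

  const double nu8pi = 8.0 * M_PI * mu / rho;  // friction: -8 pi nu u / A
  int nsteps = (int)std::lround(period / dt);
  if (nsteps < 16) stop("dt too coarse for the cycle");
  dt = period / nsteps;

  double V = heart.V0 + heart.p_fill / heart.Emin;  // end-diastolic start

  // Output sampling of the root node.
  int n_out = nsteps / out_every + 1;
  std::vector<double> out_t, out_A, out_q, out_p, prev_p;
  out_t.reserve(n_out); out_A.reserve(n_out);
  out_q.reserve(n_out); out_p.reserve(n_out);

  bool converged = false;
  int cycles_run = 0;
  double max_dp = NA_REAL;
  double vol_in = 0, vol_out = 0, storage0 = 0, storage1 = 0;
  NumericVector conv_history(n_cycles_max, NA_REAL);

  // state-based CFL audit, re-applied at every output sample
  auto cfl_check = [&](double t) {
    for (int s = 0; s < ns; ++s) {
      for (int i = 0; i < seg[s].n; ++i) {
        double c = wavespeed(seg[s].A[i], seg[s].Aref[i], seg[s].K, rho);
        if (dt * (std::fabs(seg[s].u[i]) + c) > seg[s].dx)
          stop("CFL condition violated in segment %d at t = %g s", s + 1, t);
      }
    }
  };

  // Boundary half-cell updates double the effective Courant number, so the
  // conservative form is used only where 2*dt*(|u|+c)/dx stays below 0.9;
  // otherwise the characteristic state is kept. The fallback only triggers
  // in nearly rigid (stiffened) segments, whose cells store essentially no
  // volume, so the volume budget is unaffected in practice.
  auto half_cell_ok = [&](const Segment& S, int i, double u, double c) {
    return 2.0 * dt * (std::fabs(u) + c) <= 0.9 * S.dx;
  };

  // Control surface for the volume budget: the tube network itself (the
  // terminal capacitors sit beyond the faces whose fluxes are counted).
  auto tube_volume = [&]() {
    double v = 0;
    for (int s = 0; s < ns; ++s) {
      for (int i = 0; i < seg[s].n - 1; ++i)
        v += 0.5 * (seg[s].A[i] + seg[s].A[i + 1]) * seg[s].dx;
    }
    return v;
  };

  for (int cyc = 0; cyc < n_cycles_max && !converged; ++cyc) {
    out_t.clear(); out_A.clear(); out_q.clear(); out_p.clear();
    vol_in = 0; vol_out = 0;
    storage0 = tube_volume();

    for (int k = 0; k < nsteps; ++k) {
      double t = k * dt;

      // node pressures
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        for (int i = 0; i < S.n; ++i)
          S.p[i] = p_ref + S.K * (S.A[i] / S.Aref[i] - 1.0);
      }

      if (k % out_every == 0) {
        cfl_check(t);
        out_t.push_back(t);
        out_A.push_back(seg[0].A[0]);
        out_q.push_back(seg[0].A[0] * seg[0].u[0]);
        out_p.push_back(seg[0].p[0]);
      }

      // ---- interior update (Richtmyer two-step) ----
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        const int n = S.n;
        const double lam = dt / S.dx;
        // half-step midpoint states
        std::vector<double> Ah(n - 1), uh(n - 1);
        for (int i = 0; i < n - 1; ++i) {
          double F1l = S.A[i] * S.u[i], F1r = S.A[i + 1] * S.u[i + 1];
          double F2l = 0.5 * S.u[i] * S.u[i] + S.p[i] / rho;
          double F2r = 0.5 * S.u[i + 1] * S.u[i + 1] + S.p[i + 1] / rho;
          double Am = 0.5 * (S.A[i] + S.A[i + 1]);
          double um = 0.5 * (S.u[i] + S.u[i + 1]);
          Ah[i] = Am - 0.5 * lam * (F1r - F1l);
          uh[i] = um - 0.5 * lam * (F2r - F2l)
                  - 0.5 * dt * nu8pi * um / Am;
        }
        for (int i = 0; i < n - 1; ++i) S.F1h[i] = Ah[i] * uh[i];
        for (int i = 1; i < n - 1; ++i) {
          double phl = p_ref + S.K * (Ah[i - 1] / S.Arefm[i - 1] - 1.0);
          double phr = p_ref + S.K * (Ah[i] / S.Arefm[i] - 1.0);
          double F2l = 0.5 * uh[i - 1] * uh[i - 1] + phl / rho;
          double F2r = 0.5 * uh[i] * uh[i] + phr / rho;
          S.An[i] = S.A[i] - lam * (S.F1h[i] - S.F1h[i - 1]);
          S.un[i] = S.u[i] - lam * (F2r - F2l)
                    - dt * nu8pi * S.u[i] / S.A[i];
        }
      }

      // ---- boundaries (from the time-n state) ----

      // inlet of segment 0: elastance ventricle + aortic valve
      {
        Segment& S = seg[0];
        double c0 = wavespeed(S.A[0], S.Aref[0], S.K, rho);
        double c1 = wavespeed(S.A[1], S.Aref[1], S.K, rho);
        double lamf = (c0 - S.u[0]) * dt / S.dx;
        if (lamf < 0) lamf = 0; if (lamf > 1) lamf = 1;
        double Wm = (1 - lamf) * (S.u[0] - 2 * c0) + lamf * (S.u[1] - 2 * c1);
        double E = heart.Emin + (heart.Emax - heart.Emin) *
                   activation(t + dt - std::floor((t + dt) / period) * period, heart);
        double p_lv = E * (V - heart.V0);
        // closed-valve solution: u = 0  =>  c(A) = -Wm/2
        double A_closed = rho * S.Aref[0] * Wm * Wm / (4.0 * S.K);
        double p_closed = p_ref + S.K * (A_closed / S.Aref[0] - 1.0);
        double A_in;
        if (p_lv <= p_closed) {
          A_in = A_closed;
        } else {
          A_in = S.A[0];
          for (int it = 0; it < 50; ++it) {
            double c = wavespeed(A_in, S.Aref[0], S.K, rho);
            double u = Wm + 2 * c;
            double p = p_ref + S.K * (A_in / S.Aref[0] - 1.0);
            double H = A_in * u - (p_lv - p) / heart.Rav;
            double dH = (u + c) + (S.K / S.Aref[0]) / heart.Rav;
            double Anew = A_in - H / dH;
            if (Anew < 0.05 * S.Aref[0]) Anew = 0.05 * S.Aref[0];
            if (std::fabs(Anew - A_in) <= 1e-14 * A_in) { A_in = Anew; break; }
            A_in = Anew;
          }
        }
        double c_in = wavespeed(A_in, S.Aref[0], S.K, rho);
        double u_in = (p_lv <= p_closed) ? 0.0 : (Wm + 2 * c_in);
        double q_av = A_in * u_in;
        // conservative half-cell update with the valve face flux
        S.An[0] = half_cell_ok(S, 0, u_in, c_in)
          ? S.A[0] - (2.0 * dt / S.dx) * (S.F1h[0] - q_av)
          : A_in;
        S.un[0] = u_in;
        double q_mv = (heart.p_fill > p_lv) ? (heart.p_fill - p_lv) / heart.Rmv : 0.0;
        V += dt * (q_mv - q_av);
        vol_in += dt * q_av;
      }

      // internal junctions
      for (int j = 0; j < ns - 1; ++j) {
        Segment& L = seg[j];
        Segment& R = seg[j + 1];
        int nL = L.n;
        double cLn = wavespeed(L.A[nL - 1], L.Aref[nL - 1], L.K, rho);
        double cLm = wavespeed(L.A[nL - 2], L.Aref[nL - 2], L.K, rho);
        double lamL = (L.u[nL - 1] + cLn) * dt / L.dx;
        if (lamL < 0) lamL = 0; if (lamL > 1) lamL = 1;
        double Wp = (1 - lamL) * (L.u[nL - 1] + 2 * cLn)
                    + lamL * (L.u[nL - 2] + 2 * cLm);
        double cR0 = wavespeed(R.A[0], R.Aref[0], R.K, rho);
        double cR1 = wavespeed(R.A[1], R.Aref[1], R.K, rho);
        double lamR = (cR0 - R.u[0]) * dt / R.dx;
        if (lamR < 0) lamR = 0; if (lamR > 1) lamR = 1;
        double Wm = (1 - lamR) * (R.u[0] - 2 * cR0) + lamR * (R.u[1] - 2 * cR1);

        double AL = L.A[nL - 1], AR = R.A[0];
        double ArefL = L.Aref[nL - 1], ArefR = R.Aref[0];
        double q_side = 0.0, pL = 0.0;
        for (int it = 0; it < 60; ++it) {
          double cL = wavespeed(AL, ArefL, L.K, rho);
          double cR = wavespeed(AR, ArefR, R.K, rho);
          double uL = Wp - 2 * cL, uR = Wm + 2 * cR;
          pL = p_ref + L.K * (AL / ArefL - 1.0);
          double pR = p_ref + R.K * (AR / ArefR - 1.0);
          q_side = has_side[j] ? (pL - side[j].p_wk) / side[j].R1 : 0.0;
          double F1 = pL - pR;
          double F2 = AL * uL - AR * uR - q_side;
          double a11 = L.K / ArefL, a12 = -R.K / ArefR;
          double a21 = (uL - cL) - (has_side[j] ? (L.K / ArefL) / side[j].R1 : 0.0);
          double a22 = -(uR + cR);
          double det = a11 * a22 - a12 * a21;
          double dAL = (F1 * a22 - F2 * a12) / det;
          double dAR = (a11 * F2 - a21 * F1) / det;
          AL -= dAL; AR -= dAR;
          if (AL < 0.05 * ArefL) AL = 0.05 * ArefL;
          if (AR < 0.05 * ArefR) AR = 0.05 * ArefR;
          if (std::fabs(dAL) <= 1e-13 * AL && std::fabs(dAR) <= 1e-13 * AR) break;
        }
        double cL = wavespeed(AL, ArefL, L.K, rho);
        double cR = wavespeed(AR, ArefR, R.K, rho);
        double uLs = Wp - 2 * cL, uRs = Wm + 2 * cR;
        double q_faceL = AL * uLs;
        double q_faceR = q_faceL - q_side;
        L.An[nL - 1] = half_cell_ok(L, nL - 1, uLs, cL)
          ? L.A[nL - 1] - (2.0 * dt / L.dx) * (q_faceL - L.F1h[nL - 2])
          : AL;
        L.un[nL - 1] = uLs;
        R.An[0] = half_cell_ok(R, 0, uRs, cR)
          ? R.A[0] - (2.0 * dt / R.dx) * (R.F1h[0] - q_faceR)
          : AR;
        R.un[0] = uRs;
        if (has_side[j]) {
          if (!side[j].pure) {
            side[j].p_wk += dt / side[j].C *
              (q_side - (side[j].p_wk - side[j].p_ven) / side[j].R2);
          }
          vol_out += dt * q_side;
        }
      }

      // distal terminal
      {
        Segment& S = seg[ns - 1];
        int n = S.n;
        double cn = wavespeed(S.A[n - 1], S.Aref[n - 1], S.K, rho);
        double cm = wavespeed(S.A[n - 2], S.Aref[n - 2], S.K, rho);
        double lamT = (S.u[n - 1] + cn) * dt / S.dx;
        if (lamT < 0) lamT = 0; if (lamT > 1) lamT = 1;
        double Wp = (1 - lamT) * (S.u[n - 1] + 2 * cn)
                    + lamT * (S.u[n - 2] + 2 * cm);
        double p_out = term.pure ? term.p_ven : term.p_wk;
        double A_t = solve_outlet(Wp, S.Aref[n - 1], S.K, rho, p_ref,
                                  term.R1, p_out, S.A[n - 1]);
        double c_t = wavespeed(A_t, S.Aref[n - 1], S.K, rho);
        double u_t = Wp - 2 * c_t;
        double q_t = A_t * u_t;
        S.An[n - 1] = half_cell_ok(S, n - 1, u_t, c_t)
          ? S.A[n - 1] - (2.0 * dt / S.dx) * (q_t - S.F1h[n - 2])
          : A_t;
        S.un[n - 1] = u_t;
        if (!term.pure) {
          term.p_wk += dt / term.C *
            (q_t - (term.p_wk - term.p_ven) / term.R2);
        }
        vol_out += dt * q_t;
      }

      // Lapidus artificial viscosity: conservative, gradient-activated
      // smoothing that suppresses node-to-node sawtooth modes while
      // vanishing as dx^2 for smooth fields.
      const double C_lap = 1.0;
      for (int s = 0; s < ns; ++s) {
        Segment& S = seg[s];
        const int n = S.n;
        const double fac = C_lap * dt / S.dx;
        std::vector<double> dA(n - 1), du(n - 1);
        for (int i = 0; i < n - 1; ++i) {
          dA[i] = S.An[i + 1] - S.An[i];
          du[i] = S.un[i + 1] - S.un[i];
        }
        for (int i = 1; i < n - 1; ++i) {
          S.An[i] += fac * (std::fabs(du[i]) * dA[i] - std::fabs(du[i - 1]) * dA[i - 1]);
          S.un[i] += fac * (std::fabs(du[i]) * du[i] - std::fabs(du[i - 1]) * du[i - 1]);
        }
        // half-cell diffusive-flux compensation keeps the volume budget exact
        S.An[0] += 2.0 * fac * std::fabs(du[0]) * dA[0];
        S.An[n - 1] -= 2.0 * fac * std::fabs(du[n - 2]) * dA[n - 2];
      }

      for (int s = 0; s < ns; ++s) {
        seg[s].A.swap(seg[s].An);
        seg[s].u.swap(seg[s].un);
        for (int i = 0; i < seg[s].n; ++i) {
          if (!(seg[s].A[i] > 0) || !std::isfinite(seg[s].u[i]))
            stop("solver diverged in segment %d at t = %g s (cycle %d)",
                 s + 1, t, cyc + 1);
        }
      }
    } // steps

    storage1 = tube_volume();
    cycles_run = cyc + 1;
    if (!prev_p.empty() && prev_p.size() == out_p.size()) {
      max_dp = 0;
      for (size_t i = 0; i < out_p.size(); ++i)
        max_dp = std::max(max_dp, std::fabs(out_p[i] - prev_p[i]));
      conv_history[cyc] = max_dp;
      if (max_dp < periodicity_tol) converged = true;
    }
    prev_p = out_p;
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["time"] = NumericVector(out_t.begin(), out_t.end()),
    _["area"] = NumericVector(out_A.begin(), out_A.end()),
    _["flow"] = NumericVector(out_q.begin(), out_q.end()),
    _["pressure"] = NumericVector(out_p.begin(), out_p.end()),
    _["converged"] = converged,
    _["n_cycles"] = cycles_run,
    _["max_cycle_dp"] = max_dp,
    _["conv_history"] = conv_history,
    _["vol_in"] = vol_in,
    _["vol_out"] = vol_out,
    _["storage_delta"] = storage1 - storage0,
    _["dt"] = dt
  );
}
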