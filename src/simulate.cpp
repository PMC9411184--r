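#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear interpolation of a (ny x nx, column-major) grid at (px, py).
// Outside the grid: nearest-edge value, or zero if outside_zero.
static inline void interp_force(const double *fx, const double *fy,
                                double x0, double y0, double h,
                                int nx, int ny, bool outside_zero,
                                double px, double py,
                                double &ox, double &oy) {
  double gx = (px - x0) / h;
  double gy = (py - y0) / h;
  bool out = gx < 0.0 || gx > nx - 1.0 || gy < 0.0 || gy > ny - 1.0;
  if (out && outside_zero) { ox = 0.0; oy = 0.0; return; }
  if (gx < 0.0) gx = 0.0;
  if (gx > nx - 1.000000001) gx = nx - 1.000000001;
  if (gy < 0.0) gy = 0.0;
  if (gy > ny - 1.000000001) gy = ny - 1.000000001;
  int i0 = (int)gx, j0 = (int)gy;
  double tx = gx - i0, ty = gy - j0;
  int a = j0 + i0 * ny;
  int b = j0 + (i0 + 1) * ny;
  double w00 = (1 - tx) * (1 - ty), w10 = tx * (1 - ty);
  double w01 = (1 - tx) * ty, w11 = tx * ty;
  ox = w00 * fx[a] + w01 * fx[a + 1] + w10 * fx[b] + w11 * fx[b + 1];
  oy = w00 * fy[a] + w01 * fy[a + 1] + w10 * fy[b] + w11 * fy[b + 1];
}

// Time-domain integration of an ensemble under a cyclic switching
// schedule of precomputed force grids sharing one grid geometry.
//
// pos, vel: n x 2 matrices (modified copies returned)
// fx_list, fy_list: per-state (ny x nx) force component matrices
// state_seq: 0-based indices into fx_list, one per schedule entry
// dwell: per-entry dwell times (s); the sequence loops until duration
// m_v: virtual mass (kg); gamma0 = 6 pi mu r; re_coef = 3/16 * 2 r rho0 / mu
// clamp_r: chamber radius minus particle radius (clamp + zero velocity)
// record_every: store positions every k-th step (0 = none)
// [[Rcpp::export]]
List cpp_simulate_schedule(NumericMatrix pos, NumericMatrix vel,
                           List fx_list, List fy_list,
                           double x0, double y0, double h, int nx, int ny,
                           IntegerVector state_seq, NumericVector dwell,
                           double duration, double dt,
                           double m_v, double gamma0, double re_coef,
                           double clamp_r, bool outside_zero,
                           int record_every) {
  int n = pos.nrow();
  int n_entries = state_seq.size();
  std::vector<const double *> fxp(fx_list.size()), fyp(fy_list.size());
  for (int s = 0; s < fx_list.size(); ++s) {
    fxp[s] = REAL(fx_list[s]);
    fyp[s] = REAL(fy_list[s]);
  }
  NumericMatrix p = clone(pos), v = clone(vel);
  long n_steps = (long)std::floor(duration / dt + 0.5);
  int n_rec = record_every > 0 ? (int)(n_steps / record_every) : 0;
  NumericMatrix traj_x(n_rec > 0 ? n_rec : 1, n_rec > 0 ? n : 1);
  NumericMatrix traj_y(n_rec > 0 ? n_rec : 1, n_rec > 0 ? n : 1);
  NumericVector t_rec(n_rec > 0 ? n_rec : 1);

  int entry = 0;
  double t_in_state = 0.0;
  int krec = 0;
  for (long step = 0; step < n_steps; ++step) {
    if (n_entries > 0) {
      while (t_in_state >= dwell[entry]) {
        t_in_state -= dwell[entry];
        entry = (entry + 1) % n_entries;
      }
    }
    int s = n_entries > 0 ? state_seq[entry] : 0;
    const double *fx = fxp[s];
    const double *fy = fyp[s];
    for (int i = 0; i < n; ++i) {
      double fax, fay;
      interp_force(fx, fy, x0, y0, h, nx, ny, outside_zero,
                   p(i, 0), p(i, 1), fax, fay);
      double vx = v(i, 0), vy = v(i, 1);
      double speed = std::sqrt(vx * vx + vy * vy);
      double gdrag = gamma0 * std::sqrt(1.0 + re_coef * speed);
      double fex = fax - gdrag * vx;
      double fey = fay - gdrag * vy;
      double ax = fex / m_v, ay = fey / m_v;
      p(i, 0) += vx * dt + ax * dt * dt;
      p(i, 1) += vy * dt + ay * dt * dt;
      v(i, 0) = vx + ax * dt;
      v(i, 1) = vy + ay * dt;
      double rr = std::sqrt(p(i, 0) * p(i, 0) + p(i, 1) * p(i, 1));
      if (rr > clamp_r) {
        p(i, 0) *= clamp_r / rr;
        p(i, 1) *= clamp_r / rr;
        v(i, 0) = 0.0;
        v(i, 1) = 0.0;
      }
    }
    t_in_state += dt;
    if (record_every > 0 && (step + 1) % record_every == 0 && krec < n_rec) {
      for (int i = 0; i < n; ++i) {
        traj_x(krec, i) = p(i, 0);
        traj_y(krec, i) = p(i, 1);
      }
      t_rec[krec] = (step + 1) * dt;
      ++krec;
    }
  }
  List out = List::create(_["pos"] = p, _["vel"] = v);
  if (record_every > 0) {
    out["traj_x"] = traj_x;
    out["traj_y"] = traj_y;
    out["t"] = t_rec;
  }
  return out;
}

// 1D two-state switching bench: closed-form force
//   F_q(x) = -f_max * sin(kk * (x - shift_q))
// (kk = 2k for an ideal standing wave), states alternating with equal
// dwell. Stable equilibrium of state q is at x = shift_q. Returns the
// recorded positions and the final state.
// [[Rcpp::export]]
List cpp_simulate_two_state_1d(double x, double v,
                               double f_max, double shift1, double shift2,
                               double kk, double dwell, int n_cycles,
                               double dt, double m_v, double gamma0,
                               double re_coef, int record_every) {
  double shifts[2] = {shift1, shift2};
  long steps_per_dwell = (long)std::floor(dwell / dt + 0.5);
  if (steps_per_dwell < 1) steps_per_dwell = 1;
  long n_steps = 2L * n_cycles * steps_per_dwell;
  int n_rec = record_every > 0 ? (int)(n_steps / record_every) : 0;
  NumericVector xr(n_rec > 0 ? n_rec : 1), tr(n_rec > 0 ? n_rec : 1);
  int krec = 0;
  for (long step = 0; step < n_steps; ++step) {
    int state = (int)((step / steps_per_dwell) % 2);
    double fac = -f_max * std::sin(kk * (x - shifts[state]));
    double gdrag = gamma0 * std::sqrt(1.0 + re_coef * std::fabs(v));
    double fe = fac - gdrag * v;
    double a = fe / m_v;
    x += v * dt + a * dt * dt;
    v += a * dt;
    if (record_every > 0 && (step + 1) % record_every == 0 && krec < n_rec) {
      xr[krec] = x;
      tr[krec] = (step + 1) * dt;
      ++krec;
    }
  }
  List out = List::create(_["x"] = x, _["v"] = v);
  if (record_every > 0) {
    out["x_rec"] = xr;
    out["t_rec"] = tr;
  }
  return out;
}
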