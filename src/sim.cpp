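#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Zonal shoaling update, run frame by frame.
//
// Each fish reacts to groupmates through three disjoint concentric
// shells: hard repulsion (turn away from anyone closer than r_rep),
// alignment with neighbours in the inner shell (r_rep..r_ali, weight
// w_ali), and attraction towards the centroid of neighbours in the outer
// shell (r_ali..r_att, weight w_att) - stragglers get pulled back, close
// neighbours get matched, so cohesion and polarization do not compete
// while the group is tight. Per-step wrapped-Gaussian turning noise and Gaussian
// speed noise are added; one designated follower takes its alignment
// input from the group's headings `follower_lag` frames in the past.
// Inside a wall buffer the desired heading is deflected towards the
// arena centre (deflection, not reflection, so wall encounters do not
// create speed artefacts). From frame `half_boundary` on, the playback
// multipliers in `disr` (speed, alignment, attraction, noise) apply.
//
// Speeds are preferred_speed plus an AR(1) deviation with persistence
// `speed_persistence` that is pulled towards groupmates' deviations with
// weight `speed_coupling`; this gives each pair a genuine speed
// correlation that disruption (via the alignment and noise multipliers)
// degrades, matching what playback does to live shoals.
//
// Uses R's RNG, so set.seed() in R makes the output bit-identical.
// [[Rcpp::export]]
List sim_zonal_cpp(int n_frames, int half_boundary,
                   NumericMatrix pos0, NumericVector theta0,
                   NumericMatrix edge_n, NumericVector edge_b,
                   double cx, double cy,
                   double dt, double r_rep, double r_ali, double r_att,
                   double w_ali, double w_att, double w_prev,
                   NumericVector pref_speed, NumericVector speed_noise,
                   NumericVector heading_noise,
                   double speed_coupling, double speed_persistence,
                   double activity_rho, double activity_sd,
                   int follower, int follower_lag, double wall_buffer,
                   NumericVector disr)
{
  const int n = pos0.nrow();
  const int ne = edge_n.nrow();
  NumericMatrix X(n_frames, n), Y(n_frames, n), TH(n_frames, n),
      SP(n_frames, n), DEV(n_frames, n);
  // slow per-fish behavioural-activity states (log AR(1), stationary)
  std::vector<double> lact(n);
  const double act_innov =
      activity_sd * std::sqrt(1.0 - activity_rho * activity_rho);
  for (int i = 0; i < n; ++i) {
    X(0, i) = pos0(i, 0);
    Y(0, i) = pos0(i, 1);
    TH(0, i) = theta0[i];
    SP(0, i) = pref_speed[i];
    DEV(0, i) = 0.0;
    lact[i] = activity_sd * R::norm_rand();
  }

  auto depth = [&](double px, double py) {
    double dmin = R_PosInf;
    for (int e = 0; e < ne; ++e) {
      double v = edge_n(e, 0) * px + edge_n(e, 1) * py - edge_b[e];
      if (v < dmin) dmin = v;
    }
    return dmin;  // > 0 inside
  };

  for (int t = 1; t < n_frames; ++t) {
    const bool disrupted = (t >= half_boundary);
    const double m_sp = disrupted ? disr[0] : 1.0;
    const double m_no = disrupted ? disr[3] : 1.0;
    const double wa = w_ali * (disrupted ? disr[1] : 1.0);
    const double wt = w_att * (disrupted ? disr[2] : 1.0);
    const double sc = speed_coupling * (disrupted ? disr[1] : 1.0);
    // disturbed fish keep a larger personal space: the repulsion radius
    // grows as cohesion drops
    const double rr = disrupted ? r_rep / std::sqrt(disr[2]) : r_rep;

    for (int i = 0; i < n; ++i) {
      const double px = X(t - 1, i), py = Y(t - 1, i);
      // headings the focal fish reads: delayed for the follower
      int ts = t - 1;
      if (i == follower) {
        ts = t - 1 - follower_lag;
        if (ts < 0) ts = 0;
      }
      double rx = 0, ry = 0;
      bool rep = false;
      double ax = 0, ay = 0;
      int na = 0;
      double attx = 0, atty = 0;
      int natt = 0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dx = X(t - 1, j) - px, dy = Y(t - 1, j) - py;
        const double d = std::sqrt(dx * dx + dy * dy);
        if (d < rr && d > 1e-12) {
          rep = true;
          rx -= dx / d;
          ry -= dy / d;
        } else if (d < r_ali) {
          ax += std::cos(TH(ts, j));
          ay += std::sin(TH(ts, j));
          ++na;
        } else if (d < r_att) {
          attx += dx;
          atty += dy;
          ++natt;
        }
      }
      double Dx, Dy;
      if (rep) {
        Dx = rx;
        Dy = ry;
      } else {
        // persistence gives the social weights an absolute scale
        Dx = w_prev * std::cos(TH(t - 1, i));
        Dy = w_prev * std::sin(TH(t - 1, i));
        if (na > 0) {
          const double nrm = std::sqrt(ax * ax + ay * ay);
          if (nrm > 1e-12) {
            Dx += wa * ax / nrm;
            Dy += wa * ay / nrm;
          }
        }
        if (natt > 0) {
          const double nrm = std::sqrt(attx * attx + atty * atty);
          if (nrm > 1e-12) {
            Dx += wt * attx / nrm;
            Dy += wt * atty / nrm;
          }
        }
        if (std::sqrt(Dx * Dx + Dy * Dy) < 1e-9) {
          Dx = std::cos(TH(t - 1, i));
          Dy = std::sin(TH(t - 1, i));
        }
      }
      // wall deflection inside the buffer
      {
        const double dmin = depth(px, py);
        if (dmin < wall_buffer) {
          const double nrmD = std::sqrt(Dx * Dx + Dy * Dy);
          if (nrmD > 1e-12) {
            Dx /= nrmD;
            Dy /= nrmD;
          }
          double ux = cx - px, uy = cy - py;
          const double nrmU = std::sqrt(ux * ux + uy * uy);
          if (nrmU > 1e-12) {
            const double w =
                2.0 * (1.0 - (dmin > 0 ? dmin : 0) / wall_buffer);
            Dx += w * ux / nrmU;
            Dy += w * uy / nrmU;
          }
        }
      }
      lact[i] = activity_rho * lact[i] + act_innov * R::norm_rand();
      const double act = std::exp(lact[i]);
      double th = std::atan2(Dy, Dx) +
                  heading_noise[i] * act * m_no * R::norm_rand();
      double mdev = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j != i) mdev += DEV(ts, j);
      }
      mdev /= (n - 1);
      const double dev = speed_persistence *
                             ((1.0 - sc) * DEV(t - 1, i) + sc * mdev) +
                         speed_noise[i] * act * m_no * R::norm_rand();
      DEV(t, i) = dev;
      double sp = pref_speed[i] * m_sp + dev;
      if (sp < 0) sp = 0;
      double nx = px + sp * dt * std::cos(th);
      double ny = py + sp * dt * std::sin(th);
      if (depth(nx, ny) < 0) {
        // aim straight at the centre; a step towards an interior point of
        // a convex polygon cannot leave it, clamping at the centre
        double ux = cx - px, uy = cy - py;
        const double dc = std::sqrt(ux * ux + uy * uy);
        th = std::atan2(uy, ux);
        double step = sp * dt;
        if (step > dc) step = dc;
        nx = px + step * std::cos(th);
        ny = py + step * std::sin(th);
        if (depth(nx, ny) < -1e-9)
          stop("fish escaped the arena (integration bug)");
      }
      X(t, i) = nx;
      Y(t, i) = ny;
      TH(t, i) = th;
      SP(t, i) = sp;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH,
                      _["speed"] = SP);
}
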