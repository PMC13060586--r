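#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Agent-based WHO cone assay simulator.  States are coded
// 1 = N (contacting the net), 2 = F (flying), 3 = C (resting on the cone),
// 4 = K (knocked down, absorbing).  Continuous transition hazards are
// discretised on the dt grid as P(step) = 1 - exp(-rate * dt).  Flying
// agents follow a correlated random walk clipped to the projected cone
// silhouette (an isosceles trapezoid, apex up); N agents sit on the net
// edge at the base; K agents drop to the base and stay static.  Knockdown
// hazard at each step is toxicity_hazard * cumulative net-contact time;
// irritancy multiplies the N->F and C->F rates by
// (1 + irritancy_gain * cumulative contact time).  Uses R's RNG.

struct Cone {
  double cx, apex_y, base_y, apex_hw, base_hw;
  double halfwidth(double y) const {
    return apex_hw + (base_hw - apex_hw) * (y - apex_y) / (base_y - apex_y);
  }
  bool inside(double x, double y) const {
    if (y < apex_y || y > base_y) return false;
    return std::abs(x - cx) <= halfwidth(y);
  }
};

// [[Rcpp::export]]
List simulate_cohort_cpp(int n_agents, int nstep, double dt,
                         double rate_C_to_F, double rate_F_to_C,
                         double rate_F_to_N, double rate_N_to_F,
                         double irritancy_gain, double toxicity_hazard,
                         double flight_speed, double turn_sd, double cx,
                         double apex_y, double base_y, double apex_hw,
                         double base_hw) {
  Cone cone{cx, apex_y, base_y, apex_hw, base_hw};
  int Tn = nstep + 1;
  IntegerMatrix state(Tn, n_agents);
  NumericMatrix X(Tn, n_agents), Y(Tn, n_agents), contact(Tn, n_agents);
  std::vector<double> heading(n_agents);

  // all agents start in flight at uniform positions in the cone interior
  for (int a = 0; a < n_agents; ++a) {
    double x, y;
    do {
      x = R::runif(cx - base_hw, cx + base_hw);
      y = R::runif(apex_y, base_y);
    } while (!cone.inside(x, y));
    X(0, a) = x;
    Y(0, a) = y;
    state(0, a) = 2;
    contact(0, a) = 0.0;
    heading[a] = R::runif(0.0, 2.0 * M_PI);
  }

  double lamF = rate_F_to_C + rate_F_to_N;
  double destC = lamF > 0 ? rate_F_to_C / lamF : 0.0;
  double step = flight_speed * dt;
  double mid_y = (apex_y + base_y) / 2.0;

  for (int t = 0; t < nstep; ++t) {
    for (int a = 0; a < n_agents; ++a) {
      int s = state(t, a);
      double x = X(t, a), y = Y(t, a), ct = contact(t, a);
      if (s == 1) ct += dt; // contact time accrues while on the net
      int ns = s;
      double nx = x, ny = y;
      if (s == 4) {
        // knocked down: absorbing, static on the base
      } else {
        double p_kd = 1.0 - std::exp(-toxicity_hazard * ct * dt);
        if (R::unif_rand() < p_kd) {
          ns = 4;
          ny = base_y;
        } else {
          double mult = 1.0 + irritancy_gain * ct;
          if (s == 3) {
            if (R::unif_rand() < 1.0 - std::exp(-rate_C_to_F * mult * dt))
              ns = 2;
          } else if (s == 1) {
            if (R::unif_rand() < 1.0 - std::exp(-rate_N_to_F * mult * dt))
              ns = 2;
          } else if (s == 2) {
            if (lamF > 0 && R::unif_rand() < 1.0 - std::exp(-lamF * dt))
              ns = R::unif_rand() < destC ? 3 : 1;
          }
          if (ns == 2) {
            if (s == 2)
              heading[a] += R::norm_rand() * turn_sd;
            else
              heading[a] = R::runif(0.0, 2.0 * M_PI); // take-off
            nx = x + std::cos(heading[a]) * step;
            ny = y + std::sin(heading[a]) * step;
            if (!cone.inside(nx, ny)) {
              // steer back toward the cone centre
              double ang = std::atan2(mid_y - y, cx - x);
              heading[a] = ang;
              nx = x + std::cos(ang) * step;
              ny = y + std::sin(ang) * step;
              if (!cone.inside(nx, ny)) {
                if (ny < apex_y + 1.0) ny = apex_y + 1.0;
                if (ny > base_y - 1.0) ny = base_y - 1.0;
                double hw = cone.halfwidth(ny) - 1.0;
                if (hw < 0) hw = 0;
                if (nx < cx - hw) nx = cx - hw;
                if (nx > cx + hw) nx = cx + hw;
              }
            }
          } else if (ns == 1 && s != 1) {
            // landing on the net edge at the cone base
            ny = base_y;
            double hw = base_hw - 1.0;
            if (nx < cx - hw) nx = cx - hw;
            if (nx > cx + hw) nx = cx + hw;
          } else if (ns == 3 && s == 2) {
            // alighting on the cone wall at the current height
            double hw = cone.halfwidth(y);
            nx = x >= cx ? cx + (hw - 0.5) : cx - (hw - 0.5);
          }
        }
      }
      state(t + 1, a) = ns;
      X(t + 1, a) = nx;
      Y(t + 1, a) = ny;
      contact(t + 1, a) = ct;
    }
  }
  return List::create(_["state"] = state, _["x"] = X, _["y"] = Y,
                      _["contact"] = contact);
}
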