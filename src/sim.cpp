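#include <Rcpp.h>
using namespace Rcpp;

// Analytic paraboloid bathymetry shared with make_lake(): depth at radius r
// from the lake centre, zero at and beyond the shoreline radius R.
static inline double bottom_at(double r, double max_depth, double R) {
  if (r >= R) return 0.0;
  double d = max_depth * (1.0 - (r / R) * (r / R));
  return d > 0.0 ? d : 0.0;
}

// Radial reflection at the shoreline (radius boundary), keeping the point
// strictly inside. Large overshoots are folded back iteratively.
static inline void reflect(double &x, double &y, double Rb) {
  for (int k = 0; k < 8; ++k) {
    double r = std::sqrt(x * x + y * y);
    if (r <= Rb || r == 0.0) return;
    double rnew = 2.0 * Rb - r;
    if (rnew < 0.0) rnew = 0.0;
    x *= rnew / r;
    y *= rnew / r;
  }
  double r = std::sqrt(x * x + y * y);
  if (r > Rb) { x *= 0.5 * Rb / r; y *= 0.5 * Rb / r; }
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_track(int n, double dt, int cruise,
                                 double x0, double y0,
                                 double home_x, double home_y,
                                 double revert, double sigma,
                                 double speed, double speed_sdlog,
                                 double turn_sd,
                                 double depth_k, double depth_sd,
                                 double benthic_offset,
                                 double pelagic_switch, double pelagic_return,
                                 NumericVector thermocline,
                                 double max_depth, double R) {
  NumericMatrix out(n, 3);
  double Rb = 0.995 * R;
  double x = x0, y = y0;
  reflect(x, y, Rb);
  double heading = R::runif(0.0, 2.0 * M_PI);
  int pelagic = 0;
  double sq = std::sqrt(dt);
  double bot = bottom_at(std::sqrt(x * x + y * y), max_depth, R);
  double target = bot - benthic_offset;
  if (target < 0.0) target = 0.0;
  double depth = target;

  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      if (cruise) {
        heading += R::rnorm(0.0, turn_sd);
        // lognormal step length with mean exactly speed*dt
        double len = speed * dt *
          std::exp(R::rnorm(0.0, speed_sdlog) - 0.5 * speed_sdlog * speed_sdlog);
        x += len * std::cos(heading);
        y += len * std::sin(heading);
      } else {
        x += revert * (home_x - x) * dt + sigma * sq * R::rnorm(0.0, 1.0);
        y += revert * (home_y - y) * dt + sigma * sq * R::rnorm(0.0, 1.0);
      }
      reflect(x, y, Rb);

      // two-state (benthic/pelagic) depth target with Markov switching
      if (pelagic_switch > 0.0 || pelagic_return > 0.0) {
        double u = R::runif(0.0, 1.0);
        if (!pelagic && u < pelagic_switch * dt) pelagic = 1;
        else if (pelagic && u < pelagic_return * dt) pelagic = 0;
      }
      bot = bottom_at(std::sqrt(x * x + y * y), max_depth, R);
      target = pelagic ? thermocline[i] : (bot - benthic_offset);
      if (target < 0.0) target = 0.0;
      depth += depth_k * (target - depth) * dt + depth_sd * sq * R::rnorm(0.0, 1.0);
    }
    if (depth < 0.0) depth = 0.0;
    if (depth > bot) depth = bot;
    out(i, 0) = x;
    out(i, 1) = y;
    out(i, 2) = depth;
  }
  return out;
}
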