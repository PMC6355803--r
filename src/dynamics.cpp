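#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step RK4 integration of the single-DOF trunk equation
//   I * theta'' = M_arm(t) - k * (theta - theta_P(t)) - b * (theta' - theta_P'(t))
// Pelvis angle/velocity and arm moment are sampled on the output grid and
// linearly interpolated at half steps. State is (theta, theta').
// [[Rcpp::export]]
NumericVector rk4_trunk(double k, double b, double inertia,
                        NumericVector pelvis, NumericVector pelvis_vel,
                        NumericVector arm_moment, double h,
                        double theta0, double omega0) {
  int n = pelvis.size();
  NumericVector out(n);
  double th = theta0, om = omega0;
  out[0] = th;
  for (int i = 0; i + 1 < n; ++i) {
    double p0 = pelvis[i], p1 = pelvis[i + 1], pm = 0.5 * (p0 + p1);
    double v0 = pelvis_vel[i], v1 = pelvis_vel[i + 1], vm = 0.5 * (v0 + v1);
    double m0 = arm_moment[i], m1 = arm_moment[i + 1], mm = 0.5 * (m0 + m1);

    double k1t = om;
    double k1o = (m0 - k * (th - p0) - b * (om - v0)) / inertia;

    double th2 = th + 0.5 * h * k1t, om2 = om + 0.5 * h * k1o;
    double k2t = om2;
    double k2o = (mm - k * (th2 - pm) - b * (om2 - vm)) / inertia;

    double th3 = th + 0.5 * h * k2t, om3 = om + 0.5 * h * k2o;
    double k3t = om3;
    double k3o = (mm - k * (th3 - pm) - b * (om3 - vm)) / inertia;

    double th4 = th + h * k3t, om4 = om + h * k3o;
    double k4t = om4;
    double k4o = (m1 - k * (th4 - p1) - b * (om4 - v1)) / inertia;

    th += h / 6.0 * (k1t + 2.0 * k2t + 2.0 * k3t + k4t);
    om += h / 6.0 * (k1o + 2.0 * k2o + 2.0 * k3o + k4o);
    out[i + 1] = th;
  }
  return out;
}

// Direct-form II transposed IIR filter with explicit initial state zi
// (length max(length(a), length(b)) - 1). a[0] must be 1.
// [[Rcpp::export]]
NumericVector iir_filter_zi(NumericVector b, NumericVector a,
                            NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int m = std::max(nb, na) - 1;
  std::vector<double> bc(m + 1, 0.0), ac(m + 1, 0.0), z(m + 1, 0.0);
  for (int i = 0; i < nb; ++i) bc[i] = b[i];
  for (int i = 0; i < na; ++i) ac[i] = a[i];
  for (int i = 0; i < m; ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yi = bc[0] * x[i] + z[0];
    for (int j = 0; j < m; ++j)
      z[j] = bc[j + 1] * x[i] + z[j + 1] - ac[j + 1] * yi;
    y[i] = yi;
  }
  return y;
}
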