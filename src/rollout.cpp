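#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// Does the motion segment p->q cross wall a->b? If so return parameter t in (0,1]
// along p->q of the intersection, else -1.
static double wall_hit(const double* p, const double* q,
                       const double* a, const double* b) {
  double d1 = cross2(b[0] - a[0], b[1] - a[1], p[0] - a[0], p[1] - a[1]);
  double d2 = cross2(b[0] - a[0], b[1] - a[1], q[0] - a[0], q[1] - a[1]);
  double d3 = cross2(q[0] - p[0], q[1] - p[1], a[0] - p[0], a[1] - p[1]);
  double d4 = cross2(q[0] - p[0], q[1] - p[1], b[0] - p[0], b[1] - p[1]);
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0) || (d1 != 0 && d2 == 0)) &&
      ((d3 >= 0 && d4 <= 0) || (d3 <= 0 && d4 >= 0))) {
    double denom = d1 - d2;
    if (denom == 0) return -1.0;
    return d1 / denom;
  }
  return -1.0;
}

// Hard wall constraint in the 2-D behavior plane: a step whose plane segment
// crosses a wall is stopped at the wall and slid tangentially; the point is
// nudged an epsilon back toward the pre-crossing side.
static void project_walls(const NumericMatrix& walls, double* p, double* q) {
  const int nw = walls.nrow();
  for (int iter = 0; iter < 4; ++iter) {
    double tbest = 2.0; int wbest = -1;
    for (int w = 0; w < nw; ++w) {
      double a[2] = { walls(w, 0), walls(w, 1) };
      double b[2] = { walls(w, 2), walls(w, 3) };
      double t = wall_hit(p, q, a, b);
      if (t >= 0 && t < tbest) { tbest = t; wbest = w; }
    }
    if (wbest < 0) return;
    double a[2] = { walls(wbest, 0), walls(wbest, 1) };
    double b[2] = { walls(wbest, 2), walls(wbest, 3) };
    double X[2] = { p[0] + tbest * (q[0] - p[0]), p[1] + tbest * (q[1] - p[1]) };
    double dx = b[0] - a[0], dy = b[1] - a[1];
    double dn = std::sqrt(dx * dx + dy * dy);
    if (dn == 0) { q[0] = p[0]; q[1] = p[1]; return; }
    dx /= dn; dy /= dn;
    double remx = q[0] - X[0], remy = q[1] - X[1];
    double tang = remx * dx + remy * dy;
    // normal pointing back toward the pre-crossing side
    double nx = -dy, ny = dx;
    double side = (p[0] - X[0]) * nx + (p[1] - X[1]) * ny;
    double sgn = (side >= 0) ? 1.0 : -1.0;
    double steplen = std::sqrt((q[0] - p[0]) * (q[0] - p[0]) +
                               (q[1] - p[1]) * (q[1] - p[1]));
    double eps = 1e-9 * (1.0 + steplen);
    q[0] = X[0] + tang * dx + sgn * eps * nx;
    q[1] = X[1] + tang * dy + sgn * eps * ny;
  }
  // could not resolve after sliding: stay put
  q[0] = p[0]; q[1] = p[1];
}

// Discrete transcriptional gene-circuit rollout:
//   y(t+1) = (dt/tau) * sigmoid(W y + B) + (1 - dt/tau) * y
// with optional per-step hooks, applied in the fixed order
//   state update -> displacement events -> wall constraint -> clamps.
// ev_step / clamp_step are 1-based step indices (step k produces row k+1).
// [[Rcpp::export]]
NumericMatrix cpp_rollout_circuit(NumericMatrix W, NumericVector B,
                                  NumericVector a, NumericVector y0,
                                  int n_steps,
                                  IntegerVector ev_step, NumericMatrix ev_disp,
                                  IntegerVector clamp_step,
                                  IntegerVector clamp_node,
                                  NumericVector clamp_value,
                                  NumericMatrix walls,
                                  IntegerVector wall_coords) {
  const int n = y0.size();
  NumericMatrix out(n_steps + 1, n);
  std::vector<double> y(n), ynew(n);
  for (int i = 0; i < n; ++i) { y[i] = y0[i]; out(0, i) = y0[i]; }
  const bool have_walls = walls.nrow() > 0;
  const int wc0 = have_walls ? wall_coords[0] : 0;
  const int wc1 = have_walls ? wall_coords[1] : 0;
  int ep = 0, cp = 0;
  const int n_ev = ev_step.size(), n_cl = clamp_step.size();
  bool dead = false;  // non-finite state: freeze and propagate NaN rows
  for (int k = 1; k <= n_steps; ++k) {
    if (!dead) {
      for (int i = 0; i < n; ++i) {
        double s = B[i];
        for (int j = 0; j < n; ++j) s += W(i, j) * y[j];
        ynew[i] = a[i] * sigmoid(s) + (1.0 - a[i]) * y[i];
      }
      while (ep < n_ev && ev_step[ep] == k) {
        for (int i = 0; i < n; ++i) ynew[i] += ev_disp(ep, i);
        ++ep;
      }
      while (ep < n_ev && ev_step[ep] < k) ++ep;  // defensive: skip stale events
      if (have_walls) {
        double p[2] = { y[wc0], y[wc1] };
        double q[2] = { ynew[wc0], ynew[wc1] };
        project_walls(walls, p, q);
        ynew[wc0] = q[0]; ynew[wc1] = q[1];
      }
      while (cp < n_cl && clamp_step[cp] == k) {
        ynew[clamp_node[cp]] = clamp_value[cp];
        ++cp;
      }
      while (cp < n_cl && clamp_step[cp] < k) ++cp;
      bool bad = false;
      for (int i = 0; i < n; ++i) if (!std::isfinite(ynew[i])) bad = true;
      if (bad) dead = true; else y = ynew;
    }
    for (int i = 0; i < n; ++i) out(k, i) = dead ? NA_REAL : y[i];
  }
  return out;
}

// Loss and exact gradient of L = sum_t (y[node](t) - (A cos(2 pi omega t dt) + b))^2
// through the unrolled discrete gene-circuit update, by forward-mode sensitivity
// propagation. theta = (y0 [n], W column-major [n*n], B [n]); tau = 1 fixed (a = dt).
// [[Rcpp::export]]
List cpp_circuit_loss_grad(NumericVector theta, int n, double dt, int n_steps,
                           double A, double omega, double b, int node) {
  const int p = n + n * n + n;
  std::vector<double> y(n), W(n * n), B(n);
  for (int i = 0; i < n; ++i) y[i] = theta[i];
  for (int i = 0; i < n * n; ++i) W[i] = theta[n + i];          // column-major
  for (int i = 0; i < n; ++i) B[i] = theta[n + n * n + i];
  // J: n x p sensitivity, row-major in vector (i * p + c)
  std::vector<double> J(n * p, 0.0), Jn(n * p), s(n), D(n), WJ(n);
  for (int i = 0; i < n; ++i) J[i * p + i] = 1.0;  // d y0 / d y0
  double loss = 0.0;
  NumericVector grad(p);
  const double a = dt;  // tau = 1
  const double twopi = 2.0 * M_PI;
  for (int k = 0; k <= n_steps; ++k) {
    double target = A * std::cos(twopi * omega * (k * dt)) + b;
    double r = y[node] - target;
    loss += r * r;
    for (int c = 0; c < p; ++c) grad[c] += 2.0 * r * J[node * p + c];
    if (k == n_steps) break;
    for (int i = 0; i < n; ++i) {
      double z = B[i];
      for (int j = 0; j < n; ++j) z += W[i + j * n] * y[j];
      s[i] = sigmoid(z);
      D[i] = s[i] * (1.0 - s[i]);
    }
    for (int i = 0; i < n; ++i) {
      for (int c = 0; c < p; ++c) {
        double wj = 0.0;
        for (int j = 0; j < n; ++j) wj += W[i + j * n] * J[j * p + c];
        Jn[i * p + c] = a * D[i] * wj + (1.0 - a) * J[i * p + c];
      }
      // direct parameter terms: dz_i/dW_{i,j} = y_j ; dz_i/dB_i = 1
      for (int j = 0; j < n; ++j)
        Jn[i * p + (n + j * n + i)] += a * D[i] * y[j];
      Jn[i * p + (n + n * n + i)] += a * D[i];
    }
    std::swap(J, Jn);
    for (int i = 0; i < n; ++i) {
      double z = B[i];
      for (int j = 0; j < n; ++j) z += W[i + j * n] * y[j];
      s[i] = sigmoid(z);
    }
    for (int i = 0; i < n; ++i) y[i] = a * s[i] + (1.0 - a) * y[i];
  }
  return List::create(_["loss"] = loss, _["grad"] = grad);
}
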