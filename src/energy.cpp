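#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bead-spring chain energetics in reduced units (delta = 1 ~ 30 nm,
// kBT = 1). Coordinates are (n+1) x 3 matrices of segment end points.
// All pair loops are O(n^2); n is at restriction-fragment scale
// (tens of beads), so brute force is both exact and fast.

static inline double dist3(const NumericMatrix& X, int i, int j) {
  double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
         dz = X(i, 2) - X(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Stretching energy: sum_i 0.5 * ks * (l_i - l0_i)^2
static double stretch_e(const NumericMatrix& X, const NumericVector& rest,
                        double ks) {
  int n = X.nrow() - 1;
  double e = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = X(i + 1, 0) - X(i, 0);
    double dy = X(i + 1, 1) - X(i, 1);
    double dz = X(i + 1, 2) - X(i, 2);
    double l = std::sqrt(dx * dx + dy * dy + dz * dz);
    double d = l - rest[i];
    e += 0.5 * ks * d * d;
  }
  return e;
}

// Bending energy: sum over interior end points of 0.5 * ktheta * theta^2,
// theta the planar angle between consecutive bond vectors.
// Returns NA if a zero-length bond makes an angle undefined.
static double bend_e(const NumericMatrix& X, double ktheta) {
  int np = X.nrow();
  double e = 0.0;
  for (int i = 1; i + 1 < np; ++i) {
    double ux = X(i + 1, 0) - X(i, 0), uy = X(i + 1, 1) - X(i, 1),
           uz = X(i + 1, 2) - X(i, 2);
    double vx = X(i, 0) - X(i - 1, 0), vy = X(i, 1) - X(i - 1, 1),
           vz = X(i, 2) - X(i - 1, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) return NA_REAL;
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    e += 0.5 * ktheta * th * th;
  }
  return e;
}

// Excluded volume: WCA (truncated + shifted Lennard-Jones) over all end
// point pairs (i, j), j >= i + 1. Purely repulsive, C1 at the cutoff
// 2^(1/6) * delta. A coincident counted pair yields +Inf.
static double exclude_e(const NumericMatrix& X, double eps, double delta) {
  int np = X.nrow();
  double cutoff = std::pow(2.0, 1.0 / 6.0) * delta;
  double e = 0.0;
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = dist3(X, i, j);
      if (d >= cutoff) continue;
      if (d < 1e-12) return R_PosInf;
      double q6 = std::pow(delta / d, 6.0);
      e += 4.0 * eps * (q6 * q6 - q6 + 0.25);
    }
  }
  return e;
}

// [[Rcpp::export]]
List energy_terms_cpp(NumericMatrix coords, NumericVector rest, double ks,
                      double ktheta, double eps, double delta) {
  return List::create(_["stretch"] = stretch_e(coords, rest, ks),
                      _["bend"] = bend_e(coords, ktheta),
                      _["exclude"] = exclude_e(coords, eps, delta));
}

// Analytic gradient of the total conformational energy, d E / d s_j.
// ok is set to false on degenerate geometry (zero-length bond or
// coincident excluded-volume pair).
static bool energy_grad(const NumericMatrix& X, const NumericVector& rest,
                        double ks, double ktheta, double eps, double delta,
                        NumericMatrix& G) {
  int np = X.nrow();
  int n = np - 1;
  std::fill(G.begin(), G.end(), 0.0);

  // stretch
  for (int i = 0; i < n; ++i) {
    double ux = X(i + 1, 0) - X(i, 0), uy = X(i + 1, 1) - X(i, 1),
           uz = X(i + 1, 2) - X(i, 2);
    double l = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (l < 1e-12) return false;
    double f = ks * (l - rest[i]) / l;
    G(i + 1, 0) += f * ux; G(i + 1, 1) += f * uy; G(i + 1, 2) += f * uz;
    G(i, 0) -= f * ux; G(i, 1) -= f * uy; G(i, 2) -= f * uz;
  }

  // bend: E_i = 0.5 * ktheta * theta^2, theta = acos(c),
  // c = <u, v> / (|u||v|), u = s_{i+1} - s_i, v = s_i - s_{i-1}.
  // dE/dc = -ktheta * theta / sin(theta) -> -ktheta as theta -> 0.
  for (int i = 1; i + 1 < np; ++i) {
    double ux = X(i + 1, 0) - X(i, 0), uy = X(i + 1, 1) - X(i, 1),
           uz = X(i + 1, 2) - X(i, 2);
    double vx = X(i, 0) - X(i - 1, 0), vy = X(i, 1) - X(i - 1, 1),
           vz = X(i, 2) - X(i - 1, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) return false;
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double s = std::sin(th);
    double dEdc = (th < 1e-8) ? -ktheta : -ktheta * th / std::max(s, 1e-8);
    // dc/du and dc/dv
    double inun = 1.0 / (nu * nv);
    double cuu = c / (nu * nu), cvv = c / (nv * nv);
    double dux = vx * inun - cuu * ux, duy = vy * inun - cuu * uy,
           duz = vz * inun - cuu * uz;
    double dvx = ux * inun - cvv * vx, dvy = uy * inun - cvv * vy,
           dvz = uz * inun - cvv * vz;
    G(i + 1, 0) += dEdc * dux; G(i + 1, 1) += dEdc * duy;
    G(i + 1, 2) += dEdc * duz;
    G(i, 0) += dEdc * (dvx - dux); G(i, 1) += dEdc * (dvy - duy);
    G(i, 2) += dEdc * (dvz - duz);
    G(i - 1, 0) -= dEdc * dvx; G(i - 1, 1) -= dEdc * dvy;
    G(i - 1, 2) -= dEdc * dvz;
  }

  // excluded volume (WCA): dE/dd = -(24 eps / d) * (2 q12 - q6)
  double cutoff = std::pow(2.0, 1.0 / 6.0) * delta;
  for (int i = 0; i < np; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
             dz = X(i, 2) - X(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d >= cutoff) continue;
      if (d < 1e-12) return false;
      double q6 = std::pow(delta / d, 6.0);
      double dEdd = -(24.0 * eps / d) * (2.0 * q6 * q6 - q6);
      double f = dEdd / d;
      G(i, 0) += f * dx; G(i, 1) += f * dy; G(i, 2) += f * dz;
      G(j, 0) -= f * dx; G(j, 1) -= f * dy; G(j, 2) -= f * dz;
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericMatrix energy_gradient_cpp(NumericMatrix coords, NumericVector rest,
                                  double ks, double ktheta, double eps,
                                  double delta) {
  NumericMatrix G(coords.nrow(), 3);
  if (!energy_grad(coords, rest, ks, ktheta, eps, delta, G))
    stop("degenerate geometry: zero-length bond or coincident end points");
  return G;
}

// Back-computed restraint distances: Euclidean distance between the
// midpoints of fragments pi[r] and pj[r] (0-based fragment indices).
// [[Rcpp::export]]
NumericVector backcompute_cpp(NumericMatrix coords, IntegerVector pi,
                              IntegerVector pj) {
  int m = pi.size();
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    int a = pi[r], b = pj[r];
    double mx = 0.5 * (coords(a, 0) + coords(a + 1, 0)) -
                0.5 * (coords(b, 0) + coords(b + 1, 0));
    double my = 0.5 * (coords(a, 1) + coords(a + 1, 1)) -
                0.5 * (coords(b, 1) + coords(b + 1, 1));
    double mz = 0.5 * (coords(a, 2) + coords(a + 1, 2)) -
                0.5 * (coords(b, 2) + coords(b + 1, 2));
    out[r] = std::sqrt(mx * mx + my * my + mz * mz);
  }
  return out;
}

// Gradient of the Gaussian restraint log-likelihood term
// -(1/(2 sigma^2)) * sum_r (Ds_r - D_r)^2 with respect to the coordinates.
// [[Rcpp::export]]
NumericMatrix data_gradient_cpp(NumericMatrix coords, IntegerVector pi,
                                IntegerVector pj, NumericVector targets,
                                double sigma) {
  int m = pi.size();
  NumericMatrix G(coords.nrow(), 3);
  std::fill(G.begin(), G.end(), 0.0);
  double w = 1.0 / (sigma * sigma);
  for (int r = 0; r < m; ++r) {
    int a = pi[r], b = pj[r];
    double mx = 0.5 * (coords(a, 0) + coords(a + 1, 0)) -
                0.5 * (coords(b, 0) + coords(b + 1, 0));
    double my = 0.5 * (coords(a, 1) + coords(a + 1, 1)) -
                0.5 * (coords(b, 1) + coords(b + 1, 1));
    double mz = 0.5 * (coords(a, 2) + coords(a + 1, 2)) -
                0.5 * (coords(b, 2) + coords(b + 1, 2));
    double d = std::sqrt(mx * mx + my * my + mz * mz);
    if (d < 1e-12) continue;  // flat direction; skip
    double coef = -w * (d - targets[r]) / d * 0.5;
    G(a, 0) += coef * mx; G(a, 1) += coef * my; G(a, 2) += coef * mz;
    G(a + 1, 0) += coef * mx; G(a + 1, 1) += coef * my;
    G(a + 1, 2) += coef * mz;
    G(b, 0) -= coef * mx; G(b, 1) -= coef * my; G(b, 2) -= coef * mz;
    G(b + 1, 0) -= coef * mx; G(b + 1, 1) -= coef * my;
    G(b + 1, 2) -= coef * mz;
  }
  return G;
}

// Overdamped Langevin (Brownian) dynamics on the conformational energy:
//   s <- s - (dt/gamma) * grad E + sqrt(2 kBT dt / gamma) * xi
// with per-bead displacements capped at max_disp (stabilizes the stiff
// excluded-volume force) and reflection into a sphere of radius `radius`
// about the origin. Draws from R's RNG so set.seed() governs the result.
// [[Rcpp::export]]
NumericMatrix brownian_cpp(NumericMatrix start, NumericVector rest, double ks,
                           double ktheta, double eps, double delta,
                           double kBT, double radius, int steps, double dt,
                           double gamma, double max_disp) {
  RNGScope scope;
  NumericMatrix X = clone(start);
  int np = X.nrow();
  NumericMatrix G(np, 3);
  double noise = std::sqrt(2.0 * kBT * dt / gamma);
  for (int t = 0; t < steps; ++t) {
    bool ok = energy_grad(X, rest, ks, ktheta, eps, delta, G);
    for (int r = 0; r < np; ++r) {
      double dx = noise * norm_rand();
      double dy = noise * norm_rand();
      double dz = noise * norm_rand();
      if (ok) {
        dx -= dt / gamma * G(r, 0);
        dy -= dt / gamma * G(r, 1);
        dz -= dt / gamma * G(r, 2);
      }
      double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dn > max_disp) {
        double f = max_disp / dn;
        dx *= f; dy *= f; dz *= f;
      }
      X(r, 0) += dx; X(r, 1) += dy; X(r, 2) += dz;
      double rn = std::sqrt(X(r, 0) * X(r, 0) + X(r, 1) * X(r, 1) +
                            X(r, 2) * X(r, 2));
      if (rn > radius) {
        double f = (2.0 * radius - rn) / rn;
        if (f < 0.0) f = radius / rn;  // far overshoot: project to surface
        X(r, 0) *= f; X(r, 1) *= f; X(r, 2) *= f;
      }
    }
  }
  return X;
}
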