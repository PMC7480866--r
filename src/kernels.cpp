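#include <Rcpp.h>
using namespace Rcpp;

// 2D regularized Stokeslets for the algebraic blob
//   phi_eps(r) = 3 eps^3 / (2 pi (r^2 + eps^2)^(5/2)).
// With R = sqrt(r^2 + eps^2) and xh = x - x0 the induced fields are
//   u(x) = 1/(4 pi mu) * sum_k [ f_k * (-log((R+eps)/L0) + eps(R+2eps)/(R(R+eps)))
//                               + (f_k . xh) xh (R+2eps)/(R (R+eps)^2) ]
//   p(x) = 1/(2 pi)    * sum_k (f_k . xh) (R^2 + eps R + eps^2)/(R^3 (R+eps))
// Both are finite at the source and reduce to the singular 2D Stokeslet
// kernels as r/eps -> infinity.  In 2D the Stokeslet velocity is defined
// only up to an additive constant per unit force (Stokes paradox); L0 is
// the outer screening length at which the flow of a single force is taken
// to vanish, and must exceed the domain size so that forces drag fluid
// along their own direction everywhere in the domain.

// [[Rcpp::export]]
NumericMatrix rs_velocity_cpp(NumericMatrix src, NumericMatrix f,
                              NumericMatrix targets, double eps, double mu,
                              double L0) {
  const int ns = src.nrow(), nt = targets.nrow();
  NumericMatrix out(nt, 2);
  const double c = 1.0 / (4.0 * M_PI * mu);
  const double lcut = std::log(L0);
  for (int i = 0; i < nt; ++i) {
    double ux = 0.0, uy = 0.0;
    const double tx = targets(i, 0), ty = targets(i, 1);
    for (int k = 0; k < ns; ++k) {
      const double dx = tx - src(k, 0), dy = ty - src(k, 1);
      const double r2 = dx * dx + dy * dy;
      const double R = std::sqrt(r2 + eps * eps);
      const double Re = R + eps;
      const double h1 = lcut - std::log(Re) + eps * (R + 2.0 * eps) / (R * Re);
      const double h2 = (R + 2.0 * eps) / (R * Re * Re);
      const double fx = f(k, 0), fy = f(k, 1);
      const double fdotx = fx * dx + fy * dy;
      ux += fx * h1 + fdotx * dx * h2;
      uy += fy * h1 + fdotx * dy * h2;
    }
    out(i, 0) = c * ux;
    out(i, 1) = c * uy;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector rs_pressure_cpp(NumericMatrix src, NumericMatrix f,
                              NumericMatrix targets, double eps) {
  const int ns = src.nrow(), nt = targets.nrow();
  NumericVector out(nt);
  const double c = 1.0 / (2.0 * M_PI);
  for (int i = 0; i < nt; ++i) {
    double p = 0.0;
    const double tx = targets(i, 0), ty = targets(i, 1);
    for (int k = 0; k < ns; ++k) {
      const double dx = tx - src(k, 0), dy = ty - src(k, 1);
      const double R = std::sqrt(dx * dx + dy * dy + eps * eps);
      const double fdotx = f(k, 0) * dx + f(k, 1) * dy;
      p += fdotx * (R * R + eps * R + eps * eps) / (R * R * R * (R + eps));
    }
    out[i] = c * p;
  }
  return out;
}

// Velocities at the force points themselves, exploiting the symmetry of
// the kernel (each pair is visited once).
// [[Rcpp::export]]
NumericMatrix rs_velocity_self_cpp(NumericMatrix loc, NumericMatrix f,
                                   double eps, double mu, double L0) {
  const int n = loc.nrow();
  NumericMatrix out(n, 2);
  const double c = 1.0 / (4.0 * M_PI * mu);
  const double lcut = std::log(L0);
  const double self_h1 = lcut - std::log(2.0 * eps) + 1.5;
  std::vector<double> ux(n, 0.0), uy(n, 0.0);
  for (int i = 0; i < n; ++i) {
    ux[i] += self_h1 * f(i, 0);
    uy[i] += self_h1 * f(i, 1);
    const double xi = loc(i, 0), yi = loc(i, 1);
    const double fxi = f(i, 0), fyi = f(i, 1);
    for (int k = i + 1; k < n; ++k) {
      const double dx = xi - loc(k, 0), dy = yi - loc(k, 1);
      const double R = std::sqrt(dx * dx + dy * dy + eps * eps);
      const double Re = R + eps;
      const double invRRe = 1.0 / (R * Re);
      const double h1 = lcut - std::log(Re) + eps * (R + 2.0 * eps) * invRRe;
      const double h2 = (R + 2.0 * eps) * invRRe / Re;
      const double fxk = f(k, 0), fyk = f(k, 1);
      // velocity at i from force at k (xh = +d)
      double fdx = fxk * dx + fyk * dy;
      ux[i] += fxk * h1 + fdx * dx * h2;
      uy[i] += fyk * h1 + fdx * dy * h2;
      // velocity at k from force at i (xh = -d; h2 term even in sign)
      fdx = fxi * dx + fyi * dy;
      ux[k] += fxi * h1 + fdx * dx * h2;
      uy[k] += fyi * h1 + fdx * dy * h2;
    }
  }
  for (int i = 0; i < n; ++i) { out(i, 0) = c * ux[i]; out(i, 1) = c * uy[i]; }
  return out;
}

// Dense 2N x 2N mobility matrix (stacked as x1,y1,x2,y2,...).
// [[Rcpp::export]]
NumericMatrix rs_mobility_cpp(NumericMatrix locs, double eps, double mu,
                              double L0) {
  const int n = locs.nrow();
  NumericMatrix M(2 * n, 2 * n);
  const double c = 1.0 / (4.0 * M_PI * mu);
  const double lcut = std::log(L0);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < n; ++k) {
      const double dx = locs(i, 0) - locs(k, 0);
      const double dy = locs(i, 1) - locs(k, 1);
      const double R = std::sqrt(dx * dx + dy * dy + eps * eps);
      const double Re = R + eps;
      const double h1 = lcut - std::log(Re) + eps * (R + 2.0 * eps) / (R * Re);
      const double h2 = (R + 2.0 * eps) / (R * Re * Re);
      M(2 * i, 2 * k)         = c * (h1 + dx * dx * h2);
      M(2 * i, 2 * k + 1)     = c * (dx * dy * h2);
      M(2 * i + 1, 2 * k)     = c * (dx * dy * h2);
      M(2 * i + 1, 2 * k + 1) = c * (h1 + dy * dy * h2);
    }
  }
  return M;
}

// Even-odd (ray crossing) point-in-polygon test; points exactly on an
// edge are counted as outside so that geometry guards never loop on
// boundary points.
// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericMatrix pts, NumericMatrix poly) {
  const int np = pts.nrow(), nv = poly.nrow();
  LogicalVector inside(np);
  for (int i = 0; i < np; ++i) {
    const double x = pts(i, 0), y = pts(i, 1);
    bool in = false, onedge = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      const double xa = poly(a, 0), ya = poly(a, 1);
      const double xb = poly(b, 0), yb = poly(b, 1);
      // on-edge check (collinear and within bounding box)
      const double cross = (xb - xa) * (y - ya) - (yb - ya) * (x - xa);
      if (std::fabs(cross) < 1e-14 &&
          x >= std::min(xa, xb) - 1e-14 && x <= std::max(xa, xb) + 1e-14 &&
          y >= std::min(ya, yb) - 1e-14 && y <= std::max(ya, yb) + 1e-14) {
        onedge = true;
        break;
      }
      if (((ya > y) != (yb > y)) &&
          (x < (xb - xa) * (y - ya) / (yb - ya) + xa))
        in = !in;
    }
    inside[i] = onedge ? false : in;
  }
  return inside;
}
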