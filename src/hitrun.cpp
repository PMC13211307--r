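#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Hit-and-Run sampler over {x : A x <= b} intersected with an optional
// convex quadratic {x : x'Mx + v'x <= qc} and an optional ball
// {x : ||x - bc|| <= br}. Directions are uniform on the sphere; the next
// point is uniform on the feasible chord. Uses R's RNG so set.seed()
// controls reproducibility.
//
// Returns an n x d matrix of retained samples, each separated by `thin`
// chord steps, starting from the strictly interior point x0.
// [[Rcpp::export]]
NumericMatrix hr_sample_cpp(const NumericMatrix& A, const NumericVector& b,
                            bool have_quad, const NumericMatrix& M,
                            const NumericVector& v, double qc,
                            bool have_ball, const NumericVector& bc,
                            double br, const NumericVector& x0,
                            int n, int thin) {
  const int d = x0.size();
  const int m = A.nrow();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> u(d), Mx(d), Mu(d);
  NumericMatrix out(n, d);
  const double eps = 1e-14;

  for (int k = 0; k < n; ++k) {
    for (int step = 0; step < thin; ++step) {
      bool ok = false;
      double tlo = 0.0, thi = 0.0;
      for (int attempt = 0; attempt < 100 && !ok; ++attempt) {
        // random direction
        double nrm = 0.0;
        for (int j = 0; j < d; ++j) { u[j] = norm_rand(); nrm += u[j] * u[j]; }
        nrm = std::sqrt(nrm);
        if (nrm < eps) continue;
        for (int j = 0; j < d; ++j) u[j] /= nrm;

        tlo = -HUGE_VAL; thi = HUGE_VAL;
        bool empty = false;
        // linear half-spaces
        for (int i = 0; i < m; ++i) {
          double den = 0.0, ax = 0.0;
          for (int j = 0; j < d; ++j) {
            den += A(i, j) * u[j];
            ax  += A(i, j) * x[j];
          }
          double slack = b[i] - ax;
          if (den > eps) {
            double t = slack / den; if (t < thi) thi = t;
          } else if (den < -eps) {
            double t = slack / den; if (t > tlo) tlo = t;
          } else if (slack < -1e-10) { empty = true; break; }
        }
        // quadratic constraint(s): alpha t^2 + beta t + gamma <= 0
        if (!empty && have_quad) {
          double alpha = 0.0, beta = 0.0, gamma = 0.0;
          for (int i = 0; i < d; ++i) {
            double mi_x = 0.0, mi_u = 0.0;
            for (int j = 0; j < d; ++j) {
              mi_x += M(i, j) * x[j];
              mi_u += M(i, j) * u[j];
            }
            Mx[i] = mi_x; Mu[i] = mi_u;
          }
          for (int j = 0; j < d; ++j) {
            alpha += u[j] * Mu[j];
            beta  += 2.0 * x[j] * Mu[j] + v[j] * u[j];
            gamma += x[j] * Mx[j] + v[j] * x[j];
          }
          gamma -= qc;
          if (alpha > eps) {
            double disc = beta * beta - 4.0 * alpha * gamma;
            if (disc <= 0) { empty = true; }
            else {
              double sq = std::sqrt(disc);
              double t1 = (-beta - sq) / (2.0 * alpha);
              double t2 = (-beta + sq) / (2.0 * alpha);
              if (t1 > tlo) tlo = t1;
              if (t2 < thi) thi = t2;
            }
          } else {
            // essentially linear along u
            if (beta > eps) { double t = -gamma / beta; if (t < thi) thi = t; }
            else if (beta < -eps) { double t = -gamma / beta; if (t > tlo) tlo = t; }
            else if (gamma > 1e-10) empty = true;
          }
        }
        if (!empty && have_ball) {
          double beta = 0.0, gamma = 0.0;
          for (int j = 0; j < d; ++j) {
            double dx = x[j] - bc[j];
            beta += 2.0 * dx * u[j];
            gamma += dx * dx;
          }
          gamma -= br * br;
          double disc = beta * beta - 4.0 * gamma;
          if (disc <= 0) empty = true;
          else {
            double sq = std::sqrt(disc);
            double t1 = (-beta - sq) / 2.0;
            double t2 = (-beta + sq) / 2.0;
            if (t1 > tlo) tlo = t1;
            if (t2 < thi) thi = t2;
          }
        }
        if (!empty && thi - tlo > 1e-13 &&
            std::isfinite(tlo) && std::isfinite(thi)) ok = true;
      }
      if (!ok)
        stop("hit-and-run: no feasible chord found (start not interior, "
             "or degenerate body)");
      double t = tlo + unif_rand() * (thi - tlo);
      for (int j = 0; j < d; ++j) x[j] += t * u[j];
    }
    for (int j = 0; j < d; ++j) out(k, j) = x[j];
  }
  return out;
}
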