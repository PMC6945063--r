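// Numerical kernels: Gauss-Seidel SOR for the 7-point finite-difference
// linearized Poisson-Boltzmann equation, Shrake-Rupley SASA quadrature,
// and a pairwise minimum-distance helper.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Solve  sum_f eps_f (phi_nb - phi0) * h  -  kap_i phi0  =  -src_i
// on a regular grid with Dirichlet boundaries already written into phi.
// phi is column-major with index i + nx*(j + ny*k).
// epsx has dims (nx-1, ny, nz): face between (i,j,k) and (i+1,j,k);
// epsy, epsz analogous. kap = eps_solv * kappa^2 * h^3 per node (0 inside
// the solute + Stern layer). src = 4*pi*ke*q spread per node.
// [[Rcpp::export]]
List sor_lpbe(NumericVector phi_init, IntegerVector dim,
              NumericVector epsx, NumericVector epsy, NumericVector epsz,
              NumericVector kap, NumericVector src,
              double h, double omega, double tol, int max_iter) {
  NumericVector phi = clone(phi_init);
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nxy = nx * ny;
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *kp = REAL(kap), *b = REAL(src);

  // norm of the source for the relative residual
  double bnorm = 0.0;
  for (int i = 0; i < nx * ny * nz; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm <= 0.0) bnorm = 1.0;

  double relres = R_PosInf;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        int base = nx * (j + ny * k);
        for (int i = 1; i < nx - 1; ++i) {
          int id = i + base;
          double exm = ex[(i - 1) + (nx - 1) * (j + ny * k)];
          double exp_ = ex[i + (nx - 1) * (j + ny * k)];
          double eym = ey[i + nx * ((j - 1) + (ny - 1) * k)];
          double eyp = ey[i + nx * (j + (ny - 1) * k)];
          double ezm = ez[i + nx * (j + ny * (k - 1))];
          double ezp = ez[i + nx * (j + ny * k)];
          double num = h * (exm * p[id - 1] + exp_ * p[id + 1] +
                            eym * p[id - nx] + eyp * p[id + nx] +
                            ezm * p[id - nxy] + ezp * p[id + nxy]) + b[id];
          double den = h * (exm + exp_ + eym + eyp + ezm + ezp) + kp[id];
          double newv = num / den;
          p[id] += omega * (newv - p[id]);
        }
      }
    }
    if (iter % 10 == 0 || iter == max_iter) {
      double rnorm = 0.0;
      for (int k = 1; k < nz - 1; ++k)
        for (int j = 1; j < ny - 1; ++j)
          for (int i = 1; i < nx - 1; ++i) {
            int id = i + nx * (j + ny * k);
            double exm = ex[(i - 1) + (nx - 1) * (j + ny * k)];
            double exp_ = ex[i + (nx - 1) * (j + ny * k)];
            double eym = ey[i + nx * ((j - 1) + (ny - 1) * k)];
            double eyp = ey[i + nx * (j + (ny - 1) * k)];
            double ezm = ez[i + nx * (j + ny * (k - 1))];
            double ezp = ez[i + nx * (j + ny * k)];
            double r = h * (exm * (p[id - 1] - p[id]) +
                            exp_ * (p[id + 1] - p[id]) +
                            eym * (p[id - nx] - p[id]) +
                            eyp * (p[id + nx] - p[id]) +
                            ezm * (p[id - nxy] - p[id]) +
                            ezp * (p[id + nxy] - p[id])) -
                       kp[id] * p[id] + b[id];
            rnorm += r * r;
          }
      relres = std::sqrt(rnorm) / bnorm;
      if (relres <= tol) break;
    }
  }
  return List::create(_["phi"] = phi, _["iterations"] = iter,
                      _["relres"] = relres, _["converged"] = (relres <= tol));
}

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral quadrature. Atoms with radius <= 0 (hydrogens in the
// heavy-atom convention) get zero area and do not occlude.
// [[Rcpp::export]]
NumericVector shrake_rupley(NumericMatrix xyz, NumericVector radius,
                            double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  // golden-spiral unit sphere points
  std::vector<double> sx(n_points), sy(n_points), sz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int t = 0; t < n_points; ++t) {
    double z = 1.0 - 2.0 * (t + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * t;
    sx[t] = r * std::cos(th);
    sy[t] = r * std::sin(th);
    sz[t] = z;
  }
  for (int i = 0; i < n; ++i) {
    if (radius[i] <= 0.0) { area[i] = 0.0; continue; }
    double Ri = radius[i] + probe;
    // neighbor list
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i || radius[j] <= 0.0) continue;
      double dx = xyz(j, 0) - xyz(i, 0), dy = xyz(j, 1) - xyz(i, 1),
             dz = xyz(j, 2) - xyz(i, 2);
      double cut = Ri + radius[j] + probe;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int t = 0; t < n_points; ++t) {
      double px = xyz(i, 0) + Ri * sx[t];
      double py = xyz(i, 1) + Ri * sy[t];
      double pz = xyz(i, 2) + Ri * sz[t];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double Rj = radius[j] + probe;
        double dx = px - xyz(j, 0), dy = py - xyz(j, 1), dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * acc / n_points;
  }
  return area;
}

// Minimum Euclidean distance between two coordinate sets.
// [[Rcpp::export]]
double min_pair_distance(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i)
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}
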