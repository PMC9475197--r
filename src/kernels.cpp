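#include <Rcpp.h>
using namespace Rcpp;

// Grid convention shared with the R side: colatitude rows at
// theta_i = (i + 0.5) * dtheta (i = 0..nt-1, poles excluded), longitude
// columns at phi_j = j * dphi (periodic). Fields are stored column-major as
// nt x np x 3 arrays.

static inline double row_eval(const double* F, int nt, int np, double dp,
                              int row, int chan, double ph) {
  // periodic linear interpolation along one colatitude row
  double y = ph / dp;
  double fy = std::floor(y);
  double v = y - fy;
  int j0 = (int)fy % np; if (j0 < 0) j0 += np;
  int j1 = (j0 + 1) % np;
  const double* base = F + (std::size_t)chan * nt * np;
  return (1.0 - v) * base[row + (std::size_t)j0 * nt] +
         v * base[row + (std::size_t)j1 * nt];
}

static inline void interp_point(const double* F, int nt, int np,
                                double dt, double dp,
                                double th, double ph, double* out) {
  double x = th / dt - 0.5;
  int i0 = (int)std::floor(x);
  double u = x - i0;
  for (int c = 0; c < 3; ++c) {
    double lo, hi;
    if (i0 < 0) {
      // north pole: blend the first row with its antipodal-longitude values
      lo = row_eval(F, nt, np, dp, 0, c, ph + M_PI);
      hi = row_eval(F, nt, np, dp, 0, c, ph);
      u = x + 1.0;
      out[c] = (1.0 - u) * lo + u * hi;
    } else if (i0 >= nt - 1) {
      lo = row_eval(F, nt, np, dp, nt - 1, c, ph);
      hi = row_eval(F, nt, np, dp, nt - 1, c, ph + M_PI);
      double uu = x - (nt - 1);
      if (uu > 1.0) uu = 1.0;
      out[c] = (1.0 - uu) * lo + uu * hi;
    } else {
      lo = row_eval(F, nt, np, dp, i0, c, ph);
      hi = row_eval(F, nt, np, dp, i0 + 1, c, ph);
      out[c] = (1.0 - u) * lo + u * hi;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_interp_sphere(NumericVector F, NumericVector th,
                                NumericVector ph, int nt, int np,
                                double dtheta, double dphi) {
  int nq = th.size();
  NumericMatrix out(nq, 3);
  double buf[3];
  const double* Fp = F.begin();
  for (int k = 0; k < nq; ++k) {
    interp_point(Fp, nt, np, dtheta, dphi, th[k], ph[k], buf);
    out(k, 0) = buf[0]; out(k, 1) = buf[1]; out(k, 2) = buf[2];
  }
  return out;
}

// finite-difference derivatives matching the R stencils: theta central on
// interior rows with 2nd-order one-sided at the boundary rows; phi periodic
// central.
static void srnf_core(const double* F, int nt, int np, double dt, double dp,
                      double* q, double* nmag) {
  std::size_t plane = (std::size_t)nt * np;
  std::vector<double> fu(3 * plane), fv(3 * plane);
  for (int c = 0; c < 3; ++c) {
    const double* f = F + c * plane;
    double* du = fu.data() + c * plane;
    double* dv = fv.data() + c * plane;
    for (int j = 0; j < np; ++j) {
      const double* col = f + (std::size_t)j * nt;
      double* ducol = du + (std::size_t)j * nt;
      for (int i = 1; i < nt - 1; ++i)
        ducol[i] = (col[i + 1] - col[i - 1]) / (2.0 * dt);
      ducol[0] = (-3.0 * col[0] + 4.0 * col[1] - col[2]) / (2.0 * dt);
      ducol[nt - 1] = (3.0 * col[nt - 1] - 4.0 * col[nt - 2] + col[nt - 3]) / (2.0 * dt);
    }
    for (int j = 0; j < np; ++j) {
      int jp = (j + 1) % np, jm = (j - 1 + np) % np;
      const double* cp = f + (std::size_t)jp * nt;
      const double* cm = f + (std::size_t)jm * nt;
      double* dvcol = dv + (std::size_t)j * nt;
      for (int i = 0; i < nt; ++i)
        dvcol[i] = (cp[i] - cm[i]) / (2.0 * dp);
    }
  }
  double msum = 0.0;
  for (std::size_t k = 0; k < plane; ++k) {
    double ax = fu[k], ay = fu[k + plane], az = fu[k + 2 * plane];
    double bx = fv[k], by = fv[k + plane], bz = fv[k + 2 * plane];
    double nx = ay * bz - az * by;
    double ny = az * bx - ax * bz;
    double nz = ax * by - ay * bx;
    double m = std::sqrt(nx * nx + ny * ny + nz * nz);
    q[k] = nx; q[k + plane] = ny; q[k + 2 * plane] = nz;
    nmag[k] = m;
    msum += m;
  }
  double floor_val = 1e-12 * msum / plane;
  for (std::size_t k = 0; k < plane; ++k) {
    double m = nmag[k] < floor_val ? floor_val : nmag[k];
    nmag[k] = m;
    double s = 1.0 / std::sqrt(m);
    q[k] *= s; q[k + plane] *= s; q[k + 2 * plane] *= s;
  }
}

// [[Rcpp::export]]
List cpp_srnf(NumericVector F, int nt, int np, double dtheta, double dphi) {
  std::size_t plane = (std::size_t)nt * np;
  NumericVector q(3 * plane);
  NumericVector nmag(plane);
  srnf_core(F.begin(), nt, np, dtheta, dphi, q.begin(), nmag.begin());
  q.attr("dim") = IntegerVector::create(nt, np, 3);
  nmag.attr("dim") = IntegerVector::create(nt, np);
  return List::create(_["q"] = q, _["n_mag"] = nmag);
}

// Registration energy ingredients for a candidate reparameterization gamma
// (given as unit vectors, one per grid node): interpolates the moving surface
// f2 at gamma, takes the SRNF of the composed surface (which carries the
// Jacobian factor implicitly through the chain rule of the finite
// differences), and accumulates the weighted cross-covariance with q1 for the
// Procrustes rotation. Returns A = sum_s w q1 q2^T and s2 = ||q2||^2_w, plus
// the composed surface if requested.
// [[Rcpp::export]]
List cpp_reg_parts(NumericVector f2, NumericMatrix gamma, NumericVector q1,
                   NumericMatrix w, int nt, int np, double dtheta,
                   double dphi, bool return_f = false) {
  std::size_t plane = (std::size_t)nt * np;
  std::vector<double> f2g(3 * plane);
  const double* Fp = f2.begin();
  double buf[3];
  for (std::size_t k = 0; k < plane; ++k) {
    double gx = gamma(k, 0), gy = gamma(k, 1), gz = gamma(k, 2);
    if (gz > 1.0) gz = 1.0; if (gz < -1.0) gz = -1.0;
    double th = std::acos(gz);
    double ph = std::atan2(gy, gx);
    if (ph < 0) ph += 2.0 * M_PI;
    interp_point(Fp, nt, np, dtheta, dphi, th, ph, buf);
    f2g[k] = buf[0]; f2g[k + plane] = buf[1]; f2g[k + 2 * plane] = buf[2];
  }
  std::vector<double> q2(3 * plane), nmag(plane);
  srnf_core(f2g.data(), nt, np, dtheta, dphi, q2.data(), nmag.data());
  double A[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
  double s2 = 0.0;
  const double* q1p = q1.begin();
  const double* wp = w.begin();
  for (std::size_t k = 0; k < plane; ++k) {
    double wk = wp[k];
    double a0 = q1p[k], a1 = q1p[k + plane], a2 = q1p[k + 2 * plane];
    double b0 = q2[k], b1 = q2[k + plane], b2 = q2[k + 2 * plane];
    A[0] += wk * a0 * b0; A[3] += wk * a0 * b1; A[6] += wk * a0 * b2;
    A[1] += wk * a1 * b0; A[4] += wk * a1 * b1; A[7] += wk * a1 * b2;
    A[2] += wk * a2 * b0; A[5] += wk * a2 * b1; A[8] += wk * a2 * b2;
    s2 += wk * (b0 * b0 + b1 * b1 + b2 * b2);
  }
  NumericMatrix Am(3, 3);
  std::copy(A, A + 9, Am.begin());
  List out = List::create(_["A"] = Am, _["s2"] = s2);
  if (return_f) {
    NumericVector fout(3 * plane);
    std::copy(f2g.begin(), f2g.end(), fout.begin());
    fout.attr("dim") = IntegerVector::create(nt, np, 3);
    out["f2g"] = fout;
  }
  return out;
}

// analytic eigenvalues of a symmetric 3x3 matrix (descending)
static void sym3_eig(const double S[3][3], double ev[3]) {
  double p1 = S[0][1] * S[0][1] + S[0][2] * S[0][2] + S[1][2] * S[1][2];
  if (p1 < 1e-300) {
    ev[0] = S[0][0]; ev[1] = S[1][1]; ev[2] = S[2][2];
  } else {
    double q = (S[0][0] + S[1][1] + S[2][2]) / 3.0;
    double p2 = (S[0][0] - q) * (S[0][0] - q) + (S[1][1] - q) * (S[1][1] - q) +
                (S[2][2] - q) * (S[2][2] - q) + 2.0 * p1;
    double p = std::sqrt(p2 / 6.0);
    double B[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        B[i][j] = (S[i][j] - (i == j ? q : 0.0)) / p;
    double detB = B[0][0] * (B[1][1] * B[2][2] - B[1][2] * B[2][1]) -
                  B[0][1] * (B[1][0] * B[2][2] - B[1][2] * B[2][0]) +
                  B[0][2] * (B[1][0] * B[2][1] - B[1][1] * B[2][0]);
    double r = detB / 2.0;
    if (r < -1.0) r = -1.0; if (r > 1.0) r = 1.0;
    double phi = std::acos(r) / 3.0;
    ev[0] = q + 2.0 * p * std::cos(phi);
    ev[2] = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    ev[1] = 3.0 * q - ev[0] - ev[2];
  }
  // sort descending
  for (int i = 0; i < 2; ++i)
    for (int j = i + 1; j < 3; ++j)
      if (ev[j] > ev[i]) std::swap(ev[i], ev[j]);
}

// energy for one candidate gamma stored in three column arrays
static double energy_for_gamma(const double* f2, const double* gx,
                               const double* gy, const double* gz,
                               const double* q1, const double* w,
                               int nt, int np, double dt, double dp,
                               double s1, std::vector<double>& f2g,
                               std::vector<double>& q2,
                               std::vector<double>& nmag) {
  std::size_t plane = (std::size_t)nt * np;
  double buf[3];
  for (std::size_t k = 0; k < plane; ++k) {
    double z = gz[k];
    if (z > 1.0) z = 1.0; if (z < -1.0) z = -1.0;
    double th = std::acos(z);
    double ph = std::atan2(gy[k], gx[k]);
    if (ph < 0) ph += 2.0 * M_PI;
    interp_point(f2, nt, np, dt, dp, th, ph, buf);
    f2g[k] = buf[0]; f2g[k + plane] = buf[1]; f2g[k + 2 * plane] = buf[2];
  }
  srnf_core(f2g.data(), nt, np, dt, dp, q2.data(), nmag.data());
  double A[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  double s2 = 0.0;
  for (std::size_t k = 0; k < plane; ++k) {
    double wk = w[k];
    double a[3] = {q1[k], q1[k + plane], q1[k + 2 * plane]};
    double b[3] = {q2[k], q2[k + plane], q2[k + 2 * plane]};
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) A[i][j] += wk * a[i] * b[j];
    s2 += wk * (b[0] * b[0] + b[1] * b[1] + b[2] * b[2]);
  }
  double detA = A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1]) -
                A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0]) +
                A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
  double AtA[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) s += A[k][i] * A[k][j];
      AtA[i][j] = s;
    }
  double ev[3];
  sym3_eig(AtA, ev);
  double sg0 = std::sqrt(std::max(ev[0], 0.0));
  double sg1 = std::sqrt(std::max(ev[1], 0.0));
  double sg2 = std::sqrt(std::max(ev[2], 0.0));
  double tr = sg0 + sg1 + (detA >= 0 ? sg2 : -sg2);
  double E = s1 + s2 - 2.0 * tr;
  return E > 0.0 ? E : 0.0;
}

// Fast registration energy min_O ||q1 - O srnf(f2 o gamma)||^2 for a single
// candidate gamma ((nt*np) x 3 unit vectors).
// [[Rcpp::export]]
double cpp_reg_energy(NumericVector f2, NumericMatrix gamma, NumericVector q1,
                      NumericMatrix w, int nt, int np, double dtheta,
                      double dphi, double s1) {
  std::size_t plane = (std::size_t)nt * np;
  std::vector<double> f2g(3 * plane), q2(3 * plane), nmag(plane);
  std::vector<double> gx(plane), gy(plane), gz(plane);
  for (std::size_t k = 0; k < plane; ++k) {
    gx[k] = gamma(k, 0); gy[k] = gamma(k, 1); gz[k] = gamma(k, 2);
  }
  return energy_for_gamma(f2.begin(), gx.data(), gy.data(), gz.data(),
                          q1.begin(), w.begin(), nt, np, dtheta, dphi, s1,
                          f2g, q2, nmag);
}

// Batched finite-difference energy gradient: for each of K tangent fields
// (columns 3k..3k+2 of `fields`), evaluates the energy at the normalized
// perturbation gamma + eps * B_k and returns all K energies in one call.
// [[Rcpp::export]]
NumericVector cpp_reg_energy_grad(NumericVector f2, NumericMatrix gamma,
                                  NumericMatrix fields, double eps,
                                  NumericVector q1, NumericMatrix w, int nt,
                                  int np, double dtheta, double dphi,
                                  double s1) {
  std::size_t plane = (std::size_t)nt * np;
  int K = fields.ncol() / 3;
  NumericVector out(K);
  std::vector<double> f2g(3 * plane), q2(3 * plane), nmag(plane);
  std::vector<double> gx(plane), gy(plane), gz(plane);
  for (int k = 0; k < K; ++k) {
    for (std::size_t i = 0; i < plane; ++i) {
      double x = gamma(i, 0) + eps * fields(i, 3 * k);
      double y = gamma(i, 1) + eps * fields(i, 3 * k + 1);
      double z = gamma(i, 2) + eps * fields(i, 3 * k + 2);
      double nr = std::sqrt(x * x + y * y + z * z);
      gx[i] = x / nr; gy[i] = y / nr; gz[i] = z / nr;
    }
    out[k] = energy_for_gamma(f2.begin(), gx.data(), gy.data(), gz.data(),
                              q1.begin(), w.begin(), nt, np, dtheta, dphi,
                              s1, f2g, q2, nmag);
  }
  return out;
}

// Signed Jacobian determinant of a sphere map gamma (unit-vector field on the
// grid) relative to the spherical area element: J = <gamma_u x gamma_v,
// gamma> / sin(theta). Positive everywhere for orientation-preserving maps.
// [[Rcpp::export]]
NumericMatrix cpp_jacobian(NumericMatrix gamma, int nt, int np,
                           double dtheta, double dphi,
                           NumericVector sin_theta) {
  std::size_t plane = (std::size_t)nt * np;
  std::vector<double> G(3 * plane);
  for (std::size_t k = 0; k < plane; ++k) {
    G[k] = gamma(k, 0); G[k + plane] = gamma(k, 1); G[k + 2 * plane] = gamma(k, 2);
  }
  std::vector<double> q(3 * plane), nm(plane);
  // srnf_core computes n / sqrt(|n|): recover signed J from n = q * sqrt(nm)
  srnf_core(G.data(), nt, np, dtheta, dphi, q.data(), nm.data());
  NumericMatrix J(nt, np);
  for (int j = 0; j < np; ++j) {
    for (int i = 0; i < nt; ++i) {
      std::size_t k = (std::size_t)j * nt + i;
      double s = std::sqrt(nm[k]);
      double dot = (q[k] * G[k] + q[k + plane] * G[k + plane] +
                    q[k + 2 * plane] * G[k + 2 * plane]) * s;
      J(i, j) = dot / sin_theta[i];
    }
  }
  return J;
}
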