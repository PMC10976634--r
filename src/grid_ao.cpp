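// AO amplitudes and Cartesian gradients on quadrature points (spherical AOs,
// l <= 3), with per-shell screening on the contracted radial part.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static int ncart_g(int l) { return (l + 1) * (l + 2) / 2; }
static double dfact_g(int n) { double r = 1.0; for (int k = 2 * n - 1; k > 1; k -= 2) r *= k; return r; }
static void cart_list_g(int l, int* lx, int* ly, int* lz) {
  int n = 0;
  for (int ix = l; ix >= 0; --ix)
    for (int iy = l - ix; iy >= 0; --iy) { lx[n] = ix; ly[n] = iy; lz[n] = l - ix - iy; ++n; }
}
static void c2s_rows_g(int l, std::vector<std::vector<double> >& rows) {
  int nc = ncart_g(l);
  rows.assign(2 * l + 1, std::vector<double>(nc, 0.0));
  if (l == 0) rows[0][0] = 1.0;
  else if (l == 1) { rows[0][1] = 1.0; rows[1][2] = 1.0; rows[2][0] = 1.0; }
  else if (l == 2) {
    rows[0][1] = 1.0; rows[1][4] = 1.0;
    rows[2][0] = -1.0; rows[2][3] = -1.0; rows[2][5] = 2.0;
    rows[3][2] = 1.0; rows[4][0] = 1.0; rows[4][3] = -1.0;
  } else if (l == 3) {
    rows[0][1] = 3.0; rows[0][6] = -1.0;
    rows[1][4] = 1.0;
    rows[2][1] = -1.0; rows[2][6] = -1.0; rows[2][8] = 4.0;
    rows[3][2] = -3.0; rows[3][7] = -3.0; rows[3][9] = 2.0;
    rows[4][0] = -1.0; rows[4][3] = -1.0; rows[4][5] = 4.0;
    rows[5][2] = 1.0; rows[5][7] = -1.0;
    rows[6][0] = 1.0; rows[6][3] = -3.0;
  } else stop("angular momentum above f not supported");
}

// [[Rcpp::export]]
List cpp_ao_grid(IntegerVector l, NumericMatrix centers, List exps, List coefs,
                 NumericMatrix pts, bool deriv, double screen = 1e-12) {
  int ns = l.size();
  int npt = pts.nrow();
  // AO offsets and spherical norms (same construction as the integral code:
  // primitive-normalised cartesians, solid-harmonic rows, unit self-overlap)
  std::vector<int> off(ns);
  int nao = 0;
  for (int i = 0; i < ns; ++i) { off[i] = nao; nao += 2 * l[i] + 1; }
  NumericMatrix val(npt, nao), dx, dy, dz;
  if (deriv) { dx = NumericMatrix(npt, nao); dy = NumericMatrix(npt, nao); dz = NumericMatrix(npt, nao); }
  static const double PI = 3.14159265358979323846;

  for (int is = 0; is < ns; ++is) {
    int L = l[is];
    NumericVector ex = exps[is], cf = coefs[is];
    int np = ex.size();
    std::vector<double> cc(np);
    for (int k = 0; k < np; ++k)
      cc[k] = cf[k] * std::pow(2.0 * ex[k] / PI, 0.75) *
              std::pow(4.0 * ex[k], 0.5 * L) / std::sqrt(dfact_g(L));
    // spherical renormalisation: same-scale cartesians + integer solid rows;
    // scale row m so that the contracted AO is unit-norm. Self-overlap of the
    // raw contracted cartesian block:
    int nc = ncart_g(L);
    int lx[20], ly[20], lz[20];
    cart_list_g(L, lx, ly, lz);
    std::vector<std::vector<double> > rows;
    c2s_rows_g(L, rows);
    std::vector<double> scale(2 * L + 1);
    {
      // raw overlap of cartesian pair (same center): S_ab = prod over axes of
      // odd/even moments of gaussian with exponent a+b
      std::vector<double> Scart(nc * nc, 0.0);
      for (int ka = 0; ka < np; ++ka)
        for (int kb = 0; kb < np; ++kb) {
          double p = ex[ka] + ex[kb], w = cc[ka] * cc[kb];
          double pref = std::pow(PI / p, 1.5);
          for (int a = 0; a < nc; ++a)
            for (int b = 0; b < nc; ++b) {
              int ix = lx[a] + lx[b], iy = ly[a] + ly[b], iz = lz[a] + lz[b];
              if (ix % 2 || iy % 2 || iz % 2) continue;
              double m = 1.0;
              for (int t = 1; t < ix; t += 2) m *= t / (2.0 * p);
              for (int t = 1; t < iy; t += 2) m *= t / (2.0 * p);
              for (int t = 1; t < iz; t += 2) m *= t / (2.0 * p);
              Scart[a * nc + b] += w * pref * m;
            }
        }
      for (int m = 0; m < 2 * L + 1; ++m) {
        double v = 0.0;
        for (int a = 0; a < nc; ++a)
          for (int b = 0; b < nc; ++b)
            v += rows[m][a] * rows[m][b] * Scart[a * nc + b];
        scale[m] = 1.0 / std::sqrt(v);
      }
    }
    double cx = centers(is, 0), cy = centers(is, 1), cz = centers(is, 2);
    double mn = ex[0];
    for (int k = 1; k < np; ++k) if (ex[k] < mn) mn = ex[k];
    double ccmax = 0.0;
    for (int k = 0; k < np; ++k) ccmax += std::fabs(cc[k]);
    for (int ip = 0; ip < npt; ++ip) {
      double X = pts(ip, 0) - cx, Y = pts(ip, 1) - cy, Z = pts(ip, 2) - cz;
      double r2 = X * X + Y * Y + Z * Z;
      // conservative bound on radial part (polynomial prefactor <= (1+r2)^2)
      if (mn * r2 - 0.5 * L * std::log1p(r2) > -std::log(screen / (ccmax + 1e-300)))
        continue;
      double rad = 0.0, drad = 0.0; // radial sum and its derivative factor
      for (int k = 0; k < np; ++k) {
        double e = cc[k] * std::exp(-ex[k] * r2);
        rad += e;
        drad += -2.0 * ex[k] * e;
      }
      // cartesian monomials and gradients
      double mono[20], gmx[20], gmy[20], gmz[20];
      double px[5] = {1, X, X * X, X * X * X, X * X * X * X};
      double py[5] = {1, Y, Y * Y, Y * Y * Y, Y * Y * Y * Y};
      double pz[5] = {1, Z, Z * Z, Z * Z * Z, Z * Z * Z * Z};
      for (int a = 0; a < nc; ++a) {
        mono[a] = px[lx[a]] * py[ly[a]] * pz[lz[a]];
        if (deriv) {
          gmx[a] = lx[a] > 0 ? lx[a] * px[lx[a] - 1] * py[ly[a]] * pz[lz[a]] : 0.0;
          gmy[a] = ly[a] > 0 ? ly[a] * px[lx[a]] * py[ly[a] - 1] * pz[lz[a]] : 0.0;
          gmz[a] = lz[a] > 0 ? lz[a] * px[lx[a]] * py[ly[a]] * pz[lz[a] - 1] : 0.0;
        }
      }
      for (int m = 0; m < 2 * L + 1; ++m) {
        double v = 0.0, vx = 0.0, vy = 0.0, vz = 0.0;
        for (int a = 0; a < nc; ++a) {
          double w = rows[m][a];
          if (w == 0.0) continue;
          v += w * mono[a];
          if (deriv) { vx += w * gmx[a]; vy += w * gmy[a]; vz += w * gmz[a]; }
        }
        int col = off[is] + m;
        val(ip, col) = scale[m] * v * rad;
        if (deriv) {
          dx(ip, col) = scale[m] * (vx * rad + v * drad * X);
          dy(ip, col) = scale[m] * (vy * rad + v * drad * Y);
          dz(ip, col) = scale[m] * (vz * rad + v * drad * Z);
        }
      }
    }
  }
  if (deriv) return List::create(_["val"] = val, _["dx"] = dx, _["dy"] = dy, _["dz"] = dz);
  return List::create(_["val"] = val);
}
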