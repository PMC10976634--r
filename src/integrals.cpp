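// Gaussian-basis molecular integrals via the McMurchie-Davidson scheme.
// Shells carry spherical (pure) functions up to l = 3; Cartesian blocks are
// built primitive-by-primitive, transformed to real solid harmonics and
// renormalised so every contracted AO has unit self-overlap.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys F_m(T)
static void boys(double T, int mmax, double* F) {
  if (T < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T < 35.0) {
    // series for F_mmax, then stable downward recursion
    double num = 1.0, den = 2.0 * mmax + 1.0, term = 1.0 / den, sum = term;
    for (int i = 1; i < 300; ++i) {
      num *= 2.0 * T;
      den += 2.0;
      term = num; // (2T)^i / prod_{k=0..i} (2m+1+2k)
      double d = 2.0 * mmax + 1.0;
      // rebuild denominator product incrementally instead: keep running term
      // (cheaper): term_i = term_{i-1} * 2T / (2m+1+2i)
      (void)d;
      break;
    }
    // incremental version
    sum = 1.0 / (2.0 * mmax + 1.0);
    term = sum;
    for (int i = 1; i < 500; ++i) {
      term *= 2.0 * T / (2.0 * mmax + 1.0 + 2.0 * i);
      sum += term;
      if (term < sum * 1e-17) break;
    }
    double expT = std::exp(-T);
    F[mmax] = sum * expT;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * T * F[m + 1] + expT) / (2.0 * m + 1.0);
  } else {
    double expT = std::exp(-T);
    F[0] = 0.5 * std::sqrt(PI / T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - expT) / (2.0 * T);
  }
}

// -------------------------------------------------------------- shell setup
struct Shell {
  int l;
  double c[3];
  std::vector<double> ex;   // exponents
  std::vector<double> cf;   // contraction coefficients * primitive norms
  int ao_off;               // offset into spherical AO list
  std::vector<double> scale; // per-m renormalisation
};

static double dfact(int n) { // (2n-1)!!
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

static int ncart(int l) { return (l + 1) * (l + 2) / 2; }

// cartesian component list in fixed order
static void cart_list(int l, int* lx, int* ly, int* lz) {
  int n = 0;
  for (int ix = l; ix >= 0; --ix)
    for (int iy = l - ix; iy >= 0; --iy) {
      lx[n] = ix; ly[n] = iy; lz[n] = l - ix - iy; ++n;
    }
}

// real solid harmonic coefficients on the cartesian monomials (integer shape;
// absolute normalisation fixed numerically afterwards)
static void c2s_rows(int l, std::vector<std::vector<double> >& rows) {
  int nc = ncart(l);
  rows.assign(2 * l + 1, std::vector<double>(nc, 0.0));
  if (l == 0) { rows[0][0] = 1.0; }
  else if (l == 1) { // order m=-1,0,1 -> y,z,x ; cart order x,y,z
    rows[0][1] = 1.0; rows[1][2] = 1.0; rows[2][0] = 1.0;
  } else if (l == 2) { // cart: xx,xy,xz,yy,yz,zz
    rows[0][1] = 1.0;                                     // xy
    rows[1][4] = 1.0;                                     // yz
    rows[2][0] = -1.0; rows[2][3] = -1.0; rows[2][5] = 2.0; // 2zz-xx-yy
    rows[3][2] = 1.0;                                     // xz
    rows[4][0] = 1.0; rows[4][3] = -1.0;                  // xx-yy
  } else if (l == 3) { // cart: xxx,xxy,xxz,xyy,xyz,xzz,yyy,yyz,yzz,zzz
    rows[0][1] = 3.0; rows[0][6] = -1.0;                  // 3xxy-yyy
    rows[1][4] = 1.0;                                     // xyz
    rows[2][1] = -1.0; rows[2][6] = -1.0; rows[2][8] = 4.0; // y(4zz-xx-yy)
    rows[3][2] = -3.0; rows[3][7] = -3.0; rows[3][9] = 2.0; // z(2zz-3xx-3yy)
    rows[4][0] = -1.0; rows[4][3] = -1.0; rows[4][5] = 4.0; // x(4zz-xx-yy)
    rows[5][2] = 1.0; rows[5][7] = -1.0;                  // z(xx-yy)
    rows[6][0] = 1.0; rows[6][3] = -3.0;                  // xxx-3xyy
  } else stop("angular momentum above f not supported");
}

// E_t^{ij} Hermite expansion coefficients for one axis, Gaussian product
// factor included. E has dims (l1+1) x (l2+1) x (l1+l2+1).
static void ecoef(int l1, int l2, double a, double b, double AB,
                  std::vector<double>& E) {
  int nt = l1 + l2 + 1;
  E.assign((l1 + 1) * (l2 + 1) * nt, 0.0);
  double p = a + b, mu = a * b / p;
  double XPA = -b * AB / p, XPB = a * AB / p; // P-A, P-B with AB = A-B
  // AB passed as A-B: P = (aA+bB)/p, P-A = -b(A-B)/p, P-B = a(A-B)/p
  E[0] = std::exp(-mu * AB * AB);
  for (int i = 0; i <= l1; ++i)
    for (int j = 0; j <= l2; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double v = 0.0;
        if (i > 0) {
          if (t > 0) v += 1.0 / (2.0 * p) * E[((i - 1) * (l2 + 1) + j) * nt + t - 1];
          v += XPA * E[((i - 1) * (l2 + 1) + j) * nt + t];
          if (t + 1 <= i - 1 + j) v += (t + 1) * E[((i - 1) * (l2 + 1) + j) * nt + t + 1];
        } else {
          if (t > 0) v += 1.0 / (2.0 * p) * E[(i * (l2 + 1) + j - 1) * nt + t - 1];
          v += XPB * E[(i * (l2 + 1) + j - 1) * nt + t];
          if (t + 1 <= i + j - 1) v += (t + 1) * E[(i * (l2 + 1) + j - 1) * nt + t + 1];
        }
        E[(i * (l2 + 1) + j) * nt + t] = v;
      }
    }
}

// Hermite Coulomb integrals R_{tuv} (n=0 slice) for given alpha, PC
static void hermite_R(int tmax, int umax, int vmax, double alpha,
                      double X, double Y, double Z, std::vector<double>& R0) {
  int L = tmax + umax + vmax;
  double T = alpha * (X * X + Y * Y + Z * Z);
  double F[64];
  boys(T, L, F);
  // R^n_{tuv}, build by recursion over total order (scratch reused)
  int nt = tmax + 1, nu = umax + 1, nv = vmax + 1;
  static std::vector<double> R;
  R.assign((size_t)(L + 1) * nt * nu * nv, 0.0);
  double m2a = 1.0;
  for (int n = 0; n <= L; ++n) { R[((n * nt + 0) * nu + 0) * nv + 0] = m2a * F[n]; m2a *= -2.0 * alpha; }
  for (int tot = 1; tot <= L; ++tot)
    for (int t = 0; t <= tmax; ++t)
      for (int u = 0; u <= umax; ++u)
        for (int v = 0; v <= vmax; ++v) {
          if (t + u + v != tot) continue;
          for (int n = 0; n <= L - tot; ++n) {
            double val = 0.0;
            if (t > 0) {
              val = X * R[(((n + 1) * nt + t - 1) * nu + u) * nv + v];
              if (t > 1) val += (t - 1) * R[(((n + 1) * nt + t - 2) * nu + u) * nv + v];
            } else if (u > 0) {
              val = Y * R[(((n + 1) * nt + t) * nu + u - 1) * nv + v];
              if (u > 1) val += (u - 1) * R[(((n + 1) * nt + t) * nu + u - 2) * nv + v];
            } else {
              val = Z * R[(((n + 1) * nt + t) * nu + u) * nv + v - 1];
              if (v > 1) val += (v - 1) * R[(((n + 1) * nt + t) * nu + u) * nv + v - 2];
            }
            R[((n * nt + t) * nu + u) * nv + v] = val;
          }
        }
  R0.assign(nt * nu * nv, 0.0);
  for (int t = 0; t <= tmax; ++t)
    for (int u = 0; u <= umax; ++u)
      for (int v = 0; v <= vmax; ++v)
        R0[(t * nu + u) * nv + v] = R[((0 * nt + t) * nu + u) * nv + v];
}

static std::vector<Shell> build_shells(IntegerVector l, NumericMatrix centers,
                                       List exps, List coefs) {
  int ns = l.size();
  std::vector<Shell> sh(ns);
  int off = 0;
  for (int i = 0; i < ns; ++i) {
    sh[i].l = l[i];
    sh[i].c[0] = centers(i, 0); sh[i].c[1] = centers(i, 1); sh[i].c[2] = centers(i, 2);
    NumericVector e = exps[i], c = coefs[i];
    int np = e.size();
    sh[i].ex.resize(np); sh[i].cf.resize(np);
    for (int k = 0; k < np; ++k) {
      sh[i].ex[k] = e[k];
      double norm = std::pow(2.0 * e[k] / PI, 0.75) *
        std::pow(4.0 * e[k], 0.5 * l[i]) / std::sqrt(dfact(l[i]));
      sh[i].cf[k] = c[k] * norm;
    }
    sh[i].ao_off = off;
    off += 2 * l[i] + 1;
  }
  return sh;
}

// cartesian overlap block between two shells (contracted)
static void overlap_block(const Shell& A, const Shell& B, std::vector<double>& out,
                          std::vector<double>* tkin = NULL) {
  int nca = ncart(A.l), ncb = ncart(B.l);
  out.assign(nca * ncb, 0.0);
  if (tkin) tkin->assign(nca * ncb, 0.0);
  int lxa[20], lya[20], lza[20], lxb[20], lyb[20], lzb[20];
  cart_list(A.l, lxa, lya, lza);
  cart_list(B.l, lxb, lyb, lzb);
  double AB[3] = {A.c[0] - B.c[0], A.c[1] - B.c[1], A.c[2] - B.c[2]};
  // kinetic needs l2+2 in E tables
  int l2e = B.l + 2;
  std::vector<double> Ex, Ey, Ez;
  for (size_t ka = 0; ka < A.ex.size(); ++ka)
    for (size_t kb = 0; kb < B.ex.size(); ++kb) {
      double a = A.ex[ka], b = B.ex[kb], cc = A.cf[ka] * B.cf[kb];
      double p = a + b, pref = std::pow(PI / p, 1.5);
      ecoef(A.l, l2e, a, b, AB[0], Ex);
      ecoef(A.l, l2e, a, b, AB[1], Ey);
      ecoef(A.l, l2e, a, b, AB[2], Ez);
      int nt = A.l + l2e + 1;
      // 1D overlaps S(i,j) = E_0^{ij} * sqrt(pi/p) per axis; combined pref
      for (int ia = 0; ia < nca; ++ia)
        for (int ib = 0; ib < ncb; ++ib) {
          double sx = Ex[(lxa[ia] * (l2e + 1) + lxb[ib]) * nt];
          double sy = Ey[(lya[ia] * (l2e + 1) + lyb[ib]) * nt];
          double sz = Ez[(lza[ia] * (l2e + 1) + lzb[ib]) * nt];
          out[ia * ncb + ib] += cc * pref * sx * sy * sz;
          if (tkin) {
            // T_x(i,j) = -2b^2 S(i,j+2) + b(2j+1) S(i,j) - j(j-1)/2 S(i,j-2)
            int jx = lxb[ib], jy = lyb[ib], jz = lzb[ib];
            double sxp = Ex[(lxa[ia] * (l2e + 1) + jx + 2) * nt];
            double syp = Ey[(lya[ia] * (l2e + 1) + jy + 2) * nt];
            double szp = Ez[(lza[ia] * (l2e + 1) + jz + 2) * nt];
            double sxm = jx >= 2 ? Ex[(lxa[ia] * (l2e + 1) + jx - 2) * nt] : 0.0;
            double sym = jy >= 2 ? Ey[(lya[ia] * (l2e + 1) + jy - 2) * nt] : 0.0;
            double szm = jz >= 2 ? Ez[(lza[ia] * (l2e + 1) + jz - 2) * nt] : 0.0;
            double tx = -2.0 * b * b * sxp + b * (2.0 * jx + 1.0) * sx - 0.5 * jx * (jx - 1.0) * sxm;
            double ty = -2.0 * b * b * syp + b * (2.0 * jy + 1.0) * sy - 0.5 * jy * (jy - 1.0) * sym;
            double tz = -2.0 * b * b * szp + b * (2.0 * jz + 1.0) * sz - 0.5 * jz * (jz - 1.0) * szm;
            (*tkin)[ia * ncb + ib] += cc * pref * (tx * sy * sz + sx * ty * sz + sx * sy * tz);
          }
        }
    }
}

// transform cartesian block (nca x ncb) to spherical using rows+scales
static void sph_block(const Shell& A, const Shell& B,
                      const std::vector<double>& cart, std::vector<double>& out) {
  std::vector<std::vector<double> > ra, rb;
  c2s_rows(A.l, ra); c2s_rows(B.l, rb);
  int nsa = 2 * A.l + 1, nsb = 2 * B.l + 1, ncb = ncart(B.l), nca = ncart(A.l);
  out.assign(nsa * nsb, 0.0);
  for (int ma = 0; ma < nsa; ++ma)
    for (int mb = 0; mb < nsb; ++mb) {
      double v = 0.0;
      for (int ia = 0; ia < nca; ++ia) {
        if (ra[ma][ia] == 0.0) continue;
        for (int ib = 0; ib < ncb; ++ib) {
          if (rb[mb][ib] == 0.0) continue;
          v += ra[ma][ia] * rb[mb][ib] * cart[ia * ncb + ib];
        }
      }
      out[ma * nsb + mb] = v * A.scale[ma] * B.scale[mb];
    }
}

static void set_scales(std::vector<Shell>& sh) {
  for (size_t i = 0; i < sh.size(); ++i) {
    Shell& S = sh[i];
    S.scale.assign(2 * S.l + 1, 1.0);
    std::vector<double> cart, sphr;
    overlap_block(S, S, cart);
    std::vector<std::vector<double> > rows;
    c2s_rows(S.l, rows);
    int nc = ncart(S.l);
    for (int m = 0; m < 2 * S.l + 1; ++m) {
      double v = 0.0;
      for (int ia = 0; ia < nc; ++ia)
        for (int ib = 0; ib < nc; ++ib)
          v += rows[m][ia] * rows[m][ib] * cart[ia * nc + ib];
      S.scale[m] = 1.0 / std::sqrt(v);
    }
  }
}

// [[Rcpp::export]]
List cpp_one_electron(IntegerVector l, NumericMatrix centers, List exps, List coefs,
                      NumericVector Z, NumericMatrix atom_xyz) {
  std::vector<Shell> sh = build_shells(l, centers, exps, coefs);
  set_scales(sh);
  int ns = sh.size();
  int nao = sh.back().ao_off + 2 * sh.back().l + 1;
  NumericMatrix S(nao, nao), T(nao, nao), V(nao, nao);
  NumericMatrix DX(nao, nao), DY(nao, nao), DZ(nao, nao);
  int natom = Z.size();
  std::vector<double> cart, tk, sp, sptk, Ex, Ey, Ez, R0;
  int lx1[20], ly1[20], lz1[20], lx2[20], ly2[20], lz2[20];
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j) {
      const Shell& A = sh[i]; const Shell& B = sh[j];
      overlap_block(A, B, cart, &tk);
      std::vector<double> spS, spT;
      sph_block(A, B, cart, spS);
      sph_block(A, B, tk, spT);
      int nca = ncart(A.l), ncb = ncart(B.l);
      cart_list(A.l, lx1, ly1, lz1);
      cart_list(B.l, lx2, ly2, lz2);
      // nuclear attraction + dipole (cartesian then transform)
      std::vector<double> cV(nca * ncb, 0.0), cDX(nca * ncb, 0.0),
                          cDY(nca * ncb, 0.0), cDZ(nca * ncb, 0.0);
      double AB[3] = {A.c[0] - B.c[0], A.c[1] - B.c[1], A.c[2] - B.c[2]};
      int l2e = B.l + 1; // +1 for dipole
      for (size_t ka = 0; ka < A.ex.size(); ++ka)
        for (size_t kb = 0; kb < B.ex.size(); ++kb) {
          double a = A.ex[ka], b = B.ex[kb], cc = A.cf[ka] * B.cf[kb];
          double p = a + b;
          double P[3] = {(a * A.c[0] + b * B.c[0]) / p,
                         (a * A.c[1] + b * B.c[1]) / p,
                         (a * A.c[2] + b * B.c[2]) / p};
          ecoef(A.l, l2e, a, b, AB[0], Ex);
          ecoef(A.l, l2e, a, b, AB[1], Ey);
          ecoef(A.l, l2e, a, b, AB[2], Ez);
          int nt = A.l + l2e + 1;
          double sqp = std::pow(PI / p, 1.5);
          // dipole: <a| x |b> = S(i,j+1) + Bx S(i,j), x about origin
          for (int ia = 0; ia < nca; ++ia)
            for (int ib = 0; ib < ncb; ++ib) {
              double sx = Ex[(lx1[ia] * (l2e + 1) + lx2[ib]) * nt];
              double sy = Ey[(ly1[ia] * (l2e + 1) + ly2[ib]) * nt];
              double sz = Ez[(lz1[ia] * (l2e + 1) + lz2[ib]) * nt];
              double sx1 = Ex[(lx1[ia] * (l2e + 1) + lx2[ib] + 1) * nt] + B.c[0] * sx;
              double sy1 = Ey[(ly1[ia] * (l2e + 1) + ly2[ib] + 1) * nt] + B.c[1] * sy;
              double sz1 = Ez[(lz1[ia] * (l2e + 1) + lz2[ib] + 1) * nt] + B.c[2] * sz;
              cDX[ia * ncb + ib] += cc * sqp * sx1 * sy * sz;
              cDY[ia * ncb + ib] += cc * sqp * sx * sy1 * sz;
              cDZ[ia * ncb + ib] += cc * sqp * sx * sy * sz1;
            }
          // nuclear attraction
          int tmax = A.l + B.l;
          for (int n = 0; n < natom; ++n) {
            double X = P[0] - atom_xyz(n, 0), Y = P[1] - atom_xyz(n, 1), Zc = P[2] - atom_xyz(n, 2);
            hermite_R(tmax, tmax, tmax, p, X, Y, Zc, R0);
            int nu = tmax + 1, nv = tmax + 1;
            double pref = -Z[n] * 2.0 * PI / p * cc;
            for (int ia = 0; ia < nca; ++ia)
              for (int ib = 0; ib < ncb; ++ib) {
                double v = 0.0;
                for (int t = 0; t <= lx1[ia] + lx2[ib]; ++t) {
                  double ex = Ex[(lx1[ia] * (l2e + 1) + lx2[ib]) * nt + t];
                  if (ex == 0.0) continue;
                  for (int u = 0; u <= ly1[ia] + ly2[ib]; ++u) {
                    double ey = Ey[(ly1[ia] * (l2e + 1) + ly2[ib]) * nt + u];
                    if (ey == 0.0) continue;
                    for (int w = 0; w <= lz1[ia] + lz2[ib]; ++w) {
                      double ez = Ez[(lz1[ia] * (l2e + 1) + lz2[ib]) * nt + w];
                      if (ez == 0.0) continue;
                      v += ex * ey * ez * R0[(t * nu + u) * nv + w];
                    }
                  }
                }
                cV[ia * ncb + ib] += pref * v;
              }
          }
        }
      std::vector<double> spV, spDX, spDY, spDZ;
      sph_block(A, B, cV, spV);
      sph_block(A, B, cDX, spDX);
      sph_block(A, B, cDY, spDY);
      sph_block(A, B, cDZ, spDZ);
      int nsa = 2 * A.l + 1, nsb = 2 * B.l + 1;
      for (int ma = 0; ma < nsa; ++ma)
        for (int mb = 0; mb < nsb; ++mb) {
          int I = A.ao_off + ma, J = B.ao_off + mb;
          S(I, J) = S(J, I) = spS[ma * nsb + mb];
          T(I, J) = T(J, I) = spT[ma * nsb + mb];
          V(I, J) = V(J, I) = spV[ma * nsb + mb];
          DX(I, J) = DX(J, I) = spDX[ma * nsb + mb];
          DY(I, J) = DY(J, I) = spDY[ma * nsb + mb];
          DZ(I, J) = DZ(J, I) = spDZ[ma * nsb + mb];
        }
    }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V,
                      _["DX"] = DX, _["DY"] = DY, _["DZ"] = DZ);
}

// ------------------------------------------------------------------- ERI
struct PairPrim {
  double p, P[3], cc; // exponent sum, product centre, coefficient product
};
struct PairData {
  int i, j;
  std::vector<PairPrim> pp;
};

// primitive-shell group: shells sharing centre, l and exponent ladder; the
// expensive per-primitive work is done once and scattered to all members
struct PGroup {
  int l;
  double c[3];
  std::vector<double> ex;
  std::vector<int> members; // indices into the Shell list
};

static std::vector<PGroup> group_shells(const std::vector<Shell>& sh) {
  std::vector<PGroup> gs;
  for (size_t k = 0; k < sh.size(); ++k) {
    bool found = false;
    for (size_t g = 0; g < gs.size(); ++g) {
      PGroup& G = gs[g];
      if (G.l != sh[k].l || G.c[0] != sh[k].c[0] || G.c[1] != sh[k].c[1] ||
          G.c[2] != sh[k].c[2] || G.ex.size() != sh[k].ex.size()) continue;
      bool same = true;
      for (size_t i = 0; i < G.ex.size(); ++i)
        if (G.ex[i] != sh[k].ex[i]) { same = false; break; }
      if (!same) continue;
      G.members.push_back((int)k);
      found = true;
      break;
    }
    if (!found) {
      PGroup G;
      G.l = sh[k].l; G.c[0] = sh[k].c[0]; G.c[1] = sh[k].c[1]; G.c[2] = sh[k].c[2];
      G.ex = sh[k].ex;
      G.members.push_back((int)k);
      gs.push_back(G);
    }
  }
  return gs;
}

// member-resolved cartesian ERI blocks for a group quartet:
// out[((ma*nmB+mb)*nmC+mc)*nmD+md] is a cart-quartet block
static void eri_block_grouped(const std::vector<Shell>& sh,
                              const PGroup& A, const PGroup& B,
                              const PGroup& C, const PGroup& D,
                              std::vector<std::vector<double> >& out) {
  int nca = ncart(A.l), ncb = ncart(B.l), ncc = ncart(C.l), ncd = ncart(D.l);
  int nmA = A.members.size(), nmB = B.members.size(),
      nmC = C.members.size(), nmD = D.members.size();
  size_t ncart4 = (size_t)nca * ncb * ncc * ncd;
  out.assign((size_t)nmA * nmB * nmC * nmD, std::vector<double>());
  for (size_t m = 0; m < out.size(); ++m) out[m].assign(ncart4, 0.0);
  int lxa[20], lya[20], lza[20], lxb[20], lyb[20], lzb[20];
  int lxc[20], lyc[20], lzc[20], lxd[20], lyd[20], lzd[20];
  cart_list(A.l, lxa, lya, lza); cart_list(B.l, lxb, lyb, lzb);
  cart_list(C.l, lxc, lyc, lzc); cart_list(D.l, lxd, lyd, lzd);
  double AB[3] = {A.c[0] - B.c[0], A.c[1] - B.c[1], A.c[2] - B.c[2]};
  double CD[3] = {C.c[0] - D.c[0], C.c[1] - D.c[1], C.c[2] - D.c[2]};
  int lab = A.l + B.l, lcd = C.l + D.l;
  std::vector<double> R0;
  int n1 = lab + 1;
  std::vector<double> G(ncc * ncd * n1 * n1 * n1);
  std::vector<double> blk(ncart4);
  // precompute Hermite expansion tables per primitive pair
  struct PairE {
    int ka, kb; double p, P[3];
    std::vector<double> Ex, Ey, Ez;
  };
  std::vector<PairE> pab, pcd;
  for (size_t ka = 0; ka < A.ex.size(); ++ka)
    for (size_t kb = 0; kb < B.ex.size(); ++kb) {
      double a = A.ex[ka], b = B.ex[kb], p = a + b;
      double mu = a * b / p * (AB[0]*AB[0]+AB[1]*AB[1]+AB[2]*AB[2]);
      if (mu > 46.0) continue;
      PairE e; e.ka = ka; e.kb = kb; e.p = p;
      e.P[0] = (a * A.c[0] + b * B.c[0]) / p;
      e.P[1] = (a * A.c[1] + b * B.c[1]) / p;
      e.P[2] = (a * A.c[2] + b * B.c[2]) / p;
      ecoef(A.l, B.l, a, b, AB[0], e.Ex);
      ecoef(A.l, B.l, a, b, AB[1], e.Ey);
      ecoef(A.l, B.l, a, b, AB[2], e.Ez);
      pab.push_back(e);
    }
  for (size_t kc = 0; kc < C.ex.size(); ++kc)
    for (size_t kd = 0; kd < D.ex.size(); ++kd) {
      double c = C.ex[kc], d = D.ex[kd], q = c + d;
      double nu = c * d / q * (CD[0]*CD[0]+CD[1]*CD[1]+CD[2]*CD[2]);
      if (nu > 46.0) continue;
      PairE e; e.ka = kc; e.kb = kd; e.p = q;
      e.P[0] = (c * C.c[0] + d * D.c[0]) / q;
      e.P[1] = (c * C.c[1] + d * D.c[1]) / q;
      e.P[2] = (c * C.c[2] + d * D.c[2]) / q;
      ecoef(C.l, D.l, c, d, CD[0], e.Ex);
      ecoef(C.l, D.l, c, d, CD[1], e.Ey);
      ecoef(C.l, D.l, c, d, CD[2], e.Ez);
      pcd.push_back(e);
    }
  for (size_t ipa = 0; ipa < pab.size(); ++ipa)
    for (size_t ipc = 0; ipc < pcd.size(); ++ipc) {
      const PairE& eab = pab[ipa];
      const PairE& ecd = pcd[ipc];
      size_t ka = eab.ka, kb = eab.kb, kc = ecd.ka, kd = ecd.kb;
      double p = eab.p, q = ecd.p;
      const double* P = eab.P;
      const double* Q = ecd.P;
      const std::vector<double>& E1x = eab.Ex;
      const std::vector<double>& E1y = eab.Ey;
      const std::vector<double>& E1z = eab.Ez;
      const std::vector<double>& E2x = ecd.Ex;
      const std::vector<double>& E2y = ecd.Ey;
      const std::vector<double>& E2z = ecd.Ez;
      {
          double alpha = p * q / (p + q);
          hermite_R(lab + lcd, lab + lcd, lab + lcd, alpha,
                    P[0] - Q[0], P[1] - Q[1], P[2] - Q[2], R0);
          int nru = lab + lcd + 1;
          double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
          std::fill(G.begin(), G.end(), 0.0);
          for (int ic = 0; ic < ncc; ++ic)
            for (int id = 0; id < ncd; ++id) {
              double* g = &G[(ic * ncd + id) * n1 * n1 * n1];
              int jx = lxc[ic] + lxd[id], jy = lyc[ic] + lyd[id], jz = lzc[ic] + lzd[id];
              for (int t2 = 0; t2 <= jx; ++t2) {
                double e2x = E2x[(lxc[ic] * (D.l + 1) + lxd[id]) * (lcd + 1) + t2];
                if (e2x == 0.0) continue;
                for (int u2 = 0; u2 <= jy; ++u2) {
                  double e2y = E2y[(lyc[ic] * (D.l + 1) + lyd[id]) * (lcd + 1) + u2];
                  if (e2y == 0.0) continue;
                  for (int v2 = 0; v2 <= jz; ++v2) {
                    double e2z = E2z[(lzc[ic] * (D.l + 1) + lzd[id]) * (lcd + 1) + v2];
                    if (e2z == 0.0) continue;
                    double sgn = ((t2 + u2 + v2) % 2) ? -1.0 : 1.0;
                    double w = sgn * e2x * e2y * e2z;
                    for (int t = 0; t <= lab; ++t)
                      for (int u = 0; u <= lab - t; ++u)
                        for (int v = 0; v <= lab - t - u; ++v)
                          g[(t * n1 + u) * n1 + v] +=
                            w * R0[((t + t2) * nru + (u + u2)) * nru + (v + v2)];
                  }
                }
              }
            }
          for (int ia = 0; ia < nca; ++ia)
            for (int ib = 0; ib < ncb; ++ib) {
              int ix = lxa[ia] + lxb[ib], iy = lya[ia] + lyb[ib], iz = lza[ia] + lzb[ib];
              for (int ic = 0; ic < ncc; ++ic)
                for (int id = 0; id < ncd; ++id) {
                  double* g = &G[(ic * ncd + id) * n1 * n1 * n1];
                  double v = 0.0;
                  for (int t = 0; t <= ix; ++t) {
                    double e1x = E1x[(lxa[ia] * (B.l + 1) + lxb[ib]) * (lab + 1) + t];
                    if (e1x == 0.0) continue;
                    for (int u = 0; u <= iy; ++u) {
                      double e1y = E1y[(lya[ia] * (B.l + 1) + lyb[ib]) * (lab + 1) + u];
                      if (e1y == 0.0) continue;
                      for (int w2 = 0; w2 <= iz; ++w2) {
                        double e1z = E1z[(lza[ia] * (B.l + 1) + lzb[ib]) * (lab + 1) + w2];
                        if (e1z == 0.0) continue;
                        v += e1x * e1y * e1z * g[(t * n1 + u) * n1 + w2];
                      }
                    }
                  }
                  blk[((ia * ncb + ib) * ncc + ic) * ncd + id] = pref * v;
                }
            }
          // scatter to all member quartets with contraction coefficients
          for (int ma = 0; ma < nmA; ++ma) {
            double ca = sh[A.members[ma]].cf[ka];
            if (ca == 0.0) continue;
            for (int mb = 0; mb < nmB; ++mb) {
              double cab = ca * sh[B.members[mb]].cf[kb];
              if (cab == 0.0) continue;
              for (int mc = 0; mc < nmC; ++mc) {
                double cabc = cab * sh[C.members[mc]].cf[kc];
                if (cabc == 0.0) continue;
                for (int md = 0; md < nmD; ++md) {
                  double w = cabc * sh[D.members[md]].cf[kd];
                  if (w == 0.0) continue;
                  double* dst = out[(((size_t)ma * nmB + mb) * nmC + mc) * nmD + md].data();
                  for (size_t x = 0; x < ncart4; ++x) dst[x] += w * blk[x];
                }
              }
            }
          }
        }
    }
  (void)0;
}

// contract ERI quartet block (cartesian) for shell pair AB, CD
static void eri_block(const Shell& A, const Shell& B, const Shell& C, const Shell& D,
                      std::vector<double>& out) {
  int nca = ncart(A.l), ncb = ncart(B.l), ncc = ncart(C.l), ncd = ncart(D.l);
  out.assign(nca * ncb * ncc * ncd, 0.0);
  int lxa[20], lya[20], lza[20], lxb[20], lyb[20], lzb[20];
  int lxc[20], lyc[20], lzc[20], lxd[20], lyd[20], lzd[20];
  cart_list(A.l, lxa, lya, lza); cart_list(B.l, lxb, lyb, lzb);
  cart_list(C.l, lxc, lyc, lzc); cart_list(D.l, lxd, lyd, lzd);
  double AB[3] = {A.c[0] - B.c[0], A.c[1] - B.c[1], A.c[2] - B.c[2]};
  double CD[3] = {C.c[0] - D.c[0], C.c[1] - D.c[1], C.c[2] - D.c[2]};
  int lab = A.l + B.l, lcd = C.l + D.l;
  std::vector<double> E1x, E1y, E1z, E2x, E2y, E2z, R0;
  int n1 = lab + 1, n2 = lcd + 1;
  // G[cd-component][tuv(ab)] intermediate
  std::vector<double> G(ncc * ncd * n1 * n1 * n1);
  for (size_t ka = 0; ka < A.ex.size(); ++ka)
    for (size_t kb = 0; kb < B.ex.size(); ++kb) {
      double a = A.ex[ka], b = B.ex[kb];
      double p = a + b, ccab = A.cf[ka] * B.cf[kb];
      double P[3] = {(a * A.c[0] + b * B.c[0]) / p, (a * A.c[1] + b * B.c[1]) / p,
                     (a * A.c[2] + b * B.c[2]) / p};
      ecoef(A.l, B.l, a, b, AB[0], E1x);
      ecoef(A.l, B.l, a, b, AB[1], E1y);
      ecoef(A.l, B.l, a, b, AB[2], E1z);
      double mu = a * b / p * (AB[0]*AB[0]+AB[1]*AB[1]+AB[2]*AB[2]);
      if (mu > 46.0) continue; // exp(-46) ~ 1e-20
      for (size_t kc = 0; kc < C.ex.size(); ++kc)
        for (size_t kd = 0; kd < D.ex.size(); ++kd) {
          double c = C.ex[kc], d = D.ex[kd];
          double q = c + d, cccd = C.cf[kc] * D.cf[kd];
          double nu = c * d / q * (CD[0]*CD[0]+CD[1]*CD[1]+CD[2]*CD[2]);
          if (nu > 46.0) continue;
          double Q[3] = {(c * C.c[0] + d * D.c[0]) / q, (c * C.c[1] + d * D.c[1]) / q,
                         (c * C.c[2] + d * D.c[2]) / q};
          ecoef(C.l, D.l, c, d, CD[0], E2x);
          ecoef(C.l, D.l, c, d, CD[1], E2y);
          ecoef(C.l, D.l, c, d, CD[2], E2z);
          double alpha = p * q / (p + q);
          hermite_R(lab + lcd, lab + lcd, lab + lcd, alpha,
                    P[0] - Q[0], P[1] - Q[1], P[2] - Q[2], R0);
          int nru = lab + lcd + 1;
          double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q)) *
                        ccab * cccd;
          // G_{tuv}^{(cd)} = sum_{t'u'v'} (-1)^{..} Ecd R_{t+t',..}
          std::fill(G.begin(), G.end(), 0.0);
          for (int ic = 0; ic < ncc; ++ic)
            for (int id = 0; id < ncd; ++id) {
              double* g = &G[(ic * ncd + id) * n1 * n1 * n1];
              int jx = lxc[ic] + lxd[id], jy = lyc[ic] + lyd[id], jz = lzc[ic] + lzd[id];
              for (int t2 = 0; t2 <= jx; ++t2) {
                double e2x = E2x[(lxc[ic] * (D.l + 1) + lxd[id]) * (lcd + 1) + t2];
                if (e2x == 0.0) continue;
                for (int u2 = 0; u2 <= jy; ++u2) {
                  double e2y = E2y[(lyc[ic] * (D.l + 1) + lyd[id]) * (lcd + 1) + u2];
                  if (e2y == 0.0) continue;
                  for (int v2 = 0; v2 <= jz; ++v2) {
                    double e2z = E2z[(lzc[ic] * (D.l + 1) + lzd[id]) * (lcd + 1) + v2];
                    if (e2z == 0.0) continue;
                    double sgn = ((t2 + u2 + v2) % 2) ? -1.0 : 1.0;
                    double w = sgn * e2x * e2y * e2z;
                    for (int t = 0; t <= lab; ++t)
                      for (int u = 0; u <= lab - t; ++u)
                        for (int v = 0; v <= lab - t - u; ++v)
                          g[(t * n1 + u) * n1 + v] +=
                            w * R0[((t + t2) * nru + (u + u2)) * nru + (v + v2)];
                  }
                }
              }
            }
          // contract with Eab
          for (int ia = 0; ia < nca; ++ia)
            for (int ib = 0; ib < ncb; ++ib) {
              int ix = lxa[ia] + lxb[ib], iy = lya[ia] + lyb[ib], iz = lza[ia] + lzb[ib];
              for (int ic = 0; ic < ncc; ++ic)
                for (int id = 0; id < ncd; ++id) {
                  double* g = &G[(ic * ncd + id) * n1 * n1 * n1];
                  double v = 0.0;
                  for (int t = 0; t <= ix; ++t) {
                    double e1x = E1x[(lxa[ia] * (B.l + 1) + lxb[ib]) * (lab + 1) + t];
                    if (e1x == 0.0) continue;
                    for (int u = 0; u <= iy; ++u) {
                      double e1y = E1y[(lya[ia] * (B.l + 1) + lyb[ib]) * (lab + 1) + u];
                      if (e1y == 0.0) continue;
                      for (int w2 = 0; w2 <= iz; ++w2) {
                        double e1z = E1z[(lza[ia] * (B.l + 1) + lzb[ib]) * (lab + 1) + w2];
                        if (e1z == 0.0) continue;
                        v += e1x * e1y * e1z * g[(t * n1 + u) * n1 + w2];
                      }
                    }
                  }
                  out[((ia * ncb + ib) * ncc + ic) * ncd + id] += pref * v;
                }
            }
        }
    }
}

// spherical transform of 4-index block
static void sph_block4(const Shell& A, const Shell& B, const Shell& C, const Shell& D,
                       std::vector<double>& cart, std::vector<double>& out) {
  std::vector<std::vector<double> > ra, rb, rc, rd;
  c2s_rows(A.l, ra); c2s_rows(B.l, rb); c2s_rows(C.l, rc); c2s_rows(D.l, rd);
  int nca = ncart(A.l), ncb = ncart(B.l), ncc = ncart(C.l), ncd = ncart(D.l);
  int na = 2 * A.l + 1, nb = 2 * B.l + 1, nc = 2 * C.l + 1, nd = 2 * D.l + 1;
  // transform index by index
  std::vector<double> t1(na * ncb * ncc * ncd, 0.0);
  for (int m = 0; m < na; ++m)
    for (int ia = 0; ia < nca; ++ia) {
      double w = ra[m][ia] * A.scale[m];
      if (w == 0.0) continue;
      const double* src = &cart[ia * ncb * ncc * ncd];
      double* dst = &t1[m * ncb * ncc * ncd];
      for (int k = 0; k < ncb * ncc * ncd; ++k) dst[k] += w * src[k];
    }
  std::vector<double> t2(na * nb * ncc * ncd, 0.0);
  for (int i = 0; i < na; ++i)
    for (int m = 0; m < nb; ++m)
      for (int ib = 0; ib < ncb; ++ib) {
        double w = rb[m][ib] * B.scale[m];
        if (w == 0.0) continue;
        const double* src = &t1[(i * ncb + ib) * ncc * ncd];
        double* dst = &t2[(i * nb + m) * ncc * ncd];
        for (int k = 0; k < ncc * ncd; ++k) dst[k] += w * src[k];
      }
  std::vector<double> t3(na * nb * nc * ncd, 0.0);
  for (int i = 0; i < na * nb; ++i)
    for (int m = 0; m < nc; ++m)
      for (int ic = 0; ic < ncc; ++ic) {
        double w = rc[m][ic] * C.scale[m];
        if (w == 0.0) continue;
        const double* src = &t2[(i * ncc + ic) * ncd];
        double* dst = &t3[(i * nc + m) * ncd];
        for (int k = 0; k < ncd; ++k) dst[k] += w * src[k];
      }
  out.assign(na * nb * nc * nd, 0.0);
  for (int i = 0; i < na * nb * nc; ++i)
    for (int m = 0; m < nd; ++m) {
      double v = 0.0;
      for (int id = 0; id < ncd; ++id) v += rd[m][id] * D.scale[m] * t3[i * ncd + id];
      out[i * nd + m] = v;
    }
}

static inline size_t tri(size_t i, size_t j) { return i >= j ? i * (i + 1) / 2 + j : j * (j + 1) / 2 + i; }

// [[Rcpp::export]]
NumericVector cpp_eri(IntegerVector l, NumericMatrix centers, List exps, List coefs,
                      double screen = 1e-12) {
  std::vector<Shell> sh = build_shells(l, centers, exps, coefs);
  set_scales(sh);
  std::vector<PGroup> gs = group_shells(sh);
  int ng = gs.size();
  int nao = sh.back().ao_off + 2 * sh.back().l + 1;
  size_t npair = (size_t)nao * (nao + 1) / 2;
  NumericVector out(npair * (npair + 1) / 2);
  double* eri = out.begin();
  std::vector<std::vector<double> > blks;
  std::vector<double> sblk;
  // Schwarz bounds per group pair (max over member pairs)
  std::vector<double> Qb(ng * ng, 0.0);
  for (int gi = 0; gi < ng; ++gi)
    for (int gj = 0; gj <= gi; ++gj) {
      eri_block_grouped(sh, gs[gi], gs[gj], gs[gi], gs[gj], blks);
      int nmA = gs[gi].members.size(), nmB = gs[gj].members.size();
      double mx = 0.0;
      for (int ma = 0; ma < nmA; ++ma)
        for (int mb = 0; mb < nmB; ++mb) {
          const Shell& SA = sh[gs[gi].members[ma]];
          const Shell& SB = sh[gs[gj].members[mb]];
          std::vector<double>& cart =
            blks[(((size_t)ma * nmB + mb) * nmA + ma) * nmB + mb];
          sph_block4(SA, SB, SA, SB, cart, sblk);
          int na = 2 * SA.l + 1, nb = 2 * SB.l + 1;
          for (int a = 0; a < na; ++a)
            for (int b = 0; b < nb; ++b) {
              double v = std::fabs(sblk[((a * nb + b) * na + a) * nb + b]);
              if (v > mx) mx = v;
            }
        }
      Qb[gi * ng + gj] = Qb[gj * ng + gi] = std::sqrt(mx);
    }
  for (int gi = 0; gi < ng; ++gi)
    for (int gj = 0; gj <= gi; ++gj) {
      double qij = Qb[gi * ng + gj];
      for (int gk = 0; gk <= gi; ++gk) {
        int lmax = (gk == gi) ? gj : gk;
        for (int gm = 0; gm <= lmax; ++gm) {
          if (qij * Qb[gk * ng + gm] < screen) continue;
          eri_block_grouped(sh, gs[gi], gs[gj], gs[gk], gs[gm], blks);
          int nmA = gs[gi].members.size(), nmB = gs[gj].members.size(),
              nmC = gs[gk].members.size(), nmD = gs[gm].members.size();
          for (int ma = 0; ma < nmA; ++ma)
            for (int mb = 0; mb < nmB; ++mb)
              for (int mc = 0; mc < nmC; ++mc)
                for (int md = 0; md < nmD; ++md) {
                  const Shell& SA = sh[gs[gi].members[ma]];
                  const Shell& SB = sh[gs[gj].members[mb]];
                  const Shell& SC = sh[gs[gk].members[mc]];
                  const Shell& SD = sh[gs[gm].members[md]];
                  sph_block4(SA, SB, SC, SD,
                             blks[(((size_t)ma * nmB + mb) * nmC + mc) * nmD + md],
                             sblk);
                  int na = 2 * SA.l + 1, nb = 2 * SB.l + 1,
                      nc = 2 * SC.l + 1, nd = 2 * SD.l + 1;
                  for (int a = 0; a < na; ++a) {
                    int I = SA.ao_off + a;
                    for (int b = 0; b < nb; ++b) {
                      size_t ij = tri(I, SB.ao_off + b);
                      for (int c = 0; c < nc; ++c) {
                        int K = SC.ao_off + c;
                        for (int d = 0; d < nd; ++d) {
                          size_t kl = tri(K, SD.ao_off + d);
                          size_t hi = ij >= kl ? ij : kl, lo = ij >= kl ? kl : ij;
                          eri[hi * (hi + 1) / 2 + lo] =
                            sblk[((a * nb + b) * nc + c) * nd + d];
                        }
                      }
                    }
                  }
                }
        }
      }
    }
  out.attr("nao") = nao;
  return out;
}

// J and (optionally) K from packed ERI for a list of symmetric densities
// [[Rcpp::export]]
List cpp_jk(NumericVector eri, List Ds, bool want_K) {
  int nao = as<int>(eri.attr("nao"));
  int nd = Ds.size();
  std::vector<NumericMatrix> D(nd);
  std::vector<const double*> Dp(nd);
  std::vector<NumericMatrix> Jm(nd), Km(nd);
  std::vector<double*> Jp(nd), Kp(nd);
  List Js(nd), Ks(nd);
  for (int m = 0; m < nd; ++m) {
    D[m] = as<NumericMatrix>(Ds[m]);
    Dp[m] = D[m].begin();
    Jm[m] = NumericMatrix(nao, nao);
    Jp[m] = Jm[m].begin();
    if (want_K) { Km[m] = NumericMatrix(nao, nao); Kp[m] = Km[m].begin(); }
  }
  const double* e = eri.begin();
  size_t idx = 0;
  for (int i = 0; i < nao; ++i)
    for (int j = 0; j <= i; ++j) {
      size_t ij = tri(i, j);
      int k = 0, l2 = -1; // odometer over packed (k, l2), l2 <= k
      for (size_t kl = 0; kl <= ij; ++kl) {
        if (l2 < k) ++l2; else { ++k; l2 = 0; }
        double v = e[idx++];
        if (v == 0.0) continue;
        double dij = (i == j) ? 1.0 : 2.0;
        double dkl = (k == l2) ? 1.0 : 2.0;
        bool same = (ij == kl);
        size_t oij = (size_t)j * nao + i, okl = (size_t)l2 * nao + k;
        for (int m = 0; m < nd; ++m) {
          const double* Dm = Dp[m];
          Jp[m][oij] += v * dkl * Dm[okl];
          if (!same) Jp[m][okl] += v * dij * Dm[oij];
          if (want_K) {
            double* Kx = Kp[m];
            Kx[(size_t)k * nao + i] += v * Dm[(size_t)l2 * nao + j];
            if (k != l2) Kx[(size_t)l2 * nao + i] += v * Dm[(size_t)k * nao + j];
            if (i != j) {
              Kx[(size_t)k * nao + j] += v * Dm[(size_t)l2 * nao + i];
              if (k != l2) Kx[(size_t)l2 * nao + j] += v * Dm[(size_t)k * nao + i];
            }
            if (!same) {
              Kx[(size_t)i * nao + k] += v * Dm[(size_t)j * nao + l2];
              if (i != j) Kx[(size_t)j * nao + k] += v * Dm[(size_t)i * nao + l2];
              if (k != l2) {
                Kx[(size_t)i * nao + l2] += v * Dm[(size_t)j * nao + k];
                if (i != j) Kx[(size_t)j * nao + l2] += v * Dm[(size_t)i * nao + k];
              }
            }
          }
        }
      }
    }
  for (int m = 0; m < nd; ++m) {
    NumericMatrix& J = Jm[m];
    for (int i = 0; i < nao; ++i)
      for (int j = 0; j < i; ++j) J(j, i) = J(i, j);
    Js[m] = J;
    if (want_K) {
      NumericMatrix& Kx = Km[m];
      NumericMatrix Ko(nao, nao);
      for (int i = 0; i < nao; ++i)
        for (int j = 0; j < nao; ++j)
          Ko(i, j) = 0.5 * (Kx(i, j) + Kx(j, i));
      Ks[m] = Ko;
    }
  }
  if (want_K) return List::create(_["J"] = Js, _["K"] = Ks);
  return List::create(_["J"] = Js);
}


// fetch a single ERI element (i,j,k,l are 1-based from R)
// [[Rcpp::export]]
double cpp_eri_elem(NumericVector eri, int i, int j, int k, int l) {
  size_t ij = tri(i - 1, j - 1), kl = tri(k - 1, l - 1);
  size_t a = std::max(ij, kl), b = std::min(ij, kl);
  return eri[a * (a + 1) / 2 + b];
}
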