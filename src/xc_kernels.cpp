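// Exchange-correlation kernels for the translated pair-density functionals.
//
// The parent spin-density functionals (Slater exchange + PW92 correlation for
// LDA, PBE exchange/correlation, Becke 88 exchange + LYP correlation) are
// written once, templated over a forward-mode dual-number type whose scalar
// may be real or complex. The on-top translation maps (rho, sigma, Pi) to
// effective spin densities rho/2 +- sqrt(-Pi); for Pi > 0 these form a
// complex-conjugate pair and every kernel is evaluated with complex
// arithmetic on the principal branch. Conjugate alpha/beta symmetry makes the
// energy density and all (rho, sigma, Pi) derivatives real; the imaginary
// residue is asserted below. Derivatives are exact partials of the computed
// energy expression (three dual slots: d/drho, d/dsigma, d/dPi).
#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;
static const double PI_M = 3.14159265358979323846;

static inline double x_real(double v) { return v; }
static inline double x_real(const std::complex<double>& v) { return v.real(); }

template <class T, int N>
struct Dual {
  T v;
  T d[N];
  Dual() : v(0) { for (int i = 0; i < N; ++i) d[i] = T(0); }
  template <class U>
  Dual(U x) : v(x) { for (int i = 0; i < N; ++i) d[i] = T(0); }
};

template <class T, int N>
Dual<T, N> operator+(const Dual<T, N>& a, const Dual<T, N>& b) {
  Dual<T, N> r; r.v = a.v + b.v;
  for (int i = 0; i < N; ++i) r.d[i] = a.d[i] + b.d[i];
  return r;
}
template <class T, int N>
Dual<T, N> operator-(const Dual<T, N>& a, const Dual<T, N>& b) {
  Dual<T, N> r; r.v = a.v - b.v;
  for (int i = 0; i < N; ++i) r.d[i] = a.d[i] - b.d[i];
  return r;
}
template <class T, int N>
Dual<T, N> operator-(const Dual<T, N>& a) {
  Dual<T, N> r; r.v = -a.v;
  for (int i = 0; i < N; ++i) r.d[i] = -a.d[i];
  return r;
}
template <class T, int N>
Dual<T, N> operator*(const Dual<T, N>& a, const Dual<T, N>& b) {
  Dual<T, N> r; r.v = a.v * b.v;
  for (int i = 0; i < N; ++i) r.d[i] = a.d[i] * b.v + a.v * b.d[i];
  return r;
}
template <class T, int N>
Dual<T, N> operator/(const Dual<T, N>& a, const Dual<T, N>& b) {
  Dual<T, N> r; r.v = a.v / b.v;
  for (int i = 0; i < N; ++i) r.d[i] = (a.d[i] - r.v * b.d[i]) / b.v;
  return r;
}
template <class T, int N> Dual<T, N> operator*(double s, const Dual<T, N>& a) {
  Dual<T, N> r; r.v = s * a.v; for (int i = 0; i < N; ++i) r.d[i] = s * a.d[i]; return r;
}
template <class T, int N> Dual<T, N> operator*(const Dual<T, N>& a, double s) { return s * a; }
template <class T, int N> Dual<T, N> operator+(const Dual<T, N>& a, double s) {
  Dual<T, N> r = a; r.v = a.v + s; return r;
}
template <class T, int N> Dual<T, N> operator+(double s, const Dual<T, N>& a) { return a + s; }
template <class T, int N> Dual<T, N> operator-(const Dual<T, N>& a, double s) { return a + (-s); }
template <class T, int N> Dual<T, N> operator-(double s, const Dual<T, N>& a) {
  Dual<T, N> r; r.v = s - a.v; for (int i = 0; i < N; ++i) r.d[i] = -a.d[i]; return r;
}
template <class T, int N> Dual<T, N> operator/(double s, const Dual<T, N>& a) {
  Dual<T, N> r; r.v = s / a.v;
  for (int i = 0; i < N; ++i) r.d[i] = -s * a.d[i] / (a.v * a.v);
  return r;
}
template <class T, int N> Dual<T, N> operator/(const Dual<T, N>& a, double s) { return a * (1.0 / s); }

template <class T, int N> Dual<T, N> dpow(const Dual<T, N>& a, double e) {
  using std::pow;
  Dual<T, N> r; r.v = pow(a.v, e);
  T f = e * pow(a.v, e - 1.0);
  for (int i = 0; i < N; ++i) r.d[i] = f * a.d[i];
  return r;
}
template <class T, int N> Dual<T, N> dlog(const Dual<T, N>& a) {
  using std::log;
  Dual<T, N> r; r.v = log(a.v);
  for (int i = 0; i < N; ++i) r.d[i] = a.d[i] / a.v;
  return r;
}
template <class T, int N> Dual<T, N> dexp(const Dual<T, N>& a) {
  using std::exp;
  Dual<T, N> r; r.v = exp(a.v);
  for (int i = 0; i < N; ++i) r.d[i] = r.v * a.d[i];
  return r;
}
template <class T, int N> Dual<T, N> dsqrt(const Dual<T, N>& a) {
  using std::sqrt;
  Dual<T, N> r; r.v = sqrt(a.v);
  T f = 0.5 / r.v;
  for (int i = 0; i < N; ++i) r.d[i] = f * a.d[i];
  return r;
}
template <class T, int N> Dual<T, N> dasinh(const Dual<T, N>& a) {
  Dual<T, N> s = dsqrt(a * a + 1.0);
  Dual<T, N> r; using std::log;
  r.v = log(a.v + s.v);
  T f = T(1.0) / s.v;
  for (int i = 0; i < N; ++i) r.d[i] = f * a.d[i];
  return r;
}

// ------------------------------------------------------------ LDA pieces
// Slater exchange of the uniform gas, e_x(rho) per volume
template <class D> D slater_unif(const D& rho) {
  const double Cx = 0.75 * std::pow(3.0 / PI_M, 1.0 / 3.0);
  return -Cx * dpow(rho, 4.0 / 3.0);
}

// PW92 G interpolation
template <class D>
D pw92_G(const D& rs, double A, double a1, double b1, double b2, double b3, double b4) {
  D srs = dsqrt(rs);
  D den = 2.0 * A * (b1 * srs + b2 * rs + b3 * srs * rs + b4 * rs * rs);
  return -2.0 * A * (1.0 + a1 * rs) * dlog(1.0 + 1.0 / den);
}

// PW92 correlation energy per particle eps_c(rs, zeta)
template <class D> D pw92_eps(const D& rs, const D& zeta) {
  D e0 = pw92_G(rs, 0.031091, 0.21370, 7.5957, 3.5876, 1.6382, 0.49294);
  D e1 = pw92_G(rs, 0.015545, 0.20548, 14.1189, 6.1977, 3.3662, 0.62517);
  D mac = pw92_G(rs, 0.016887, 0.11125, 10.357, 3.6231, 0.88026, 0.49671);
  const double c = 1.0 / (std::pow(2.0, 4.0 / 3.0) - 2.0);
  D f = (dpow(1.0 + zeta, 4.0 / 3.0) + dpow(1.0 - zeta, 4.0 / 3.0) - 2.0) * c;
  const double fpp0 = 8.0 / (9.0 * (std::pow(2.0, 4.0 / 3.0) - 2.0));
  D z4 = zeta * zeta * zeta * zeta;
  return e0 - mac * f * (1.0 - z4) / fpp0 + (e1 - e0) * f * z4;
}

// ------------------------------------------------------------ GGA pieces
// PBE exchange per spin via spin scaling: 1/2 e_x[2 ra, 4 saa]
template <class D> D pbe_x_spin(const D& ra, const D& saa) {
  const double kappa = 0.804, mu = 0.2195149727645171;
  D rho = 2.0 * ra;            // doubled density
  D sig = 4.0 * saa;
  D kf2 = dpow(rho, 2.0 / 3.0) * std::pow(3.0 * PI_M * PI_M, 2.0 / 3.0);
  D s2 = sig / (4.0 * kf2 * rho * rho);
  D Fx = 1.0 + kappa - kappa / (1.0 + mu * s2 / kappa);
  return 0.5 * slater_unif(rho) * Fx;
}

// PBE correlation, total (needs rho, zeta, sigma_total)
template <class D> D pbe_c(const D& ra, const D& rb, const D& sig) {
  const double beta = 0.06672455060314922;
  const double gamma = (1.0 - std::log(2.0)) / (PI_M * PI_M);
  D rho = ra + rb;
  D zeta = (ra - rb) / rho;
  D rs = dpow(3.0 / (4.0 * PI_M) / rho, 1.0 / 3.0);
  D eps = pw92_eps(rs, zeta);
  D phi = 0.5 * (dpow(1.0 + zeta, 2.0 / 3.0) + dpow(1.0 - zeta, 2.0 / 3.0));
  D kf = dpow(3.0 * PI_M * PI_M * rho, 1.0 / 3.0);
  D ks2 = 4.0 * kf / PI_M;
  D phi2 = phi * phi;
  D t2 = sig / (4.0 * phi2 * ks2 * rho * rho);
  D phi3 = phi2 * phi;
  D x = -1.0 * eps / (gamma * phi3);
  // overflow guard: deep in the complex-translated regime |x| can exceed the
  // exp() range; the capped region carries negligible weight
  if (std::fabs(x_real(x.v)) > 500.0) {
    double sc = 500.0 / std::fabs(x_real(x.v));
    x = x * sc;
  }
  D expo = dexp(x);
  D Aa = beta / gamma / (expo - 1.0);
  D At2 = Aa * t2;
  D H = gamma * phi3 *
        dlog(1.0 + beta / gamma * t2 * (1.0 + At2) / (1.0 + At2 + At2 * At2));
  return rho * (eps + H);
}

// Becke 88 exchange per spin; ga is the (possibly complex) directed gradient
// magnitude with ga*ga = saa, chosen on the translation branch
template <class D> D b88_x_spin(const D& ra, const D& ga) {
  const double beta = 0.0042;
  D r43 = dpow(ra, 4.0 / 3.0);
  D x = ga / r43;
  const double Cxs = 1.5 * std::pow(3.0 / (4.0 * PI_M), 1.0 / 3.0);
  return -r43 * (Cxs + beta * x * x / (1.0 + 6.0 * beta * x * dasinh(x)));
}

// LYP correlation (Miehlich-Savin-Stoll-Preuss closed form)
template <class D>
D lyp_c(const D& ra, const D& rb, const D& saa, const D& sab, const D& sbb) {
  const double a = 0.04918, b = 0.132, c = 0.2533, d = 0.349;
  const double CF = 0.3 * std::pow(3.0 * PI_M * PI_M, 2.0 / 3.0);
  D rho = ra + rb;
  D r13 = dpow(rho, -1.0 / 3.0);
  D den = 1.0 + d * r13;
  D omega = dexp(-c * r13) / den * dpow(rho, -11.0 / 3.0);
  D delta = c * r13 + d * r13 / den;
  D sig = saa + 2.0 * sab + sbb;
  D term1 = -a * 4.0 / den * ra * rb / rho;
  D inner = ra * rb * (std::pow(2.0, 11.0 / 3.0) * CF * (dpow(ra, 8.0 / 3.0) + dpow(rb, 8.0 / 3.0)) +
                       (47.0 / 18.0 - 7.0 / 18.0 * delta) * sig -
                       (2.5 - delta / 18.0) * (saa + sbb) -
                       (delta - 11.0) / 9.0 * (ra * saa + rb * sbb) / rho) -
            2.0 / 3.0 * rho * rho * sig +
            (2.0 / 3.0 * rho * rho - ra * ra) * sbb +
            (2.0 / 3.0 * rho * rho - rb * rb) * saa;
  return term1 - a * b * omega * inner;
}

// full spin-resolved kernel: energy density per volume
// fun: 0 = LDA(Slater+PW92), 1 = PBE, 2 = BLYP
template <class D>
D exc_spin(int fun, const D& ra, const D& rb, const D& saa, const D& sab,
           const D& sbb, const D& ga, const D& gb) {
  if (fun == 0) {
    D rho = ra + rb;
    D zeta = (ra - rb) / rho;
    D rs = dpow(3.0 / (4.0 * PI_M) / rho, 1.0 / 3.0);
    return 0.5 * (slater_unif(2.0 * ra) + slater_unif(2.0 * rb)) +
           rho * pw92_eps(rs, zeta);
  } else if (fun == 1) {
    return pbe_x_spin(ra, saa) + pbe_x_spin(rb, sbb) +
           pbe_c(ra, rb, saa + 2.0 * sab + sbb);
  } else if (fun == 2) {
    return b88_x_spin(ra, ga) + b88_x_spin(rb, gb) + lyp_c(ra, rb, saa, sab, sbb);
  }
  stop("unknown functional code");
}

// ------------------------------------------------- translated entry point
// inputs per point: rho >= floor, sigma = |grad rho|^2, pi = correlated
// on-top pair density. Returns exc and exact partials wrt (rho, sigma, pi).
// [[Rcpp::export]]
List cpp_xc_translated(int fun, NumericVector rho, NumericVector sigma,
                       NumericVector pi_corr, double imag_tol = 1e-8) {
  int n = rho.size();
  NumericVector exc(n), vrho(n), vsig(n), vpi(n);
  IntegerVector regime(n);
  typedef Dual<cplx, 3> D;
  double max_imag = 0.0;
  for (int g = 0; g < n; ++g) {
    double rh = rho[g], sg = sigma[g], pi = pi_corr[g];
    if (rh <= 1.0000001e-12) { // density floor: no XC contribution
      exc[g] = vrho[g] = vsig[g] = vpi[g] = 0.0;
      regime[g] = 0;
      continue;
    }
    if (sg < 1e-28) sg = 1e-28; // keep sqrt(sigma) differentiable
    // clamp |pi| away from 0 so the even-in-q cancellation stays accurate
    double tiny = 1e-10 * rh * rh; // keeps q >= 1e-5*rho: even-in-q dual
                                   // cancellation noise stays ~1e-9 while the
                                   // evaluation-point shift is O(1e-10 rho^2)
    if (std::fabs(pi) < tiny) pi = -tiny;
    double pmin = -0.25 * rh * rh;
    if (pi < pmin) {
      if (pi < pmin - 1e-10 - 1e-10 * rh * rh)
        stop("on-top pair density below -rho^2/4: unphysical polarization");
      pi = pmin;
    }
    // keep the effective polarization strictly below 1 so that fractional
    // powers of (1 - zeta) stay differentiable (full polarization is the
    // boundary of the translation domain)
    if (pi <= pmin * (1.0 - 1e-13)) pi = pmin + std::max(-1e-13 * pmin, 1e-30);
    // cap the effective polarization at |zeta| = 5: physically meaningful
    // regions stay far below this; it only regularises vanishing-density
    // tails where the quartic active-orbital product outruns the density
    double pmax_eff = 6.25 * rh * rh;
    if (pi > pmax_eff) pi = pmax_eff;
    regime[g] = pi > 0.0 ? 1 : 0;
    D r; r.v = rh; r.d[0] = 1.0;
    D s; s.v = sg; s.d[1] = 1.0;
    D p; p.v = pi; p.d[2] = 1.0;
    D q = dsqrt(-1.0 * p);          // principal branch: i*sqrt(pi) if pi > 0
    D ra = 0.5 * r + q;
    D rb = 0.5 * r - q;
    D zeta = 2.0 * q / r;
    D gr = dsqrt(s);                // |grad rho| (real, >= 0)
    D ga = 0.5 * gr * (1.0 + zeta); // directed effective spin gradients
    D gb = 0.5 * gr * (1.0 - zeta);
    D saa = ga * ga, sbb = gb * gb, sab = ga * gb;
    D e = exc_spin<D>(fun, ra, rb, saa, sab, sbb, ga, gb);
    // conjugate symmetry: each output must be real relative to its own scale
    double im = std::fabs(e.v.imag()) / std::max(1.0, std::fabs(e.v.real()));
    for (int k = 0; k < 3; ++k)
      im = std::max(im, std::fabs(e.d[k].imag()) / std::max(1.0, std::fabs(e.d[k].real())));
    if (im > imag_tol)
      stop("imaginary residue %g in translated functional at rho=%g pi=%g", im, rh, pi);
    if (im > max_imag) max_imag = im;
    exc[g] = e.v.real();
    vrho[g] = e.d[0].real();
    vsig[g] = e.d[1].real();
    vpi[g] = e.d[2].real();
    if (!std::isfinite(exc[g]) || !std::isfinite(vrho[g]) ||
        !std::isfinite(vsig[g]) || !std::isfinite(vpi[g]))
      stop("non-finite kernel value at rho=%g sigma=%g pi=%g", rh, sg, pi);
  }
  return List::create(_["exc"] = exc, _["vrho"] = vrho, _["vsigma"] = vsig,
                      _["vpi"] = vpi, _["regime"] = regime, _["max_imag"] = max_imag);
}

// ------------------------------------------------- plain spin-DFT entry
// real spin densities and gradient invariants; derivative slots:
// (ra, rb, saa, sab, sbb). Used by the restricted/unrestricted KS reference.
// [[Rcpp::export]]
List cpp_xc_spin(int fun, NumericVector ra_, NumericVector rb_,
                 NumericVector saa_, NumericVector sab_, NumericVector sbb_) {
  int n = ra_.size();
  NumericVector exc(n), vra(n), vrb(n), vsaa(n), vsab(n), vsbb(n);
  typedef Dual<double, 5> D;
  for (int g = 0; g < n; ++g) {
    D ra; ra.v = ra_[g]; ra.d[0] = 1.0;
    D rb; rb.v = rb_[g]; rb.d[1] = 1.0;
    D saa; saa.v = saa_[g]; saa.d[2] = 1.0;
    D sab; sab.v = sab_[g]; sab.d[3] = 1.0;
    D sbb; sbb.v = sbb_[g]; sbb.d[4] = 1.0;
    // guard strictly zero spin densities (one-electron regions)
    if (ra.v < 1e-15) ra.v = 1e-15;
    if (rb.v < 1e-15) rb.v = 1e-15;
    if (saa.v < 1e-30) saa.v = 1e-30;
    if (sbb.v < 1e-30) sbb.v = 1e-30;
    D ga = dsqrt(saa), gb = dsqrt(sbb);
    D e = exc_spin<D>(fun, ra, rb, saa, sab, sbb, ga, gb);
    exc[g] = e.v; vra[g] = e.d[0]; vrb[g] = e.d[1];
    vsaa[g] = e.d[2]; vsab[g] = e.d[3]; vsbb[g] = e.d[4];
  }
  return List::create(_["exc"] = exc, _["vra"] = vra, _["vrb"] = vrb,
                      _["vsaa"] = vsaa, _["vsab"] = vsab, _["vsbb"] = vsbb);
}
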