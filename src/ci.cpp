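// Determinant-based CAS configuration interaction: alpha/beta string spaces,
// single-excitation tables, direct sigma = H C products for a spin-summed
// Hamiltonian H = sum h'_tu E_tu + 1/2 sum g_tuvw E_tu E_vw, spin-summed
// one- and two-body reduced density matrices, and the Hamiltonian diagonal.
#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cmath>
using namespace Rcpp;

static long choose_l(int n, int k) {
  if (k < 0 || k > n) return 0;
  long r = 1;
  for (int i = 1; i <= k; ++i) r = r * (n - k + i) / i;
  return r;
}

// lexicographic rank of an ascending occupation list
static long string_rank(const std::vector<int>& occ, int norb) {
  int k = occ.size();
  long r = 0;
  int prev = -1;
  for (int i = 0; i < k; ++i) {
    for (int o = prev + 1; o < occ[i]; ++o)
      r += choose_l(norb - 1 - o, k - 1 - i);
    prev = occ[i];
  }
  return r;
}

static void gen_strings(int norb, int nel, std::vector<std::vector<int> >& out) {
  out.clear();
  if (nel == 0) { out.push_back(std::vector<int>()); return; }
  std::vector<int> occ(nel);
  for (int i = 0; i < nel; ++i) occ[i] = i;
  while (true) {
    out.push_back(occ);
    int i = nel - 1;
    while (i >= 0 && occ[i] == norb - nel + i) --i;
    if (i < 0) break;
    ++occ[i];
    for (int j = i + 1; j < nel; ++j) occ[j] = occ[j - 1] + 1;
  }
}

// excitation table: rows (I, J, t*norb+u, sign) for a_t^+ a_u |I> = sign |J>
static IntegerMatrix excitation_table(int norb, int nel,
                                      const std::vector<std::vector<int> >& strs) {
  std::vector<int> rows;
  int ns = strs.size();
  for (int I = 0; I < ns; ++I) {
    const std::vector<int>& occ = strs[I];
    std::vector<bool> occup(norb, false);
    for (size_t i = 0; i < occ.size(); ++i) occup[occ[i]] = true;
    for (size_t iu = 0; iu < occ.size(); ++iu) {
      int u = occ[iu];
      // diagonal t = u
      rows.push_back(I); rows.push_back(I); rows.push_back(u * norb + u); rows.push_back(1);
      for (int t = 0; t < norb; ++t) {
        if (occup[t] || t == u) continue;
        std::vector<int> no;
        no.reserve(occ.size());
        for (size_t i = 0; i < occ.size(); ++i) if (occ[i] != u) no.push_back(occ[i]);
        // count permutation sign: position where u was, position where t goes
        int pu = 0; while (no.size() && pu < (int)no.size() && no[pu] < u) ++pu;
        int pt = 0; while (pt < (int)no.size() && no[pt] < t) ++pt;
        no.insert(no.begin() + pt, t);
        int sgn = ((pu + pt) % 2) ? -1 : 1;
        long J = string_rank(no, norb);
        rows.push_back(I); rows.push_back((int)J); rows.push_back(t * norb + u); rows.push_back(sgn);
      }
    }
  }
  int nr = rows.size() / 4;
  IntegerMatrix M(nr, 4);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < 4; ++c) M(r, c) = rows[4 * r + c];
  return M;
}

// [[Rcpp::export]]
List cpp_ci_space(int norb, int na, int nb) {
  std::vector<std::vector<int> > sa, sb;
  gen_strings(norb, na, sa);
  gen_strings(norb, nb, sb);
  IntegerMatrix occa(sa.size(), std::max(na, 1)), occb(sb.size(), std::max(nb, 1));
  for (size_t i = 0; i < sa.size(); ++i)
    for (int k = 0; k < na; ++k) occa(i, k) = sa[i][k];
  for (size_t i = 0; i < sb.size(); ++i)
    for (int k = 0; k < nb; ++k) occb(i, k) = sb[i][k];
  IntegerMatrix exa = excitation_table(norb, na, sa);
  IntegerMatrix exb = excitation_table(norb, nb, sb);
  return List::create(_["norb"] = norb, _["na"] = na, _["nb"] = nb,
                      _["nstra"] = (int)sa.size(), _["nstrb"] = (int)sb.size(),
                      _["occa"] = occa, _["occb"] = occb,
                      _["exa"] = exa, _["exb"] = exb);
}

// grouped excitation entries for one tu, flat arrays for speed
struct ExGroup { std::vector<int> I, J; std::vector<double> s; };

static void apply_E_grouped(const ExGroup& ga, const ExGroup& gb,
                            const double* C, int nstra, int nstrb, double* T) {
  // alpha excitations act on the row index; loop beta columns outermost so
  // every inner access stays within one contiguous column
  int na = ga.I.size();
  if (na) {
    for (int jb = 0; jb < nstrb; ++jb) {
      const double* src = C + (size_t)jb * nstra;
      double* dst = T + (size_t)jb * nstra;
      for (int r = 0; r < na; ++r) dst[ga.J[r]] += ga.s[r] * src[ga.I[r]];
    }
  }
  int nb = gb.I.size();
  for (int r = 0; r < nb; ++r) {
    const double* src = C + (size_t)gb.I[r] * nstra;
    double* dst = T + (size_t)gb.J[r] * nstra;
    double s = gb.s[r];
    for (int ia = 0; ia < nstra; ++ia) dst[ia] += s * src[ia];
  }
}

// transpose-accumulate: dst += s * src with (I, J) swapped roles, used for
// sigma += E_ij U (same pattern as apply)
static void build_groups(const IntegerMatrix& ex, int ntu, std::vector<ExGroup>& g) {
  g.assign(ntu, ExGroup());
  for (int r = 0; r < ex.nrow(); ++r) {
    int tu = ex(r, 2);
    g[tu].I.push_back(ex(r, 0));
    g[tu].J.push_back(ex(r, 1));
    g[tu].s.push_back(ex(r, 3));
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sigma(NumericMatrix C, NumericMatrix h1eff, NumericMatrix g2,
                        List space, int chunk = 24) {
  IntegerMatrix exa = space["exa"], exb = space["exb"];
  int nstra = space["nstra"], nstrb = space["nstrb"], norb = space["norb"];
  int ntu = norb * norb;
  size_t nd = (size_t)nstra * nstrb;
  NumericMatrix sig(nstra, nstrb);
  std::vector<ExGroup> ga, gb;
  build_groups(exa, ntu, ga);
  build_groups(exb, ntu, gb);
  const double* Cp = C.begin();
  double* Sp = sig.begin();
  // one-electron part: sigma += sum_tu h'_tu E_tu C
  {
    std::vector<double> T(nd);
    for (int tu = 0; tu < ntu; ++tu) {
      double h = h1eff(tu / norb, tu % norb);
      if (h == 0.0) continue;
      std::fill(T.begin(), T.end(), 0.0);
      apply_E_grouped(ga[tu], gb[tu], Cp, nstra, nstrb, T.data());
      for (size_t k = 0; k < nd; ++k) Sp[k] += h * T[k];
    }
  }
  // two-electron part: 1/2 sum_{ij,kl} g_{ij,kl} E_ij E_kl C, blocked so the
  // g-contraction runs as dgemm: U(:, ij) = sum_kl T(:, kl) g[kl, ij]
  std::vector<double> T((size_t)chunk * nd);
  std::vector<double> U((size_t)chunk * nd);
  std::vector<double> Gblk((size_t)chunk * chunk);
  for (int ij0 = 0; ij0 < ntu; ij0 += chunk) {
    int nij = std::min(chunk, ntu - ij0);
    std::fill(U.begin(), U.begin() + (size_t)nij * nd, 0.0);
    for (int kl0 = 0; kl0 < ntu; kl0 += chunk) {
      int nkl = std::min(chunk, ntu - kl0);
      std::fill(T.begin(), T.begin() + (size_t)nkl * nd, 0.0);
      for (int c = 0; c < nkl; ++c)
        apply_E_grouped(ga[kl0 + c], gb[kl0 + c], Cp, nstra, nstrb,
                        T.data() + (size_t)c * nd);
      for (int c2 = 0; c2 < nij; ++c2)
        for (int c1 = 0; c1 < nkl; ++c1)
          Gblk[(size_t)c2 * nkl + c1] = g2(kl0 + c1, ij0 + c2);
      int m = (int)nd;
      double one = 1.0;
      F77_CALL(dgemm)("N", "N", &m, &nij, &nkl, &one, T.data(), &m,
                      Gblk.data(), &nkl, &one, U.data(), &m FCONE FCONE);
    }
    // sigma += 1/2 E_ij U(:, ij)
    for (int c = 0; c < nij; ++c) {
      int ij = ij0 + c;
      const double* u = U.data() + (size_t)c * nd;
      const ExGroup& a = ga[ij];
      int na = a.I.size();
      if (na) {
        for (int jb = 0; jb < nstrb; ++jb) {
          const double* src = u + (size_t)jb * nstra;
          double* dst = Sp + (size_t)jb * nstra;
          for (int r = 0; r < na; ++r) dst[a.J[r]] += 0.5 * a.s[r] * src[a.I[r]];
        }
      }
      const ExGroup& b = gb[ij];
      for (size_t r = 0; r < b.I.size(); ++r) {
        const double* src = u + (size_t)b.I[r] * nstra;
        double* dst = Sp + (size_t)b.J[r] * nstra;
        double s = 0.5 * b.s[r];
        for (int iaa = 0; iaa < nstra; ++iaa) dst[iaa] += s * src[iaa];
      }
    }
  }
  return sig;
}

// spin-summed 1- and 2-RDM between bra and ket:
// D_tu = <bra|E_tu|ket>, G_tuvw = <bra|E_tu E_vw|ket> - delta_uv D_tw
// [[Rcpp::export]]
List cpp_rdm12(NumericMatrix bra, NumericMatrix ket, List space, bool want2 = true) {
  IntegerMatrix exa = space["exa"], exb = space["exb"];
  int nstra = space["nstra"], nstrb = space["nstrb"], norb = space["norb"];
  int ntu = norb * norb;
  size_t nd = (size_t)nstra * nstrb;
  NumericMatrix D(norb, norb);
  std::vector<ExGroup> ga, gb;
  build_groups(exa, ntu, ga);
  build_groups(exb, ntu, gb);
  // K^{tu} = E_tu ket for all tu
  std::vector<double> K((size_t)ntu * nd, 0.0);
  for (int tu = 0; tu < ntu; ++tu)
    apply_E_grouped(ga[tu], gb[tu], ket.begin(), nstra, nstrb, K.data() + (size_t)tu * nd);
  const double* B = bra.begin();
  for (int t = 0; t < norb; ++t)
    for (int u = 0; u < norb; ++u) {
      const double* k = K.data() + (size_t)(t * norb + u) * nd;
      double v = 0.0;
      for (size_t m = 0; m < nd; ++m) v += B[m] * k[m];
      D(t, u) = v;
    }
  if (!want2)
    return List::create(_["D"] = D);
  // Kb^{ut} = E_ut bra;  G = (E_ut bra) . (E_vw ket) - delta
  std::vector<double> Kb((size_t)ntu * nd, 0.0);
  bool same = false;
  // reuse K when bra == ket (pointer compare is enough for our callers)
  if (bra.begin() == ket.begin()) same = true;
  if (!same)
    for (int tu = 0; tu < ntu; ++tu)
      apply_E_grouped(ga[tu], gb[tu], bra.begin(), nstra, nstrb, Kb.data() + (size_t)tu * nd);
  NumericVector G((R_xlen_t)ntu * ntu);
  G.attr("dim") = IntegerVector::create(norb, norb, norb, norb);
  for (int tu = 0; tu < ntu; ++tu) {
    int t = tu / norb, u = tu % norb;
    const double* kb = same ? K.data() + (size_t)(u * norb + t) * nd
                            : Kb.data() + (size_t)(u * norb + t) * nd;
    for (int vw = 0; vw < ntu; ++vw) {
      int v = vw / norb, w = vw % norb;
      const double* kk = K.data() + (size_t)vw * nd;
      double val = 0.0;
      for (size_t m = 0; m < nd; ++m) val += kb[m] * kk[m];
      if (u == v) val -= D(t, w); // normal ordering correction
      G[(size_t)t + (size_t)norb * (u + (size_t)norb * (v + (size_t)norb * w))] = val;
    }
  }
  return List::create(_["D"] = D, _["G"] = G);
}

// Hamiltonian diagonal for Davidson preconditioning
// [[Rcpp::export]]
NumericMatrix cpp_hdiag(NumericMatrix h1eff, NumericMatrix g2, List space) {
  IntegerMatrix occa = space["occa"], occb = space["occb"];
  int nstra = space["nstra"], nstrb = space["nstrb"], norb = space["norb"];
  int na = space["na"], nb = space["nb"];
  NumericMatrix out(nstra, nstrb);
  std::vector<int> oa(na), ob(nb);
  for (int I = 0; I < nstra; ++I) {
    for (int k = 0; k < na; ++k) oa[k] = occa(I, k);
    for (int J = 0; J < nstrb; ++J) {
      for (int k = 0; k < nb; ++k) ob[k] = occb(J, k);
      std::vector<int> nt(norb, 0), nal(norb, 0), nbe(norb, 0);
      for (int k = 0; k < na; ++k) { nt[oa[k]]++; nal[oa[k]] = 1; }
      for (int k = 0; k < nb; ++k) { nt[ob[k]]++; nbe[ob[k]] = 1; }
      double e = 0.0;
      for (int t = 0; t < norb; ++t) {
        if (!nt[t]) continue;
        e += h1eff(t, t) * nt[t];
        for (int v = 0; v < norb; ++v) {
          if (!nt[v]) continue;
          e += 0.5 * g2(t * norb + t, v * norb + v) * nt[t] * nt[v];
        }
      }
      for (int t = 0; t < norb; ++t)
        for (int u = 0; u < norb; ++u) {
          if (t == u) continue;
          // <E_tu E_ut> over a determinant: sum_s n_ts (1 - n_us)
          double x = nal[t] * (1 - nal[u]) + nbe[t] * (1 - nbe[u]);
          if (x != 0.0) e += 0.5 * g2(t * norb + u, u * norb + t) * x;
        }
      out(I, J) = e;
    }
  }
  return out;
}
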