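---
title: "Variational multiconfigurational pair-density functional theory in vpdft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational multiconfigurational pair-density functional theory in vpdft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Kohn–Sham DFT with spin-density functionals fails qualitatively for strongly
correlated systems: stretched bonds, antiferromagnetically coupled metals,
and states whose spin components should be degenerate.
Multiconfigurational pair-density functional theory (MC-PDFT) replaces the
spin densities with two variables that are well defined for any
multiconfigurational wave function: the total density $\rho(r)$ and the
on-top pair density $\Pi(r)$, the probability density of finding two
electrons at the same point. The energy is assembled exactly as in
Kohn–Sham theory,

$$E \;=\; E_{\mathrm{nuc}} + \mathrm{Tr}(h\,D) +
  \tfrac12\,\mathrm{Tr}(D\,J[D]) + E_{xc}[\rho,\tilde\Pi],$$

with no exact-exchange term: the kinetic energy enters through the wave
function via $\mathrm{Tr}(h\,D)$, the Coulomb term is the classical
repulsion of the total density, and all exchange and correlation lives in
the pair-density functional.

`vpdft` works with the *correlated* on-top pair density
$\tilde\Pi = \Pi - \rho^2/4$, which vanishes identically for a closed-shell
single determinant and is computable from the active-space quantities alone:

$$\tilde\Pi(r) = \tfrac12 \sum_{tuvw} \Gamma^{\mathrm{ns}}_{tuvw}\,
  \phi_t(r)\phi_u(r)\phi_v(r)\phi_w(r),$$

where $\Gamma^{\mathrm{ns}}_{tuvw} = \Gamma_{tuvw} - D_{tu}D_{vw}
+ \tfrac12 D_{tw}D_{uv}$ is the nonseparable part of the spin-summed active
two-body density matrix (convention
$\Gamma_{tuvw} = \langle \hat E_{tu}\hat E_{vw} - \delta_{uv}\hat E_{tw}\rangle$).
Only the active molecular orbitals are ever evaluated on the grid for this
term, so its cost scales with the (small) active space, not with the system.

## Translated functionals and the complex regime

The exchange–correlation functionals are *translations* of standard
spin-density functionals. For a single determinant,
$\rho_{\alpha,\beta} = \rho/2 \pm \sqrt{-\tilde\Pi}$ recovers the exact spin
densities, so the translated functional is exactly congruent with spin-DFT
in that limit (the package asserts this numerically against its own
restricted and unrestricted KS implementations). For correlated states with
$\tilde\Pi > 0$ the effective spin densities become a complex-conjugate
pair, $\rho/2 \pm i\sqrt{\tilde\Pi}$; every kernel (Slater and Becke-88
exchange, PW92, PBE and LYP correlation) is then evaluated with complex
arithmetic on the principal branch. Conjugate $\alpha\beta$ symmetry makes
the energy density and all of its derivatives real; the imaginary residue is
checked at every point. The available functionals are `ctLDA`
(Slater + PW92), `ctPBE` and `ctBLYP`, plus real-only `tLDA`/`tPBE`/`tBLYP`
variants that clamp $\tilde\Pi$ at zero.

Effective spin gradients scale $\nabla\rho$ by $(1 \pm \zeta)/2$ with
$\zeta = 2\sqrt{-\tilde\Pi}/\rho$; the gradient of $\tilde\Pi$ itself is not
propagated. The derivatives used in the potentials are the *exact* partial
derivatives of the implemented energy expression with respect to
$(\rho, |\nabla\rho|^2, \tilde\Pi)$, obtained by forward-mode dual numbers
over complex scalars. This includes the $\tilde\Pi$- and
$\rho$-dependence of $\zeta$ inside the gradient channels: that is what
makes the analytic orbital and CI gradients agree with finite differences
of the energy to $10^{-6}$ Hartree, which the test suite enforces on three
molecules. Two numerical regularisations are applied and matter only in
vanishing-density tails: densities below $10^{-12}$ contribute no XC, and
the effective polarization is capped at $|\zeta| = 5$ (physical regions stay
far below this; without the cap, the complex-continued PW92 interpolation
overflows where the quartic active-orbital product decays more slowly than
the density).

## Gradients, Fock matrices and the two-step optimizer

Differentiating $E_{xc}$ produces a Kohn–Sham-like potential $v^{xc}$ (the
$\rho$ channel, assembled in the AO basis with the usual GGA
gradient terms) and a two-electron-like tensor
$w^{xc}_{puvw} = \sum_g w_g\, (\partial e/\partial\tilde\Pi)\,
\chi_p\phi_u\phi_v\phi_w$, kept with one AO and three active indices. The
orbital gradient is the antisymmetric part of a generalized Fock matrix
built from $G = h + J[D] + v^{xc}$ (no exchange term) and the
$w^{xc}\cdot\Gamma^{\mathrm{ns}}$ contraction, restricted to the
nonredundant rotations (inactive–active, inactive–virtual,
active–virtual). The CI step receives effective integrals
$h^{\mathrm{eff}}_{tu} = G_{tu} - \tfrac12\sum_{vw}w^{xc}_{tuvw}D_{vw}$ and
$g^{\mathrm{eff}} = w^{xc}$, whose CI gradient equals the exact CI gradient
of the PDFT energy at the expansion point. They are only first-order
consistent: away from the point the quadratic CI model is not the energy,
which is why a standard Davidson solve fails for variational MC-PDFT.

The optimizer is therefore two-step:

* **CI step.** For CASSCF, Davidson diagonalization of the active
  Hamiltonian (dense fallback below dimension 400, diagonal-preconditioned
  subspace iteration above). For variational MC-PDFT, a quasi-Newton
  minimisation on the unit sphere whose integrals are *re-evaluated at
  every CI iteration* (densities → grid $\tilde\Pi$ → kernels → effective
  integrals), with a diagonal-Hamiltonian preconditioner and a backtracking
  line search on the true re-evaluated energy, so every accepted step
  decreases the actual PDFT energy.
* **Orbital step.** A quasi-Newton rotation $C \to C e^{\kappa}$ with a
  diagonal Hessian from generalized-Fock and occupation differences
  (floored at 0.05 Ha to prevent runaway steps along nearly redundant
  rotations), an L-BFGS curvature update whose direction is discarded
  whenever the interleaved CI re-solve has spoiled descent, a trust radius
  (initial 0.3), and a backtracking line search at fixed CI coefficients.

Convergence requires both the orbital-gradient maximum (default
$10^{-5}$ Ha; a few $10^{-4}$ for the dissociation scans, whose energies
are converged far tighter than that through the line searches) and the
energy change (default $10^{-8}$ Ha). Two pragmatic exits supplement this:
a stationary tail in which the energy is flat while weakly coupled
rotations still polish slowly is accepted after several consecutive
sub-threshold energy changes, and near dissociation — where the active
space contains degenerate empty orbitals and the gradient wanders on an
energetically flat manifold — a fit that reaches the iteration cap with
energy changes below $3\times10^{-5}$ Ha is accepted and flagged
(`capped = TRUE`). The final gradient is stored on the fit object either
way. Warm-started scan continuation points use a reduced trust radius
(0.05–0.1), which keeps the optimizer on the solution branch being tracked
instead of tunnelling to other local solutions (CASSCF-like methods
genuinely have several, differing in active-orbital character). The
perturbative variant (`ppdft`) evaluates the translated functional once on
converged CASSCF densities.

## Self-contained quantum-chemistry layer

No external electronic-structure backend is used anywhere: the package
carries its own McMurchie–Davidson Gaussian integral engine (spherical
functions up to $f$, general contractions shared at the primitive level,
Schwarz screening, packed 8-fold-symmetric storage), SCF with DIIS and level
shifting, a determinant CAS-CI with BLAS-blocked sigma vectors, and an
atom-centred quadrature grid: Mura–Knowles log-3 radial grids with a
Gauss–Legendre × uniform azimuthal product rule (exact to angular degree
$2n_\theta - 1$), three-tier pruning, and Becke fuzzy-cell weights with
Bragg-radius size adjustment. Grid levels 1–6 map to 35–110 radial shells
and 9–27 polar nodes; level 3 integrates the water density to
$10^{-7}$ relative. Because the same grid is used on both sides of every
consistency check (and in both the energy and its analytic derivatives),
the finite-difference validations are exact at any grid level; grid density
only affects absolute energies, and the dissociation energies reported by
the scans are differences in which most of the residual grid error cancels.

## Basis sets

Basis data are plain-text files under `inst/extdata/basis`. STO-3G, 6-31G
and cc-pVDZ (H, C) were transcribed from the standard published
tabulations. For Mg and Cu no published triple-zeta data could be bundled;
the package instead *generates* a synthetic substitute
(`generate_et_basis()`): an even-tempered primitive ladder per angular
channel, generally contracted with the atomic-SCF orbitals of the neutral
atom (ANO style), the outermost primitives left free, and rule-based
polarization shells (two $d$ sets for Mg, one $f$ for Cu). The shipped
`synthetic-etzv` file is the output of that generator; the Mg atom comes
within 2 mHa of the Hartree–Fock limit, the Cu atom within about 0.1 Ha.
This is a deliberate, clearly labelled stand-in, not a published set: metal
dimer dissociation energies computed with it carry a basis error of a few
hundredths of an eV relative to calculations with established
triple-zeta sets, in addition to functional and scan-granularity effects.

## Benchmark drivers and chosen problem sizes

The workflow layer provides warm-started dissociation scans (scanned from
the asymptote inward to track one solution branch; $D_e$ is the energy at
the largest scanned distance minus a local cubic interpolation of the
minimum), active-space ladders, natural occupations, dipole moments (for
variational states these match the field-derivative to the enforced
tolerance; the perturbative state visibly does not, which is one of the
motivations for the variational formulation), and a singlet–triplet gap
driver. The acceptance script reproduces, at desk scale: the water/6-31G
single-determinant-to-full-CI lowering (full CI over all 13 orbitals,
1.66 million determinants); benzene $\pi$-space CAS(6,6)/cc-pVDZ natural
occupations for CASSCF and variational MC-ctPBE (the variational
occupations collapse towards 2/0 — the reduced active-space dependency that
makes the perturbative energy rise with active-space size); the Mg2
CAS(4,8) MC-ctPBE curve (a weak van-der-Waals-like minimum, absent at the
CASSCF level; 3.4–3.9 Å in 0.25 Å steps plus the 10 Å asymptote); and Cu2
CAS(2,2) CASSCF/MC-ctPBE curves (2.1–2.6 Å plus 10 Å, the interior chained
upward from a cold start at the shortest distance so the variational
optimization tracks its lowest solution branch through the minimum). Scan
grids use three to four interior points bracketing the minimum plus the
asymptote, at grid level 1 (Mg2) or 2 (Cu2); these sizes were chosen once
as the smallest that keep the interpolated $D_e$ stable at the 0.01 eV
level. Chromium dimer curves with
CAS(12,12) are out of desk scale and are not attempted; the
variational-versus-perturbative binding ordering they illustrate is covered
on smaller fixtures.

## Degenerate and edge inputs

Zero-size active spaces are legal and reduce exactly to restricted KS-DFT
(asserted to $10^{-8}$ Ha); CAS(1,1) on hydrogen reduces to unrestricted
KS. High-spin sectors are selected by $M_s$; the $M_s = 0$ component of a
triplet gives the same density and on-top pair density as the high-spin
component, and the package reproduces that degeneracy to quadrature
accuracy. Davidson falls back to dense diagonalization for small CI spaces;
2-RDM partial traces are asserted against the 1-RDM on every build;
negative grid densities beyond $-10^{-10}$ and on-top values below
$-\rho^2/4 - 10^{-10}$ raise errors rather than being silently clamped.

## Known limitations

Only pure (non-hybrid) LDA/GGA translations are implemented; the
fully-translated ("ft") variants with pair-density gradient terms are out
of scope by design. Single-state optimization only: no state averaging, and
excited roots are not tracked. The determinant CI is dense-vector based and
practical to roughly CAS(12,12). The synthetic metal basis and the absence
of scalar-relativistic corrections limit quantitative agreement for Cu2 at
the few-hundredths-of-an-eV level. Checkpointing uses RDS files.
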