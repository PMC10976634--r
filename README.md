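# vpdft — variational multiconfigurational pair-density functional theory

`vpdft` is a self-contained R implementation of multiconfigurational
pair-density functional theory (MC-PDFT) in which the wave function —
orbitals *and* CI coefficients — is optimized **variationally** under the
pair-density functional, rather than taken from a converged CASSCF
calculation ("perturbative" MC-PDFT). It is aimed at quantum chemists who
want to study strong correlation (bond breaking, metal dimers, open
shells) at a cost close to Kohn–Sham DFT.

## The method in brief

For a CAS wave function with inactive (doubly occupied) and active
orbitals, the energy is a Kohn–Sham-like functional

```
E = E_nuc + Tr(h D) + 1/2 Tr(D J[D]) + E_xc[rho, Pi~]
```

with no exact exchange. `E_xc` is a *translated* spin-density functional
(ctLDA, ctPBE, ctBLYP) evaluated at effective spin densities

```
rho_a,b(r) = rho(r)/2 ± sqrt(-Pi~(r)),
```

where `Pi~ = Pi − rho²/4` is the correlated on-top pair density: zero for a
closed-shell determinant, computable from the nonseparable active 2-RDM
alone, and *positive* where correlation puts extra same-point pair density
— there the effective spin densities form a complex-conjugate pair and the
kernels are evaluated in complex arithmetic (the energy stays real by
conjugate symmetry). Orbitals and CI coefficients minimise this energy
through a two-step quasi-Newton optimizer whose CI step re-evaluates the
effective integrals at every iteration; all analytic gradients are verified
against finite differences in the test suite.

Everything underneath — Gaussian integrals (McMurchie–Davidson, spherical
functions up to f), DFT quadrature grids with Becke partitioning, RHF/UHF
and restricted/unrestricted KS baselines, determinant CAS-CI with a
Davidson solver — is implemented inside the package (R + Rcpp); no external
quantum-chemistry program is required.

## Worked example

Water with a CAS(2,2) active space, comparing CASSCF, perturbative and
variational MC-ctPBE:

```r
library(vpdft)
sys <- build_system(system.file("extdata", "geometries", "water.xyz",
                                package = "vpdft"), basis = "6-31g")
cas <- mcscf(sys, cas = c(2, 2), method = "casscf", conv_grad = 1e-4)
print(cas)
#> CASSCF CAS(2,2): E = -75.9849671578 Ha (22 macro-iterations)
pp  <- perturbative_energy(cas, "ctPBE")
vv  <- mcscf(sys, cas = c(2, 2), method = "vpdft", functional = "ctPBE",
             grid = pp$grid, conv_grad = 1e-4)
c(casscf = cas$E, ppdft = pp$E, vpdft = vv$E)
#>    casscf     ppdft     vpdft
#> -75.98497 -76.29556 -76.29864
natural_occupations(vv)
#> [1] 1.9991906243 0.0008093757
dipole_moment(vv)          # Debye
#> [1]  5.068337e-15 -8.337707e-06  2.422597e+00
```

The CASSCF energy sits ~0.31 Ha above the pair-density-functional energies
(the functional supplies the dynamic correlation); the variational energy is
below the perturbative one, as it must be, and its natural occupations are
closer to 2/0 — the reduced active-space dependency that is one of the
method's selling points. A command-line driver with the same capabilities
is installed at `inst/scripts/vpdft` (`vpdft run config.yaml`,
`vpdft scan config.yaml`, `vpdft ladder config.yaml`).

Basis sets are read from plain-text tables bundled with the package
(STO-3G, 6-31G, cc-pVDZ); for the metal dimers a synthetic even-tempered
triple-zeta-quality set generated by `generate_et_basis()` is shipped as
`synthetic-etzv` (see the methods vignette for what that substitution
implies).

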