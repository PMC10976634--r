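Package: vpdft
Title: Variational Multiconfigurational Pair-Density Functional Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-contained quantum-chemistry engine for multiconfigurational
    pair-density functional theory (MC-PDFT) with complex-translated
    pair-density functionals (ctLDA, ctPBE, ctBLYP). Provides Gaussian-basis
    molecular integrals (McMurchie-Davidson), Becke-partitioned quadrature
    grids, restricted Hartree-Fock and Kohn-Sham baselines, determinant-based
    CAS configuration interaction with a Davidson eigensolver, two-step
    quasi-Newton CASSCF, and both perturbative and fully variational MC-PDFT
    in which orbitals and CI coefficients minimise a Kohn-Sham-like energy
    whose exchange-correlation term is a translated functional of the total
    density and the correlated on-top pair-density. Includes drivers for
    dissociation curves, active-space ladders, natural occupations and dipole
    moments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: Rcpp, stats, utils, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
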