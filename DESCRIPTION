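Package: alchemr
Title: Alchemical Free-Energy Estimators, Diagnostics, and Toy-System Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators for alchemical free-energy differences between
    coupled Hamiltonians: Bennett acceptance ratio (BAR), thermodynamic
    integration (TI), extended TI with ensemble reweighting to a dense
    lambda grid (X-TI), enveloping distribution sampling (EDS), the hybrid
    EDS-TI scheme, and two-dimensional TI over a (lambda, kappa) coupling
    grid.  Ships Metropolis Monte Carlo sampling of analytically tractable
    toy systems (Gaussian families with closed-form free energies, and a
    four-state restrained-water/side-chain model with a steric clash,
    solved by deterministic quadrature), an automated EDS parameter search,
    error estimation by block averaging and bootstrap, thermodynamic-cycle
    closure metrics, convergence and prolongation algorithms, and a
    plain-text series format compatible with xvg-style output of molecular
    dynamics codes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
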