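Package: redoxlra
Title: Linear-Response Redox Free Energies from Vertical Energy Gaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes one-electron oxidation free energies and redox
    potentials from ensembles of vertical energy gaps sampled on the
    reduced and oxidized surfaces, using the linear response
    approximation and exponential (Zwanzig) averaging, with Marcus
    free-energy parabolas, bootstrap uncertainties, and convergence
    diagnostics (running averages, gap histograms, PCA decorrelation).
    Includes solvation-structure analysis (minimum-image radial
    distribution functions, first-shell radius and coordination
    number, solute-counterion distance binning), construction of
    QM/MM electrostatic-embedding regions under center-of-mass and
    shortest-atom-distance water-selection criteria with cutoff
    sweeps, readers and writers for multi-frame XYZ, minimal PDB and
    gap tables, and a synthetic generator producing gap ensembles
    with linear-response statistics and solvated cubic boxes so the
    whole pipeline is testable without molecular dynamics or quantum
    chemistry software.
License: MIT
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
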