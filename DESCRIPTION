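Package: mlphotodyn
Title: Machine-Learned Potentials for Nonadiabatic Surface-Hopping Photodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains feed-forward neural-network potentials for several coupled
    electronic states (energies, forces as analytic derivatives, phase-corrected
    nonadiabatic couplings, dipole moments and optional spin-orbit couplings),
    drives fewest-switches surface-hopping molecular dynamics with an ensemble
    of such networks, grows the training set by ensemble-disagreement adaptive
    sampling, and optimizes and analyzes conical intersections. Analytic
    multi-state diabatic model Hamiltonians serve as the electronic-structure
    reference so the whole pipeline is testable without external quantum
    chemistry, including the wavefunction-phase problem that makes off-diagonal
    couplings unlearnable without phase correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
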