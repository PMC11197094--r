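Package: radscav
Title: Radical-Scavenging, Chelation and Repair Kinetics of Antioxidants
    from Quantum-Chemical Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit that turns tabulated quantum-chemical
    energetics of antioxidant reaction channels (reaction free energies,
    Marcus reorganization energies, activation free energies, pKa ladders)
    into solution-phase kinetics: Eyring transition-state rate constants,
    Marcus electron-transfer barriers, Smoluchowski diffusion limits with
    Collins-Kimball apparent rates, branching ratios, acid-base speciation
    and pH-corrected overall rate constants, Cu(II) chelation equilibria
    with Boltzmann populations, pro-oxidant and hydroxyl-radical-
    inactivating-ligand (OIL) classification, and repair and regeneration
    feasibility for oxidatively damaged biomolecules. Ships a curated
    galangin benchmark dataset and a synthetic pathway-ensemble generator
    for property testing.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
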