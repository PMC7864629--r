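Package: neurophys
Title: Electrophysiological and Molecular Phenotyping of iPSC-Derived Neuron Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and statistics for cellular-electrophysiology
    studies of induced pluripotent stem cell (iPSC)-derived neurons. Implements
    current-clamp action-potential and afterhyperpolarization measurements
    (dV/dt threshold, half-width, fast/medium/slow AHP), input resistance and
    quality-control gating, Henderson-equation liquid junction potentials,
    multi-electrode array well metrics with Poisson-surprise burst detection,
    drug-subtraction voltage-clamp analysis with activation time-constant fits,
    relative gene expression by the two-housekeeping-gene 2^(-dCt) scheme, and
    the associated ANOVA / Fisher protected-LSD statistics. Seeded synthetic
    generators (conductance-based neuron, spike rasters with planted bursts,
    Boltzmann-gated currents, Ct tables) allow every stage to be exercised and
    validated without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
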