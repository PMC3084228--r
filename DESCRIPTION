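Package: offtargetr
Title: Structural Proteome-Wide Off-Target Screening with Ensemble MM/GBSA
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for structure-based off-target prediction.
    Compares ligand binding sites on C-alpha traces with a geometric potential
    and sequence-order-independent alignment scored against an extreme-value
    (Gumbel) background; transfers ligand poses through site superpositions and
    filters them by steric clashes and a normalized docking score; estimates
    ensemble binding free energies with MM/GBSA (OBC generalized-Born polar
    solvation, LCPO solvent-accessible surface area, normal-mode vibrational
    entropy) over trajectory snapshot ensembles; runs trajectory stability
    diagnostics; and propagates the qualitative effect of off-target inhibition
    through a signed biological network. Includes deterministic synthetic
    complex and trajectory generators so that every stage can be exercised and
    tested without external docking or molecular-dynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
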