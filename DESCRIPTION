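Package: idpdesign
Title: De Novo Design of Intrinsically Disordered Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs artificial intrinsically disordered protein (IDP)
    sequences of a requested length (50-200 residues) and target per-residue
    disorder probability (0.55-0.95 in 0.05 steps). A library of 10-residue
    building blocks is generated by rejection sampling against a pluggable
    per-residue disorder scorer and filed into nine target-score families;
    sequences are assembled by tandem-repeat initialization followed by
    iterated central insertion under a dual smoothness/accuracy acceptance
    criterion, then trimmed to length. Also provides closed-form
    hydrodynamic (Stokes radius power laws) and circular-dichroism
    (mean residue ellipticity) utilities for characterizing designed
    sequences, a FASTA command-line interface, and a benchmark harness for
    the designer's calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
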