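Package: flexcdr
Title: Antibody CDR Sequence-Structure Co-Design with Flexible Anchor Augmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-level (C-alpha) co-design of antibody complementarity
    determining regions (CDRs) against an antigen context. Implements
    flexible-CDR data augmentation by anchor shifting, masked-loop graph
    encoding of antibody-antigen complexes, an E(3)-equivariant graph
    neural network with per-layer coordinate masking and an amino-acid
    prediction head, the full structure/sequence training loss suite with
    layer-wise local losses, a seeded training loop with validation
    checkpointing, CDR design by probability sampling, and a generator of
    synthetic antibody-like complexes for desk-scale experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
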