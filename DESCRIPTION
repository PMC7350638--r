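Package: oriScan
Title: Replication-Origin Inference on Circular DNA Replicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-based prediction of replication origins on circular
    (and linear) DNA, motivated by autonomously replicating sequences of
    large extrachromosomal circular DNA (eccDNA) replicons. Provides
    windowed A+T / G+C composition tracks on circular sequences, exact and
    IUPAC-degenerate consensus scanning (including a bundled registry with
    the 17 bp extended ARS consensus), DNA-unwinding-element (DUE)
    detection with nearest-neighbor helical-instability scoring, a
    from-scratch wedge-model DNA curvature engine (helical axis path,
    circumradius curvature profile, bend calling, PDB export), an
    integrative origin caller, and a synthetic circular-replicon generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
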