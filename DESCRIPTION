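Package: evodesign
Title: Evolutionary Multiobjective Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An NSGA-II engine for multistate protein sequence design with
    biophysically informed composite mutation operators, pluggable objective
    functions, combined-structure construction for tied multistate sequence
    decoding, and a suite of analysis metrics (native sequence recovery,
    positional entropy, hypervolume, normalized BLOSUM62 similarity, spectral
    embedding, alignment trimming and percentile similarity to annotated
    sequence sets). Ships surrogate position-specific scoring matrix
    objectives and procedural toy backbone generators so that every pipeline
    stage runs and is testable at desk scale, while neural scorers
    (inverse-folding, protein language models, structure-prediction
    composites) attach through documented plugin contracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
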