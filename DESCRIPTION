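Package: deNovoMol
Title: Multiobjective De Novo Molecular Design with Fragment-Based
    Generative Models and Reinforcement Learning
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale framework for de novo design of drug-like small
    molecules. Provides molecule standardization and drug-likeness
    filtering, BRICS/RECAP retrosynthetic fragmentation with
    fragment-combination enumeration, invertible SMILES and five-row
    graph-matrix encodings, three generative architectures (an LSTM/GRU
    recurrent SMILES model, a decoder-only sequence transformer, and a
    graph transformer with valence-masked decoding that emits only valid
    molecules), and a multiobjective reinforcement-learning explorer in
    which generated molecules are scored by a configurable environment of
    objectives, desirability modifiers and thresholds, and rewarded by a
    dynamic weighted sum or by Pareto ranking with crowding-distance or
    Tanimoto-distance tie-breaking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineOB,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'deNovoMol-package.R'
    'openbabel.R'
    'molgraph.R'
    'fragmentation.R'
    'AllClasses.R'
    'molprep.R'
    'corpus-smiles.R'
    'corpus-graph.R'
    'autodiff.R'
    'nn-backend.R'
    'generators.R'
    'gen-rnn.R'
    'gen-seqtrans.R'
    'gen-graphtrans.R'
    'environment.R'
    'moo.R'
    'explorer.R'
    'fixtures.R'
    'cli.R'
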