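Package: ecgredund
Title: Informational Redundancy Quantification and Reduction for Multichannel ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the informational redundancy of multichannel
    electrocardiogram (ECG) recordings using binned entropy, mutual
    information, normalized mutual information (NMI), and per-channel and
    set-level redundancy fractions. Provides redundancy reduction and
    augmentation strategies for the standard 12-lead system: fixed and
    searched lead subsets, the inverse Dower transform to a 3-channel
    vectorcardiogram, corpus-level principal component truncation, and a
    15-channel augmented input. Includes a controllable synthetic
    dipole-based 12-lead generator for ground-truth experiments, readers
    for WFDB and delimited multichannel records, class-imbalance loss
    weights, and standard classifier performance metrics with macro
    averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'evaluation.R'
    'records-io.R'
    'transforms.R'
    'infotheory.R'
    'selection.R'
    'synthgen.R'
    'cli.R'
    'wfdb.R'
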