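Package: coconet
Title: RNA Contact Prediction by Convolution on Coevolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts nucleotide-nucleotide contacts in structured RNAs from
    multiple sequence alignments. A mean-field direct coupling analysis (DCA)
    layer infers a Potts model from the alignment and scores site pairs by
    direct information; a shallow convolutional layer then re-weights the
    resulting score map with one or two small learned filters (optionally
    routed by Watson-Crick pair identity) before a top-n output layer ranks
    candidate contacts. Includes convex least-squares filter training with
    repeated k-fold cross-validation, contact-map ground truth extraction
    from PDB/mmCIF structures, secondary/tertiary contact stratification,
    PPV and MCC evaluation, coevolutionary window-pattern analysis, and a
    seeded synthetic-alignment generator (Gibbs sampling from planted Potts
    models) so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'alignment-io.R'
    'coconet-package.R'
    'config.R'
    'convolution.R'
    'evaluation.R'
    'mfdca.R'
    'structure.R'
    'synthetic.R'
    'training.R'
    'utils.R'
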