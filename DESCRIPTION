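Package: mirTarNet
Title: miRNA Microarray, qRT-PCR and miRNA-Target Hub Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workflow for small two-color miRNA microarray
    studies with qRT-PCR validation and in silico target-network analysis.
    Implements normexp background correction (normal background plus
    exponential signal, posterior-mean correction with offset), global
    lowess MA normalization, Welch unequal-variance differential-expression
    calling with joint p-value and log2-ratio selection thresholds,
    delta-delta-Cp relative quantification with optional primer-efficiency
    correction, reconciliation of array and qRT-PCR calls, integration of
    predicted and validated miRNA-target interaction sources with score
    filters, bipartite miRNA-target network construction, degree-based hub
    target selection with predicted direction of target mRNA change, and
    synthetic-data generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'stats.R'
    'normexp.R'
    'array-io.R'
    'array-de.R'
    'qpcr.R'
    'mti.R'
    'synthetic.R'
    'example-data.R'
    'pipeline.R'
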