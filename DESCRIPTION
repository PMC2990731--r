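Package: mhcqsar
Title: QSAR Prediction of MHC Peptide Binding with Amino-Acid Principal
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative structure-activity (QSAR) modelling of peptide
    binding to MHC class I and class II molecules. Peptides are encoded as
    z-scale descriptors (amino-acid scores on the first principal components
    of physicochemical property scales) and binding affinity ln(ic50) is
    modelled per allele by partial least squares regression (NIPALS) with
    variable importance in projection (VIP), or by ensembles of single
    hidden-layer perceptrons trained under two cross-validation schemes
    (multi-tour random holdback, and averaging over random subsets with
    mean/SEM/CV% reporting). Includes strong/weak-binder categorical
    evaluation (AROC), a synthetic binding-data generator emulating the
    subset structure and assay-limit censoring of public IEDB-style
    datasets, proteome k-mer test-set sampling, and VIP heat-map
    visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    nnet,
    jsonlite,
    ggplot2,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
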