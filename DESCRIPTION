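Package: biovep
Title: Biophysics-Informed Variant Effect Prediction from Deep Mutational Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains supervised variant effect predictors on deep mutational
    scanning (DMS) data using per-residue feature matrices that combine one-hot
    sequence encodings, principal components of amino-acid physicochemical
    properties, per-site mutational energy terms (Rosetta-style ddG components),
    and residue flexibility (RMSF). Provides linear, dense, sequence-convolution
    and graph-convolution regressors over residue contact graphs, reproducible
    random / mutational-extrapolation / positional-extrapolation data splits,
    enrichment scoring from sequencing read counts, a library-size by read-depth
    resampling benchmark, and a fully synthetic fitness-landscape generator whose
    ground truth is an explicit function of the energy table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
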