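Package: fedglio
Title: Federated Deep Learning for Glioma Subtype Classification from Multi-Site MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale implementation of a federated learning scheme for
    glioma and glioma-subtype (IDH genotype, LGG/HGG grade) classification
    from two-modality MRI. Provides a dynamically regularized federated
    optimizer (FedDyn-style with a focal-loss objective), a two-stream
    convolutional classifier with attention-weighted feature fusion, toy
    unpaired image-domain mapping with a cycle-consistency objective,
    slice-to-patient majority-vote aggregation, and a deterministic synthetic
    multi-site scan generator with class imbalance and scanner-style domain
    shift for fully reproducible experiments on one CPU.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
NeedsCompilation: yes
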