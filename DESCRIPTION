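Package: fibercluster
Title: Self-Supervised Deep Embedding and Anatomically Informed Clustering
    of Tractography Streamlines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parcellates diffusion MRI tractography into fiber clusters with a
    self-supervised pipeline: streamlines are embedded by a Siamese
    edge-convolution network trained to regress pairwise minimum average
    direct-flip (MDF) distances, clustered in embedding space with a
    Student's-t soft assignment that can be modulated by gray-matter
    anatomical agreement, and cleaned by cluster-adaptive outlier removal.
    Includes TRK/TCK/VTK tractogram I/O, NIfTI label-volume support,
    parcellation quality metrics (Davies-Bouldin index, white matter
    parcellation generalization, tract anatomical and surface profile
    coherence), and a ground-truthed synthetic tractography generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
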