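Package: fcmparc
Title: Fuzzy C-Means Parcellation of Resting-State Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Soft parcellation of resting-state BOLD fMRI into functional
    networks by fuzzy-c-means clustering of voxelwise correlation maps.
    Provides temporal preprocessing (linear detrending, zero-phase low-pass
    filtering, nuisance and global-signal regression, DVARS frame
    censoring), construction of voxel-by-voxel Pearson correlation
    features, fuzzy-c-means with a Xie-Beni convergence monitor and both
    random-cube and seeded-sphere initialization, multi-run consensus
    averaging, a cluster-dispersion validity measure with local-minimum
    selection of the number of clusters, spatial and temporal similarity
    matching of clusters within and across solutions, voxelwise
    classification-uncertainty maps, and a synthetic BOLD generator with
    planted hierarchical (system/network) covariance structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    igraph,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
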