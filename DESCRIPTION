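Package: fmridict
Title: Sparse Dictionary Decomposition of Whole-Brain fMRI into Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes whole-brain 4D fMRI recordings into concurrent
    functional networks by sparse representation. The voxel time series of one
    subject are aggregated into an m x n signal matrix which is factorized,
    via online (mini-batch) dictionary learning with an l1 sparsity penalty
    and unit-ball atom constraints, into a temporal basis (one atom per
    network) and a sparse spatial coefficient matrix. Coefficient rows are
    mapped back to the brain grid, z-scored and thresholded into candidate
    network maps, and identified against labeled resting-state network
    templates by spatial overlap, with group-wise consensus across subjects.
    Includes a voxel-sampling module that trains the dictionary on a subset
    of voxels for speed, a synthetic-fMRI generator with planted networks for
    validation, and a command-line pipeline producing NIfTI maps, CSV tables
    and PNG reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse
Config/testthat/edition: 3
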