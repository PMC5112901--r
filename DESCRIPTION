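Package: lcfp
Title: Local Connectome Fingerprinting for Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs spin distribution functions (SDFs) from
    diffusion-weighted MRI in a common stereotaxic space by q-space
    diffeomorphic reconstruction, samples their magnitudes along a
    per-voxel fiber-direction atlas into high-dimensional local
    connectome fingerprints, and provides the statistical layer for
    subject identification (root-mean-squared-error distances, d-prime,
    leave-one-out linear discriminant classification, generalized
    extreme value error modeling) and for similarity quantification
    (similarity index, longitudinal trend tests, kinship group
    comparisons with permutation inference). A synthetic multi-subject
    diffusion phantom generator with controllable between-subject
    variability, temporal drift, kinship sharing and Rician noise makes
    the whole pipeline runnable without any external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
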