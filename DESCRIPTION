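Package: tractoprof
Title: Tractometry of Streamline Bundles with Along-Tract Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for region-of-interest based tract selection from
    whole-brain tractograms, standard-deviation based bundle cleaning,
    super-fiber (core fiber) estimation, Gaussian-weighted 100-node tract
    profiles of voxelwise diffusion metrics, export of tract masks and
    profile tables, and tract-to-tract agreement metrics (Dice overlap,
    streamline density correlation, bundle adjacency). Includes voxelwise
    diffusion tensor fitting (weighted least squares) with FA, MD, RD and AD
    map creation, readers and writers for MRtrix track files (.tck) and
    NIfTI-1 volumes, and a seeded synthetic phantom generator so every stage
    is testable without acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    oro.nifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'agreement.R'
    'bundle.R'
    'coords.R'
    'dti.R'
    'io-nifti.R'
    'io-tck.R'
    'phantom.R'
    'pipeline.R'
    'profiling.R'
    'roi.R'
    'tractparams.R'
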