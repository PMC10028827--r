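Package: MetadKinetics
Title: Residence Times, Binding Modes and Structure-Kinetics Relationships
    from Infrequent Metadynamics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts infrequent well-tempered metadynamics unbinding
    trajectories into residence-time estimates and machine-learned
    structure-kinetics relationships. Rescales biased first-passage times by
    the accumulated acceleration factor, fits the empirical CDF of the
    rescaled dissociation times to a homogeneous Poisson process, checks
    reliability with a two-sample Kolmogorov-Smirnov test against the fitted
    exponential, and bootstraps the residence time. Recovers unbiased
    free-energy surfaces and interaction-energy distributions by exponential
    reweighting of the deposited bias, detects free-energy basins and
    classifies ligand binding modes. Builds residue-substituent
    interaction-energy feature tables, trains tree-ensemble regressors on
    log10 residence times, and ranks kinetic modulators by permutation
    importance and additive per-sample attributions. Includes a seeded
    synthetic-data generator that emulates biased unbinding time series and
    feature datasets with planted kinetic modulators, ligand Tanimoto
    similarity utilities, and PLUMED COLVAR-dialect readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    ranger,
    xgboost,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
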