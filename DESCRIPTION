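Package: bholdcvr
Title: Cerebrovascular Reactivity Mapping from Breath-Hold BOLD-fMRI with
    Lagged General Linear Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of breath-hold BOLD-fMRI cerebrovascular
    reactivity (CVR): processing of capnograph recordings into end-tidal CO2
    (PetCO2) traces and breath-hold-induced PetCO2 changes, construction of
    PetCO2- and block-based BOLD signal models with single- and double-gamma
    hemodynamic response functions over a delay/dispersion grid, voxelwise
    lagged general linear model fitting with per-voxel lag selection by
    partial F-statistic, derivation of CVR (percent per mmHg) and relative
    hemodynamic lag maps with percentile thresholding and region-of-interest
    summaries, and rank-based model comparison statistics (Friedman, Conover
    post-hoc, sign-flip permutation). Includes a synthetic-data module that
    simulates breath-hold paradigms, capnograph traces, motion parameters and
    4D BOLD volumes with known per-voxel ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
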