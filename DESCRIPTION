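Package: strokefc
Title: Lesion-Aware Denoising and Connectivity Evaluation for Stroke rs-fMRI
Version: 0.1.0
Authors@R: person("fMRI", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Confound modelling, denoising and functional-connectivity
    evaluation for resting-state fMRI of stroke patients. Implements
    lesion-adjusted tissue noise masks, anatomical CompCor, lesion-overlap
    ICA noise regressors, hemodynamic lag mapping with a hemispheric QC
    gate, three denoising pipeline presets (CompCorGS, CompCorLesionGS,
    ICLesionCompCorGS), Ledoit-Wolf shrinkage correlation connectomes, and
    pipeline-evaluation statistics (positive/negative lesion mean strength,
    functional connectivity contrast, modularity Q). Includes a synthetic
    stroke-subject generator with known ground truth for end-to-end
    validation, plus minimal NIfTI-1 and BIDS-style TSV input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
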