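Package: cardiodti
Title: Multi-Phase Cardiac Diffusion Tensor MRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for multi-phase in vivo cardiac diffusion tensor
    imaging of the left ventricle. Builds and audits second-order
    motion-compensated diffusion encoding waveforms (gradient moments and
    b-value), simulates annular left-ventricle phantoms with prescribed
    transmural helix-angle profiles and Rician noise, preprocesses
    diffusion-weighted image stacks (phase-correlation rigid registration,
    repetition averaging, k-space zero-fill interpolation), fits the diffusion
    tensor by nonlinear least squares, derives helix, transverse and sheetlet
    (E2A) angle maps in local cardiac coordinates with AHA segmentation,
    summarises transmural helix-angle profiles, helix angle range (HAR) and
    its change across cardiac phases, analyses trigger-delay scout series,
    and reports non-parametric group statistics with intraclass correlation
    reproducibility measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
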