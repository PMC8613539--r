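Package: radcine
Title: Deep Artifact Suppression for Radial Real-Time Cardiac MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for highly undersampled
    tiny golden-angle radial real-time cardiac cine MRI. Provides radial
    trajectory generation with analytic density compensation, exact
    non-uniform discrete Fourier forward/adjoint operators for retrospective
    undersampling of magnitude cines, a synthetic beating-heart phantom
    corpus with interventional-device (balloon catheter and guidewire)
    simulation, a residual U-Net with convolutional LSTM blocks at every
    scale for stateful frame-by-frame de-aliasing, a truncated
    backpropagation-through-time training engine, image-quality metrics
    (MAE, MSE, PSNR, SSIM) with paired nonparametric statistics, a
    sliding-window reconstruction baseline, and a streaming reconstructor
    emulating low-latency frame-by-frame inference with recurrent-state
    warm-up.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
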