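Package: qmriseq
Title: Open-Source Pulse Sequences, Bloch Simulation, and T1/T2 Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and validating open-source quantitative MRI
    acquisitions without a scanner. Constructs inversion-recovery spin-echo
    (IRSE), turbo spin-echo (TSE), and multi-echo TSE pulse sequences in a
    Pulseq-dialect text format, executes them on numerical phantoms with an
    isochromat Bloch-equation simulator, reconstructs Cartesian k-space with
    optional Hamming apodization and sum-of-squares channel combination, fits
    voxel-wise T1 and T2 parameter maps from the inversion-recovery and
    exponential-decay signal models, and reports image-quality (PSNR, SSIM)
    and relative RF-power metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    signal,
    jsonlite,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    png
Config/testthat/edition: 3
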