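Package: pastsvd
Title: Spatiotemporal SVD Denoising for Low-Fluence Photoacoustic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoising of radiofrequency (RF) frame sequences from
    photoacoustic imaging systems with low-fluence excitation sources
    (LEDs, laser diodes). Frame stacks are rearranged into a Casorati
    matrix and the quasi-static tissue signal is extracted by a
    randomized truncated singular value decomposition; the tissue
    subspace rank is estimated automatically from the 99%-energy
    bandwidth of the temporal singular vectors and from the spatial
    similarity matrix of the spatial singular-vector magnitudes.
    Includes frame-averaging and wavelet (db4, universal soft
    threshold) baselines, delay-and-sum image reconstruction, image
    quality metrics (PSNR, SSIM, EPI, SNR, CNR, axial FWHM), and a
    synthetic vascular RF simulator with stepwise axial motion and
    calibrated Casorati-domain Gaussian noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
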