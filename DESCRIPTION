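Package: wavecal
Title: Learned Wavelet Cross-Attention Compression for Grayscale Medical-Style Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid learned codec for single-channel 8-bit grayscale images
    in the style of CT/MRI slices. The pipeline decomposes an image with a
    multi-level 2-D discrete wavelet transform, reweights the high-frequency
    subband features against low-frequency structural queries with multi-head
    cross-attention, encodes the combined features with a convolutional
    variational autoencoder under a Gaussian latent prior, and compresses the
    quantized latent code losslessly with an adaptive arithmetic (range)
    coder. Includes a seeded generator of anatomy-like phantom images, a
    neural pixel-context predictor, a trainable 3x3 post-reconstruction
    spatial filter, reference image-quality metrics (MSE, PSNR, SSIM, NCC,
    bits per pixel), a self-describing bitstream container, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
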