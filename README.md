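# wavecal

Learned compression for grayscale medical-style images in R: a hybrid codec
that combines a 2-D discrete wavelet transform, multi-head cross-attention
over the subbands, a convolutional variational autoencoder with a Gaussian
latent prior, uniform scalar quantization, and adaptive arithmetic coding.

Radiology archives store terabytes of CT/MRI slices; generic codecs spend
bits uniformly, while diagnostically critical structure (lesion rims, bone
boundaries) is spatially sparse. wavecal's pipeline separates structure from
detail and lets attention decide which high-frequency content matters:

```
I --DWT--> {LL, LH, HL, HH} --CAL--> features --VAE encoder--> (mu, sigma)
      --quantize(mu)--> symbols --adaptive arithmetic coder--> bitstream
bitstream --decode--> z_hat --VAE decoder--> features --iDWT--> I_hat --3x3 filter--> output
```

The attention block computes `softmax(Q K' / sqrt(d_k)) V` per head (8 heads,
embedding dimension 64), with queries projected from the low-frequency `LL`
features and keys/values from the detail channels; a residual connection
preserves the details at initialization. Training minimizes
`lambda1 * L_MSE + lambda2 * L_perceptual + lambda3 * KL` (a BCE+KL variant is
selectable), with Adam, Xavier-normal initialization, a 70/15/15 split, and
early stopping (patience 10). Reconstruction quality is reported as MSE,
PSNR (`20 log10(255 / sqrt(MSE))`), SSIM (Gaussian 11x11 window), the
uncentered correlation NCC, and rate as bits per pixel including the
container header.

The package also provides: a seeded generator of anatomy-like phantoms
(ellipse anatomy, bone-like rims, Gaussian lesions, additive noise), a neural
pixel-context predictor (3x3 and 1x8 windows, hidden layers 20-18-5), a
trainable 3x3 post-reconstruction filter, and a command-line interface. All
networks are implemented natively in R (vectorized im2col convolutions,
analytic backpropagation verified against finite differences, Adam).

## Worked example

Train a small codec on seeded phantoms and compress a held-out image:

```r
library(wavecal)

imgs  <- generate_phantom_set(200, 32L, 32L, seed = 101L)
fit   <- train_codec(imgs, demo_model(c(32L, 32L), seed = 7L),
                     demo_train_config(seed = 42L))
log   <- fit$log
log$val_recon_mse[log$epoch == 0] / log$val_recon_mse[nrow(log)]
#> [1] 10.18883

te  <- imgs[fit$split$test_ids]
bs  <- compress(te[[1]], fit$model, quantizer_config(step = 0.25, clip_range = 511L))
rec <- decompress(bs, fit$model)
evaluate_pair(te[[1]], rec, n_bits = bitstream_n_bits(bs))
#>   image_id      mse psnr_db        cc      ssim     bpp time_ms
#> 1      img 666.6693 19.8917 0.9404301 0.5105111 0.90625      NA
```

Thirty epochs on 200 tiny phantoms cut the validation reconstruction MSE by
~10x; the reconstruction at ~0.9 bits/pixel (a 9x size reduction versus
8-bit raw) is ~5.7 dB above the constant-mean baseline (14.23 dB) for this
image class. The quantizer step is matched to the latent scale (this model's
codes reach |mu| ~ 40, so the default step 0.05 with clip 127 would
saturate). These are desk-scale numbers meant to show the machinery
learning, not clinical performance.

The same operations are available from a shell:

```sh
Rscript inst/cli/wavecal.R simulate --n 20 --size 64 --seed 1 --out-dir phantoms
Rscript inst/cli/wavecal.R train --size 32 --n 200 --seed 1 --model model.rds
Rscript inst/cli/wavecal.R compress --model model.rds --input phantoms/phantom_0001.png --out x.wcal
Rscript inst/cli/wavecal.R decompress --model model.rds --input x.wcal --out rec.png
Rscript inst/cli/wavecal.R evaluate --original phantoms/phantom_0001.png --reconstructed rec.png --bitstream x.wcal
```

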