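# pastsvd

Spatiotemporal SVD denoising for photoacoustic (PA) imaging with
low-fluence excitation sources.

## The problem

PA systems built around LEDs or laser diodes deliver very little optical
energy per pulse, so the radiofrequency (RF) signals recorded by the
ultrasound array are buried in broadband noise (SNRs of −5 to −15 dB are
typical). These sources fire at kHz repetition rates, though, so many
nearly identical frames are available. The classical fix — averaging tens
to hundreds of frames — destroys temporal resolution and smears any
motion. `pastsvd` implements a denoiser that exploits the *joint*
spatial-temporal coherence of tissue signal instead.

## The method

A stack of RF frames `(n_x, n_z, n_t)` is reshaped into the Casorati
matrix `S` of size `(n_x·n_z) × n_t` (one flattened frame per column) and
decomposed as

```
S = U Δ V*
```

where `U` holds spatial singular vectors, `V` temporal ones, and `Δ` the
singular values in descending order. Quasi-static tissue signal is
spatiotemporally coherent and concentrates in the few leading singular
value components (SVCs); thermal noise is incoherent and spreads across
the rest. Denoising keeps the leading k components. For speed, the
subspace is found with a randomized sketch: `S′ = S R` with Gaussian `R`,
a pivoted QR gives the orthonormal basis `Q` (sharpened by power
iteration), and the denoised data are

```
P = Q Q* S .
```

The tissue-subspace rank k is estimated automatically from two
statistics, and the conservative minimum of the two is used by default:

* **temporal** — the 99%-energy bandwidth of each temporal singular
  vector; tissue vectors are narrowband, noise vectors span the whole
  band, and the rank is the last order before the bandwidth curve
  expands toward the full band;
* **spatial** — the similarity matrix `C(n,m)`, the Pearson correlation
  between the magnitude images `|u_n|` and `|u_m|`; the tissue subspace
  appears as a leading block of mutually correlated orders.

Baselines (trailing-window frame averaging; per-A-line db4 wavelet
denoising with universal soft thresholding), delay-and-sum image
reconstruction, the image-quality metrics (PSNR, global SSIM, edge
preservation index, ROI SNR/CNR, axial FWHM) and a synthetic vascular RF
simulator are included, so the whole evaluation loop runs from one
package.

## Worked example

Simulate the standard motion study — a 128-element, 7 MHz linear array
over 38.4 mm recording 100 frames of a vascular phantom whose vessel
band steps axially by 0, 1, 2 and −1 mm every 25 frames, with Gaussian
noise added in the Casorati domain at −10 dB — then estimate the rank and
denoise:

```r
library(pastsvd)

sim <- simulate_sequence("motion", snr_db = -10, seed = 1)
est <- estimate_rank(to_casorati(sim$noisy))
est
#> Tissue-subspace rank estimate: 4 (temporal 4, spatial 4; 75 orders analyzed)

den  <- stsvd_denoise(sim$noisy, denoise_config(rank = "auto-min",
                                                window_frames = 75, seed = 2))
grid <- image_grid(sim$noisy$geometry, z_range_mm = c(8, 23), dz_mm = 0.15)
m    <- evaluate_denoising(den$stack, sim$clean, grid = grid,
                           frames = seq(5, 100, by = 10))
mn   <- evaluate_denoising(sim$noisy, sim$clean, grid = grid,
                           frames = seq(5, 100, by = 10))
round(c(noisy = mean(mn$psnr), denoised = mean(m$psnr)), 1)
#>    noisy denoised
#>     12.7     23.2
```

Both rank estimators resolve the four motion states, and denoising
raises the image-domain PSNR against the noise-free reference by about
10 dB. Sweeping the retained-SVC count shows why rank selection matters
(`svc_sweep(sim$noisy, sim$clean, ks = 1:7)`): PSNR climbs to its
maximum at k = 4 — the number of motion states — and declines once noise
components are admitted.

A command-line front end wrapping the same functions lives at
`inst/cli/pastsvd.R` (subcommands `simulate`, `rank`, `denoise`,
`evaluate`; sequences travel as NIfTI volumes with JSON metadata
sidecars).

## Limitations

The simulator replaces Monte-Carlo photon transport and full-wave
acoustics with an exponential-fluence absorber map and an analytic
delay-and-attenuate point-source model; it reproduces the bandwidth,
time-of-flight geometry and low-rank temporal structure that the
denoiser senses, but not reverberation, acoustic attenuation or
out-of-plane effects. Reconstruction is delay-and-sum. See the methods
vignette (`vignettes/pastsvd-methods.Rmd`) for the model, parameter
choices and design decisions.
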