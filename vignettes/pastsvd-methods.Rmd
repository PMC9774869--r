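---
title: "Spatiotemporal SVD denoising for low-fluence photoacoustic imaging: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal SVD denoising: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pastsvd)
```

## The signal model

Low-fluence photoacoustic (PA) systems record RF frames at kHz rates.
Over a window of tens to hundreds of frames the tissue is quasi-static:
its contribution to the Casorati matrix `S` (size `(n_x·n_z) × n_t`, one
flattened frame per column) is a matrix of very low rank whose temporal
singular vectors vary slowly and whose spatial singular vectors share
the vascular geometry. Thermal noise is i.i.d. across space and time, so
its energy spreads thinly over all singular components. Truncating the
SVD

```
S = U Δ V*,   P = Σ_{k ≤ k̂} σ_k u_k v_k*
```

separates the two. The package computes the truncation either exactly
(through the `n_t × n_t` Gram matrix — cheap for the short windows used
here) or with a randomized sketch (`S R` with Gaussian `R`, pivoted QR,
power iteration), which is the method of choice when `n_x·n_z` and the
frame budget grow. Both backends are exposed and tested against each
other; the randomized path (`rsvd_denoise()`, `truncated_factors()`)
matches the exact rank-k truncation to better than 1e-3 relative
Frobenius error whenever the spectrum has a gap after the k-th value.

Two conventions worth stating once: RF data are real, so the conjugate
transpose is a transpose; and singular vectors carry a deterministic
sign (largest-magnitude entry of each spatial vector positive), so
repeated decompositions are bit-reproducible. Flattening is
element-major (`row = (x−1)·n_z + z`), fixed package-wide so that
reshaped `|u_k|` diagnostics and the filter always agree; singular
values are invariant to this choice.

## Rank selection

`estimate_rank()` implements two non-parametric estimators on the
leading `min(n_t, 75)` orders.

**Temporal (99% bandwidth).** For each temporal singular vector the
double-sided PSD is computed (DC-centered; each side takes half the DC
bin and, for even lengths, half the Nyquist bin) and the smallest
symmetric-from-DC band holding 99% of the side's energy is expressed as
a fraction of the side's band; the two sides are averaged (a `max`
reducer is available). The rank is the last order before this curve
expands toward the full band, detected as the first crossing of
`expansion_threshold`.

The threshold default is 0.8. Noise vectors are white and measure
≥ 0.95 of the band. Tissue vectors measure well under 0.7 — including
the hardest realistic case, piecewise-constant temporal courses produced
by stepwise motion, whose spectra have slowly decaying 1/f² tails and
therefore 99% bandwidths around 0.55–0.67 (measured across seeds at
−10 dB, 100 frames). A threshold at 0.5 would sit *below* the tissue
regime and collapse every stepwise-motion estimate to 1; 0.8 sits inside
the empty gap between the regimes, so the detector is insensitive to its
exact value. Very short windows (n_t ≲ 40) push boxcar tails above 0.8;
at such window lengths the estimator should be given smoother motion or
an explicit rank.

**Spatial (similarity matrix).** `C(n,m)` is the Pearson correlation
between the magnitude images `|u_n|` and `|u_m|` over all pixels.
Tissue orders form a leading block of mutually correlated columns; the
estimator grows k while every column of the leading block keeps a mean
off-diagonal correlation above a threshold.

The absolute height of the tissue block is not stable: at −10 dB roughly
40% of each spatial vector's energy is noise leakage (the leakage scales
as `m σ_w² / σ_signal²` with `m = n_x·n_z`), and the leading-block
correlations measured across phantom geometries range from ~0.02 to
~0.17, while noise-order correlations stay below ~0.01 (they scale like
`1/√m`). What *is* stable is the ratio between the two, about an order
of magnitude. The default threshold is therefore adaptive: 3× the
90th-percentile absolute off-diagonal correlation among the trailing
half of the analyzed orders (which are noise-dominated by
construction), floored at 0.005 and capped at 0.5. A fixed threshold
remains available via `threshold =`.

When the two estimators disagree, the pipeline's `"auto-min"` default
takes the conservative minimum (preferring noise rejection over signal
completeness); both values are always reported.

## The denoising pipeline

`stsvd_denoise()` slides a window (default 75 frames, stride 1) along
the sequence. Per window it forms the Casorati matrix, resolves the rank
(explicit or automatic), truncates to exactly the k leading SVCs, and
emits the window's newest frame — a causal choice compatible with
real-time display; frames before the first full window are taken from
the first window's truncation. Per-window seeds derive deterministically
from the master seed. Note the distinction between the filter
(exact rank-k truncation, so that retaining "k SVCs" means exactly k)
and `rsvd_denoise()`'s raw range projection `Q Q* S`, whose rank can
reach k + oversampling; the pipeline uses the former, since sweeping k
is only meaningful when k components are actually kept.

Baselines:

* `frame_average()` — trailing running mean, the standard
  high-repetition-rate baseline.
* `dwt_denoise()` — per-A-line multilevel db4 wavelet transform
  (periodized, implemented in the package and verified to be an
  orthonormal perfect-reconstruction transform), noise σ estimated from
  the finest detail coefficients by MAD/0.6745, soft thresholding at the
  universal level σ√(2 ln n_z). A separable 2-D mode is available;
  1-D along depth is the default because the noise model is per-sample
  white noise on RF traces.

## Synthetic data

The simulator generates the study conditions used throughout the tests:

* **Phantom** — procedurally generated meandering vessels (default 8,
  radii 0.15–0.4 mm) on a 40 × 40 mm grid at 0.1 mm spacing, confined to
  10–20 mm depth; amplitude decays exponentially with depth (0.15/mm) as
  a fluence surrogate, so deep vessels are weak.
* **Acquisition** — 128 elements at 0.3 mm pitch (38.4 mm aperture),
  7 MHz center frequency, 80.9% −6 dB fractional bandwidth. The
  sampling rate (40 MHz), sound speed (1500 m/s) and depth-sample count
  (640, i.e. 24 mm one-way — covering the vessel band, its +2 mm motion
  extreme and the pulse tails) are package defaults chosen as typical
  values for this array class; all are configurable.
* **Forward model** — each absorber pixel contributes a
  Gaussian-enveloped bipolar pulse at one-way time of flight with 1/r
  attenuation, superposed linearly. This preserves what the denoiser
  senses — bandwidth, geometry, and the low-rank temporal structure —
  and omits full-wave effects (reverberation, diffraction detail,
  attenuation dispersion).
* **Motion** — whole-pixel axial shifts of the vessel band; the default
  schedule is four 25-frame groups at 0, 1, 2, −1 mm. The clean Casorati
  rank then equals the number of distinct states exactly, which is what
  makes rank-recovery claims testable.
* **Noise** — i.i.d. Gaussian added over the whole Casorati matrix with
  variance `mean(S²)·10^(−SNR/10)`; realized SNR is within 0.1 dB of the
  request for ≥ 1e5 entries. Default levels −5/−10/−15 dB.

Passing tests on these data show that the estimators and the filter
behave correctly when their assumptions (low-rank coherent signal,
white noise) hold at realistic SNRs and geometry. They do not
demonstrate robustness to in vivo effects: probe-pressure deformation,
flow pulsatility, correlated (parasitic) noise, or fluence fluctuation.

## Metrics

PSNR follows the amplitude-peak convention used in this literature,
`10 log10(max(X)/MSE)`; the conventional squared-peak form is available
via `convention = "standard"`. SSIM is the global single-window form
with `C1 = (0.01·255)²`, `C2 = (0.03·255)²`, computed after jointly
rescaling both images to the 8-bit range (disable with
`rescale = FALSE`). EPI is the normalized correlation of mean-subtracted
3×3 Laplacian-filtered images (center −4, cross neighbors 1, reflective
borders) over the whole image. ROI SNR is `10 log10` of the
mean-signal-amplitude to mean-noise-σ ratio — note, a factor 10 on an
amplitude ratio, again following this literature's definition — and CNR
is `|μ_s − μ_n| / σ_n`. Axial FWHM interpolates the half-maximum
crossings on a ×10 linearly upsampled profile. Degenerate inputs (zero
noise σ, zero-variance Laplacian, boundary peaks, missing crossings) are
errors, not NaNs.

## Numerical choices

* All computation in double precision; the NIfTI container stores
  samples as float32 (one save/load cycle rounds once, after which round
  trips are bit-exact).
* Randomized sketch defaults: oversampling 8, two power iterations,
  re-orthonormalization (QR) after every half-step to prevent the basis
  collapsing onto the dominant direction in floating point.
* `svd_filter()` with an all-false mask returns the zero matrix;
  rank-0 is never chosen automatically (estimates are clamped to ≥ 1).
* Delay-and-sum uses one-way delays (PA convention), linear
  interpolation between samples, no apodization, and precomputed
  gather tables so that evaluating many frames is cheap.
* Problem sizes used by the test-suite and the acceptance script —
  100-frame sequences, 640 depth samples, metric averages over evenly
  spaced frame subsets where full sweeps are not the point — were chosen
  to keep a complete run in minutes on a single core while preserving
  the spatial-to-temporal dimension ratio (`n_x·n_z ≫ n_t`) that the
  estimators' statistics rely on.

## Known limitations

* Rank selection assumes `n_x·n_z ≫ n_t`; for small arrays or very long
  windows the noise bulk narrows and both estimators lose their margin.
* The temporal estimator's bandwidth gap shrinks for very short windows
  (boxcar tails) and for tissue that moves continuously rather than in
  steps; the spatial estimator's block contrast shrinks when vessels
  decorrelate strongly between motion states.
* The wavelet baseline operates per frame and cannot exploit
  inter-frame coherence; it is included as the single-frame reference
  point, not as a competitive denoiser.
* No GPU path; the randomized backend is the intended route to larger
  problems.
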