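---
title: "Models and methods behind ncamsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ncamsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncamsim)
```

`ncamsim` simulates and analyses a low-cost NDVI measurement system: a
NIR-sensitive RGB camera behind either a long-pass (580 nm cut-on) or a
two-band-pass (650/850 nm) filter, calibrated against a hyperspectral
reference on a cohort of greenhouse corn plants. This vignette is the
package's own account of the models inside it: what is assumed, what is
parameterized, which choices were genuinely open, and what the synthetic
experiments can and cannot show.

## 1. The sensor forward model

A channel value is modelled as the wavelength integral of plant reflectance
times illumination times the channel's spectral sensitivity
(`simulate_channels()`, trapezoidal rule on the shared grid). Writing band
means instead of integrals, the long-pass system obeys

$$ \begin{pmatrix} R_C \\ G_C \\ B_C \end{pmatrix} =
   \begin{pmatrix} j_1 & k_1 \\ j_2 & k_2 \\ j_3 & k_3 \end{pmatrix}
   \begin{pmatrix} R_{lp} \\ N_{lp} \end{pmatrix}, $$

with red band 580–700 nm and NIR band 700–1100 nm (truncated at the 1000 nm
grid maximum, since the hyperspectral reference stops there), and the
two-band-pass system the analogous 3×2 relation on 620–690 nm and
810–890 nm. `band_sensitivity_matrix()` computes these coefficients as
window means of the effective (filtered) sensitivities, so a flat unit
sensitivity maps to exactly 1.

**Sensitivity curves.** Measured curves for the de-filtered sensor are not
shipped; `rgbn_sensitivities()` is a synthetic Gaussian-mixture stand-in
with visible peaks at 600/540/460 nm (R/G/B), a 1% visible cross-talk
floor, and a common NIR shoulder rising past 700 nm so the three channels
respond equally beyond ~800 nm. Construction of an `ncam_camera()` enforces
the qualitative structure this geometry must deliver: `j1 >> j2 > j3` for
the long-pass red band, `l1 >> l2 ≈ l3` and `m1 ≈ m2 ≈ m3` for the
two-band-pass bands. The filter of the two-band-pass system is modelled as
Gaussian passbands (exactly half-peak at ±FWHM/2); its red centre is taken
as 650 nm — product designations and the 620–690 nm window point to 650
rather than 640, and the choice is configurable. The long-pass edge is a
logistic with a 10 nm transition width.

**Channel purity.** For a whiteboard-calibrated channel that senses only
red and NIR light, `channel_value_model()` implements
$C_c = (\alpha\lambda N_w + \beta\theta R_w)/(\alpha N_w + \beta R_w)$:
monotone in the NIR-red sensitivity ratio $\alpha/\beta$, with limits
$\theta$ (pure red) and $\lambda$ (pure NIR). Because vegetation has
$\lambda \gg \theta$, the channel with the largest $\alpha/\beta$ — always
blue here — is brightest, which is why these cameras render plants blue and
why the blue channel plays the NIR role in the formula baseline.

## 2. The synthetic cohort

The generator's defaults *are* the study conditions: 14 replicates of a
2×2 water-by-nitrogen factorial (56 plants), one scene per plant plus three
whiteboard references (171 images).

**Ground-truth NDVI.** Per-plant NDVI is drawn from a Beta distribution on
[0.587, 0.749] moment-matched to mean 0.686 and CV 0.058 (shape parameters
≈ 1.79 and 1.14). The implied skewness is ≈ −0.37 — slightly stronger than
the −0.334 the matched cohort reports, a consequence of fitting two moments
on a fixed support; we accept it rather than add a third shape parameter.
Draws use stratified inversion (one draw per probability stratum of the
Beta, randomly permuted over plants): the marginal distribution is
unchanged, but a 56-plant cohort reproduces the target mean and CV reliably
instead of only on average. This is a deliberate generator-design choice —
the cohort is meant to *be* the documented population, not a loose sample
from it.

**Plant spectra.** `generate_plant_spectrum()` uses a vegetation template:
trough level `r` in the red, a green bump (amplitude 0.09, 550 nm), and a
logistic red edge to an NIR plateau (0.45, scaled ×0.94 under drought).
Both NDVI band means are linear in `r`, so the trough is solved in closed
form and the spectrum's NDVI equals its target to machine precision.
Nitrogen shifts the red-edge inflection, 715 + 5·(N − 2.4) nm with 5 nm
logistic width. The steep, late edge matters: it keeps the nitrogen signal
inside 700–800 nm — visible to the long-pass camera, invisible both to the
two-band-pass windows and to the 680 nm ground-truth band. A shallower or
earlier edge would leak nitrogen variation into $b_{680}$ itself, distorting
the ground truth and the camera comparison.

**Nitrogen ground truth.** No distribution is documented for the matched
study; the synthetic defaults are declared, not inferred: high ≈ 3.0, low
≈ 1.8 % dry mass, SD 0.3, clipped above 0.5. Nitrogen is drawn
independently of NDVI. Consequence: the two-band-pass camera, which cannot
see the red edge, has essentially zero nitrogen skill here (LOOCV R² ≈ 0),
whereas a real cohort's nitrogen–chlorophyll correlation would lend it
indirect skill. The lp > tp ordering is the mechanism under test and is
unaffected; the tp magnitude is not comparable to field values.

**Scenes and noise.** Each scene is an elliptical wobbled canopy mask
(cover fraction U(0.20, 0.40)) over a soil background (0.20–0.24, weak red
edge). Plant pixels get multiplicative amplitude jitter (2%) and an NIR
tilt (3%) that spreads per-pixel NDVI; a common red-trough rescale (root
solved) then restores the plant-mean NDVI to the target within 1e-6, so the
truth table stays exact. The whole cube is multiplied by a per-plant
lognormal brightness factor (sdlog 0.25) modelling the taller-plants-are-
brighter illumination effect; because flat-whiteboard calibration cannot
remove it, raw channel means are right-skewed across the cohort, and
channel-sum normalization is what removes it — the same argument the
measurement chain makes. Camera rendering adds per-pixel lognormal
illumination noise (2%) and additive Gaussian noise (0.002), with optional
16-bit quantization against a whiteboard-referenced gain.

**Scale.** Scenes default to 48 × 64 pixels with the full 513-band grid —
about 1/50 of the real sensor. A full-resolution cube would occupy ~330 MB
in double precision (18 GB per cohort), which serves no statistical purpose
here: every downstream quantity is a foreground mean over hundreds of
pixels. The size is configurable for users who want larger scenes.

## 3. Image processing

Calibration divides each image by its whiteboard image (zero whiteboard
pixels are masked and counted, not silently propagated). Camera images are
segmented by the blue-red index `(Bc − Rc)/(Bc + Rc) ≥ t`; pixels with zero
denominator read as background for any positive threshold. The threshold
`t` is not documented anywhere authoritative; the default 0.1 sits roughly
midway between the background index (~0.02 on the synthetic scenes) and the
plant index (≥ 0.2), and is exposed as a parameter. Hyperspectral cubes are
segmented by a red-edge box difference — mean(750–800 nm) −
mean(660–690 nm) ≥ 0.05 — our reconstruction of a red-edge "convolution"
method whose exact kernel is not published; both routes agree with the
synthetic truth masks to better than 99%. Foreground averaging yields one
channel triplet per camera and one mean spectrum per cube per plant;
`true_color()` renders cubes through NIR-rejected visible sensitivities,
white-balanced so the whiteboard is neutral.

## 4. Preprocessing and estimators

Camera features are channel-sum ratios `r = Rc/(Rc+Gc+Bc)`,
`b = Bc/(Rc+Gc+Bc)`; green is omitted as redundant (the three ratios sum
to 1). Spectra go through log10(1/R) (the chemometrics absorbance
convention — the natural-log variant is available), multiplicative scatter
correction against the training-mean reference, and mean centering.
Whether the matched analysis refit preprocessing inside each
cross-validation fold is unknown; `ncamsim` always refits on training rows
only (`fit_spectra_preprocessor()` bound into `loocv()`), the stricter,
leakage-free reading.

Estimators (`ncam_fit()` families):

* **mlr** — OLS with intercept; the nitrogen variant adds the `r·b`
  interaction.
* **gp_matern** — zero-mean GP, Matérn-5/2 kernel; length-scale, signal and
  noise variances maximize the marginal likelihood, seeded from a fixed
  3×3×2 multi-start grid (length-scales 0.3/1/3 × the median pairwise
  distance of standardized inputs, signal 0.5/1/2 × SD(y), noise 0.05/0.2 ×
  SD(y)) and polished by Nelder-Mead. Inputs and response are standardized
  internally; a jitter of 1e-10 stabilizes the Cholesky.
* **svr_quadratic** — ε-insensitive SVR, degree-2 polynomial kernel
  (γ = 1/p, coef0 = 1), defaults C = 1, ε = 0.001, via `e1071::svm`.
  Kernel families are fixed (Matérn, quadratic) rather than re-selected by
  accuracy; alternatives are a configuration away.
* **plsr** — NIPALS with 3 latent variables by default; successive scores
  are orthogonal by construction, and at full rank the predictions coincide
  with least squares (both properties are tested, plus a cross-check
  against an independent PLS implementation).

`loocv()` is an explicit n-fold refit loop — for OLS it equals the
hat-matrix closed form to 1e-10, which the tests use as the independent
oracle.

## 5. Evaluation conventions

`regression_metrics()` reports R² = 1 − SSres/SStot, RMSE, MAE, and
MPE = 100·MAE/mean(truth). The aggregate MPE convention is chosen because
it reproduces the worked reference value (MAE 0.0064 at cohort mean 0.686 →
0.93%); a per-sample variant is available. Note the formula baseline is
scored with its raw values as predictions under this R² — its calibration
bias then yields large negative R², whereas published comparisons that
regress formula values on truth report the correlation-based R² of that
regression; the two are not comparable. Bland–Altman limits use the
standard 1.96 × sample-SD convention, without confidence intervals on the
limits.

## 6. What the synthetic experiments show — and what they don't

On the default cohort (seed 20200605) the package reproduces the
qualitative findings end to end: the two-band-pass camera beats the
long-pass camera at NDVI (cleaner red/NIR separation), learned models beat
the channel formula on both cameras, the ordering reverses for nitrogen
(red-edge access), raw channel brightness is right-skewed until
normalization, blue > green > red channel means with tp-blue > lp-blue, and
Bland–Altman agreement of the best model is tight and unbiased. Absolute
accuracies are higher than a real greenhouse delivers (tp-MLR R² ≈ 0.999
here): the generator omits specular reflections, canopy geometry and
shadows, sensor nonlinearity, demosaicing artefacts, and biological
deviations from a two-parameter spectral template. Passing these tests
therefore validates the algebra, the processing chain and the direction of
every effect — not field-level error magnitudes.

Problem sizes were chosen for a desk-scale run: the full default study
(56 plants, 48 × 64 × 513 cubes, four estimators × two cameras under LOOCV,
plus nitrogen models) completes in well under a minute, and the whole test
suite in about half a minute.

## 7. Degenerate inputs and numerical conventions

Zero-variance targets make R² (and skewness) undefined — both error out
rather than return NaN. Zero whiteboard pixels are masked and counted.
Zero-denominator index pixels are background by convention. MSC refuses
samples whose regression slope on the reference is ~0; PLSR stops on
degenerate deflation. The NDVI bands are closed 5 nm half-width windows
(≈9 grid points on the default grid), so band means are robust to grid
phase while constant spectra remain exact. All randomness flows from one
integer seed through deterministic per-plant, per-stage sub-seeds, so any
scene or image can be regenerated in isolation and full runs are
reproducible byte for byte.
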