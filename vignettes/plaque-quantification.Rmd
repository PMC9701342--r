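---
title: "Quantifying dental plaque from smile photographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dental plaque from smile photographs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfieplaque)
```

## The measurement model

Classical plaque indices are categorical: each tooth surface is scored
plaque present/absent and the subject's index is the percent of positive
surfaces. That definition measures where plaque is, not how much of the
tooth it covers. `selfieplaque` implements the complementary, quantitative
measurement: on a smartphone photograph of the smile, the area covered by
plaque on the six anterior teeth is measured in pixels and expressed as a
fraction of the total tooth area,

$$\text{fraction} = 100 \cdot \frac{PA}{TA} \quad (\%),$$

and a linear calibration maps that anterior fraction to an estimate of the
full-mouth index:

$$\mathrm{SVPI} = -7.5 + 1.14 \cdot \text{fraction}, \qquad
  \mathrm{SDPI} = 40.62 + 0.44 \cdot \text{fraction}.$$

SVPI estimates the Visible Plaque Index (no staining); SDPI estimates the
O'Leary disclosed index (after a disclosing dye). The coefficients above are
the shipped defaults (`default_calibration()`); `fit_calibration()` refits
them by ordinary least squares when a new cohort of paired (anterior
fraction, full-mouth clinical index) observations is available.

The pipeline assumes: (i) a 24-bit RGB photograph; (ii) a binary tooth mask
delimiting the anterior teeth — segmentation is deliberately *not*
automated, because in the source protocol it is a human cutting step, and
the mask-file contract keeps that step explicit and auditable; (iii) plaque
differs from clean enamel chiefly in colour **saturation** — disclosing dye
is strongly saturated, enamel is nearly achromatic. Hue and brightness are
never constrained.

## Colour representation and thresholding

`rgb_to_hsb()` performs the standard HSV decomposition and rescales every
channel to the byte range: hue as degrees × 255/360, saturation and
brightness as fraction × 255, each rounded. The 8-bit convention matches
the imaging tools the protocol standardises on and makes all three planes
directly histogrammable into 256 bins.

A consequence worth stating: byte-scaled hue quantises 360° into 255 levels.
Inverting the decomposition therefore does not reproduce the source pixel
exactly — the hue-driven middle RGB channel can shift by up to
chroma × 0.71°/60° ≈ 3 levels, while the brightness-driven maximum channel
returns within ±1. The test suite asserts exactly these derived bounds.
Saturation, the only channel the method thresholds, is unaffected by hue
quantisation.

`otsu_threshold()` implements Otsu's criterion on a 256-bin histogram:
choose the level $t$ maximising the between-class variance
$\omega_0\omega_1(\mu_0-\mu_1)^2$ of the split $\{\le t, > t\}$. Numerical
choices, all covered by tests against an exhaustive brute-force oracle:

* ties are broken by the smallest maximising level (deterministic);
* a single-occupied-level histogram is degenerate — the level itself is
  returned, so the strictly-greater "high" class is empty. This is what
  makes a noise-free, plaque-free tooth yield a plaque fraction of exactly
  zero rather than an arbitrary split;
* bands in `apply_band_threshold()` are closed at both ends, the threshold
  semantics of the standard imaging tools;
* histograms are always computed within the tooth mask, so the (0, 0, 0)
  sentinel that `crop_to_mask()` writes outside the teeth can never bias a
  threshold.

`detect_plaque()` exposes both readings of the original, human-in-the-loop
selection: `fixed_band` takes the operator's saturation window verbatim, and
`auto_otsu` is the automatic surrogate. Which Otsu class is plaque is a
genuine ambiguity (the protocol text does not say); the high-saturation
class is the default because dye and plaque are the saturated phase on
enamel, and `plaque_class = "low"` flips the rule for imaging setups where
the contrast is reversed. The mode, threshold or band, and class are echoed
into every measurement for provenance.

## Calibration: percent, not unit fraction

The calibration equations are applied to the *percent* fraction, not the
raw PA/TA ratio. With the ratio in [0, 1], the visible-mode line
$-7.5 + 1.14x$ would be negative over its whole domain and could never
produce a positive index — so percent is the only self-consistent reading.
Because this is an interpretation rather than a stated fact, the run
configuration retains a `fraction_scale = "unit"` switch that feeds the raw
ratio instead, making the alternative reading reproducible in one flag.

Calibration outputs are unclamped by default: the negative visible-mode
intercept legitimately maps small fractions below zero, and clamping is a
presentation concern (`clamp = TRUE`, and reports carry both values).

The refit is plain single-predictor OLS via `stats::lm()`. The source
analysis calls its fit "multiple linear regression" while printing
single-predictor equations; no second predictor is identifiable from the
printed models, so none is fitted.

## Clinical indices

`compute_index()` scores percent-positive surfaces from dichotomous
per-surface records, keyed by FDI tooth codes with third molars excluded.
Four surfaces per tooth (buccal, lingual, mesial, distal — the O'Leary
convention) are used for both the visible and disclosed indices so the two
are computed over the same denominator; the number of surfaces scored per
tooth for the visible index is not fixed by any published definition we
reproduce, so uniformity was chosen over guessing. Missing teeth simply
contribute no records: the denominator is the observed surface count.
The anterior partial indices (VPIant, DPIant) restrict to the twelve
incisors and canines, FDI 13–23 and 33–43.

## Rank correlation

Spearman's rho is computed as the Pearson correlation of average ranks
(mean rank for ties). The two-sided p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom; for
$n \le 8$ an exact permutation p over all $n!$ orderings is reported
alongside, since the t approximation is least trustworthy exactly where
enumeration is cheap. The suite checks (on generated data) that the two
agree in the accept/reject decision at α = 0.05 in at least 95 % of random
small-n instances, and that rho matches `stats::cor.test()` — which serves
as an independent cross-check, not as the implementation.

## What the synthetic data emulate — and what they do not

`generate_smile()` draws a row of elliptical teeth (default 6: four
incisors, two canines, mildly tapered toward the canines) on a dark oral
background and accretes plaque from the cervical margin downward with a
jittered front — the cervical margin because that is where plaque
accumulates clinically. Defaults, chosen once as the study conditions:
640 × 480 pixels (a desk-scale stand-in for 1600 × 1200 capture), enamel
colour (235, 228, 215) — saturation ≈ 22 of 255 — plaque colour
(186, 120, 36) — saturation ≈ 205 — and additive per-channel Gaussian noise
with sd 3 (clipped to the byte range), the simplest model consistent with
smartphone JPEG capture. The requested coverage is hit exactly in pixels
(the returned truth is the pixel count), within 0.5 percentage points of
the request by construction.

`generate_cohort()` emulates the validation cohort: 47 subjects by default,
anterior fractions uniform on [0, 60] %, full-mouth indices generated as
calibration(fraction) + N(0, sd = 5), clamped to [0, 100] (a warning is
raised if clamping touches more than a quarter of the values — the signal
that the noise/calibration combination is pushing subjects off-scale).
Per-surface records (28 teeth × 4 surfaces per staining state) are sampled
so each subject's computed index matches the generated value to the nearest
achievable count (quantisation ≤ 100/112 %), and the anterior partial
indices are then *computed* from those records rather than drawn.

What passing the closed-loop tests shows: the thresholding, area accounting,
calibration algebra and rank statistics are internally correct under
bimodal, well-separated saturation with moderate noise. What it does not
show: performance on real photographs — specular highlights, uneven
lighting, gingival-margin ambiguity, camera-dependent colour rendering and
JPEG chroma artefacts are all absent from the generator, deliberately so.
The package measures images; it does not certify that any particular
imaging protocol yields separable saturation classes.

## Problem sizes and determinism

Every stochastic element is seeded explicitly; `generate_smile()` and
`generate_cohort()` restore the global RNG state on exit, and identical
seeds give byte-identical images and tables. The test suite exercises the
closed loop at 240 × 180 to 480 × 360 pixels across target fractions
5–95 %, Otsu against brute force on 100+ random histograms, and OLS
parameter recovery on 100 seeded 47-subject cohorts (checked against the
generative coefficients within two standard errors; the disclosed-mode line
is used for that check because the visible-mode intercept is negative, so
boundary clamping at zero would bias the recovery target). These sizes were
chosen to make the properties sharp while keeping the suite quick to run
routinely.

## Known limitations

* Tooth segmentation is an input, not a capability: mask quality bounds
  measurement quality, and the gingival margin is the hard part of drawing
  one on disclosed teeth.
* Otsu assumes a bimodal saturation histogram inside the mask. A
  plaque-free but *noisy* tooth violates this — the automatic threshold will
  split the noise and report spurious plaque; the fixed-band mode (or the
  degenerate noise-free case) is the appropriate tool there.
* The shipped calibrations were estimated on anterior-teeth smile imagery;
  applying them to other tooth groups or imaging geometries is
  extrapolation.
* The per-image measurement is global: no per-tooth or per-surface
  localisation is attempted, because no quantity downstream requires it.
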