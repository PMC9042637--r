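---
title: "Adaptive median filtering and morphological edge enhancement for ultrasound images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive median filtering and morphological edge enhancement for ultrasound images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usenhance)
```

## The problem

B-mode ultrasound frames — the pelvic-floor examinations this toolkit was
designed around are a typical case — suffer from two unrelated degradations:
multiplicative speckle texture intrinsic to coherent imaging, and impulse
("salt-and-pepper") corruption in which isolated pixels are replaced by
extreme gray values. Plain median filtering removes impulses but blurs the
anatomical interfaces (bladder neck, urethral axis) that the clinician
actually measures. The pipeline implemented here therefore (1) removes only
pixels it has positively identified as impulses, (2) extracts edges with
grayscale morphological gradients, and (3) sharpens only the detected edge
regions, leaving everything else bit-identical.

## The impulse detector

For each pixel `F(a,b)` the ascending array `S` of its `M x M` window
(default `M = 3`) is formed. `S_min`, `S_max`, `S_med` are the window
minimum, maximum and median; `N1` is the 0-based position of the first
entry strictly above the minimum and `N2` the last entry strictly below the
maximum, so positions `0..N1-1` hold the run of minima and `N2+1..M*M-1`
the run of maxima.

**Stage 1 (screening).** A pixel is a *quasi-noise candidate* iff it equals
a window extreme while the window median is itself not an impulse value
(`0 < S_med < 255`). Constant windows carry no evidence and are always
signal. The value-based median test matters in practice: on a flat
background (the near-black border outside the scan fan, say) the median
coincides with `S_min`, yet it is perfectly reliable — a range-based test
would permanently protect every impulse sitting on flat territory.

**Stage 2 (confirmation).** Candidates are confirmed by comparing the local
slope `K1` at the candidate against the adaptive threshold `Q = S_med / ε`.
For a minimum-valued centre,

```
K1 = (S[N1] - F) / ((N1 + 1)/2)
```

the slope from the first above-minimum entry down to the midpoint of the
run of minima. For a maximum-valued centre the package's default
(`k1_variant = "symmetric"`) mirrors this exactly across the top of the
array:

```
K1 = (F - S[N2]) / ((M*M - N2)/2)
```

An alternative form (`k1_variant = "as_printed"`) with numerator
`F - S[N1]` and denominator `M*M - 1 - N2` is also provided. It is not the
default because its numerator measures the window maximum against a
*near-minimum* interior value: on any textured image — speckle above all —
almost every ordinary local maximum then clears `Q` and gets "confirmed",
which we measure as roughly 5% of clean pixels falsely replaced on the
reference phantom versus roughly 0.5% for the symmetric form. That defeats
the design goal that signal points receive no processing. The two variants
coincide whenever the window maximum is unique, so the choice only matters
in windows containing repeated extremes.

The window-average slope `K2 = (S[N2] - S[N1]) / (N2 - N1)` (defined as 0
when the sorted interior collapses, `N2 <= N1`) is computed alongside. How
`K1`, `K2` and `Q` combine is genuinely open; the default rule is
`|K1| >= Q` confirms noise (`Q` is explicitly the second-stage test), and a
stricter conjunction `|K1| > |K2|` and `|K1| >= Q` is available as
`confirm_rule = "k1_vs_k2_and_q"`. Neither is claimed to be uniquely
correct; both are first-class and covered by the same reference
implementation.

**Replacement.** A confirmed impulse is replaced by the median of the
smallest window — growing `3 -> 5 -> 7` (`M_max = 7`, the usual adaptive
median compromise between detail preservation and robustness at high noise
density) — whose median is not itself that window's extreme; failing that,
the `M_max` median. Signal pixels and unconfirmed candidates are copied
bit-for-bit.

`denoise()` implements this in compiled code; `brute_force_denoise()` is a
literal per-pixel transcription built from the exported per-window
operations, kept as a permanently maintained oracle — the test suite
asserts exact agreement between the two on batches of random images across
the full parameter grid.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 2 | threshold divisor; `Q = S_med/ε` (intensity units). Larger ε lowers Q and makes the detector more aggressive; the benchmark sweeps 1, 2, 4. |
| `M0` | 3 | detection window side (pixels) |
| `M_max` | 7 | replacement-window growth limit (pixels) |
| `k1_variant` | `symmetric` | max-case K1 form, see above |
| `confirm_rule` | `k1_vs_q` | stage-2 combination rule |
| `border_mode` | `reflect` | symmetric edge extension; replication is available. Reflection avoids manufacturing fresh extremes at the border. |

## Morphological gradients

All morphology is flat (binary) structuring elements; the default is the
3x3 square. Dilation is the local maximum over the reflected SE, erosion
the local minimum, so the adjunction and duality identities hold exactly in
integer arithmetic; opening and closing are the usual compositions. Five
gradient operators are provided (`g` image, `D` SE; ⊕ dilation, Θ erosion,
∘ opening, · closing):

* `P1 = (g ⊕ D) − (g · D)`
* `P2 = (g ∘ D) − (g Θ D)`
* `P3 = ((g ∘ D) ⊕ D) − ((g · D) Θ D)`
* `P4 = ((g ∘ D) ⊕ D) − (g ∘ D)`
* `P5 = (g · D) − ((g · D) Θ D)`

`P2`–`P5` difference opened/closed images, so an isolated impulse — which
opening removes and closing fills — produces little or no response: the
anti-noise property the test suite asserts by counting nonzero responses.
`P1`, `P2`, `P4`, `P5` are provably non-negative from the ordering chain
erosion ≤ opening ≤ identity ≤ closing ≤ dilation; `P3` can in principle go
negative and is clamped at 0 like the rest (gradients are used as
magnitudes and mask sources, so clamping, not absolute value, is the
appropriate resolution). The default pipeline operator is `P4`; all five
are selectable and the benchmark sweeps them.

## Edge-region enhancement

The gradient image is binarised into an edge mask — by Otsu's criterion on
the histogram of *nonzero* gradient values (flat regions contribute exact
zeros that would otherwise dominate the histogram), or by a fixed
threshold for reproducible toy cases. On the mask,

```
output = clip(round(denoised + λ · edge), 0, 255)
```

with gain `λ` (default 1); off the mask the output *is* the denoised image,
asserted as bit-equality in the tests. Additive gradient sharpening is the
minimal operator consistent with "enhance the edge region, leave the rest
unchanged"; `λ = 0` degrades gracefully to pure denoising. Enhancement is
applied to the denoised image by default — filtering precedes edge work in
the pipeline — but `enhance_source = "raw"` boosts the unfiltered input
instead for comparison.

## Quality metrics

`img_mse`, `img_psnr`, `img_snr`, `img_ssim` are whole-image,
population-moment (divide-by-G) definitions; logarithms are base 10 and
SNR/PSNR are reported in dB. PSNR is `10·log10(G_max²/MSE)` with
`G_max = 255`. SSIM is the global three-factor product (luminance,
contrast, structure) with stabilisers `c1 = (0.01·255)²`,
`c2 = (0.03·255)²`, `c3 = c2/2` — the conventional constants; with
`c3 = c2/2` the three-factor product is algebraically the familiar
two-factor SSIM, and the tests assert that identity numerically to 1e-10.
Identical images give MSE 0, SSIM 1 and infinite PSNR/SNR by convention; a
constant reference with a nonzero residual makes SNR meaningless and is
raised as an error rather than returned as `-Inf`.

## The phantom generator

`make_phantom()` emulates the *displayed* (8-bit, post scan-conversion)
content of a pelvic B-mode frame: a dark fan-shaped field border at a
near-black noise floor (intensity 8 — real scan-converted frames are not
exactly zero outside the fan, and an exactly-zero border would make pepper
noise there undetectable by construction), mid-gray tissue background
(mean 120), anechoic elliptical inclusions at 0.3x background, bright
curvilinear interfaces at 1.8x background, all multiplied by unit-mean
gamma speckle. The shape parameter `speckle_looks` sets the speckle
contrast `1/sqrt(looks)`; the default 16 (contrast 0.25) models
log-compressed, compounded display-domain texture — raw-envelope values of
1–4 looks would overstate the texture of a displayed image, since the
generator multiplies in display domain rather than compressing an envelope
model. Impulse corruption replaces an exact count `round(density·G)` of
distinct pixels so tests can assert counts, not expectations.

What the phantom does **not** model: beam-width-dependent resolution,
attenuation and time-gain compensation, shadowing/enhancement artefacts,
anisotropic speckle correlation, and real anatomy. Passing tests therefore
demonstrate the algorithmic properties (detection, preservation, ordering,
determinism) under controlled conditions, not clinical image quality.

## Reference study conditions and what the benchmark shows

The package's reference conditions, used by the test suite and the
acceptance script, are 128x128 phantoms, impulse densities
{0.05, 0.10, 0.20}, ε ∈ {1, 2, 4}, operators P1–P5, 20 replicates —
a 900-run grid that completes in a few minutes on one CPU. Each replicate
is paired (the same phantom and corruption underlie the before/after
metrics). In every anti-noise condition with ε ≥ 2 the replicate-mean SNR,
PSNR and SSIM rise and MSE falls after processing; the exceptions are
exactly the conditions the method's own physics predicts: at ε = 1 the
threshold `Q = S_med` is so strict that only ~21% of impulses are
confirmed, and the plain gradient P1 — which the anti-noise operators
exist to supersede — then sharpens rings around the residual impulses,
costing more error than denoising removed. The benchmark reports these
cells like any others rather than hiding them. Oracle-equivalence checks
run on 32x32 random images, where the literal reference implementation is
affordable.

At the default settings (density 0.10, ε = 2) the detector confirms about
77% of corrupted pixels while falsely replacing about 0.5% of clean ones,
and denoising alone raises PSNR by about 7 dB. The residual misses are
dominated by windows containing several impulses of the same polarity
(which stretch the sorted-array runs that K1's denominator counts) and by
speckle draws that land within `Q` of the impulse value; raising ε trades
false positives for recall, and the benchmark logs both so the trade-off is
auditable rather than hidden in a default.

## Numerical and degenerate-case choices

* Intensities are integers 0–255 end to end; only slopes, thresholds and
  metrics are floating point. Ties in sorting are harmless (values, not
  indices, enter every formula).
* Constant windows: signal, never modified. Two-valued windows with no
  strict interior: `K2 = 0`.
* `Q = 0` (zero median) confirms any nonzero `|K1|` — intended: a zero
  median means the neighbourhood is black and any bright centre is
  suspect.
* Otsu on a single-valued nonzero histogram selects every nonzero pixel
  (threshold falls at 0), which is the sensible limit for synthetic step
  images.
* Border reflection is symmetric (edge pixel included), identical in the
  filter and the morphology so composed stages see one consistent image
  extension.

## Limitations

The detector targets impulse noise only; speckle itself is left alone by
design (the phantom's speckle is *context*, not a target). Recall degrades
as impulse density grows because multi-impulse windows blunt `K1` —
clusters of equal-valued impulses are intrinsically hard for a
single-pass, 3x3 slope test; repeated application of `denoise()` (the
label counts are monotone non-increasing across passes, asserted in the
tests) recovers some of them. SSIM here is the global variant; windowed
SSIM maps are out of scope. DICOM, 16-bit depth and cine loops are out of
scope.
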