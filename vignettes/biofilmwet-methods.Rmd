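---
title: "Wettability-based biofilm detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wettability-based biofilm detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmwet)
```

## The problem

A biofilm — microorganisms embedded in a matrix of extracellular polymeric
substances (EPSs) — changes the wettability of the surface it colonises:
the mixed polysaccharide/protein/lipid matrix is, on balance, more
hydrophilic than typical engineering plastics. `biofilmwet` implements two
complementary ways of exploiting this for in-situ detection on macroscopic
surfaces, together with the reference assay used to validate them:

1. **Crystal-violet stain quantification** from flatbed-scanner images of
   petri dishes: dye darkness is converted to an optical-density (OD)
   scale, calibrated against neutral-density (ND) filter standards, and
   summarised as a mean stain density and a percent stained area.
2. **Liquid-squeezing wettability assessment** from video: a 1-s air-jet
   blows the liquid film off the dish bottom; the diameter of the dry
   (liquid-squeezed) area over time quantifies wettability. Hydrophilic
   (e.g. biofilm-covered) surfaces resist squeezing and rewet quickly.
3. **Captive-bubble contact angles** as the classical cross-check: an air
   bubble pressed against the submerged, downward-facing surface.

All three pipelines are exercised end to end on seeded synthetic phantoms
with stored ground truth, so the package is fully testable without any
laboratory data.

## Stain quantification

### Gamma decompensation

Scanner output is gamma-encoded for display. With counts $I$ at bit depth
$b$ and scanner gamma $\gamma$, the decompensated brightness is

$$ I' = -\frac{\gamma}{\ln 10} \, \ln\!\frac{I}{2^b - 1}, $$

which is $0$ at full-scale white, strictly decreasing in $I$, and behaves
like an optical density. Defaults are $\gamma = 1.8$ and $b = 8$, the
values of the reference scanner. Counts below 1 are clipped to 1 before
the logarithm: the transform diverges at $I = 0$ and a saturated-black
pixel carries no usable gradation. The synthetic dish phantom inverts this
mapping exactly — $I = (2^b-1)\,10^{-I'/\gamma}$ — so the noise-free
encode/decode round trip is bounded only by count rounding; the per-pixel
bound is $(\gamma/\ln 10)\,|\ln(I_r/I_t)|$ with $|I_r - I_t| \le 0.5$
counts. Note this bound grows toward dark pixels, which is why densities
whose encoded intensity would round below one count are rejected outright.

### Calibration, ROI, threshold, area ratio

Density is obtained from the line $d = c_1 I' + c_0$ fitted by ordinary
least squares through ND-standard readings (the reference set is OD 0.6,
0.9, 1.2). Recovery of known coefficients from noise-free *readings* is
exact to floating point; through a rendered 8-bit image it is limited to
about $10^{-2}$ by quantization of the mean reading — an intrinsic limit
of the bit depth, not of the fit.

The analysis area is the disc of half the dish-bottom radius around the
dish centre (`extract_roi()`), which avoids the wall meniscus. Geometry is
normally supplied; `detect_dish_circle()` offers a rough automatic
fallback (centroid and median radius of strong-gradient pixels within a
radius band) rather than a full Hough transform, which the clean, nearly
centred scans this is meant for do not need. The stained/unstained
threshold is the midpoint between the group-average mean density of
initial-state dishes and that of incubated dishes, computed **per dish
type** (bare and plasma-treated polystyrene separately), since the two
substrates have different base tints; the pipeline then reports
$100 \times$ the fraction of ROI pixels with density strictly above the
threshold. Ties count as unstained — a measure-zero convention that merely
has to be fixed. Group statistics are computed over per-dish means (one
number per dish), not pooled pixels.

## Liquid-squeezing analysis

### Segmentation and diameter

The baseline is the mean of all frames before jet onset. Each frame is
segmented on the absolute difference to the baseline: Otsu's threshold
(manual override available), morphological closing (disc radius 2 px),
connected-component labelling, and selection of the component containing
the nozzle axis (or nearest by centroid). Two guards keep a truly dry-free
frame *exactly* empty, which the residual-diameter contract requires:

* components smaller than `min_area_px = 9` are rejected as noise
  speckle;
* the Otsu threshold is floored at `min_diff = 20` counts — a quarter of
  the default 80-count dry/wet contrast — so that Otsu cannot split the
  noise histogram of a frame with no signal.

The diameter is the equivalent-circle diameter
$2\sqrt{A/\pi}\cdot\text{scale}$ of the selected component (the commercial
system's definition is unknown; a maximum-Feret alternative sits behind
`method = "feret"`). Sample times are re-anchored so $t = 0$ is the
manifest's jet-onset timestamp.

### Indexes

Two indexes summarise each experiment, both arithmetic means over closed
windows (timestamps compared with $10^{-9}$ s tolerance):

* **mean squeezed diameter**, over $t \in [0.63, 0.9]$ s — the later,
  steady phase of a 1-s jet; smaller means more wettable;
* **residual diameter**, over $t \in [1.23, 1.5]$ s, after the jet; it is
  exactly 0 when every in-window mask is empty (full rewetting), otherwise
  the mean is reported however small.

### Oscillation frequency

Hydrophilic uncolonised surfaces show a diameter oscillation (around 6 Hz
in the reference conditions). `oscillation_frequency()` takes the
periodogram of the mean-detrended in-window diameters and reports the
dominant peak when its power exceeds 4× the median spectral power. Two
additional guards reflect what short, pixel-quantised series can support:
variation below `min_sd_mm = 0.05` (one pixel pitch at the default scale)
is not a resolvable oscillation and yields `NA`; and an optional
`candidate_band_hz` raises an error when the frame rate is below twice the
band's upper edge, since an aliased peak would otherwise be reported at
the wrong frequency. The bundled `wettability_indexes()` estimates the
frequency over the last 55 % of the jet interval: over the full window the
opening and spreading ramps dominate the detrended spectrum and produce a
spurious ~1 Hz peak for perfectly non-oscillatory trajectories.

## Captive-bubble contact angle

The bubble silhouette below the baseline row is binarised (Otsu), the
background class identified along the frame border, and the largest
foreground component touching the baseline traced. A circle is fitted to
the boundary by algebraic least squares, excluding points within 5 px of
the baseline where the silhouette is cut by the solid. With the centre a
signed distance $h$ beyond the baseline into the bubble phase and radius
$r$, the angle through the bubble is $90^\circ + \arcsin(h/r)$.

Two deliberate simplifications: the circle model ignores gravity
distortion, defensible for 2–5 µL bubbles, with the RMS fit residual
exposing violations; and the reported angle is the **bubble-side** angle,
under which a *smaller* angle indicates a *more hydrophobic* surface —
`water_side_angle()` converts to the complementary convention. The
commercial meter's convention is not documented; the chosen one reproduces
the qualitative surface ordering but could only be verified against raw
meter images.

## Gated two-sample comparison

Group differences are tested with the gated procedure: a two-sided
variance-ratio F-test (larger variance in the numerator, doubled tail
capped at 1) decides at `alpha_gate = 0.05` between Student's
pooled-variance t-test and Welch's t-test with Welch–Satterthwaite degrees
of freedom. All tests are two-sided — the conventional reading of the
reported significance tiers — and no multiple-testing correction is
applied by default (a Bonferroni option exists). A sample with zero
variance makes the variance ratio degenerate and is an error. Under the
null the gated procedure holds its nominal 5 % size to within Monte-Carlo
error (checked at 10,000 replicates, $n = 5$ per group).

## The synthetic study and what it does (not) show

`condition_spec()` encodes the four study conditions with the printed
group values as defaults: bare polystyrene initially (two-step squeezing:
5 mm shoulder held to 0.2 s, then a 17 mm plateau, no recovery);
plasma-treated polystyrene initially (6 Hz, 1 mm-amplitude oscillation
about 6.8 mm, partial recovery to 5.0 mm); and the two 14-day
biofilm-covered conditions (fast rise to 6.0 / 5.6 mm, full recovery
within 0.1 s). The jet runs 1 s; replicates jitter the plateau and
residual multiplicatively (σ = 3 %). Values the study does not report are
fixture conventions fixed once: 60 fps, 0.05 mm/px, 80-count dry/wet
contrast, 3-count frame noise, 0.05–0.1 s opening ramps. Trajectories are
phenomenological piecewise-linear/sinusoidal templates — there is no
air-jet fluid dynamics — and phantom noise is additive clipped Gaussian on
counts.

Consequently, passing tests demonstrate that the *measurement chain*
(segmentation → diameter → windowed indexes; decompensation → calibration
→ coverage; contour → circle fit → angle) recovers known ground truth
under realistic noise, and that the study's qualitative ordering
(PS-initial largest mean index; 14-d conditions smallest with residual
exactly 0) is reproduced. They do not validate the templates against real
jet–liquid physics, uneven illumination, or non-circular dry regions.

## Problem sizes and numerical choices

Property tests run 20 seeded replicates per trajectory regime (smaller
two-step plateau, 12 mm, to keep frames compact), 20 coverage phantoms
spanning 0–90 %, angle sweeps over 60–150° (10 noisy seeds per angle) and
10,000 null replicates for the test-size check; the end-to-end demo in the
test suite uses 2 replicates per condition, while the acceptance script
runs the study's own group sizes (N = 3, 9, 3, 6). Per-frame diameter
recovery is asserted within $\max(2\cdot\text{scale},\ 3\%)$ and index
recovery within 0.3 mm; coverage within 2 percentage points; angles within
2° noise-free and 5° at 10-count noise. All generators draw from one
seeded stream per call, so identical specs and seeds reproduce outputs
bit-identically.

## Known limitations

* The decompensation model assumes a single global gamma and no flat-field
  correction; uneven illumination is only mitigated by the half-radius ROI.
* Equivalent-circle diameters understate strongly non-circular dry
  regions; the Feret option bounds the discrepancy but neither matches an
  unknown vendor definition.
* The circle-fit angle degrades near 180° (tiny baseline chord) and the
  detector requires the bubble to touch the baseline; a surface that
  repels the bubble entirely is reported as a detection error, not an
  angle.
* Oscillation frequencies are resolved only to one spectral bin of the
  analysis window (about 1.1 Hz for a 0.9-s window at 60 fps).
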