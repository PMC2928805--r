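---
title: "Methods: quantifying worm neuromuscular phenotypes"
author: "nemaphene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying worm neuromuscular phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaphene)
```

# Scope

`nemaphene` implements the quantification steps of four classic *C. elegans*
neuromuscular assays — head-bend posture, crawling speed, fluorescence
puncta intensity, and evoked postsynaptic currents — together with the group
statistics used to compare genotypes (mean ± s.e.m., Welch's t-test, one-way
ANOVA, Dunnett's multiple comparison). Every pipeline is backed by a seeded
synthetic-data generator whose ground truth is computed from the analytic
form of the scene, never from rendered pixels, so recovery can be tested
without any external data.

# Posture: the first supplementary angle

A single worm is imaged crawling on an agar plate. The analysis places 13
points at equal arc-length intervals along the body midline from the tip of
the nose to the tail, and reports the *first supplementary angle*: 180°
minus the interior angle at point 2 formed by points 1–2–3, i.e. the turning
angle between the first two midline chords. Mutants with exaggerated
anterior bending (BK-channel and dystrophin-complex mutants) show larger
first angles than the wild type. The reported statistic is the angle at
*maximal head-swing extension*: the maximum of the per-frame absolute angle
over an analysis window, by default 15–60 s after the recording starts, when
animals are stimulated to move forward rapidly and the phenotype is most
prominent.

The midline algorithm is:

1. **Segmentation** — global Otsu threshold with automatic polarity
   detection (the smaller intensity class is the worm), hole filling,
   largest connected component within area bounds (`segment_worm()`).
2. **Skeleton** — Zhang–Suen thinning, then the skeleton is pruned to its
   single longest endpoint-to-endpoint geodesic (all spurs discarded). A
   skeleton without endpoints (a closed loop) is reported as a coiled
   posture and the frame is skipped.
3. **Sub-pixel refinement** — a smoothing spline is fitted to the skeleton
   path (default one degree of freedom per ~12 px of arc), then each vertex
   is moved to the midpoint of the perpendicular foreground run. When the
   grayscale frame is available the run is measured on a
   normalized-intensity coverage map, whose anti-aliased edges localize the
   boundary to a fraction of a pixel; the final refinement pass is left
   unsmoothed so a sharp head bend is not rounded away.
4. **Tips** — the skeleton stops short of the nose and tail. Each end is
   extended to the body tip: among rays fanned ±12° around the terminal
   tangent, the apex of the rounded cap is the farthest sub-pixel boundary
   crossing; if the maximum sits at the fan edge (a flat or cornered mask
   end) the tangent ray is used instead.
5. **Head assignment** — imaging cannot distinguish nose from tail, so
   orientation is matched across frames by endpoint proximity and the end
   whose centroid-relative offset aligns with the direction of motion is
   labelled the nose (crawling worms lead with the nose). Below a net-motion
   threshold the label is `"unassigned"` unless the user overrides it. The
   angle magnitude itself is end-symmetric only when the bend is anterior,
   which is why the label is tracked explicitly.

**Accuracy.** On synthetic worms (1 mm body at 5 µm/px) the pipeline
recovers head bends of 10–60° with a mean absolute error of ~1.5° at a
pixel-noise level of 10% of the worm–plate contrast, and reads below 0.6°
on straight worms. The residual, angle-dependent part of the error is a
known geometric effect: at a sharp bend the perpendicular-run midpoint is
pulled toward the inside of the corner by up to `h/2·(sec(θ/2) − 1)` of the
local half-width `h`, so very large bends are slightly underestimated. The
error scales with pixel size; finer sampling reduces it proportionally.

The sign of the bend in the image frame (positive = toward image-left of
the nose→tail direction) is available as an attribute, but no dorsoventral
identity is claimed — that would require anatomical information the image
does not carry.

# Locomotion: average speed

`track_centroids()` segments each frame and records a coverage-weighted
sub-pixel centroid; failed frames are flagged, never interpolated.
`average_speed()` divides the summed path length over consecutive
valid-frame pairs by their summed elapsed time. Path-length speed (rather
than net displacement over duration) is the deliberate choice: a
head-bending worm with little net dispersal still has locomotor activity,
and this matches what commercial object trackers report for this assay. No
temporal smoothing is applied by default; undulation-induced centroid
wobble is accepted as part of the measurement.

# Puncta: background-subtracted linescan peaks

Fluorescently tagged channel and dystrophin-complex proteins appear as
puncta along muscle membranes and nerve cords. Quantification follows
linescan practice: `sample_profile()` interpolates the image bilinearly at
equidistant positions (step ≤ 1 px) along a user-supplied polyline and
averages across a perpendicular band (default 3 px). `detect_puncta()`
finds local maxima above `median + k·σ` (default `k = 3`, with σ estimated
robustly from first differences), enforcing a minimum separation.
`measure_puncta()` reports `net = peak_grey − background`, where
`peak_grey` is the profile maximum within ±w of the peak and `background`
is the local 10th percentile excluding ±3w around every peak — a low
percentile rather than the minimum, for robustness to noise. Nets are
linear in camera gain and invariant to additive offsets. Note that the
perpendicular averaging attenuates puncta that are narrow relative to the
band; profiles should be compared only across images acquired with
identical exposure, gain and pinhole settings, which remains the user's
responsibility.

# Evoked currents

Whole-cell voltage-clamp recordings of body-wall muscle (holding potential
−60 mV, digitized at 2.9 kHz) yield evoked postsynaptic currents after
optogenetic stimulation of motor neurons. For a trace with stimulus onset
`t0`:

* **baseline** — mean current over the 20 ms before `t0`;
* **amplitude** — maximum |I − baseline| in a post-stimulus search window,
  reported as a positive magnitude with polarity; the peak is refined by a
  three-point parabola unless it sits on the first sample (instantaneous
  rise);
* **half-time decay (t½)** — time from the peak to the first crossing of
  50% of the peak deviation, linearly interpolated between samples. This is
  the standard synaptic convention (from the peak, not from the stimulus).
  On noisy traces (pre-stimulus sd > 0.5% of amplitude) a five-sample
  moving average stabilizes the crossing; on clean traces raw interpolation
  keeps the closed forms exact: a monoexponential decay of constant τ gives
  t½ = τ·ln 2 to within interpolation error at 2.9 kHz.
* **charge integral** — |∫(I − baseline) dt| in pC from onset to the first
  time the deviation falls below 5% of amplitude and stays there ≥ 2 ms,
  capped at 200 ms (all three parameters are configuration keys, since the
  window rule of the original acquisition software is not documented);
  partial segments at the window edges are included by interpolation.
* **normalized trace** — `(I − baseline)` divided by the extreme sample
  deviation, so the normalized peak is exactly 1 regardless of amplitude
  and polarity; kinetics can then be compared across genotypes.

The simulator (`make_trace()`) uses a difference-of-exponentials kernel
`e^{−t/τd} − e^{−t/τr}` (pure `e^{−t/τd}` when τr = 0) rescaled so the
analytic peak equals the nominal amplitude; its ground-truth charge is
`A·(τd − τr)/g_peak` and its half-decay is the analytic root of the kernel.
The sampling grid is anchored at the stimulus (TTL-triggered acquisition),
inward currents deflect negative, and a trace too short to decay to 5% of
peak is flagged `"decay truncated"` in its sidecar.

# Statistics

`group_summary()` reports n, mean and s.e.m. (= sd/√n, with the n−1
denominator). `t_test_unpaired()` defaults to Welch's unequal-variance
test — the safer default when the variance assumption is unstated; it
coincides with the pooled test for equal sizes and variances, and the
pooled form is available by flag. `one_way_anova()` is the standard
between/within decomposition. `dunnett()` compares each treatment with a
control using pooled-error t statistics and adjusts the p-values by seeded
Monte Carlo from the joint null of the max-|T| statistic (default 10⁵
draws): group means are drawn as normals scaled by 1/√n and the pooled sd
as √(χ²ν/ν), which reproduces the correlated multivariate-t null exactly in
distribution. Adjusted p-values are floored at the raw p, since familywise
error can never undercut the per-comparison error and Monte-Carlo jitter
would otherwise violate the guarantee for a family of one. Calibration over
2000 simulated null datasets puts the t-test, ANOVA and Dunnett familywise
rejection rates within sampling error of the nominal 5%. No additional
correction across different metrics is applied.

# Synthetic data: what it emulates, and what it does not

`worm_spec()` describes a sinuous worm built from cumulative turning angles
over equal arc-length steps, so body length is conserved exactly under any
bending. The head bend is injected as a constant tangent offset over the
first body twelfth with the turn concentrated at the second of the 13
nominal points, and undulation is tapered in only beyond the second
twelfth: this makes the 13-point first angle equal the specified
`head_bend_angle` *identically*, rather than approximately — spreading the
turn over a finite window would make the chord angle deviate from the
nominal value. The body centroid (width-weighted, i.e. what a mask centroid
measures) translates at exactly the specified speed, with the undulation's
centroid wobble removed by construction. Rendering tests pixels against the
local half-width with 4× supersampling, giving anti-aliased,
sub-pixel-stable masks; Gaussian read noise is added from a private seeded
stream.

Default study conditions, chosen once as typical of crawling assays:
1 mm adult, 40 µm maximal half-width with elliptical taper, undulation
amplitude 25° at 0.65 body lengths and 0.3 Hz, frames every 0.5 s. The
pixel calibration is not dictated by the assay (no instrument is modelled),
so the default of 5 µm/px is arbitrary and configurable; posture accuracy
improves proportionally at finer calibrations. Test problem sizes (4-frame
movies for posture recovery, 30-frame movies for speed, 2000-replicate
calibration loops) are the package's own choice of desk-scale conditions.

The generators deliberately do **not** emulate: worm texture or internal
intensity structure, self-coiling or omega turns (coils are *detected* and
skipped, not traced), multiple animals, illumination gradients, or
non-Gaussian camera noise. Passing recovery tests therefore demonstrates
correctness of the geometry and signal processing under clean-plate
assumptions, not robustness to every real-world artifact.

# Determinism

Every seeded computation (rendering noise, trace noise, Dunnett draws) runs
through a private RNG scope that saves and restores the caller's random
state, so identical specs with identical seeds are bit-reproducible and
never perturb user code.

```{r example}
mv <- render_movie(worm_spec(head_bend_angle = 30, speed = 100,
                             n_frames = 4, noise_sd = 60, seed = 1))
res <- analyze_posture(mv$stack, window = c(0, 5))
res$angle            # close to the constructed 30 degrees
as.numeric(average_speed(track_centroids(mv$stack)))  # close to 100 um/s
```
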