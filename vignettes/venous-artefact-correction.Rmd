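---
title: "Methods: venous artefact, inverted voxels, and hV4 map correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: venous artefact, inverted voxels, and hV4 map correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deoxygenated blood in large draining veins — above all the transverse
sinuses, which run close to the ventral surface of occipital cortex —
perturbs the local magnetic field and depresses the mean EPI signal of
nearby voxels. On a normalised mean map this appears as a contiguous dark
band, the *venous eclipse*. Cortex underneath such a vein can respond to
visual stimulation with a *sign-inverted* BOLD time course: the signal
decreases during stimulation rather than increasing. In retinotopic mapping
experiments these inverted voxels produce disordered polar-angle maps and
apparent holes in visual-field coverage, and human V4 (hV4) — whose lower
visual quarterfield abuts the typical path of the transverse sinus — is the
area most often reported "incomplete".

This package implements the complete analysis chain for diagnosing and
correcting that artefact, and a synthetic cortical-patch generator that
reproduces its statistical structure so every stage can be validated
end-to-end against ground truth.

## Models and procedures

### Haemodynamics

The canonical HRF is a double gamma: a positive lobe peaking at 5 s minus
an undershoot lobe peaking at 15 s scaled by 1/6, each lobe the unit-peak
shape $(t/p)^p e^{p-t}$, sampled at 0.1 s over 32 s and normalised to unit
peak. The HRF literature names many parameterisations; these values are the
conventional mid-range choice, and they place the peak of the block
response to a 4 s stimulus — sampled on the TR = 2 s grid — at 8 s after
stimulus onset, which is the latency the full-field control analysis keys
on.

One numerical convention matters here: TR-grid stimulus series are treated
as step functions, convolved at the kernel's 0.1 s resolution, and then
*sampled at volume onsets*. Convolving at TR resolution instead shifts the
on-grid block-response peak to 6 s. All TR-grid convolutions go through a
single Toeplitz operator built from the response to one TR of stimulation,
so the choice is made once, in one place.

### The pRF forward model and estimator

A voxel's population receptive field (pRF) is an isotropic 2-D Gaussian in
visual-field coordinates (centre $x_0, y_0$; size $\sigma$). The predicted
time course is the per-frame overlap of that Gaussian with the binary
stimulus aperture, HRF-convolved, scaled by an amplitude $\beta$ and offset
by a baseline. `fit_prf()` estimates the nonlinear parameters by a
two-stage coarse-to-fine search: an 11 × 11 lattice of centres over
±5.5° crossed with $\sigma \in \{0.25, 0.5, 1, 2, 4\}°$ (605 candidates,
amplitude and baseline solved in closed form per candidate), followed by
Nelder–Mead refinement of $(x_0, y_0, \log\sigma)$ with the linear
parameters profiled out (relative tolerance $10^{-6}$, 500-iteration cap;
positions clamped to twice the display extent, $\sigma \ge 0.05°$). The
log-$\sigma$ parameterisation keeps the simplex away from the degenerate
small-$\sigma$ boundary. If refinement fails to improve on the grid
winner, the grid winner is returned and the voxel flagged — refined RSS is
never allowed to exceed its start.

Three further design choices deserve explanation:

* **Per-run baselines.** Mapping runs (bowtie + ring + bar) are fitted
  jointly by concatenation, but every run keeps its own intercept. Scans
  have arbitrary DC offsets in practice, and the flipping correction
  (below) reflects each run about its own mean, which shifts per-run
  offsets; a single global baseline would push corrected voxels out of the
  model class. One amplitude $\beta$ is shared across runs, with each
  run's prediction scaled to unit range so runs contribute comparably.
* **Non-negative amplitude.** By default $\beta \ge 0$ — the positive-BOLD
  assumption. This is what makes the inverted-voxel correction
  consequential: if $\beta$ were free, an exactly inverted time course
  would be absorbed by a sign flip of $\beta$ and flipping could never
  change a map. Under the constraint, an inverted voxel's best "positive"
  explanation is a mirrored or ipsilateral receptive field (bowtie
  responses half a cycle out of phase look like the diametrically opposite
  polar angle; ring responses half a cycle out of phase look like a
  shifted eccentricity), which is exactly the spurious ipsilateral
  coverage seen in disturbed maps. `allow_negative = TRUE` is available
  for diagnostic use.
* **Degenerate fits.** Voxels with variance explained below 0.1 are
  excluded from coverage and smoothness computations. The floor is
  deliberately permissive and configurable.

### Travelling-wave phase

`fft_phase_map()` reads phase and coherence at the stimulus frequency bin.
Because the bowtie is a *double* wedge rotating one full revolution per
cycle, each polar angle is stimulated twice per revolution: bowtie
responses live at twice the rotation frequency, and their phase encodes
polar angle modulo 180°, which is injective within one hemifield. Analyses
of bowtie runs therefore use the $2 n_{cycles}$ bin.

### Classification and correction

Voxel classes come from the Pearson correlation of the full-field control
run against the HRF-convolved ON/OFF reference: positive when $r \ge 0$
(zero, including constant voxels, counts positive — flipping a
zero-correlation voxel is a no-op in expectation), inverted when $r < 0$.
Negative voxels beyond the 5.5° stimulated eccentricity are negative BOLD
responses (NBRs, neuronal suppression just outside the stimulus), not
venous artefact, and are excluded from area analyses by default.

The correction reflects each flagged voxel's time course about its own
temporal mean, $y' = 2\bar y - y$. This is the unique pointwise definition
that exactly negates the correlation while leaving the voxel's mean — and
hence the normalised mean map — untouched, and it is an involution. The
flip threshold is 0 (all negative correlations) by default; a threshold of
0.1 reproduces the conservative variant that only corrects correlations
strictly below −0.1 (the strict comparison is a deliberate reading of
"stronger than").

### Coverage, completeness, smoothness

Visual-field coverage uses a pRF density map on a 201 × 201 field lattice.
The default construction is the **max-profile envelope**: the map value at
a field point is the maximum over usable voxels of the unit-height
Gaussian pRF profile, so a point reaches the 0.8 threshold whenever it
lies within ≈ 0.67 σ of some pRF centre. A sum-of-Gaussians mode
(normalised by the map maximum) is provided as an alternative, but it is
not the default: with pRF sizes growing linearly with eccentricity, the
sum construction concentrates its maximum wherever centres crowd, and
large well-mapped regions then fall below any fixed fraction of that
maximum — the 0.8/20% machinery only behaves as intended under the
envelope reading, which is also the field's standard coverage plot.

Each hemifield is divided into four 45° sectors from the upper vertical
meridian (upper, middle-upper, middle-lower, lower). Sector coverage is
the percentage of sector grid area (eccentricity ≤ 5.5°) at or above the
density threshold; a sector is *complete* when its percentage, rounded
half-up to a whole number, reaches 20%. Round-half-up is a choice —
"nearest whole number" leaves ties open — and it makes the boundary exact:
19.4 → incomplete, 19.5 → complete.

Map smoothness: polar angles of an ROI are mapped linearly to luminance,
the lattice is rotated so the principal angle gradient runs along the
image x-axis, each column is summarised by its mean included luminance,
the column profile is min–max normalised, and the statistic is the
profile's total variation (sum of absolute successive differences). A
clean monotone ramp spanning the full range scores exactly 1; phase
disturbances add variation, so larger is rougher. A literal RMS-contrast
reading of the column summary would score an ideal horizontal ramp 0 in
every column and could not satisfy "ideal map ↦ 1"; the column-mean
reading is the one under which that statement holds, and is what this
package computes. A constant image (no angular gradient) scores 0 and is
flagged degenerate rather than smooth.

### Eclipse detection

Hand-drawn eclipse ROIs remain first-class inputs (`eclipse_roi()`), and
`detect_eclipse()` offers an automated surrogate: voxels below the 0.15
intensity quantile of the mean map are grouped into 4-connected lattice
components, and components of at least 20 voxels with major/minor axis
elongation of at least 2 (vessel shadows are elongated) form the ROI. An
empty result is the valid "absent" outcome.

## What the synthetic generator emulates

`make_retinotopic_patch()` builds a rows × cols voxel sheet (default
30 × 30; tests also use 20 × 20) with column bands for V1, V2, V3 (5 each),
hV4 (11) and a peripheral NBR band (4). Polar angle runs along rows from
the upper to the lower vertical meridian with small per-column offsets
(dense angular sampling); eccentricity runs along columns within each
band, 0.5–5.5° for the mapped areas and 5.7–6.6° for the NBR band. pRF
size follows σ = 0.3 + 0.2·eccentricity — standard retinotopic
phenomenology; the paper-level analyses need realistic density maps but do
not pin these numbers.

Signal model per depth layer (grey/white, 1 mm, 2.5 mm): baseline 100 with
5% voxel-wise baseline heterogeneity (EPI brightness varies across voxels;
this is also what makes depth-integrated eclipse detection genuinely
harder), response amplitude β = 2 on unit-range predictions, Gaussian
noise SD 1. NBR voxels respond with −1.5 and noise SD 0.5: strongly
negatively correlated, bright, and less noisy than inverted voxels. The
venous eclipse is an elongated 3-row band crossing V3/hV4/periphery near
the lower hV4 border; its fractional intensity drop is (0.45, 0.30, 0.10)
at (2.5 mm, 1 mm, grey/white), tapering linearly (0.15…1) along the band
as a vessel shadow fades at its ends, and its inverted-voxel probabilities
(0.8, 0.5, 0.2) are realised as *nested* quota samples, so prevalence
decays monotonically with depth by construction, as a vein's influence
penetrating from the surface should. The depth-integrated series is the
unweighted mean of the three layers. All randomness flows from the single
spec seed.

Scenario constructions:

* `missing_lower` compresses the hV4 angular range to [0°, 120°) and has
  no eclipse (an "incongruent" configuration). The cut sits 15° short of
  the lower sector because pRFs are extended: centres hugging a sector
  boundary cover ≈ 0.67 σ beyond it, and integrating that spill over
  eccentricity leaves roughly a quarter of the lower sector covered if the
  map runs all the way to 135° — a map missing *only* the geometric sector
  would not measure as incomplete.
* `subject10` keeps the full hemifield in ground truth but places a
  maximal eclipse (inversion probability 1 at every depth) over all hV4
  voxels beyond 110° for the same reason: what the measurement loses must
  extend slightly past the sector boundary for the lower quadrant to
  classify incomplete before correction. After flipping, the fits recover
  the true geometry and the quadrant classifies complete — the package's
  end-to-end restoration demonstration.

What the generator does **not** emulate: folded cortical geometry and
partial-volume effects, physiological (respiratory/cardiac) noise spectra
and temporal autocorrelation, vein-induced *delayed* (as opposed to
inverted) responses, pRF-size misestimation near borders, and the
empirical latency difference between inverted and positive responses (an
exactly mirrored response cannot peak at a different time). Passing tests
therefore demonstrate the correctness and internal consistency of the
analysis chain under the assumed signal model, not its performance on real
tissue.

## Problem sizes and runtimes

The shipped tests run the full chain at 20 × 20 (400 voxels, single
mapping run) for pipeline mechanics and at 30 × 30 (900 voxels, bowtie +
ring + bar jointly, 548 concatenated volumes) for the recovery and
restoration checks; aperture movies are rendered at 51 × 51 samples for
fitting (0.22°/sample, comfortably below the thinnest aperture feature)
and 101 × 101 by default for standalone rendering. These sizes keep a full
`R CMD check`-style run in the minutes range on a single core while
leaving every statistic well away from small-sample artefacts.

## Known limitations

* The amplitude constraint makes "inverted voxel" and "unfittable voxel"
  partially interchangeable at low SNR; the variance floor, not the sign
  of the fitted amplitude, decides usability.
* Eclipse detection assumes lattice geometry; for surface-sampled real
  data the manual-ROI path is the intended route.
* The congruence labelling follows the lower quadrant only, by design;
  other sectors' status enters the report but not the label.
* Bowtie phase identifies polar angle modulo 180°; across-hemifield phase
  comparisons need the pRF fits, not the travelling-wave map.
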