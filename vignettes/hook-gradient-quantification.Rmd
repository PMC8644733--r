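---
title: "Quantifying apical-hook geometry and auxin reporter gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apical-hook geometry and auxin reporter gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hookquant)
```

## The measurement problem

Dark-grown dicot seedlings form an apical hook: the upper hypocotyl bends
through up to 180 degrees, protecting the meristem as the seedling pushes
through soil. Hook formation and maintenance depend on an auxin maximum on
the concave (inner) side of the bend, and transcriptional auxin reporters
such as DR5-driven GUS make that asymmetry visible as a staining gradient
across the hook tissue.

`hookquant` turns two kinds of raw material into numbers:

* **hook-angle tables** — per-seedling angles between the hypocotyl axis
  and the imaginary line joining the cotyledons, measured manually on
  photographs and recorded per genotype, day of darkness and treatment
  concentration;
* **reporter-stained photographs with landmark annotations** — from which
  the staining signal is read along the bisector chord of the hook, from
  the concave to the convex tissue edge.

Both feed a small set of summary statistics and group comparisons, and a
synthetic image generator provides analytic ground truth for every stage.

## Conventions and the geometric model

**Angle convention.** The hook angle is the angle between the oriented
hypocotyl direction (proximal to distal) and the oriented cotyledon
direction: 180 degrees is a fully closed hook (cotyledon line antiparallel
to the hypocotyl), 0 is fully open. Published angle series plot numbers
without stating the convention; this one makes formed hooks read near 180
and unfolding monotonically decrease the angle, which matches how such
series are usually drawn.

**Image coordinates** are `(row, col)`, 0-based, pixel centers at integer
coordinates, used consistently for landmarks, rays and chords.

**Bisector ray.** The staining is read along the bisector of the hook
angle. From the landmark directions `d_h` (hypocotyl) and `d_c`
(cotyledon line), the ray starts at the hook vertex — the interior corner
of the hook, on the concave tissue edge — and points along
`unit(d_h − d_c)`. This vector lies on the bisector line of the vertex
angle (it makes equal unoriented angles with both arms) and its sign is
chosen to point *away from* the open wedge between the hypocotyl and the
cotyledons, i.e. across the tissue towards the convex edge; for a closed
hook it degenerates gracefully to the hypocotyl direction, piercing the
top of the bend. The opposite sign, pointing into the concave air gap,
would never cross tissue and could not support chord detection. The ray is
undefined at angle 0, where the two directions coincide; hooks that curl
past 180 degrees are likewise outside the supported range, since the
interior-angle bisector is no longer well defined there, and no guess is
attempted.

**Landmark-based, not automatic.** Angles in this assay tradition are
measured interactively in a general-purpose image tool; `hookquant`
expects landmarks (from annotation or from the generator) and deliberately
does not attempt seedling segmentation.

## The staining profile and its statistics

The photograph is converted to a scalar signal with the classic luminance
weights (0.299, 0.587, 0.114), rounded to integer gray levels. Polarity is
explicit: `"stain_dark"` inverts (`max_value − luminance`) so that heavier
blue staining means larger signal — the natural choice for GUS
photographs, where the auxin maximum is the darkest tissue — while
`"stain_bright"` keeps gray levels as they are (used for the synthetic
renders, which already encode signal as brightness). Whether published
gray-value curves were inverted before plotting is typically not stated,
so the choice is a recorded parameter rather than a silent default, and
every downstream statistic is defined on the signal after polarity
handling.

The tissue chord is found by walking the bisector ray: the first sample
above a background threshold opens the tissue run, the last contiguous
sample closes it. Endpoints are then refined to the *local half-maximum*
crossing — the midpoint between the nearby tissue plateau and the nearby
background — which localizes the true edge to sub-pixel precision; a raw
detection-threshold crossing would sit wherever the threshold happens to
cut the 1-pixel edge ramp and bias the chord outward. The `"auto"`
threshold (midpoint of the ray's minimum and maximum) suits clean
two-level images; for strongly graded tissue over a known background an
explicit threshold between background and the dimmest tissue is the right
tool, and the simulated fixtures record one in their config.

Sampling is single-pixel bilinear interpolation at equal arc-length steps
(default target 0.5 px; the step is refined so the last sample lands
exactly on the chord end). Because hook diameters differ between
seedlings, positions are normalized affinely onto `[0, 1]` (0 = concave,
1 = convex) and values are linearly interpolated onto a uniform grid of
`n_points = 101` positions — "intervals" without a stated count in the
assay tradition; 101 gives a 0.01 resolution on the normalized axis,
comfortably below measurement noise. No background subtraction is applied
by default and signal stays in native units ("arbitrary units"); nothing
is rescaled silently.

Two per-seedling statistics summarise a profile `g(s)`:

* **total integrated intensity**, the trapezoidal integral of `g` over
  `[0, 1]`;
* **ARDI**, the Auxin Response Distribution Index: the smallest `s*` at
  which the cumulative trapezoidal integral reaches half of the total,
  with linear interpolation of the cumulative inside the bracketing grid
  interval. A uniform profile gives 0.5; concave-concentrated staining
  gives smaller values. ARDI is scale-invariant, so staining intensity and
  staining *distribution* are decoupled. Plateaus of zero signal crossing
  exactly half mass resolve to their leftmost point — an explicit
  tie-break where any choice inside the plateau would be defensible.

```{r ardi-example}
s <- seq(0, 1, length.out = 101)
prof <- intensity_profile(s, 60 + 160 * exp(-3 * s))
c(area = integrated_intensity(prof), ardi = ardi(prof),
  analytic = analytic_ardi(3, 60, 160))
```

## Group comparisons and dose-response

Per-group staining patterns are reported as pointwise mean ± SD curves on
the common grid (sample SD, denominator `n − 1`, defined as 0 for a single
profile). ARDI and area are compared across genotypes by one-way ANOVA
with Tukey's HSD post-test; angle tables with genotype × treatment
structure use two-way fixed-effects ANOVA with interaction. The Tukey
p-values are computed directly from the studentized-range distribution
(Tukey–Kramer standard errors when group sizes differ), and group letters
come from the standard insert-and-absorb compact-letter-display algorithm,
so that groups sharing a letter are never significantly different and
every non-significant pair shares one. The two-way procedure requires a
balanced design with at least two observations per cell — the designs this
assay produces are (approximately) balanced, and requiring balance removes
the Type-I/II/III sums-of-squares ambiguity by contract. Tukey comparisons
run over all cell pairs, recorded as such in the output. `alpha` defaults
to 0.05 everywhere and is configurable.

Auxin-transport-inhibitor series are summarised two ways:

* **dose-response slope** between two named concentrations, in degrees per
  decade: `(mean angle at c_high − mean angle at c_low) / log10(c_high /
  c_low)`. Tested dose series are log-spaced (0.005, 0.05, 0.5, 5 µM), so
  per-decade change is the natural scale; the mock (0 µM) group is
  excluded from the log axis by construction. A more negative slope means
  a stronger response.
* **minimum effective concentration**: the smallest tested dose whose
  angle distribution differs from mock under the one-way ANOVA + Tukey
  procedure — the *sensitivity* readout, complementary to the slope's
  *strength* readout.

## The synthetic generator

Real photographs of this assay come without ground truth, so the package
carries a generator whose geometry makes every target quantity analytic.
A seedling is drawn as a straight hypocotyl joined to a circular arc of
interior angle `hook_angle_true` plus a short cotyledon stub tangent to
the arc end. With an arc, the bisector of the hook angle is exactly the
radial line through the arc midpoint: the true chord runs from the inner
to the outer arc edge and has length `2 × tissue_half_width`, and the
landmarks, vertex and chord endpoints are known in closed form.

Across each tissue cross-section, at relative depth `u` (0 = concave
edge, 1 = convex edge), the staining is `B + S0·exp(−λu)`: a baseline
plus exponential decay, the simplest monotone family with a closed-form
cumulative, for which `analytic_ardi()` solves the half-mass equation to
below 1e−9. Measured staining curves in this assay are empirical; the
exponential family is a modelling choice for verification, not a claim
about GUS chemistry. Noise is additive zero-mean Gaussian, clipped to the
valid intensity range, consumed in a documented order (one column-major
image-sized draw) so seeds are portable. Rendering is anti-aliased by
2× supersampling with block averaging, so edge pixels carry
partial-coverage values and the tissue boundary can be localized to a
fraction of a pixel.

Default study conditions, chosen once as realistic for 8-bit photographs
of this assay and used by the registered scenarios: 256×256 images,
`tissue_half_width` 16 px, background 10, baseline `B = 60`, amplitude
`S0 = 160`, noise sd 8 (5% of `S0`), hook angles drawn uniformly on
120–170 degrees. Scenarios differ only in the decay: `wt_like` (λ = 3,
concave maximum), `hyl1_like` (λ = 0.3, flattened gradient — the
microprocessor-mutant-like condition), `flat_gradient` (λ = 0, ARDI
exactly 0.5) and `concave_shifted` (λ = 6). Angle-table simulations use
the log-spaced dose grid above with Gaussian noise clipped to `[0, 180]`.

What the generator does *not* emulate: cotyledon staining (visible in
real photographs but never quantified — only the hook chord is read),
non-uniform illumination, staining saturation, JPEG artefacts, or
curvature beyond a circular arc. Passing the closure tests therefore
demonstrates that the measurement chain is unbiased on geometrically
clean, well-thresholded images; it does not validate landmark placement
or thresholding on difficult real photographs.

```{r closure, eval = FALSE}
fx <- file.path(tempdir(), "fixtures")
sim <- run_simulate(fx, scenario = "wt_like", n = 10, seed = 1,
                    noise_sd = 0)
res <- run_quantify(fx, file.path(tempdir(), "out"),
                    polarity = "stain_bright",
                    background_threshold = sim$config$background_threshold,
                    step = 0.25)
max(abs(res$summaries$ardi - sim$truth[[1]]$ardi_true))  # < 0.01
```

## Numerical choices and degenerate inputs

* ARDI root: smallest crossing, linear interpolation on the cumulative;
  all-zero profiles raise a degenerate-profile error rather than return an
  arbitrary number.
* Integration: trapezoid on the stored grid; on 101 points the
  discretization error for the profile family above is below 1e−4,
  an order under the measurement noise.
* Chord detection: sampling step 0.5 px by default (0.25 px in the
  closure tests), bilinear interpolation, half-maximum edge refinement;
  a uniform ray raises a no-tissue error, and a tissue run that reaches
  the image border raises an out-of-bounds error rather than returning a
  truncated chord.
* Edge blending: at a finite-resolution tissue boundary the first and
  last ~1 px of samples mix tissue and background; this biases neither
  the chord endpoints (half-maximum refinement) nor, measurably, ARDI
  (closure within 0.01 at zero noise), but pointwise profile values
  inside the 1-px blend zone at each end should not be over-interpreted.
* Zero residual variance in ANOVA (identical values within groups):
  identical means are reported as not different, distinct means as
  separated with certainty, instead of propagating `0/0`.
* RNG: every simulating function takes a `seed` and restores the caller's
  RNG state, so package calls never perturb a user's random stream.

## Known limitations

* Hooks curling past 180 degrees are out of range by design.
* The two-way ANOVA refuses unbalanced designs instead of choosing a
  sums-of-squares type silently.
* Biological-replicate nesting is not modelled (replicates are pooled, as
  in the assay tradition this follows); outputs carry `n` and SD so
  either SEM convention can be derived downstream.
* Dose-response analysis compares two-point slopes; it does not fit
  four-parameter logistic curves.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the generator at 30
seedlings per scenario for recovery experiments, 500 null simulations for
ANOVA calibration, 50 random profiles against a 1e5–1e6-point fine-grid
oracle, and 100 random similarity transforms for geometric invariance —
sizes at which the Monte-Carlo error of each check sits well below the
tolerance it asserts.
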