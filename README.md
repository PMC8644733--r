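# hookquant

Quantification of apical-hook geometry and auxin-reporter staining
gradients in dark-grown seedlings.

Dicot seedlings germinating in darkness form an apical hook whose
maintenance depends on an auxin maximum on the concave (inner) side of the
bend. Two assays dominate the phenotyping of this structure, and
`hookquant` implements both as a reproducible pipeline:

* **Hook angle** — the angle between the hypocotyl axis and the imaginary
  line joining the cotyledons, here with the convention 180° = fully
  closed hook, 0° = fully open, measured from landmark annotations and
  analysed across genotype × day × treatment-concentration tables
  (ANOVA + Tukey letters, dose-response slopes in degrees per decade of
  inhibitor concentration, minimum effective concentrations).
* **Staining gradient along the hook** — reporter staining (e.g.
  DR5::GUS) converted to a scalar signal, read along the *bisector chord*
  of the hook from the concave to the convex tissue edge, normalized onto
  a [0, 1] position axis, and summarised per seedling by

  - the **total integrated intensity** `A = ∫₀¹ g(s) ds` (trapezoidal), and
  - the **ARDI** (Auxin Response Distribution Index): the smallest `s*`
    with `∫₀^{s*} g(s) ds = A / 2`. ARDI is 0.5 for uniform staining,
    < 0.5 when signal concentrates on the concave side, and is invariant
    to overall staining intensity.

Because photographs of this assay come without ground truth, the package
includes a synthetic seedling generator (straight hypocotyl + circular-arc
hook + cotyledon stub, cross-section staining `B + S0·e^{−λu}`, Gaussian
noise) for which the hook angle, chord endpoints, integrated intensity and
ARDI are all known analytically — so every stage of the measurement chain
is testable end to end.

## Worked example

Analytic profile statistics:

```r
library(hookquant)
s <- seq(0, 1, length.out = 101)
prof <- intensity_profile(s, 60 + 160 * exp(-3 * s))
round(c(area = integrated_intensity(prof), ardi = ardi(prof),
        analytic = analytic_ardi(3, 60, 160)), 4)
#>     area     ardi analytic
#> 110.6818   0.3472   0.3472
```

The half-mass point sits at s = 0.347 — well toward the concave side, as
expected for a decay-3 gradient — and the 101-point grid measurement
agrees with the closed form to 4 decimals.

Full image pipeline on simulated seedlings (render → landmarks → bisector
chord → profile → summaries):

```r
fx  <- file.path(tempdir(), "fx"); out <- file.path(tempdir(), "out")
sim <- run_simulate(fx, scenario = "wt_like", n = 6, seed = 42)
res <- run_quantify(fx, out, polarity = "stain_bright",
                    background_threshold = sim$config$background_threshold,
                    step = 0.25)
res$summaries[, c("seedling_id", "area", "ardi", "hook_angle_deg")]
#>  seedling_id  area   ardi hook_angle_deg
#>  wt_like_001 110.3 0.3526          165.7
#>  wt_like_002 109.7 0.3571          166.9
#>  wt_like_003 106.8 0.3487          134.3
#>  wt_like_004 107.8 0.3520          161.5
#>  wt_like_005 107.1 0.3546          152.1
#>  wt_like_006 107.2 0.3428          146.0
```

The measured ARDIs scatter around the scenario's analytic truth (0.3472)
with the expected noise; `out/` now holds `profiles.csv`,
`summaries.csv`, `ensembles.csv`, per-day comparison CSVs and a
machine-readable `run_log.json`.

Dose-response slopes from an angle table (injected slopes −100, −60,
−140 deg/decade, 5° measurement noise, n = 30 per group):

```r
gm <- data.frame(genotype = rep(c("Col-0", "hyl1-2", "se-1"), each = 2),
                 concentration_uM = rep(c(0.005, 0.05), 3),
                 mean_angle = c(160, 60, 150, 90, 170, 30))
tb <- simulate_angle_table(gm, noise_sd = 5, n_per_group = 30, seed = 42)
dose_response_slope(tb, 0.005, 0.05)
#>  genotype day slope_deg_per_decade mean_low mean_high n_low n_high
#>     Col-0   2              -100.95    160.3     59.39    30     30
#>    hyl1-2   2               -61.05    151.0     89.91    30     30
#>      se-1   2              -138.77    168.7     29.92    30     30
```

A less negative slope (`hyl1-2`) means a weaker response to the transport
inhibitor; a more negative one (`se-1`) a stronger response. Group
comparisons print Tukey letter displays:

```r
one_way_anova_tukey(angles, genotypes)
#> One-way ANOVA with Tukey HSD post-test (alpha = 0.05)
#>   group  n     mean       sd letters
#>   Col-0 10 151.2833 4.218947       a
#>  hyl1-2 10 119.6739 5.642405       b
#>    se-1 10 141.8298 6.426137       c
```

A command-line wrapper over the same functions lives at
`inst/cli/hookquant.R` (subcommands `simulate`, `quantify`,
`dose-response`). See the vignette
(`vignettes/hook-gradient-quantification.Rmd`) for the model,
conventions, parameter defaults and limitations.

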