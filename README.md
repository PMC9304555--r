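# somistiff

Stiffness mapping and antero-posterior periodicity analysis of embryonic
somite tissue from AFM force–distance curves.

During early vertebrate development, spinal motor axons grow through the
anterior half of each somite segment and avoid the posterior half. Beyond
the classical chemical guidance cues, the two half-sclerotomes differ
mechanically: AFM indentation of embryonic somite strips shows the
posterior half to be stiffer than the anterior half, with tissue stiffness
varying periodically along the antero-posterior (A/P) axis at the spatial
period of one somite segment. `somistiff` implements the complete
computational chain behind that kind of measurement — from raw approach
force–distance curves to the paired anterior/posterior statistics — for
researchers in tissue mechanobiology who want a tested, scriptable,
fully reproducible version of this pipeline. Because raw AFM recordings of
this type are rarely deposited, the package ships a physics-based synthetic
generator so that every stage can be validated by parameter recovery
against a known ground truth.

## The models at the core

**Hertz contact.** A sphere of radius *R* pressed a depth *δ* into an
elastic half-space experiences

> *F* = (4/3) · *K* · √*R* · *δ*^(3/2),  *K* = *E* / (1 − *ν*²),

where *K* is the apparent reduced elastic modulus (Pa). For each approach
curve the contact point is detected by an exhaustive piecewise-model scan
(flat baseline before contact, Hertzian rise after, with the linear
baseline and *K* profiled out at every candidate), the indentation is
computed as *δ* = *z* − *d* (piezo travel minus cantilever deflection,
measured from contact), and *K* is estimated by least squares over the
contact portion up to the trigger force.

**A/P periodicity.** Per-curve *K* values are assembled into a raster map;
the mean of three dorso-ventral rows gives the A/P profile *y*(*t*), which
is fitted by nonlinear least squares to

> *y*(*t*) = *C* + *α* · sin(*ωt* + *φ*),

initialized at *C*₀ = (max *y* + min *y*)/2, *α*₀ = max *y* − *C*₀,
*ω*₀ = 2π/15 ≈ 0.42 (one segment per fifteen 15-µm steps), and
*φ*₀ ∈ {0, π} depending on whether the strip starts with a posterior or an
anterior half-sclerotome. Goodness of fit is reported as the Pearson
correlation between fitted and observed values.

**Region statistics.** Anterior/posterior half-segment summaries are
compared with a Shapiro–Wilk-gated battery (paired *t*-test when both
samples look normal at *p* ≥ 0.01, a log10 branch when they normalize under
transformation, a Wilcoxon rank-sum test otherwise), and stage-resolved
cell-density tables are compared per somite stage with Wilcoxon tests.

## Worked example

Simulate one somite strip (3 × 45 raster, 15 µm step, sinusoidal truth
with C = 40 Pa, α = 2π Pa, 2 Pa stiffness noise, 5 nm deflection noise),
then run the full analysis:

```r
library(somistiff)

tf     <- make_truth_field(C_true = 40, alpha_true = 2*pi, seed = 1, k_noise_sd = 2)
bundle <- simulate_grid(tf, noise_sd_um = 0.005, seed = 1)
fits   <- fit_grid(bundle)
map    <- assemble_map(fits, step_um = 15)
print(map)
#> Stiffness map: 3 (D/V) x 45 (A/P) at 15 um step, 0 missing cell(s)
#>   K range: 28.4 .. 56.2 Pa

fit <- fit_sinusoid(ap_profile(map), segment_length_points = 15,
                    starts_with = "unknown")
print(fit)
#> Sinusoid fit over 45 points: y(t) = 41.511 + 6.762 * sin(0.4236 t + 6.180)
#>   RSS = 269.9 Pa^2, Pearson R (fitted vs observed) = 0.889

ann <- assign_halves(45, 15, starts_with = tf$starts_with)
cmp <- compare_regions(summarize_regions(map, ann))
print(cmp)
#> Posterior vs anterior half-segments (n = 3, mean of per-segment K):
#>   paired-t: statistic = 8.792, two-tailed p = 0.01269
#>   mean posterior - anterior difference = 7.86 Pa
```

The fitted angular frequency (0.424 rad/step against the generating
2π/15 ≈ 0.419) says the stiffness pattern repeats once per somite segment;
the paired test recovers the posterior-stiffer polarity injected by the
generator. `run_pipeline(somistiff_config(seed = 1))` executes the same
chain end-to-end, persisting every intermediate table with JSON sidecars
and a run manifest.

## Package layout

- `R/` — simulation (`make_truth_field`, `simulate_grid`,
  `simulate_cell_counts`), curve processing (`find_contact_point`,
  `fit_hertz`, `process_curve`), mapping (`assemble_map`, `ap_profile`),
  periodicity (`sinusoid_init`, `fit_sinusoid`, `periodicity_summary`),
  region statistics (`assign_halves`, `normality_gate`, `compare_regions`,
  `compare_density`), file formats and the pipeline runner.
- `vignettes/somite-stiffness-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, and what the
  synthetic validation does and does not show.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
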