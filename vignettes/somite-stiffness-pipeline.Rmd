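---
title: "From force-distance curves to somite stiffness periodicity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From force-distance curves to somite stiffness periodicity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somistiff)
```

`somistiff` turns batches of AFM approach force–distance curves recorded on
embryonic somite strips into spatial maps of tissue stiffness, an
antero-posterior (A/P) periodicity estimate, and paired anterior/posterior
half-sclerotome statistics. This vignette is the package's own account of
the science and of the design decisions behind it: the models and their
assumptions, every tunable parameter with its unit and default, what the
synthetic generator emulates (and deliberately does not), and the numerical
choices that make the pipeline reproducible.

## 1. The measurement model

A sphere-tipped cantilever of spring constant $k_c$ approaches the tissue.
Before contact the deflection $d$ is zero up to noise; past the contact
position $z_0$ the bead indents the sample and the cantilever restoring
force balances the Hertzian contact force:

$$k_c\,d \;=\; \tfrac{4}{3}\,K\sqrt{R}\,\delta^{3/2},
\qquad \delta = (z - z_0) - d,$$

with $R$ the bead radius and $K = E/(1-\nu^2)$ the apparent reduced elastic
modulus, the stiffness measure reported without committing to a Poisson
ratio. The approach stops when the force reaches the set force (the
acquisition trigger). Units are centralized once: piezo position and
deflection in µm, $k_c$ in N/m, force in nN (1 N/m × 1 µm = 1000 nN),
moduli in Pa.

Assumptions inherited from the Hertz model: the sample is an isotropic,
homogeneous, linear-elastic half-space; the indentation is quasi-static
(no viscoelastic rate dependence); adhesion is negligible; and
$\delta \ll R$. The last assumption is *knowingly violated* for very soft
tissue at a 3 nN set force — at $K = 40$ Pa with an 18.5 µm bead the final
indentation is $\delta = (F/(\tfrac43 K\sqrt R))^{2/3} \approx 5.6$ µm,
i.e. $0.3\,R$. The pipeline follows the standard practice of fitting the
Hertz form anyway and reporting $K$ as an *apparent* modulus; every fit
carries a `hertz_small_indentation` flag (FALSE when
$\delta_{\max}/R > 0.3$) so consumers can see when the small-indentation
regime was left.

### Probe defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| `spring_constant` | 0.035 | N/m | midpoint of the 0.03–0.04 N/m soft tipless cantilevers used for embryonic tissue |
| `bead_radius_um` | 18.5 | µm | 37 µm diameter polystyrene bead probe |
| `set_force_nN` | 3.0 | nN | acquisition trigger |
| `approach_speed_um_s` | 10 | µm/s | metadata only; the analysis is quasi-static |

## 2. The synthetic generator: what it emulates

No public raw data of this kind exists, so the generator is a first-class,
tested module, not a fixture. It emulates exactly the structure the
analysis assumes:

* **A periodic stiffness field.** `make_truth_field()` builds
  $K(\text{row}, t) = C + \alpha\sin(\omega t + \varphi)$ on a raster
  (rows = dorso-ventral, columns = A/P, 15 µm step), constant across rows,
  with $\omega = 2\pi/L$ for a segment length of $L$ points (default 15).
  A `"square"` profile places two exact levels $C\pm\alpha$ on the half
  labels instead; it is the calibration used for recovery checks because
  its half means are exact by construction. The phase follows the
  fit's half-order convention: $\varphi = 0$ starts posterior,
  $\varphi = \pi$ starts anterior.
* **Calibration.** The default strip uses $C = 40$ Pa. For the square
  profile $\alpha = 4$ Pa pins the anterior/posterior half means at 36
  and 44 Pa. For the sinusoid the same half means require
  $\alpha = 2\pi$ Pa, since the mean of $|\sin|$ over a half period is
  $2/\pi$; that is the default amplitude.
* **Forward-simulated curves.** `simulate_force_curve()` solves the
  implicit force balance per sample by bracketed root-finding
  ($d \in [0, z - z_0]$, tolerance $10^{-12}$ µm — both sides are monotone
  in $d$, so the bracket is guaranteed), truncates at the first sample
  exceeding the set force, and adds Gaussian deflection noise plus an
  optional linear baseline tilt. The paper-style acquisition gives no
  noise magnitude or sample count, so these are explicit configuration
  defaults, not inferred values: 5 nm deflection noise, 160 samples per
  curve, one third of them pre-contact. When the ramp is built
  automatically the true contact point falls exactly on a sample, which
  makes zero-noise round trips bit-clean.
* **Reproducible rasters.** `simulate_grid()` derives one RNG substream
  per grid point from (seed, row, column), so a bundle is identical no
  matter the traversal order, and any single curve can be regenerated in
  isolation.
* **Cell counts.** `simulate_cell_counts()` draws nucleus counts per
  fixed-area ROI from a negative binomial law
  ($\mathrm{Var} = \mu + \phi\mu^2$, Poisson as $\phi \to 0$; the count
  distribution is a modeling choice, as none is reported for this kind of
  data). Anterior ROIs sit at the baseline density; posterior ROIs at
  baseline × ratio(stage), with ratio 1 before somite stage X and rising
  linearly by 0.1 per stage from X — the stage-dependent posterior
  densification the density analysis is meant to detect. Defaults:
  5 embryos, stages V–XV, baseline 100 nuclei/ROI, dispersion 0.05.

**What the generator does not emulate** — and therefore what passing tests
cannot show about real data: tissue heterogeneity beyond the 1-D periodic
field (no dorso-ventral gradients, no segment-length jitter between
somites), adhesion or viscoelastic force response, instrument drift other
than a linear baseline, correlated noise, partial bead–tissue contact at
segment boundaries, and any imaging realism behind the cell counts
(segmentation errors, ROI placement). Parameter recovery on these
synthetics validates the *estimators*; it cannot certify accuracy on
tissue whose physics departs from the Hertz model.

## 3. Curve processing

**Contact detection.** The published descriptions of this experiment defer
the contact-point method to a citation, so the package treats the strategy
as a documented, replaceable design choice. The implemented default is an
exhaustive scan: every admissible sample is a candidate contact; for each,
the curve is modeled as a linear baseline before the candidate and
baseline + Hertzian rise after it, and the baseline (intercept + slope)
and $K$ are profiled out by a single linear fit over the whole curve. The
candidate minimizing the total residual wins. The scan is deterministic,
exact on noise-free curves, translation-equivariant in $z$, and invariant
to deflection offset and tilt.

Profiling the baseline *inside* the scan matters: correcting the baseline
first with a fixed pre-contact line fit and then scanning lets the line's
estimation error (which is correlated across the whole curve) masquerade
as a contact shift, and simulation shows it roughly triples the spread of
the detected contact. With the baseline as a profiled nuisance the scan
sits at its Fisher-information limit, which for the default acquisition
(5 nm noise, $K = 40$ Pa, 160 samples) is about 0.2 µm. The test suite
asserts that measured accuracy (95% of curves within 0.5 µm, no bias)
rather than a sub-resolution figure the information content cannot
support. A curve whose deflection never rises `noise_mult` (default 6)
baseline-residual SDs above the leading-quarter trend is reported as
"no contact" — an error, not a silent zero.

**Indentation and fit.** Past the detected contact,
$\delta_i = (z_i - z_0) - (d_i - d_0)$ and $F_i = k_c (d_i - d_0)$: the
deflection at contact is subtracted explicitly, a convention the
$\delta = z - d$ shorthand leaves implicit. `fit_hertz()` estimates $K$
by the closed form $K = \sum F_i x_i / \sum x_i^2$ with
$x_i = \tfrac43\sqrt{R}\,\delta_i^{3/2}$ over the contact portion up to
`max_force_nN` (default 3 nN, mirroring the trigger so the fit range
matches acquisition). An optional 1-D search refines a small contact
offset jointly (`refine_contact`, off by default). A negative estimate is
returned flagged `converged = FALSE`; batch processing (`fit_grid`) turns
failures into missing cells, never dropped rows.

## 4. Map, profile, periodicity

`assemble_map()` places fits on the raster by rounding coordinates to the
nearest node (coordinates must land within 10% of the step; duplicates are
an error). `ap_profile()` averages a row selection per A/P step — default
the three central dorso-ventral rows, the "mean of three values" profile;
which three rows of a taller scan to use is not specified anywhere, so the
choice is configurable and recorded in the output metadata. Positions are
reported both as 0-based step index $t$ and in µm.

`fit_sinusoid()` fits $y(t) = C + \alpha\sin(\omega t + \varphi)$ by
Levenberg–Marquardt least squares (`minpack.lm`, relative tolerance
$10^{-8}$, 200 iterations), started from
$C_0 = (\max y + \min y)/2$, $\alpha_0 = \max y - C_0$,
$\omega_0 = 2\pi/L$, and $\varphi_0 = 0$ (posterior start), $\pi$
(anterior start), or both when the half-order is unknown — the lower-RSS
solution wins, ties toward $\varphi_0 = 0$. Because $(\alpha, \varphi)$
and $(-\alpha, \varphi + \pi)$ describe the same curve, parameters are
canonicalized to $\alpha \ge 0$, $\varphi \in [0, 2\pi)$, making the
output unique regardless of where the optimizer lands. Missing profile
points are dropped from the objective, never imputed. The goodness-of-fit
summary is the Pearson correlation between fitted and observed values (not
between model and truth — on real data there is no truth).
`periodicity_summary()` averages $\omega$ and $R$ across strips as
exchangeable replicates, excluding and counting non-converged fits;
a single strip reports sd = 0 by convention.

## 5. Region statistics

`assign_halves()` cuts the A/P extent into consecutive segments of $L$
points and each segment into halves, the anterior half taking the extra
point when $L$ is odd (8 + 7 at $L = 15$); partial terminal segments are
dropped. `summarize_regions()` always records both the mean and the median
per half — both centers are in common use for such summaries — and the
consumer picks one.

The test battery follows the conventional gate: Shapiro–Wilk on each
sample at $p \ge 0.01$; both pass → paired $t$; both pass only after log10
(requires positive values) → paired $t$ on log10; otherwise Wilcoxon. The
Wilcoxon branch is the *rank-sum* (unpaired) test by default, taking that
name at its word even though halves are paired within segments; a paired
signed-rank option sits behind `paired_wilcoxon = TRUE`. Exact Wilcoxon
p-values are used for small tie-free samples, the normal approximation
with mid-rank tie correction otherwise. Zero-variance paired differences
yield a flagged degenerate result rather than an exception, so batch runs
complete. No multiple-testing correction is applied across somite stages
(densities are reported per stage); nothing prevents applying
`p.adjust` downstream.

Cell-density normalization has two defensible readings, so both are
implemented: `"mean-of-all-ROIs"` (default; each count divided by its
embryo's grand mean — per embryo, to remove embryo-level size effects) and
`"relative-to-anterior"` (posterior counts divided by their paired
anterior count). The scheme is recorded in the output.

## 6. Numerical choices and degenerate inputs

* Root-finding for the forward model: Brent bracketing on $[0, z - z_0]$,
  tolerance $10^{-12}$ µm; the residual force balance is verified in tests
  to $<10^{-6}$ nN at every sample.
* The contact scan requires at least 8 samples on each side of a
  candidate; curves shorter than ~18 samples are rejected.
* Constant profiles make the sinusoid initialization degenerate
  ($\alpha_0 = 0$) and are rejected with an explicit error; profiles
  shorter than two segments likewise.
* Optimizer non-convergence from every phase start returns a
  non-converged result carrying the optimizer messages — summaries count
  these rather than aborting.
* All CSV artifacts serialize numbers as decimal text at 9 significant
  digits, so write → read → write reproduces identical bytes across
  platforms; JSON sidecars carry probe metadata, seeds, truth parameters
  and the configuration hash of the run that produced them.
* `run_pipeline()` executes simulate → fit-curves → map/profile →
  periodicity → stats from a validated configuration (unknown keys
  rejected; a seed is mandatory whenever simulation runs), persists every
  intermediate, and writes a manifest with stage timings and warnings.
  The same configuration and seed reproduce all numeric outputs.

## 7. Validation scale and limitations

The shipped tests validate the chain at desk scale: strips of 3 × 45 to
3 × 105 points, 160 samples per curve, 100–200 seeds for the simulation
studies — sizes chosen so the full suite runs in well under a minute per
module while keeping Monte-Carlo margins comfortable. Noise-free round
trips recover $K$ to machine precision across 10–100 Pa; under the default
5 nm noise the per-curve median $K$ stays within 5% and the recovered
frequency of the default strip within a few percent of the generating
value.

Known limitations, restated plainly: the Hertz fit reports an apparent
modulus outside its small-indentation regime for soft tissue; the contact
detector's precision is information-limited (~0.2 µm at the default
acquisition), which matters for thin or very soft samples; segment
boundaries are taken as exactly periodic (no per-somite length jitter);
the unpaired Wilcoxon branch discards pairing information by design
fidelity rather than statistical optimality; and the synthetic validation
speaks to estimator correctness, not to the adequacy of the Hertz model
for real sclerotome tissue.
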