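---
title: "Modelling visual-acuity performance fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling visual-acuity performance fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Human vision is not uniform around fixation. At a fixed eccentricity,
performance on most visual tasks is better along the horizontal meridian
(HM) than the vertical meridian (VM) — the *horizontal–vertical anisotropy*
(HVA) — and better on the lower than the upper vertical meridian — the
*vertical-meridian asymmetry* (VMA). These polar-angle patterns are called
*performance fields*. For visual acuity they can be quantified by measuring
orientation-discrimination accuracy for gratings of varying spatial
frequency (SF) at isoeccentric locations and asking how the highest usable
SF changes with the angular distance from the VM.

`acuityfields` implements that analysis as a reusable, fully testable
pipeline. Because raw observer data are not redistributable, the package
includes a first-class synthetic-observer module whose ground truth is the
set of fitted linear equations relating log10 SF estimates to angular
distance; every downstream stage (psychometric fitting, criterion
inversion, mixed models, asymmetry summaries) can therefore be validated by
parameter recovery.

## The psychometric model

Accuracy at one location is modelled as a decreasing cumulative normal of
log10 spatial frequency,

$$f(\mathrm{SF}) = \gamma + (1 - \gamma - \lambda)\,
  \Phi\!\big(\beta\,(\alpha - \log_{10}\mathrm{SF})\big),$$

with guess rate $\gamma = 0.5$ (two-alternative task, fixed), lapse rate
$\lambda$ (estimated in $[0, 0.1]$, a standard lapse ceiling), location
$\alpha$ (log10 cpd) and slope $\beta$ (per log10 cpd). Writing the model
as decreasing in SF is equivalent to fitting an increasing cumulative
normal on the sign-flipped log-SF axis.

Two criterion points summarise each location:

* **SF threshold** — the SF supporting 75%-correct discrimination,
* **SF cutoff** — the SF at which accuracy falls to 51% (effectively
  chance).

Both have closed forms,
$x_p = \alpha - \Phi^{-1}\!\big((p-\gamma)/(1-\gamma-\lambda)\big)/\beta$,
implemented in `invert_performance()`. The slope is reported as the
*maximum slope* $\beta' = (1-\gamma)\,\beta/\sqrt{2\pi}$, the steepest
derivative of the fitted curve, which is comparable across
parameterisations.

Fitting (`fit_psychometric()`) maximises the binomial likelihood of the
per-SF correct counts. Numerical choices:

* parameters bounded ($\alpha \in [\log_{10}1, \log_{10}24]$,
  $\beta \in [0.5, 100]$, $\lambda \in [0, 0.1]$);
* deterministic multi-start grid ($\alpha$ at nine quantiles of the
  observed log SFs, $\beta \in \{2, 8, 32\}$, $\lambda \in \{0, 0.05\}$);
  starts are ranked by likelihood and bounded quasi-Newton optimisation
  (`nlminb`) is run from the best five, which reaches the same optimum as
  optimising from every start at a fraction of the cost;
* probabilities are clipped to $[10^{-9}, 1-10^{-9}]$ inside the
  likelihood so it stays finite; at these data sizes the clip never moves
  the optimum;
* likelihood plateaus within $10^{-6}$ are resolved by preferring the
  smallest $\lambda$, then the smallest $\beta$ (the simplest curve);
* all-correct or all-incorrect data (or a single SF level) cannot
  constrain the curve: such fits are flagged `degenerate` rather than
  raising, and their estimates propagate as `NA`.

The fit optimum is verified in the test suite against an independent
brute-force grid search of the same likelihood.

## The experimental design being emulated

The design tests 24 isoeccentric locations (10 deg eccentricity, 15°
polar-angle steps; adjacent centres are $2 \times 10 \sin 7.5^\circ \approx
2.6$ deg apart). Each 300-trial block tests four locations separated by
90°, rotated from the VM by 0°–90° in 15° steps; each location's SF grid
holds 13 values in 0.25-cpd steps around a centre plus the fixed anchors 2
and 12 cpd that pin the asymptotes (15 values; near-anchor centres are
clamped to $[2, 12]$ and deduplicated, a boundary rule the source design
leaves unspecified).

The default schedule (`schedule_blocks()`) is 4 sessions of 7 blocks
cycling the seven rotations. Because the rotation-0 and rotation-90 layouts
both land on the four cardinals, cardinals accumulate 8 blocks (600
expected trials) and noncardinals 4 blocks (300), matching the reported
cardinal oversampling ("tested twice more") and per-location trial bands
(621 ± 85 and 331 ± 48). The exact session-to-rotation mapping is not
documented for the original study; cycling rotations is the simplest
integer schedule inside those bands. `cardinal_extra_blocks` adds further
cardinal blocks without breaking the 300-trial block structure.

Between blocks, each location's grid centre is re-set to the running fitted
threshold, rounded to the grid step (0.25 cpd), clamped to $[2.25, 11.75]$,
and only moved when the change exceeds a 0.5-cpd dead band
(`recenter_sf_grid()`). The source procedure says only that ranges were
adjusted "if needed" to stay centred on the dynamic range; the dead band
and rounding are this package's concrete rule. Recentring matters: with a
fixed 7-cpd centre, VM locations of low-acuity observers would leave the
falling flank of the psychometric function unsampled between the 2-cpd
anchor and the lowest centred value, degrading threshold recovery.

## The synthetic observer

`performance_field_model()` holds, per visual field and viewing condition,
linear ground-truth equations for the log10 threshold and cutoff as a
function of angular distance $d$ from the VM. The defaults are the fitted
equations from the study being modelled:

* binocular cohort (14 observers): threshold $0.7083 + 0.00194\,d$ (upper
  VF), $0.7922 + 0.00115\,d$ (lower VF); cutoff $0.8326 + 0.00197\,d$ and
  $0.9067 + 0.00114\,d$;
* two-condition cohort (7 observers): the per-condition VF-averaged
  equations (monocular threshold $0.7085 + 0.00151\,d$, binocular
  $0.7406 + 0.00150\,d$; cutoffs $0.8188 + 0.00186\,d$ and
  $0.8545 + 0.00147\,d$), split into per-VF lines using the binocular
  cohort's upper–lower offsets, since no per-VF-by-condition equations are
  published. The two tables are kept separate because the cohorts differ
  (their VF-averaged binocular intercepts disagree by ~0.01 log10 cpd).

From the two lines at a location, `params_from_truth()` solves for the
unique $(\alpha, \beta)$ whose 75% and 51% points sit exactly on them, so
$\beta$ varies smoothly with polar angle exactly as the two lines imply.
Design choices:

* **Lapse defaults to 0** so that the printed threshold *and* cutoff lines
  are simultaneously exact ground truth; the original analysis estimates
  $\lambda$ but never reports it. A nonzero `lambda` is available for
  robustness studies.
* **Observer variability**: each observer has a random intercept $u_i$
  added to both lines, $u_i \sim N(0, \sigma_{\mathrm{obs}}^2)$ with
  $\sigma_{\mathrm{obs}} = 0.06$ log10 cpd by default — chosen (as a
  package default, not a published value) to match the reported
  between-observer SDs of about 1 cpd around 7.8 cpd at the HM.
* **Centred draws**: `draw_observers()` centres the i.i.d. draws to exact
  zero mean by default. With 7–14 observers the sample mean of uncentred
  intercepts alone has SD 0.016–0.023 log10 cpd, which would dominate any
  cohort-level recovery comparison; centring makes the simulated cohort's
  mean lines equal the specified population lines, so recovery error
  measures the pipeline, not cohort sampling. `center = FALSE` restores
  strictly i.i.d. draws.
* **Horizontal meridian**: the upper- and lower-VF lines disagree slightly
  at $d = 90$; the HM ground truth is their mean, and in the visual-field
  mixed models the HM estimates are duplicated into both VF groups (each
  VF is reported with seven distance levels including 90°).
* **Conditions** enter only through the per-condition line table; the same
  $u_i$ applies to both conditions of an observer.
* **Randomness**: one master seed; observer-by-condition substreams are
  derived deterministically from it, and the between-block recentring fits
  are deterministic, so trial tables are byte-reproducible.

What the generator does **not** emulate: orientation-specific biases, eye
dominance and nasal/temporal differences, learning or fatigue across
sessions, serial dependence, fixation instability, and any non-Bernoulli
trial dependence. Passing recovery tests therefore shows the pipeline is
consistent and unbiased under the stated statistical model, not that real
data meet that model.

## Asymmetry statistics

`fit_angular_model()` fits
$y \sim d \times \mathrm{VF} (\times \mathrm{condition}) + (1 \mid
\mathrm{observer})$ by maximum likelihood (lme4). ML rather than REML keeps
likelihoods comparable across fixed-effect structures, and on the balanced
designs used here the fixed effects coincide with ordinary least squares
either way (verified against an OLS oracle to $10^{-6}$). Visual field is
coded $\pm 0.5$ (upper $-0.5$, lower $+0.5$) and condition $\pm 0.5$
(binocular $+0.5$), so the distance main effect is the group-averaged
slope and per-group lines are main effect $\mp$ half the interaction; the
derived lines are returned directly in `$lines`. When a factor is not a
predictor, estimates are first averaged over it within observer and
distance — this reproduces both the VF-averaged and per-VF
parameterisations of the published equations from one estimates table.

`cardinal_asymmetries()` computes HVA = HM/VM and VMA = LVM/UVM ratios on
the linear (cpd) scale, per observer and from group means.
`rm_anova()` provides the repeated-measures ANOVAs (via a multivariate
linear model, car's Type-III decomposition) with Greenhouse–Geisser epsilon
estimated from the sample covariance of the within-subject cells,
partial $\eta^2 = SS_e/(SS_e + SS_{err})$, and both corrected and
uncorrected degrees of freedom; two-level factors are trivially spherical
($\varepsilon = 1$). `paired_t_cohen()` and `pearson_r()` cover the paired
comparisons and the HVA–VMA correlation. No multiplicity correction is
applied anywhere (none is applied in the source analysis); p values are
reported raw.

`accuracy_ratio_by_sf()` computes the raw-accuracy HVA and VMA ratios per
SF level, keeping levels whose pooled accuracy lies in $[0.55, 0.95]$ (the
package's concrete reading of "within the dynamic range") and at least 4
contributing observers, reporting the observer count per point.

## Problem sizes and reproducibility

The full-scale study conditions are 14 binocular observers (and 7 in the
two-condition variant) at ~600 trials per collapsed location; one such
simulation plus all fits takes roughly half a minute. The test suite runs
the full-scale recovery at ten master seeds and checks single-seed
tolerances (±10% relative on slopes, ±0.02 log10 on intercepts) plus
agreement of the across-seed mean with the generating values within two
Monte-Carlo standard errors; an additional unbiasedness property uses 20
seeds at a reduced design (6 observers, one session) where the same checks
apply with proportionally wider Monte-Carlo bands.
`scripts/acceptance.R` reruns the two full-scale pipelines at a
user-supplied seed and writes the recovered line parameters as JSON.

## Known limitations

* Because the HM ground truth is the average of the two VF lines and HM
  estimates enter both VF groups, the *expected* per-VF regression line
  under the generator differs slightly from the raw generating line (the
  upper-VF threshold slope by about +2%, exactly derivable from the
  noise-free expectations). Recovery tests account for this implied
  expectation.
* SF-cutoff estimates carry a small negative finite-sample bias (a few
  thousandths of a log10 unit at the vertical meridian, i.e. ~0.5%):
  with a true lapse of zero, the estimated lapse is bounded below at zero
  and the threshold-centred grids sample the 51% tail sparsely, so the
  extrapolated cutoff sits slightly low on average. The effect is several
  times smaller than the recovery tolerances and would equally affect any
  maximum-likelihood analysis of this design.
* The per-VF-by-condition ground-truth lines are a reconstruction (printed
  per-condition averages plus the binocular cohort's VF offsets), not
  published equations.
* Mixed-model inference is Wald-based (normal-approximation CIs and t
  statistics); no Satterthwaite/Kenward–Roger degrees of freedom.
* Confidence intervals for psychometric parameters themselves (bootstrap
  or Bayesian) are out of scope, as are adaptive staircases and
  alternative sigmoids (Weibull, logistic).
* `rm_anova()` always reports GG-corrected values alongside uncorrected
  ones; it does not implement a Mauchly-test decision rule.
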