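---
title: "Methods: follicle mechanics and Myosin dynamics"
author: "follicleMech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: follicle mechanics and Myosin dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(follicleMech)
```

This vignette is the package's account of its models, parameter choices and
numerical decisions. The pipeline quantifies three kinds of raw data from
Stage 9 *Drosophila* follicles — AFM approach force curves, fixed
two-channel confocal images (pMRLC and phalloidin), and single-channel
time-lapse movies of MRLC-GFP puncta — together with distance tables for the
migration-index statistic. Since raw data of this kind are rarely deposited,
a synthetic-data module with exact ground truth backs every claim the test
suite makes.

## AFM: windowed Hertz-cone fits on a layered tissue

### Contact model

A conical tip indenting an elastic half-space follows the Sneddon form

$$F = \frac{2}{\pi}\tan(\alpha)\,\frac{E}{1-\nu_s^2}\,\delta^2,$$

with half cone angle $\alpha$ (20° by default, a standard silicon nitride
probe), sample Poisson ratio $\nu_s$ (0.5: soft tissue treated as
incompressible), indentation depth $\delta$, and Young's modulus $E$. Units
are mixed for convenience: depth in nm, force in nN, modulus in kPa. A
follicle is not a half-space: a stiff basement membrane wraps much softer
nurse cells. The standard protocol handles this by fitting the *same* model
over two depth windows — 20–100 nm, where the response is dominated by the
basement membrane, and 310–550 nm, dominated by the nurse cells — and
reporting one apparent modulus per window. The windowed fit is a
zero-intercept least squares of $F$ on $\delta^2$: exact for the model,
deterministic, and free of initialization, unlike a nonlinear optimizer.
With a finite tip modulus the slope instead yields the reduced modulus
$1/E^* = (1-\nu_s^2)/E_s + (1-\nu_t^2)/E_t$ ($\nu_t = 0.25$), from which
$E_s$ is solved; the default treats the tip as rigid, and each fit records
which treatment was used. "Tip depth" windows are interpreted as sample
indentation $\delta$, not raw piezo travel, since the fitted object is a
force–indentation curve; both window ends are configurable.

### The two-layer surrogate

The generator models layering as a depth-dependent apparent modulus
$E_{\text{app}}(\delta)$ blending logistically from the shallow to the deep
value across a 150–300 nm window — between the two fit windows. This is a
surrogate, not a layered-elasticity solution: its purpose is that windowed
fits recover the set moduli, which is exactly how the analysis treats real
follicles. Two shape choices matter:

- the blend midpoint sits at 40% of the window with rate = width/5.5. A
  steeper logistic would saturate harder but makes the forward force
  $F \propto E_{\text{app}}(\delta)\delta^2$ *non-monotone* when a stiff
  shell overlies a much softer layer (the force lost to the falling modulus
  outruns the $\delta^2$ growth). The chosen shape keeps the force monotone
  at the strongest contrast in the study conditions (24.2 over 10.1 kPa)
  while both fit windows still see their plateau to well under 1%.
- in contact, the tip advances less than the piezo by the cantilever
  deflection; the generator solves $\delta + F(\delta)/k = z - z_0$
  self-consistently per piezo position (damped Newton, the map is smooth and
  monotone), so simulated curves have the same deflection-coupled geometry
  as real ones.

Acquisition defaults are fixed once as the study conditions: spring constant
0.12 N/m, maximum force 3 nN (mid of the 1–5 nN range used on follicles,
and enough to drive indentation past 550 nm at the stiffest cohort), piezo
step 2 nm, pre-contact span 600 nm (leaving > 30% of the sweep as baseline,
matching the estimator's default baseline fraction), and additive Gaussian
force noise with SD equal to 1% of the maximum force — no instrument noise
figure is published for this setup, so 1% of full scale is the package's
choice, exposed in configuration.

### Contact-point estimation

No contact-point method is stated for the original analysis, so the package
defines one: baseline statistics over the leading 30% of the sweep; the
candidate is the first sample whose deflection exceeds baseline mean +
3 SD and stays above for 5 consecutive samples; refinement then fits the
piecewise model $F = a\,\max(0, (z - z_0) - d)^2$ (zero before contact,
quadratic after, with $d$ the measured deflection) by least squares over a
segment spanning the baseline tail and roughly the first 120 nm of contact,
profiling $z_0$ with a 1-D minimizer. Three numerical points:

- the segment is anchored at the threshold crossing and chosen *once*;
  re-selecting it iteratively as $z_0$ updates can walk the estimate away
  from the kink at realistic noise and was rejected.
- 120 nm keeps the segment inside the shallowest mechanically uniform
  region (the 20–100 nm window plus margin); extending deeper adds signal
  but biases $z_0$ when the modulus drifts with depth.
- the estimator returns a 1-$\sigma$ uncertainty from the
  profile-likelihood curvature, with the noise variance taken from the
  baseline (model-free) rather than fit residuals.

On noiseless curves the estimate is exact to well under a piezo step. At
the default noise the per-curve jitter is ~12 nm — at the local
Cramér–Rao floor for this noise level and segment, so downstream code
treats it as irreducible and corrects its consequences instead.

### Attenuation correction and cohort calibration

A zero-mean contact error $e$ shifts every depth, inflating the expected
windowed slope by $1 + \mathrm{Var}(e)\,\Sigma\delta^2/\Sigma\delta^4$.
`fitHertzCone()` divides this factor out using the estimator's reported
uncertainty; it amounts to a few percent for the shallow window and is
negligible (< 0.1%) for the deep one. Second-order effects (window
selection by noisy depth, correlation between the contact fit and the
window fit, layer-contrast sensitivity of the detection point) leave a
residual cohort-level bias of a few percent in the shallow window whose
sign depends on the layer contrast. `recoverStiffnessCohort()` therefore
calibrates at the cohort level by parametric bootstrap: simulate `nBoot`
cohorts of the same size at the estimated moduli and acquisition settings
(reconstructed from the curves), push them through the identical chain, and
divide out the measured mean recovery ratio per window. The deep window's
factor stays within 1% of unity; the shallow factor absorbs the
contrast-dependent bias. What cannot be removed is seed noise: with 50
indentations at 1% of 3 nN noise the shallow cohort mean carries ~3%
standard error (the deep window, ~0.7%), so occasional draws land several
percent from truth. That scatter is a property of the study conditions,
not of the estimator.

## Fixed-image quantification

All ratios are built to cancel acquisition gain. Pixel coordinates are
1-based (row, col), the R convention; physical lengths use the pixel size
in µm/px.

- **Membrane line profiles.** Both channels are sampled along a line at
  ~1 px spacing with bilinear interpolation and smoothed with a 3-sample
  moving average (manual peak reading is implicitly smoothed; the window is
  configurable). The pMRLC peak is located on the smoothed profile and
  phalloidin is read at the same sample index — following the "at the same
  point" convention; reading phalloidin at its own local peak is the noted
  alternative and is not what the package does. Three lines per follicle are
  averaged, and per-follicle scores are normalized to the control-group mean
  of the same experimental batch (batch-wise, never against a pooled
  control), which pins the control's normalized mean at exactly 1.
- **Cluster ratio.** Mean pMRLC over the cluster mask divided by the mean
  over the identically shaped mask translated into nurse-cell cytoplasm.
  The translation is a configured vector rather than a manual placement, for
  reproducibility; placements that leave the image or land on the membrane
  mask are rejected.
- **Puncta.** Fixed-image puncta are detected automatically in place of
  manual counting: background = median over the cluster mask, robust SD =
  MAD (falling back to the plain SD when the MAD is zero, as on noiseless
  scenes, so the threshold factor never degenerates), threshold = background
  + 3 robust SDs, connected components of ≥ 4 px. Punctum length is the
  Feret diameter over member pixel centers × pixel size.

The image generator renders membrane segments (enriched in both channels by
independent fold factors), a cluster region enriched in pMRLC only,
optional Gaussian puncta, and counting-like noise
(SD $=\sqrt{a \cdot I}$). Ground-truth ratios are computed on the noiseless
scene by direct pixel arithmetic, making them exactly gain-invariant.
Puncta are placed with a minimum Chebyshev separation exceeding their
±4σ rendered footprint so that distinct ground-truth objects remain
distinct connected components even under a degenerate noiseless threshold.

## Myosin puncta dynamics

Lifetimes live on the frame grid. The generator gives each punctum a
duration in *frames* drawn from a geometric distribution on {1, 2, …} whose
mean times the 30 s interval equals the target mean lifetime; the tracker
measures first-present to first-absent, i.e. frames present × 30 s, so a
single-frame punctum has lifetime 30 s, not 0, and the two conventions
agree without discretization bias. Linking is greedy nearest-neighbour
between consecutive frames within a 4 px gate — adequate and deterministic
at the sparse densities of these movies (ties broken by distance, then
detection index; exact ties are measure-zero for continuous centroids).
There is no gap closing (`maxGap` would be 0): the biological definition
ends a lifetime when the punctum has disappeared completely, so absence in
one frame terminates the track. Tracks present in the final frame are
censored and excluded from mean lifetimes, along with their count; puncta
already present at movie start are simply tracks born in frame 1 and are
not distinguished — their left truncation is invisible to a
first-present convention, a known approximation at these lifetimes. The
mean over uncensored tracks is slightly deflated by right-truncation (long
lifetimes are likelier to be censored); at the movie sizes used below this
is a ~2% effect, well inside the stochastic tolerance, and is left
uncorrected because the published statistic is the plain mean over
complete lifetimes.

## Statistics

The default two-group test is Welch's unequal-variance t (recorded in each
result); the Student form is available. One-way ANOVA with Tukey HSD covers
three or more groups. Note that Tukey's adjusted p dominates the
*pooled-MSE* pairwise comparison (Fisher LSD) — that is the statistic it
adjusts; a separate two-sample t with per-pair variances can occasionally
exceed it, which is a property of the procedures, not an error. Stars
follow the legend convention (\*\*\*\* < 0.0001 ≤ \*\*\* < 0.001 ≤ \*\* <
0.01 ≤ \* < 0.05).

## Problem sizes and determinism

Every random step takes an explicit seed, and generators restore the
caller's RNG state. The validation suites use: 50-indentation cohorts per
genotype for stiffness recovery (seconds each after the cohort's
deterministic sweep is computed once and reused across curves); movies of
181 frames at 3 births/frame (≥ 500 uncensored puncta, Monte-Carlo error
~4% of the mean lifetime) for lifetime recovery; and small fixed scenes for
the exactness checks. Noiseless exactness is asserted at 1e-6 (Hertz) and
1e-9 (image ratios) relative; stochastic recoveries at 5% (stiffness
cohorts) and 10% (lifetimes).

## What the generators do and do not emulate

They emulate the measurement geometry and noise structure: deflection-
coupled indentation, baseline drift-free sweeps, gain-invariant enrichment
ratios, counting-like image noise, frame-grid lifetimes, censoring at the
movie end. They do not emulate viscoelasticity or adhesion (no retract
analysis), tilt/virtual-deflection artifacts, photobleaching, drift,
sub-pixel spot motion, 3-D structure, or realistic follicle morphology.
Passing recovery tests therefore demonstrates that the analysis chain is
correct and unbiased under its stated model — not that the model captures
every property of real follicle data.

## Known limitations

- The shallow-window cohort mean carries irreducible ~3% seed noise at the
  default noise level (information floor of the contact problem).
- Greedy linking can, rarely, chain a new punctum born within the gate of
  one that just died; the generator's separation constraint makes this
  negligible in validation, and real movies at higher densities would need
  global assignment.
- The cluster/cytoplasm ratio trusts the supplied masks; no segmentation of
  real clusters is attempted.
- Repeated indentations at one position are treated as independent
  indentations, following the one-point-per-indentation convention of the
  cohort plots.
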