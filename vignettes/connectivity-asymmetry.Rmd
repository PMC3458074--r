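---
title: "Seed connectivity, hemispheric asymmetry, and FA laterality with fcasym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed connectivity, hemispheric asymmetry, and FA laterality with fcasym}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcasym)
```

## The analysis model

`fcasym` implements a seed-based resting-state functional connectivity
(RSFC) analysis built around hemispheric laterality. The scientific
object is a bilateral seed region pair — in the motivating application,
the cognitive division of the anterior cingulate cortex — sitting on a
left–right *symmetric* voxel grid, so that mirroring a statistical map
across the midline is an exact index permutation and left-seed and
right-seed connectivity maps become directly comparable voxel by voxel.

Per subject the chain is:

1. **Cleaning.** Each voxel series is detrended, band-pass filtered
   (default 0.01–0.08 Hz, the conventional low-frequency resting band),
   and orthogonalized against nuisance regressors, optionally including
   the global mean signal (on by default; its use is standard but
   debated, hence the switch).
2. **Connectivity mapping.** The seed signal is the unweighted mean
   series over the ROI voxels; the map is the voxelwise Pearson
   correlation with that signal, variance-stabilized by the Fisher
   transform $z = \operatorname{atanh}(r)$. Correlations at exactly
   $\pm 1$ are clipped to $\pm(1 - 10^{-7})$ so $z$ stays finite; clip
   counts are reported on the map.
3. **Laterality contrast.** The right-seed Z-map is left–right flipped
   and subtracted from the left-seed Z-map. On the contrast, the right
   half of the brain compares each seed with its ipsilateral hemisphere
   and the left half with its contralateral hemisphere.

Group inference uses voxelwise one-sample t maps (within-group
networks), paired t maps on left-seed versus flipped right-seed Z-maps
(within-group asymmetry), and pooled-variance two-sample t maps
(between-group differences; Welch available). Significance is assessed
by two-tailed voxel thresholds combined with Monte-Carlo cluster-extent
correction in the AlphaSim tradition: `simulate_cluster_null()` draws
i.i.d. standard-normal volumes, smooths them to a configurable FWHM,
thresholds two-tailed at the nominal voxel $p$, and records the maximum
suprathreshold cluster extent; `extent_threshold()` converts the null
into the minimal extent $k^*$ whose familywise exceedance probability is
at most $\alpha$.

The DTI arm computes fractional anisotropy from tensor eigenvalues,

$$\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
  \frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},$$

ROI mean FA per hemisphere, and the asymmetry index
$\mathrm{AI} = (\mathrm{right}-\mathrm{left})/[0.5(\mathrm{right}+\mathrm{left})]$,
negative for leftward (left > right) asymmetry. Group tests are pooled
two-sample t on left FA, right FA and AI, plus a one-sample t of AI
against zero per group (the laterality test). Brain–behavior association
uses Pearson correlation with two-tailed p from
$t = r\sqrt{(n-2)/(1-r^2)}$ and Bonferroni adjustment over the family of
tested pairs; imaging measures are extracted from 3 mm-radius spheres
around between-group peak voxels (voxel-center distance, inclusive — on
a 3 mm grid that is the 7-voxel cross).

## The synthetic-data generator

Because subject-level imaging data for studies of this design are
rarely shareable, every stage is exercised on synthetic data with
planted structure (`sim_config()`, `generate_bold()`, `generate_fa()`,
`generate_behavior()`). The generator emulates the study design the
package targets:

* grid 24 × 28 × 24 voxels at 3 mm isotropic (27 mm³ per voxel, so the
  familiar extent–volume pairs 14 → 378, 13 → 351, 10 → 270 mm³ hold);
  the first axis is the flip axis and must have even extent so every
  voxel has a mirror partner and the flip needs no interpolation;
* two groups ("control", "patient") of 30 subjects for the functional
  arm and 29/24 for the DTI arm;
* per seed side a latent unit-variance AR(1) series (default lag-1
  correlation 0.3, giving a realistic effective df; the temporal noise
  model is otherwise unconstrained by the design, so AR(1) is a package
  choice); seed-ROI voxels carry the latent plus noise, and each target
  voxel carries $w\,s(t) + \sqrt{1-w^2}\,\varepsilon(t)$, so with unit
  noise SD the population correlation with the latent is exactly $w$;
* default couplings: a bilateral striatum-like pair at $w = 0.6$ in
  controls reduced to $0.3$ in patients, a frontal pair with a
  right-greater-than-left coupling asymmetry (0.55 vs 0.40) that
  increases in patients, and a posterior region with negative coupling
  that strengthens in patients;
* per-subject ROI FA drawn from truncated normals at the study's
  reported group means/SDs (left 0.525/0.505, right 0.471/0.433),
  planting both the leftward asymmetry and the right-hemisphere patient
  deficit; in eigenvalue mode each ROI voxel gets an axially symmetric
  tensor whose FA equals the drawn value exactly, so the FA computation
  recovers the table to machine precision;
* a behavioral table at the study's printed means/SDs (Stroop condition
  times and accuracies, symptom subscales with total = sum of subscales,
  onset age, illness duration, medication dose), fixed female counts
  12/30 and 13/30, one subject per group missing Stroop data, and a
  planted correlation $\rho = -0.532$ between the FA asymmetry index and
  the negative-symptom score in patients;
* acquisition defaults $T = 120$ volumes at TR = 2 s are stand-ins (the
  design's acquisition parameters are not pinned by the package) and are
  configurable.

With `mirror = TRUE` the two seed latents are shared and the noise field
is mirrored voxel-for-voxel, making the 4D data exactly left–right
symmetric; the entire asymmetry pipeline then returns *identically* zero
contrasts (bit-exact, not merely small), which the test suite pins.

What the generator does **not** emulate: scanner artifacts, motion,
physiological noise, spatially varying autocorrelation, anatomical
realism, or registration error. Passing tests therefore demonstrate the
correctness and calibration of the statistical machinery under the
stated generative model, not robustness to real-data artifacts.

## Numerical and design choices

**Cleaning is one orthogonal projection.** A naive chain —
detrend, then filter, then regress — is not idempotent: the trend basis
has in-band energy, so each stage partially reintroduces what an earlier
stage removed (a second pass changed the output by about 6% relative
norm at $T = 60$ in our measurements; this is the well-known modular
pipeline reintroduction problem). `clean_bold()` therefore band-passes
the data *and* the nuisance design (trend basis plus confounds) and
projects the filtered nuisance out of the filtered data, removing the
residual global mean last. The output is simultaneously trend-free,
in-band and confound-orthogonal, the cleaner is exactly idempotent, and
the cleaned data have an exactly zero global mean series. The
stand-alone `detrend()`, `bandpass()` and `regress_confounds()`
operations remain available and individually exact.

**Band-pass by FFT masking.** Discrete Fourier bins whose folded
frequency lies outside [low, high] (edges inclusive) are zeroed. The
response is exactly reproducible: an in-band bin-aligned sinusoid is
untouched, an out-of-band one removed entirely; no filter-design
ambiguity.

**Cluster null without data-driven rescaling.** The smoothing kernel is
normalized so that smoothed white noise has *exactly* unit marginal
variance everywhere, including at grid edges (the separable
truncated-kernel variance is divided out per voxel). Consequently no
sample re-standardization of the simulated field is needed — and none is
applied, because standardizing by the sample SD of a small mask visibly
distorts the suprathreshold rate (we measured 0.0245 instead of the
closed-form 0.0488 for the probability of any suprathreshold voxel on a
50-voxel mask at voxel $p = 0.001$).

**Strict extent rule.** "Cluster size > k voxels" is read literally:
clusters survive only with extent strictly greater than `min_extent`, so
the conventional `> 14` rule keeps 15-voxel clusters and kills 14-voxel
ones;
`extent_threshold()` returns the minimal significant extent $k^*$, and
`correct_map(min_extent = kstar - 1)` retains extents $\ge k^*$. The
boundary is pinned by tests.

**Correction regimes.** Within-group connectivity: voxel $p < 0.001$,
extent > 14. Within-group asymmetry: $p < 0.001$, extent > 10, plus the
two-criterion rule — a paired-t cluster counts only where it intersects
the union of the corrected left-seed and flipped-right-seed maps, and
extents are *not* re-checked after intersection (the regimes' interaction
order is ambiguous in the tradition this follows; the choice is pinned by
a test). Between-group connectivity: $p < 0.001$, extent > 10, corrected
inside the *union* of the two within-group significant maps ("combined"
could mean union or intersection; union is implemented, giving the more
inclusive search region). Between-group asymmetry: $p < 0.01$,
extent > 13, inside the union of the two corrected within-group
asymmetry masks. Cluster connectivity defaults to faces-only
(6-neighborhood), configurable to 18 or 26.

**Seed summary.** The seed series is the unweighted ROI mean; a first
eigenvariate would be the main alternative, but the mean matches the
symmetric-ROI construction (mirrored data give bit-identical left and
right seed means) and is what the flip-exactness guarantees rely on.

**Post-hoc region direction.** "Mean t of a region, tested by one-sample
t" is implemented as subject-level region means followed by a group
one-sample t — the only version computable per subject; the region mean
of the group t-map is available from the corrected maps directly for
reporting.

**Degenerate inputs.** Voxels with zero across-subject variance get
$t = 0$ and are counted (so an all-constant map is flagged rather than
infinite); constant voxel series get $r = 0$ with a count; empty masks,
rank-deficient confounds, mismatched grids, negative eigenvalues and
non-positive completion times are rejected with diagnostics.

## Calibration experiments and problem sizes

The test suite runs every calibration on sizes chosen to finish in
minutes while keeping the statistical question intact; the sizes are
package choices, stated here:

* **Familywise calibration.** On a 20³ grid with 6 mm FWHM and voxel
  $p = 0.001$, $k^*$ is taken from a 2000-iteration null and 1000 null
  group analyses are corrected with it. Group size is 300 smoothed-noise
  subjects: the extent null simulates a *Gaussian* field (as AlphaSim
  does), while a group analysis thresholds a *t* field, whose sample-SD
  denominator is spatially rougher and fragments excursion clusters. At
  large df the approximation is good (measured familywise rate ≈ 0.038
  at df 149 against the Gaussian-truth ≈ 0.045 at the discrete
  threshold); at df ≈ 40 the same procedure is measurably conservative
  (≈ 0.025). This
  df-dependence is a property of the Gaussian-null tradition itself and
  is the package's main documented caveat about the correction.
* **Coupling recovery.** The planted between-group reduction
  ($w$: 0.6 → 0.3, $n$ = 30/30, $T$ = 120) is recovered on a reduced
  12 × 14 × 12 grid with a 27-voxel planted target across 100 generator
  seeds; the planted effect (Fisher-z difference ≈ 0.38, per-subject
  SE ≈ 0.09) is so large relative to the design that detection is
  expected in essentially every seed, and the test requires ≥ 90%.
* **FA deficit power.** 500 datasets at the reported right-ROI
  means/SDs and group sizes give a pooled-t rejection rate near the
  analytic power (≈ 0.72) — comfortably above the majority criterion.
* **Correlation recovery.** 500 datasets recover the planted
  $\rho = -0.53$ with the correct sign essentially always at $n = 24$.

`scripts/acceptance.R` recomputes the same quantities from scratch at
reduced replicate counts and writes them as JSON.

## Known limitations

* The Gaussian extent null is conservative for low-df t maps (above).
* The flip demands data already on a symmetric grid; no template
  construction, registration or interpolation is provided.
* The DTI arm takes skeleton/ROI masks as inputs; tensor fitting from
  raw diffusion signals, eddy/motion correction and skeleton projection
  are out of scope.
* Welch two-sample maps carry a single summary df (rounded median of the
  voxelwise Satterthwaite df), not a per-voxel df image.
* Global-signal regression is a configuration choice; the sign and
  interpretation of negative correlations after it remain debated in the
  field, and the package takes no position beyond the switch.
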