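---
title: "Methods: voxelwise brain entropy mapping and group inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxelwise brain entropy mapping and group inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package computes

Brain entropy (BEN) mapping treats each voxel of a resting-state fMRI
acquisition as a univariate time series and summarizes its temporal
irregularity with Sample Entropy (SampEn). For a series of length $T$,
templates are the length-$m$ windows starting at positions
$1, \dots, T - m$. Writing $B$ for the number of unordered template pairs
whose Chebyshev distance is at most the tolerance, and $A$ for the number
of those same pairs that still match when both windows are extended by one
timepoint,

$$\mathrm{SampEn}(m, r) \;=\; \ln\!\frac{B}{A}
  \;=\; -\ln \widehat{P}\big(\text{match at } m+1 \mid \text{match at } m\big).$$

Because the same starting positions are used at both window lengths
(the Richman–Moorman convention), every length-$(m{+}1)$ match is also a
length-$m$ match, so $A \le B$ and the estimate is non-negative whenever
it is defined. `ben_map()` applies this per voxel inside a brain mask and
propagates undefined voxels (no matches, or a constant series) as `NA`
rather than imputing them; they are removed from the output mask so group
analyses only ever see defined values.

A full study then proceeds: subject-level motion QC
(`framewise_displacement()`, `qc_subject()`), discarding of initial
volumes, motion nuisance regression, Gaussian smoothing, voxelwise BEN,
mass-univariate group statistics with permutation family-wise error (FWE)
control (`fit_glm()`, `omnibus_f()`, `contrast_t()`,
`permutation_fwe_threshold()`), Monte-Carlo cluster-extent correction
(`monte_carlo_cluster_threshold()`, `apply_cluster_correction()`), and
the quadratic stage-trajectory fit (`stage_trajectory_fit()`).
`run_study()` / `run_pipeline()` tie the stages together.

# Entropy parameters and conventions

* **Template length `m = 3`, tolerance `r = 0.6`** (defaults). These are
  the values validated for resting-state BEN mapping; both are exposed
  everywhere they matter.
* **Tolerance scaling.** With `tolerance_mode = "sd"` the effective
  tolerance is $r \cdot \widehat{\sigma}$ with $\widehat{\sigma}$ the
  *sample* standard deviation ($n-1$ normalization) of the full series.
  We chose the sample SD because the method descends from a MATLAB
  toolbox lineage in which `std()` normalizes by $n-1$; the choice makes
  SampEn exactly invariant to affine rescaling of the signal. An absolute
  tolerance mode is available.
* **Tie handling.** A pair at distance exactly $r$ counts as a match
  (`<=`); `strict = TRUE` switches to `<` for sensitivity checks. For
  continuous data the two differ on a measure-zero set.
* **Template-count convention.** Descriptions of the counting step are
  ambiguous about whether length-$m$ windows use $T-m+1$ or $T-m$
  starting positions. We use $T-m$ for both lengths, which is the
  convention that guarantees $A \le B$; the alternative can produce
  negative "entropies". This is the one place we knowingly normalize an
  ambiguous verbal description to the standard algorithm.
* **Small-sample behavior.** SampEn is upward-biased in short series: at
  $T = 138$, i.i.d. Gaussian input gives a mean around $1.13$ against the
  asymptotic conditional-probability limit
  $-\ln(2\Phi(r/\sqrt{2}) - 1) \approx 1.1128$. The bias is a property of
  the estimator, not an implementation artifact; the test suite measures
  it explicitly.

The compiled fast path is an early-terminating pairwise scan; its
correctness is established by equivalence (to $10^{-12}$) with an
independent brute-force double loop over 100 random series across
$m \in \{1,2,3\}$, $r \in \{0.2, 0.6, 1.0\}$, $T \in \{20, 138\}$, not by
construction.

# Preprocessing and quality control

Framewise displacement is the Power convention: sum of absolute backward
differences of the three translations (mm) plus the three rotations
(radians) scaled by a 50 mm sphere radius; the first frame is 0. QC
excludes a subject when max |translation| exceeds 2 mm, max |rotation|
exceeds 2 degrees, or mean FD exceeds 0.5 mm; each violated rule is
reported by name, and the thresholds are parameters. Motion files are
read as radians (the realignment-tool dialect); the degree rule converts
internally.

The first two volumes are discarded before any analysis (steady-state
magnetization). Nuisance regression projects each voxel series on an
intercept plus the six motion parameters and keeps the residuals with the
series mean restored; the regressor set is motion-only by default because
nothing beyond motion is part of the method's stated temporal correction,
but arbitrary extra columns are accepted. Smoothing is separable Gaussian
convolution with $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in
voxel units and reflective boundaries — reflective, because zero-padding
darkens the rim of the small masks used here. QC runs on the post-discard
trace so that the reported mean FD describes exactly the frames being
analyzed.

# Group statistics

All group models are ordinary least squares fitted voxelwise against a
shared design. The design builder codes diagnosis as indicators against
the HC reference (absent levels are dropped), sex as a male indicator,
and mean-centers continuous covariates; interaction columns are products
of the (centered) components, so main effects stay interpretable.
Missing values in requested columns are an error, which forces explicit
listwise deletion upstream rather than silent dropping. t contrasts are
two-sided throughout, since effects in both directions are scientifically
meaningful here.

For the five-group omnibus F we control FWE with max-statistic
permutation in the Freedman–Lane scheme: residuals from the reduced model
are permuted over subjects, the omnibus F is recomputed at every voxel,
and the $(1-\alpha)$ quantile of the max-over-voxels F is the threshold.
We chose permutation over parametric random-field corrections because it
is assumption-light and directly testable by simulation (the suite checks
near-nominal control on null data); voxel-level Bonferroni is available
implicitly by comparing with `qf(1 - alpha/V, ...)` if a cheap
alternative is wanted. Exchangeability under the reduced model is the one
assumption, satisfied by construction in the synthetic cohorts.

Cluster-extent correction is Monte-Carlo: simulate Gaussian fields on the
mask grid, smooth them to the *stated* FWHM (the smoothing actually
applied to the data — we deliberately do not estimate smoothness from
residual maps, which keeps the procedure exactly testable), re-standardize
within the mask, threshold two-sidedly at the voxel-level p, and record
the maximum cluster size per iteration. The returned $k$ is the smallest
extent with family-wise probability at most $\alpha$; clusters of size
$\ge k$ (strictly greater than $k-1$) survive. Default connectivity is
18 (faces + edges), the common neuroimaging choice; every report carries
the connectivity used. The 6-SD t-tau/A-beta ratio outlier rule is
implemented as specified, with one documented caveat: with $n$ subjects a
lone outlier can sit at most $(n-1)/\sqrt{n}$ sample SDs from the mean,
so the rule cannot remove anything below $n = 38$ — at realistic cohort
sizes (hundreds) it behaves as intended.

# Stage trajectory

The inverse-U hypothesis — entropy rising slightly from healthy aging
through early impairment, then falling catastrophically toward dementia —
is tested by regressing subject-level ROI entropy on ordinal stage
(HC = 0, SMC = 1, EMCI = 2, LMCI = 3, AD = 4) with linear and quadratic
terms. A quadratic is the minimal functional embodiment of "inverse-U";
the equal-spacing ordinal coding is an interpretive assumption, not a
claim, and the raw stage means with standard errors are always reported
alongside so the parametric choice is transparent. Because it is unclear
whether such a curve should be fitted to subjects or to group means, both
fits are returned (`coef` and `means_coef`); they agree closely for
balanced cohorts. The verdict flag requires a negative quadratic
coefficient with two-sided $p < 0.05$.

# The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable
without downloading imaging data. Its defaults are the study conditions:

* **Geometry**: 24×24×24 grid at 3 mm isotropic, 140 timepoints at
  TR = 3 s; the first two volumes are discarded by the pipeline, leaving
  the 138 analyzed frames.
* **Cohort**: five diagnosis groups with age, sex and MMSE distributions
  taken from the published cohort characteristics (note MMSE is *not*
  monotone across stages there: the SMC group scores slightly above HC,
  and the defaults preserve that); education, RAVLT, FAQ, delayed recall
  and CSF biomarkers use values typical of ADNI-style elderly cohorts,
  with CSF A-beta declining and t-tau rising along the continuum.
* **Entropy control**: each voxel is a stationary Gaussian AR(1) series;
  the lag-one autocorrelation $\varphi$ is the entropy knob (higher
  $\varphi$, lower SampEn — a mapping verified by the entropy property
  suite, with mean SampEn strictly decreasing over
  $\varphi \in \{0, 0.3, 0.6, 0.9\}$). Controlling entropy through
  $\varphi$ rather than targeting SampEn values directly keeps the
  generator independent of the quantity being estimated.
* **Implanted effects** (inside the pseudo-DMN/MTL/PFC blocks only):
  baseline $\varphi$ per stage (0.50, 0.45, 0.40, 0.62, 0.75) — a U in
  $\varphi$, hence an inverse-U in entropy, lowest-entropy at AD;
  $\varphi$ slopes of $\mp 0.008$ per year of age (controls/patients),
  $+0.012$ per education year in controls only, and $\pm 0.0012$ per
  pg/mL CSF A-beta with opposite signs in controls and patients.
  Covariates are centered at age 73, 16 education years and 180 pg/mL,
  and the resulting $\varphi$ is clipped to $[0.02, 0.95]$. Effect sizes
  are deliberately large ($\varphi$ differences $\ge 0.2$ between extreme
  stages) so that 20 subjects per group suffice to recover every sign;
  power at published cohort sizes is out of scope.
* **Motion**: slow random walks that pass QC with wide margin; with
  probability 0.05 a subject instead draws a QC-violating trace (a
  2.5 mm translation drift, a 2.5 degree rotation drift, or jitter
  pushing mean FD above 0.5 mm), exercising the exclusion path.
* The NULL block and the background carry a fixed $\varphi = 0.5$ and no
  covariate effects; they are the specificity control.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: hemodynamic response shapes, cardiac
and respiratory physiology, scanner drift and artifacts, spatial
anatomy and registration error, spatially correlated noise beyond the
applied smoothing, non-Gaussian signals, and any coupling between motion
and the signal. Results on this generator validate the *machinery*
(estimators, error control, sign recovery under the assumed model), not
the biology.

# Numerical choices and degenerate inputs

* Entropy-undefined voxels ($B = 0$, $A = 0$, or zero SD) are flagged and
  excluded from the group mask, never imputed.
* Voxels with zero residual variance produce `NA` statistics rather than
  infinities; the F map is clipped below at 0.
* The permutation threshold is the order statistic
  $\lceil (1-\alpha) N \rceil$ of the max-F sample, so `alpha = 1`
  returns the distribution's minimum.
* Cluster labels are assigned in scan order and tables are sorted
  lexicographically by peak index, making outputs deterministic; voxel
  indices in tables are 0-based (world coordinates, when needed, come
  from the affine).
* All simulation entry points take a `seed` and save/restore the RNG
  state, so runs are pure functions of (configuration, seed); multi-seed
  stages derive sub-seeds from a single stream.

# Problem sizes

The shipped tests and the acceptance script run the study at 20 subjects
per group on the 24-cubed grid with 140 timepoints, 500 permutations and
500 Monte-Carlo cluster iterations, null-calibration batches of 200
datasets, and 2000-replicate entropy simulations. These sizes were chosen
so the whole suite completes comfortably on a single desktop core while
leaving every check well inside its Monte-Carlo error budget; all of them
scale up through ordinary arguments.

# Known limitations

* Smoothness for cluster correction is the applied FWHM, not estimated
  from residuals; data smoothed by unknown amounts need an external
  smoothness estimate.
* The trajectory model assumes equally spaced ordinal stages.
* The GLM is homoscedastic OLS; robust or mixed-effects variants are out
  of scope, as are longitudinal models.
* Slice-timing correction, realignment (motion *estimation*), and
  spatial normalization are out of scope: the package consumes aligned
  images and externally estimated motion traces.
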