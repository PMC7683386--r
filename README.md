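# benmap

Voxelwise brain entropy (BEN) mapping and group inference for
resting-state fMRI, with a synthetic ADNI-style cohort generator so the
entire analysis is testable end to end without any imaging download.

The package is aimed at neuroimaging researchers studying temporal
complexity of the resting brain across aging and the Alzheimer's disease
continuum (HC, SMC, EMCI, LMCI, AD): it computes per-voxel Sample
Entropy maps, applies the standard motion quality-control and nuisance
steps, runs mass-univariate group statistics with permutation
family-wise error control and Monte-Carlo cluster-extent correction,
and fits the inverse-U stage trajectory of entropy.

## The statistic

For a voxel time series of length *T*, templates are the length-*m*
windows starting at positions 1 … *T − m*. With *B* the number of
unordered template pairs whose Chebyshev distance is within the
tolerance and *A* the number of those pairs still matching when extended
to length *m* + 1,

> SampEn(m, r) = ln(B / A) = −ln P̂(match at m+1 | match at m),

computed with *m* = 3 and tolerance *r* = 0.6 × SD of the series by
default. Higher SampEn means more temporal irregularity. Group analyses
are ordinary least squares per voxel: a five-group omnibus *F* (FWE
controlled by Freedman–Lane max-statistic permutation), post-hoc *t*
contrasts thresholded at voxel *p* < 0.005 with an AlphaSim-style
Monte-Carlo minimum cluster extent, and a quadratic regression of ROI
entropy on ordinal disease stage whose negative curvature is the
inverse-U verdict.

## Worked example

```r
library(benmap)

# one voxel: entropy falls as the signal becomes more autocorrelated
sample_entropy(ar1_series(138, phi = 0.2, seed = 1), m = 3, r = 0.6)
#> [1] 1.1787
sample_entropy(ar1_series(138, phi = 0.8, seed = 1), m = 3, r = 0.6)
#> [1] 0.8067

# full synthetic study: 20 subjects/group, 24^3 grid, 140 timepoints
study <- run_study(list(seed = 1))
print(study)
#> Synthetic brain-entropy study
#>   100 subjects simulated, 97 retained after QC/biomarker filters
#>   omnibus F: 609 voxels above the permutation FWE threshold (8.84)
#>   AD vs HC: 3 surviving clusters (voxel p <= 0.005, size >= 6)
#>   effect-ROI hits: DMN TRUE, MTL TRUE, PFC TRUE; NULL ROI hit: FALSE
#>   stage-trajectory quadratic: -0.0284 (p = 2.21e-23)
```

Reading the output: three subjects were excluded by the motion rules
(2 mm translation / 2° rotation / 0.5 mm mean FD); the five groups
differ in entropy at the family-wise-corrected omnibus level; the
AD-vs-HC contrast survives cluster correction in all three implanted
effect regions (the surviving peak *t* values are negative, i.e. AD
below HC) and nowhere in the null control region; and the stage
trajectory has significantly negative curvature — the inverse-U: entropy
rises slightly from HC through EMCI, then falls sharply in LMCI and AD:

```r
study$trajectory$stage_summary
#>  stage label  n   mean      se
#>      0    HC 20 1.0423 0.0062
#>      1   SMC 20 1.0651 0.0044
#>      2  EMCI 19 1.0900 0.0045
#>      3  LMCI 19 0.9766 0.0096
#>      4    AD 19 0.8691 0.0099
```

Per-region covariate effects reproduce the implanted sign pattern, e.g.
in the combined effect regions the age effect is positive in controls
(t = 2.46) and negative in patients (t = −2.84), education is negative
in controls and null in patients, and the entropy–CSF-Aβ association is
negative in controls (t = −19.6) and positive in patients (t = 7.40):
see `study$roi_stats`.

`run_pipeline(config, out_dir)` additionally writes NIfTI maps, CSV
tables and a JSON manifest; `inst/cli/benmap-pipeline.R` is a thin shell
wrapper around it.

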