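---
title: "Methods: drought time-course metabolomics with droughtmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought time-course metabolomics with droughtmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtmet)
```

# The study design and the data model

`droughtmet` analyzes multifactorial GC-MS time-course metabolomics of
drought stress in *Arabidopsis thaliana*. The emulated design crosses three
genotypes (wild-type Col-0, the brassinosteroid receptor overexpressor
*BRL3ox*, and the *quad* receptor mutant), two tissues (shoot, root), a
watering regime (a well-watered control series and a withholding series over
six days), and five biological replicates. Day 0 ("basal") precedes the
intervention and is shared by both series, so the full design is
3 × 2 × 5 × (1 + 6 + 6) = 390 samples. `enumerate_design()` expands exactly
this grid; modelling day 0 as its own regime level avoids double-counting
the pre-treatment point.

Abundance data live in an `abundance_matrix`, a metabolites × samples
matrix with an explicit processing state (`raw_peak`, `normalized`, `log`).
The state gate means each stage refuses inputs it was not designed for
(e.g. outlier flagging requires log-scale data). Missing values mean "peak
not detected" and are never imputed; a metabolite missing in every sample
of a tissue is reported as "not identified in that tissue", and this report
is recomputed after every sample filter so QC can never silently erase a
metabolite's last observation.

# Normalization and quality control

Raw peak areas are normalized in two steps: division by the
internal-standard peak (ribitol, spiked at constant amount per extraction)
and then by the sample's fresh weight in mg, giving abundance per mg fresh
weight. Because a per-sample detector or extraction gain scales the
standard peak and every metabolite peak alike, the first division cancels
it exactly; the implementation performs the two divisions sequentially so
the cancellation is bit-exact for binary-representable gains. The standard
row is removed from the output, and no further statistical normalization is
applied.

Sample QC follows the pooled-quartile median rule: after log
transformation, Q1 and Q3 are computed over *all* pooled non-missing
measurements (linear-interpolation quantiles, the common default; the
estimator is not prescribed by the upstream protocol), and a sample is
flagged when its own median lies strictly above Q3 or strictly below Q1.
Strictness means a median exactly at a quartile is kept. The log base
defaults to natural log and is configurable; published quartile values
cannot be pinned to a base, which is why the package validates the rule on
per-sample medians and quartiles directly rather than trying to re-derive
dataset-level constants. Quartiles are pooled across tissues by default
(matching the description of the rule as applied to "all measurements");
nothing prevents calling the flagger per tissue on a subset.

PCA diagnostics (`pca_scores()`) center and scale metabolites to unit
variance, exclude metabolites with any missing value listwise, and drop
zero-variance metabolites with a warning since they cannot be unit-scaled.

# Group comparisons and shoot/root partitioning

`compare_groups()` applies a two-sided pooled-variance Student's t-test per
metabolite between two factor levels inside an optional condition filter.
Two-sidedness is a deliberate reading of an unstated choice; the
significance threshold defaults to raw p < 0.025 as used in the source
analyses, and Benjamini–Hochberg q-values are reported alongside for
transparency without changing the default call. Fold-changes are log
fold-changes of the comparison group relative to the reference-group
median (medians, not means, match the reporting convention); on log data
the difference of medians is used, which is identical because the median
commutes with monotone transforms. Degenerate inputs follow explicit
conventions: both groups constant and equal gives t = 0, p = 1; a
metabolite with fewer than two observations in either group is reported,
not tested.

`shoot_root_ratios()` builds the derived shoot-to-root variable from
samples paired by (genotype, regime, day, replicate). If either member of a
pair was removed by QC the pair is dropped and listed — discarding one
tissue's replicate discards its counterpart. Ratios are reported as
log-ratios; zero denominators yield missing values with a warning rather
than infinities. `compare_ratio_groups()` then reuses the same t engine, so
testing ratios is provably identical to testing differences of log tissue
values.

# Differential time-course dynamics

`fit_time_course()` treats day as a continuous covariate and fits, per
metabolite, the full polynomial model
`value ~ genotype * (day + … + day^degree)` by QR least squares, sharing
one decomposition across all complete metabolites for speed (incomplete
metabolites fall back to per-metabolite fits on complete cases). Two
F-tests are reported: *global* (all time and genotype terms against the
intercept-only model) and *differential* (all genotype and genotype×time
terms against the reference-genotype polynomial), with BH adjustment
across metabolites. This is a deliberately simplified re-implementation of
the two-step polynomial-regression idea — global fit, then coefficient
comparison — without stepwise variable selection. The degree defaults to 2
(quadratic), enough to capture accelerating accumulation over a six-day
window without overfitting seven time points; `select_differential()`
gates on q < 0.05 and an R² ≥ 0.6 fit-quality filter. Watered and drought
series are analyzed separately, each including the shared basal day.

Exactly constant metabolites are a defined degenerate case (p = 1 — an
exact fit of the smaller model is no evidence for the larger one), and
under pure-null simulation the differential test's type-I error is
calibrated (checked at nominal 0.05 over 2,000 simulated metabolites).
`cluster_profiles()` groups selected metabolites by complete-linkage
hierarchical clustering of their standardized median time profiles.

# Dynamical network biomarkers

The DNB idea: approaching a critical transition, a dominant group of
molecules sharply increases its variance (SDin) and intra-correlation
(PCCin) while decorrelating from the rest (PCCout), summarized per cluster
by the composite index CI = SDin × PCCin / PCCout. `compute_ci()` is that
formula with its domain contracts (PCCout must be positive). Absolute
Pearson correlations are used throughout, and SDin is the mean of member
standard deviations (the pooled-SD alternative is not used; this choice is
documented rather than prescribed upstream).

`detect_dnb()` works on one genotype × tissue at a time. Log abundances
are standardized against the day-0 controls (z-scores by the reference
mean and SD; zero-SD metabolites are excluded with a record), which
operationalizes "drastic increase relative to control". Metabolite modules
are then identified **once**, by complete-linkage hierarchical clustering
on the distance 1 − |Pearson r| computed across all pooled drought case
samples (days 1–6). Per-day clustering was evaluated and rejected: with
five replicates per day, pairwise correlation estimates are so noisy that
complete linkage cannot hold a module together from one day's replicates
(planted-module recovery stayed below 25% in simulation), whereas pooling
the 30 case samples stabilizes membership. For each day, SDin, PCCin,
PCCout and CI of every module of at least `min_cluster_size` members
(default 2 — reported DNBs can be pairs) are computed from the replicates
at that day.

The reported DNB is the module whose CI rises most sharply relative to its
own trajectory (max/median spike ratio), and the critical point is that
module's CI-maximum day, ties broken toward the earlier day (the
early-warning reading). Selecting by relative spike rather than by the
single global CI maximum follows directly from the "drastic increase"
criteria and has a practical advantage: the day-0 reference SD is
estimated from five samples, and its noise scales a metabolite's whole
standardized row; a within-trajectory ratio cancels that scale exactly,
while an absolute maximum does not.

**Power caveat.** With five replicates per day and correlation confined to
the critical day, module identification is only partly identified: the
pooled-case correlation between planted members is ≈ 0.5 with sampling
noise ≈ 0.17, and complete linkage must keep all pairwise links intact.
In simulation at the emulated study conditions the planted critical day
and members are jointly recovered in roughly 40% of datasets — the method
needs more replication, a known weakness of DNB analysis on metabolite
panels, whose generally weak correlations limit the CI's resolution. At 15
replicates per time point the same detector recovers ≈ 85% of planted
transitions, which the test suite verifies; conclusions from the
five-replicate design should treat DNB calls as exploratory.

# Pathway-level multi-omics integration

`overrepresentation_p()` is the one-sided upper-tail hypergeometric
(Fisher's exact) test of a hit list against an annotated set within a
measured universe; `fisher_combine()` is Fisher's combined probability
test, −2Σln p against chi-square with 2k degrees of freedom.
`integrate_pathways()` applies both per pathway for genes and metabolites
separately and combines the two p-values; an omic with no annotated
members in a pathway (after restriction to its measured universe) enters
the combination as p = 1, which reproduces published rows where the
metabolite p-value is printed as 1. Duplicated identifiers count once.
Annotation is a plain three-column table supplied by the user; no pathway
database is downloaded.

# The synthetic-data generator

`simulate_dataset()` emits raw peak areas, metadata with fresh weights,
and ground-truth labels. What it emulates, and the defaults chosen where a
value had to be fixed:

- **Baselines**: per-metabolite log10 abundances uniform on [−3, 3],
  reproducing the several-orders-of-magnitude spread of GC-MS panels.
- **Replicate noise**: log-normal with CV 0.2, a typical biological
  replicate CV for bulked plant samples.
- **Tissue divergence**: per-metabolite shoot-vs-root offsets, SD 1.5
  natural-log units. Tissue is the dominant structured factor in the real
  data (PCA separates tissues), so the generator must carry it for the PCA
  diagnostic to be meaningful.
- **Fresh weights**: 55 ± 5 mg (shoot) and 30 ± 5 mg (root) aliquots.
- **Internal standard and detector**: the measured peak is
  concentration × fresh weight × detector factor, the detector factor
  log-uniform in [0.5, 2] applied to every row including the ribitol row
  (constant spiked amount), so two-step normalization cancels it exactly.
- **Osmoprotectants**: six sugars/amino acids accumulate as
  baseline × exp(rate × day) in the drought series only, rate 0.3/day for
  WT and quad and 0.7/day for BRL3ox (steeper accumulation in the
  overexpressor); the watered series is time-flat.
- **DNB module**: four metabolites whose critical-day drought replicates
  get noise inflated 3× with pairwise correlation 0.8, induced by one
  shared latent factor with loading √0.8 — the simplest construction with
  a tunable pairwise correlation. Other days stay uncorrelated.
- **Outliers**: eight samples with all metabolite rows (not the standard
  row — an extraction artifact, unlike detector gain, does not scale the
  spiked standard proportionally and must survive normalization for the QC
  rule to have anything to find) shifted by 10^±2, direction random.

What it does **not** emulate: chromatographic artifacts, retention-index
drift, batch effects (none were detected in the source data), missing-value
mechanisms tied to abundance, or genotype differences at basal conditions.
Passing recovery tests on this generator therefore demonstrates that the
estimators are correct and calibrated for the stated statistical structure,
not that real chromatograms of this design would yield the same power.

# Numerical choices and degenerate inputs

- Quantiles: type-7 linear interpolation; outlier flags use strict
  inequalities.
- t-test: pooled variance computed by the textbook closed form, vectorized
  across metabolites; zero-variance groups follow explicit p ∈ {0, 1}
  conventions; the engine is cross-checked against `stats::t.test` in the
  tests.
- Least squares: shared QR decompositions; exact-fit degeneracies resolved
  by relative-tolerance guards (an exact small-model fit gives p = 1).
- Clustering: `stats::hclust` complete linkage throughout; identical rows
  always co-cluster.
- Write/read: numeric values serialized with 17 significant digits so
  round trips are bit-identical; the NA token is "NA" and empty fields
  parse as missing.
- Problem sizes in the test suite (60 metabolites × 390 samples; 50
  simulated datasets for DNB recovery, 100 for dynamics; 2,000 metabolites
  for null calibration; 10,000 draws for the uniformity check) were chosen
  so each property is measured with enough precision for its asserted
  bound while the whole suite stays fast.

# Known limitations

- DNB module identification is under-replicated at five replicates per
  day (see the power caveat above); the package reports it faithfully and
  quantifies the limitation rather than hiding it.
- The dynamics module is not a port of the referenced two-step regression
  package: no stepwise selection path, so selected sets can differ from
  that implementation on borderline metabolites.
- Published dataset-level quartiles cannot be reproduced without the
  deposited data and the (unstated) log base; the QC rule is therefore
  validated on its own contract and on the published per-sample medians.
- Fisher's combination assumes independent per-omic p-values; gene and
  metabolite evidence for the same pathway are correlated in reality, so
  combined p-values are an evidence ranking, not calibrated error rates.
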