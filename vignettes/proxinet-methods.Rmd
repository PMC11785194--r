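---
title: "proxinet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proxinet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxinet)
```

# Scope

`proxinet` implements the analysis path of a proximity-labeling interactome
study: a split-TurboID bait (here, the tau microtubule-binding repeat
domain) biotinylates its neighbours in cells; streptavidin-captured proteins
are quantified label-free (LFQ) against mock transfections; the resulting
interactor list is then integrated with a human brain cohort proteome (TMT,
CTL/AD/PSP diagnoses) through a signed weighted co-expression network and
one-tailed Fisher exact enrichment. The package starts from quantified
protein x sample matrices; database search, quantification and wet-lab
steps are out of scope, as are curation of GO/marker/RBP reference lists
(all consumed as inputs).

Every stage is exercised against synthetic data generators that emulate the
statistical structure of the two experiments, so each claim the package
makes about its own correctness is backed by a planted-truth recovery test
or an independent oracle (enumeration, brute force, hand computation).

# AP-MS stage

## Missingness filter

Proteins absent in 50% or more of samples (`max_missing_frac = 0.5`,
strictly: missing fraction `>= 0.5` is removed) are filtered before
imputation. The boundary case matters: a protein missing in exactly half
the samples is removed.

## Left-censored imputation

LFQ missingness is treated as left-censoring: a missing value means the
protein sat near or below the detection noise level in that run. Following
the Perseus convention, each sample's noise level is taken as
`mean - 1.8 * SD` of its observed log2 intensities, and every missing cell
in that sample is drawn from a Gaussian centred there with SD
`0.3 * sample SD`. Both multipliers are parameters
(`imputation_params(shift, width)`). The phrase "between +/- 0.3 SD of the
noise level" admits a literal truncated reading; `truncate = TRUE` clips
draws to one imputation SD around the centre, but the untruncated Gaussian
is the default because that is what the reference implementation draws.
Imputation never touches observed cells, and an imputation seed makes the
matrix reproducible.

A known consequence, visible in the package's own tests: when missingness
is moderate (tens of percent for low-abundance proteins), imputed
mock-group values sit systematically below the censored truth, so volcano
plots gain a tail of spurious moderate fold changes among heavily-imputed
null proteins. The planted-effect recovery tests therefore distinguish
complete-data behaviour (exact recovery of the planted set) from
MNAR-default behaviour (all planted proteins recovered; imputation-driven
false positives possible at the two-fold boundary).

## Differential enrichment

Two groups use a pooled-variance (Student's) two-tailed t-test per protein;
Welch is available behind `dea_params(welch = TRUE)` but is not the
default, since the pooled test is what the name "Student's t-test" denotes.
More than two groups use one-way ANOVA with Tukey studentized-range
pairwise p-values; because tiny Tukey estimates are numerically unreliable,
any pairwise Tukey p below `10^-8.5` is replaced by the
Bonferroni-corrected pairwise t-test p (`tukey_floor`). BH FDR is computed
across proteins, and both raw and adjusted p are always reported. Volcano
classification uses `log2FC >= 1` (a two-fold change) and raw `p < 0.05` by
default — raw, because volcano plots conventionally display unadjusted p —
with `use_fdr_for_class = TRUE` switching the gate to BH-adjusted p.

Degenerate proteins with zero within-group variance get a machine-epsilon
variance floor; a protein identical in both groups reports `log2fc = 0`,
`p = 1`.

# Cohort harmonization

## TAMPOR

Batch artifacts are removed by an iterative median polish of ratios: within
each batch, every protein is divided by its median over that batch's
central-tendency samples (pooled global internal standards, GIS, by
default; `gis_mode = "all_samples"` relaxes this); the polish then
alternates subtracting sample medians and protein medians (over
central-tendency samples) of the log2 ratios until the largest adjustment
falls below `1e-6` (default) or 250 iterations. The converged matrix has
log2 central tendency 0. Only the endpoint and the ratio construction are
fixed by the method's description; the iteration schedule and tolerance are
therefore exposed as parameters. Proteins with no usable central-tendency
value in some batch cannot be ratio-normalized there and are dropped with a
message.

## Bootstrap covariate regression

Age, sex and postmortem interval are removed per protein by OLS on centred
covariates plus protected diagnosis dummies; the coefficient used for
removal is the median over 1000 non-parametric bootstrap resamples of
samples (median, not mean, exactly as the method specifies). Resamples
missing a protected group level are redrawn and counted. Only the centred
covariate terms are subtracted, so protein means and protected-variable
effects are untouched by construction.

Two statistical facts shape the tests here. First, with ~120 samples the
per-protein OLS coefficient noise is of order 0.01 log2/yr for age, and for
proteins sharing a latent module factor that noise is *shared* — it does
not average out across a module. Recovery of a planted 0.05 log2/yr age
coefficient to +/-0.01 is therefore asserted on a seed-averaged estimate.
Second, under a null (no planted covariate effects) the removed component
is pure estimation noise, so individual cells can shift by several tenths
of a log2 unit even though protein means are preserved exactly; the null
test bounds the mean per-cell perturbation, not the maximum.

# Signed co-expression network

The network stage is implemented from first principles (no external
network library) and verified against hand-computed and brute-force
oracles:

* **Correlation**: biweight midcorrelation throughout, with
  `u = (x - median) / (9 * MAD)` weights `(1 - u^2)^2` on `|u| < 1`, and a
  Pearson fallback (with a message) when MAD is zero. Pearson can be
  selected for the whole network via `cor_method = "pearson"`. No outlier
  cap is applied by default.
* **Adjacency**: signed soft-thresholding `((1 + r)/2)^beta`, `beta = 9`.
* **TOM**: mean-denominator topological overlap,
  `TOM_ij = (l_ij + a_ij) / (0.5 (k_i + k_j) + 1 - a_ij)`; dissimilarity
  `1 - TOM`.
* **Dendrogram**: average-linkage `hclust` on the TOM dissimilarity.
* **Dynamic hybrid cut**: merge heights are rescaled to [0, 1]; walking
  from the root, a branch becomes a module when it has at least
  `min_module_size = 25` leaves, core scatter (mean rescaled internal merge
  height) at most `maxCoreScatter`, and a join gap of at least
  `minGap = 0.75 (1 - maxCoreScatter)`; `deepSplit` 0..4 maps to
  `maxCoreScatter` {0.64, 0.73, 0.82, 0.91, 0.95} following the
  dynamic-tree-cut convention, with `deepSplit = 2` the default. The
  outermost qualifying branch wins. The PAM stage then assigns each
  unassigned protein to the module with smallest average dissimilarity
  among modules under its nearest cluster-containing ancestor branch
  (dendrogram-respecting), ties broken by lowest module label. Everything
  is deterministic; labels are renumbered by decreasing module size, 0 is
  grey/unassigned.
* **Eigengenes**: first principal component of the module's z-scored
  profiles over samples, sign-aligned with the mean module profile;
  variance explained is reported.
* **Merge and reassignment**: modules whose eigengenes are closer than
  `merge_cut_height = 0.07` on the `1 - cor` scale merge (average-linkage
  cut); then one kME-based reassignment pass moves proteins whose
  own-module correlation is not significant at `reassign_p = 0.05` while a
  foreign module's is, and is larger. The reassignment rule is
  deliberately conservative — in large modules every member correlates
  significantly with its own eigengene, so the pass fires mainly for
  marginal proteins, which matches how reassignment thresholds behave in
  practice.
* **kME / traits / edges**: signed module membership is the bicor of
  protein and eigengene with t-transform p-values; module-trait tables are
  bicor of eigengene and numeric trait with stars at 0.05/0.01/0.001;
  per-module exports take the top 5% of intra-module TOM pairs
  (count rounded up, lexicographic tie-break).

Module-trait correlations use eigengenes rather than module mean
abundance: the two are nearly collinear for well-formed modules and the
eigengene is the standard one-vector module summary. Grey proteins are
excluded from eigengene, kME-hub and edge outputs. The computation is
single-block: at desk scale (<= 10k proteins) the full matrices fit in
memory, so no block partitioning is needed.

# Enrichment and integration

Enrichment is the one-tailed hypergeometric Fisher exact test, computed by
the `phyper` tail (verified against direct binomial-coefficient enumeration
over every 2x2 table with background up to 60). Odds ratios use a 0.5
Haldane correction only when a cell is zero. BH correction is applied
within each list across modules (module FET) or across retained sets (GMT
enrichment, with set-size bounds applied after background intersection) —
matching per-panel FDR annotation practice. Depletion testing exists behind
a flag but is never the default.

Backgrounds matter and are explicit everywhere: all network proteins for
module FET, all quantified (filter-passing) proteins for AP-MS GO
enrichment. Cross-dataset joins normalize gene symbols to upper case by
default, since symbol case conventions differ between human and mouse
datasets.

Heatmap matrices are per-protein z-scores clipped to [-4, 4]; constant rows
map to 0. Clipping is idempotent for rows whose z-scores already lie
within the bounds (a clipped outlier changes the row SD, so re-scaling a
clipped row is deliberately not a no-op). Venn/UpSet region counts cover
all `2^k - 1` membership patterns, and annotation joins (RBP class,
compartment, insolubility, interactome membership) are left joins that
count their matches.

# Synthetic data: what it emulates, and what it does not

`generate_apms` emulates a 10-bait vs 6-mock LFQ pulldown: per-protein
baselines `N(30, 2)` log2 units, replicate noise SD 0.5, planted bait
effects spanning log2FC 1-8, and logistic left-censoring
`P(missing) = plogis((value - 26.5) * -1)`, which yields roughly 10%
overall missingness concentrated in the low-intensity tail (the low end of
what LFQ experiments show). The separation of baseline spread from
replicate noise is deliberate: it is what makes low-abundance proteins
preferentially missing, and it gives the volcano realistic behaviour.

`generate_cohort` emulates a three-group (46/49/26) multi-batch cohort:
each planted module is driven by one latent factor, protein
`= baseline + loading * (factor + noise)` with loadings `|N(1, 0.2)|` and
noise calibrated so within-module correlation is exactly the requested
`r_w`; module factors share a global factor to hit the requested
between-module `r_b`; batch offsets are additive in log2; GIS references
are within-batch pooled means plus SD-0.02 noise; age/sex/PMI act linearly
on designated modules; diagnosis shifts the designated module's factor
mean; traits are `loading * factor + noise` with a target correlation.

Not emulated: peptide-level roll-up, ratio compression, ion interference,
non-Gaussian abundance distributions, correlated missingness across
samples, multiple shared factors per module, or real protein identities.
Passing the recovery tests therefore demonstrates that the implementations
are correct and calibrated under the generating model — not that the
biological conclusions of any particular dataset are reproduced.

# Numerical choices and degenerate inputs

* Zero within-group variance in DEA: machine-epsilon variance floor;
  identical groups report `p = 1`.
* `bicor` falls back to Pearson per vector when MAD = 0, and errors on
  constant vectors; vectors shorter than 4 are rejected.
* Eigengene of a single-protein module is that protein's z-profile.
* Tree-cut and PAM tie-breaks are by lowest index/label, making the whole
  network path run-to-run deterministic.
* Dendrogram heights are rescaled by the observed min/max; a degenerate
  flat dendrogram rescales to all-zero heights.
* TAMPOR medians ignore missing values; non-convergence warns with the
  final delta rather than failing.
* All stage seeds derive from one global seed through fixed per-stage
  offsets, so inserting or skipping a stage never reshuffles another
  stage's randomness.

# Problem sizes used in the shipped verification

The test suite and `scripts/acceptance.R` run at desk scale, chosen so the
full suite completes in minutes while keeping every estimate's Monte-Carlo
error well inside its tolerance: 2000-protein AP-MS simulations (20 seeds)
for type-I error and effect recovery; 400-protein, 121-sample cohorts for
module recovery (ARI over 10 seeds, trait loadings over 20); 2000-protein
default cohorts (6 seeds, 1000 bootstraps) for harmonization; the full
enumeration sweep (all 2x2 tables, background up to 60) and 1000 random
graphs for the enrichment and TOM kernels.

# Known limitations

* The dynamic hybrid cut follows the published criteria but is an
  independent implementation; on pathological dendrograms (nested modules
  separated by gaps smaller than `minGap`) its branch decomposition may
  differ from other implementations. The deepSplit mapping is exposed so
  users can trade sensitivity against robustness.
* The PAM stage assigns every unassigned protein whose ancestor branch
  contains a module; like any PAM stage it will absorb background proteins
  into modules when backgrounds are large. Disable with
  `pam_stage = FALSE` when grey membership matters.
* Perseus-style imputation biases fold-change estimates upward for
  proteins with asymmetric group missingness; this is inherent to the
  method, documented above, and visible in the package's own tests.
* Module-trait p-values are not corrected for the number of module x trait
  cells; stars reflect nominal significance, as in standard module-trait
  heatmaps.
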