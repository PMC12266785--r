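---
title: "Models and methods in agewaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in agewaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agewaves)
```

agewaves analyses how immune-cell transcriptomes change over the human
lifespan. This vignette is the package's own account of the statistics it
implements, the choices behind them, and what the synthetic cohorts used in
testing do and do not establish about real data.

## Bulk models

### The linear age model

For every gene the package fits, by ordinary least squares on
log2(TPM + 1) values,

$$y_g = \alpha_g + \beta_{1g}\,\mathrm{age} + \beta_{2g}\,\mathrm{sex}
  + \varepsilon_g,$$

with age in whole years and sex as a 0/1 contrast whose reference level is
the alphabetically first (so the coding is deterministic and documented).
Age and sex are tested with Type II — marginal — sums of squares:
SS(age | sex) and SS(sex | age), each on 1 degree of freedom against the
full-model residual. This makes the age test invariant to the sex
composition of the cohort, which matters because lifespan cohorts rarely
have identical sex ratios at every age. Age p-values are adjusted across
genes with the Benjamini–Hochberg step-up procedure.

Thresholds are strict inequalities throughout: a gene is an age-DEG iff
`q_age < 0.05`, and it is eligible for downstream enrichment iff it is a
DEG with `|beta_age| > 0.005` per year (about half a log2 unit over a
century — smaller slopes are statistically real in large cohorts but
biologically negligible). Both counts are exposed so users can report DEGs
with either convention. Degenerate genes (zero variance, hence a 0/0 F
ratio) report `beta_age = 0`, `p_age = 1` rather than failing the run;
genes with zero *residual* variance (noiseless signal) report `p` near 0
as they should.

The implementation solves the normal equations for all genes at once
against the shared design matrix, which is why a 2,000-gene scan takes
milliseconds; tests verify the coefficients and F statistics against a
per-gene closed-form solve and against `car::Anova` on `lm` fits.

### LOESS trajectories and shape clustering

Nonlinear change is summarised per gene by a LOESS fit of expression on
age: span 0.75 (each local fit uses the 75% nearest samples), local degree
2, tricube weights, no robustness iterations — the default local-regression
semantics of `stats::loess`, computed with the exact `"direct"` surface so
that predictions agree with a pointwise weighted-least-squares oracle to
numerical precision. Predictions are evaluated on an integer-year grid over
the observed age range, because donor ages are reported in whole years.

Curves are z-scored across the grid before clustering, so clusters capture
*shape*, not amplitude or baseline. Genes whose fitted curve has
numerically zero variance have no shape; they are set aside in a dedicated
"flat" cluster (label 0) because their z-score is undefined. Shaped genes
are grouped by agglomerative clustering (Euclidean distance, complete
linkage by default — the `hclust` default semantics; linkage is exposed)
and the tree is cut at a user-chosen k, by default constrained to 6–12
groups, the range in which lifespan trajectory atlases are usually
presented. The package records mean silhouette widths across the k range
(`trajectory_silhouettes`) as a guide, but deliberately does not choose k:
no selection rule is claimed, and k remains a user decision.

### DE-SWAN: transient waves of change

Linear models miss changes confined to a window of ages. The sliding-window
scan tests, for every center k from 10 to 90 years (step 1 by default),

$$y_g = \alpha_g + \beta_{1g} I_k + \beta_{2g}\,\mathrm{sex}
  + \varepsilon_g,$$

where $I_k$ indicates whether a sample's age falls above or below k within
a ±10-year window: ages in `[k−10, k)` are "low", ages in `[k, k+10]` are
"high", everything else is excluded. The boundary age equal to k goes to
"high"; this half-open convention is arbitrary but fixed, documented and
tested. Windows with fewer than 3 samples on either side, or with a single
sex, are flagged underpowered and skipped.

The window indicator is tested with the same Type II machinery as the age
model, and BH adjustment is performed *within each center across genes* —
matching the per-center DEG-count presentation of the wave curve; an
adjustment across centers would mix hypotheses from overlapping windows of
very different power. Counts of genes below each q cutoff (0.001, 0.01,
0.05 by default) form the count curves; crests are local maxima of the
q < 0.05 curve after a width-3 moving-average smooth (partial windows at
the ends) that suppresses single-center noise. `find_crests` itself
defaults to no smoothing so its plateau and endpoint rules are exact:
plateaus report their midpoint center (left-of-middle for even lengths, so
crest ages always lie on the center grid), endpoints qualify when they
exceed their single neighbour, and a constant curve has no crests.
Top DEGs at a crest require `q < 0.01` and `|beta| > 0.5`, split into local
increase and decrease by the sign of the window coefficient.

### Batch adjustment

Multi-study lifespan cohorts are always multi-batch. `combat_adjust`
applies the parametric empirical-Bayes location/scale adjustment
(`sva::ComBat`) with age and sex protected during standardization, so the
biological signal the downstream models test is not absorbed into batch
terms. The wrapper adds the contract the pipeline needs: a single-batch
cohort passes through unchanged; a batch perfectly confounded with a
protected covariate is rejected with a diagnostic (the location/scale
model is not identifiable); and genes with numerically zero residual
variance are passed through untouched, since they carry no noise to
shrink. `batch_qc` reports per-batch medians and the sample–sample Pearson
correlation matrix before and after, summarised by the between-batch
median spread.

Two properties deserve explicit framing. First, "leaves a batch-free
cohort unchanged" is only meaningful for noiseless data: any
empirical-Bayes method estimates small nonzero batch terms from noise and
must adjust them, so the invariance test uses a noiseless cohort, where
pass-through makes it exact. Second, after adjustment the per-gene
between-batch mean differences are not zero — they retain the sampling
noise any finite cohort has (shrinkage in fact leaves *less* spread than a
cohort simulated without batch effects at all). What adjustment removes is
the systematic component, and that is what the recovery checks measure:
the across-gene mean residual offset (a few hundredths of a pooled SD at
the tested conditions) and the stability of age-slope estimates against a
seed-paired batch-free simulation (relative deviations well under 10%).

## Cell-level statistics

**Gene-set scoring.** The score of a cell is the mean expression of the
set minus the mean expression of a control set matched on expression
level: genes are ranked by dataset-average expression and cut into
`n_bins = 25` equal-size bins, and for each set gene `ctrl_size = 50`
controls are drawn from its bin (seeded, without replacement, set genes
excluded; a bin smaller than `ctrl_size` contributes all its genes). The
defaults are the established single-cell convention for this scoring
scheme and are exposed as parameters. Bin-matching makes the score robust
to global shifts in expression level, and a test hook (`control_pool`)
lets the control set equal the gene set, which must give exactly zero.
The default set is the 20-gene SASP signature (`sasp_genes`) used to score
monocyte inflammatory phenotype.

**Rank-sum DE.** Per-gene two-sided Wilcoxon rank-sum tests with midranks
and the tie-corrected normal approximation; when both groups have at most
10 cells the p-value instead comes from exhaustive enumeration of group
assignments, with the two-sided value defined as
`min(1, 2·min(P(W≤w), P(W≥w)))` — small fixtures deserve exact p-values.
The log2 fold change follows the single-cell convention on log-normalized
data, `log2((expm1(mean_A)+1e-9)/(expm1(mean_B)+1e-9))`, because the
0.25 threshold that defines DEGs was calibrated inside that convention;
a DEG needs `q < 0.05` *and* `log2FC > 0.25`, both strict.

**Proportions and frailty.** Per-sample cell-type fractions are correlated
with donor age (Pearson), flagged at |PCC| > 0.2 and > 0.4, and summarised
with a degree-2 polynomial trend (degree unconstrained by theory; 2 is
enough to express the fast-early/slow-late pattern and is configurable).
Zero-variance proportions report PCC 0 with a flag rather than NA.
Age groups use the fixed lifespan bins — child 1–11, young 23–58, aged
60–72, advanced-aged 77–100 years — with gaps deliberately unassigned, and
frailty is a status, not an age bin: a donor is frail iff older than 65
with a Rockwood deficit index above 0.2, both strict.

## TCR repertoire indices

Clone sizes within a (sample, subtype) group yield the Gini coefficient
$\sum_{ij}|x_i-x_j|/(2n^2\bar x)$ (computed by the sorted-order identity,
tested against the double loop) and the entropy-evenness expansion index
$1 - H/H_{\max}$ in bits. A single-clone repertoire returns expansion 1 by
convention: $H_{\max}=0$ leaves the ratio undefined, and 1 is the limit of
vanishing evenness. Transition potential is the cell-count-weighted mean
Shannon entropy of each clone's distribution across subtypes; the pairwise
variant restricts to the two subtypes and weights each clone by its total
cells within the pair, which makes transition(A,B) = transition(B,A) exact
(weighting by one side alone would break symmetry for unequal splits).
Entropy base 2 throughout — indices are in bits. All indices are computed
per donor and never pooled across donors.

## The synthetic-data generator

The generator defines the conditions under which every estimator is
validated: a 1–99-year cohort of 180 samples (ages drawn as whole years,
uniform by default, with an "even" scheme exposed since real cohorts are
described only as evenly spread), balanced sexes assigned by seeded
permutation, batches assigned round-robin, and expression built as
archetype mean + batch offset + batch-scaled Gaussian noise — exactly the
location/scale generative model the batch-correction method assumes, which
is what makes correction testable by parameter recovery. Ages, sexes and
noise are drawn before batch parameters are applied, so seed-paired runs
with and without batch effects differ only in the batch terms.

Four trajectory archetypes cover the shapes lifespan cohorts show: flat;
linear (default ±0.02 log2 units/year — about 2 units over the lifespan,
a clearly detectable but not overwhelming drift at noise SD 0.5);
saturating (a logistic rise of amplitude 1 centred at `change_age` with
scale `half_width`, the early-fast-then-plateau pattern); and transient.

The transient archetype needs a word on its shape. The sliding-window
statistic at center k is the difference of window means — effectively a
box-smoothed derivative of the mean trajectory. A *symmetric* bump
therefore produces near-zero signal at its own center and maximal signal
at its two flanks: a cohort of symmetric bumps at age 40 would show twin
DEG-count peaks near 34 and 46 and a dip at 40, and the flank locations
drift with the bump width and the integer-age window asymmetry. Since the
purpose of the archetype is a crest at a *known, controllable* age, the
transient shape is an asymmetric difference of logistics: a rapid onset
whose inflection sits exactly at `change_age` (scale `half_width/4`),
followed by a slow return to baseline (offset inflection at
`change_age + 3·half_width`, scale `half_width`). The maximal rate of
change — and hence the DEG-count crest — is then at `change_age`, and the
slow decay contributes only a weak, dispersed signal decades later. The
recovery checks place the global count maximum at 39–42 across seeds for
onset age 40.

Cell-level matrices use normal log-scale expression around a common
baseline with per-type additive marker shifts; clonotype tables draw clone
sizes from geometric (mean 1/rate, closed form used in tests) or power-law
distributions, with a subtype-sharing matrix controlling how clones span
subtypes (identity = no sharing). The last clone of a sample is truncated
to hit the requested cell count exactly.

What the generator does *not* emulate: count-level sampling noise and
mean–variance dependence, library-size variation, dropout and sparsity of
real single-cell data, correlated gene modules, cohort age structure that
differs from uniform, or TCR sequence-level processes (clones are abstract
labels). Passing recovery tests therefore demonstrates correctness of the
estimators under their assumed models — not robustness to the full
messiness of real cohorts.

## Numerical conventions and problem sizes

Tolerances: exact identities are tested at 1e-10–1e-12; LOESS against its
WLS oracle at 1e-6; flatness is declared below a relative curve-variance
of 1e-10. Monte-Carlo checks use 2 standard errors over 20 replicate
seeds. The validation suite and the acceptance script run the full designs
— 2,000 genes × 180 samples for the DE-SWAN and calibration checks (20
seeds each), 200 genes for trajectory recovery, 300 genes × 120 samples
for batch recovery — sizes chosen so each property is measured with
comfortable Monte-Carlo margins while a complete run stays in the tens of
seconds on one CPU. The pipeline demo (`pipeline_config()`) uses a smaller
300-gene cohort for the same reason.

Known limitations: the q-values are BH-adjusted p-values (a Storey-type
estimate would be less conservative when many genes change); the DE-SWAN
centers step yearly and crests are reported on that grid; hierarchical
clustering ties are resolved by `hclust`'s deterministic merge order, so
cluster *labels* are only stable up to permutation; and the frailty rule
is a hard threshold with no uncertainty propagation.
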