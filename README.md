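# agewaves

Tools for studying how peripheral blood mononuclear cell (PBMC)
transcriptomes change across the human lifespan — and for telling apart the
three temporal signatures that lifespan cohorts show: **linear** drift,
**nonlinear** trajectories that move fast in early life and then plateau,
and **transient waves** of change concentrated around particular ages.
The package also covers the cell-level side of immunosenescence analyses:
per-cell gene-set (SASP) scoring, rank-sum differential expression,
cell-type proportion/age correlation, Rockwood-style frailty
classification, and T-cell receptor (TCR) repertoire clonality indices.

Because the cohorts these methods were designed for are controlled-access,
the package ships a synthetic-cohort generator with known ground truth so
every estimator can be exercised end-to-end with parameter recovery.

## The statistics at the core

* **Linear age model** (`fit_age_lm`). Per gene,
  `y_g = α_g + β₁g·age + β₂g·sex + ε`, fitted by OLS on log2(TPM + 1)
  values; age and sex are tested with Type II (marginal) sums of squares —
  SS(age | sex) against the full-model residual — and age p-values are
  Benjamini–Hochberg adjusted across genes. DEGs: `q < 0.05`;
  enrichment-eligible DEGs additionally need `|β₁| > 0.005` per year.
* **LOESS trajectory clustering** (`fit_trajectories`,
  `cluster_trajectories`). A span-0.75, degree-2 local regression per gene
  over age; predicted curves are z-scored (shape-only) and grouped by
  complete-linkage hierarchical clustering into a user-chosen number of
  clusters (6–12 by default).
* **DE-SWAN sliding-window scan** (`deswan_scan`). For every center k in
  10–90, ages within ±10 years are binarized below/above k and each gene
  is fitted with `y_g = α_g + β₁g·I_k(low/high) + β₂g·sex + ε`; DEG counts
  per center at several q cutoffs trace the "wave" curve, whose local
  maxima are the crest ages. Top crest DEGs: `q < 0.01` and `|β₁| > 0.5`.
* **Batch adjustment** (`combat_adjust`). Parametric empirical-Bayes
  location/scale batch correction protecting age and sex, with QC
  (`batch_qc`) comparing per-batch medians and sample correlation before
  and after.
* **Cell-level statistics** (`score_gene_set`, `rank_sum_de`,
  `proportion_age_correlation`, `classify_frailty`). Gene-set scores use
  expression-bin-matched control genes (mean set expression minus mean
  control expression per cell; default set: the 20-gene SASP signature in
  `sasp_genes`). Rank-sum DE applies `p.adj < 0.05` and `log2FC > 0.25`
  with exact enumeration for small groups. Frailty: age > 65 and deficit
  index > 0.2.
* **TCR repertoire indices** (`gini_coefficient`, `expansion_index`,
  `transition_index`). Gini `Σᵢⱼ|xᵢ−xⱼ|/(2n²x̄)` over clone sizes; clonal
  expansion `1 − H/H_max` over clone frequencies (bits); transition
  potential as the cell-count-weighted entropy of each clone's spread
  across subtypes.

## Worked example

```r
library(agewaves)

arch <- archetype_table(500,
  kind = c(rep("flat", 350), rep("linear", 75), rep("transient", 75)),
  slope = 0.02, change_age = 40, half_width = 8, amplitude = 1)
cohort <- simulate_cohort(n_samples = 180, age_range = c(1, 99), arch,
                          batch_offsets = c(0, 1), noise_sd = 0.5, seed = 42)
cohort
#> expression_cohort: 500 genes x 180 samples
#>   age range: 1-99  sex: F=90 M=90  batches: 2
#>   carries simulation ground truth

cohort <- combat_adjust(filter_genes(cohort))
summary(fit_age_lm(cohort))
#> age-associated differential expression (q < 0.05 strict)
#>   DEGs: 82 of 500 (78 up, 4 down)
#>   enrichment-eligible (|beta_age| > 0.005 ): 75

dw <- deswan_scan(cohort)
dw
#> deswan: 500 genes, 81 centers (+/- 10 years)
#>   crest ages (q < 0.05 curve): 19, 26, 40, 46, 60, 64, 87, 89
head(top_degs(dw), 3)
#>    center  gene      beta            q direction
#> 17     40 g0446 1.0896632 3.789041e-08  increase
#> 33     40 g0473 0.8293298 8.916553e-06  increase
#> 11     40 g0438 0.8680487 8.133619e-05  increase
```

The 75 transient genes were planted with their onset at age 40 and the
scan's dominant crest lands exactly there (the other listed crests are
small local maxima of the noisy count curve — compare their heights in
`attr(dw$crests, "height")`). The linear model finds the planted linear
genes (75 enrichment-eligible DEGs) plus a handful of transient genes whose
wave also has a net linear component.

Clonality indices on simulated repertoires (a young donor with an even
repertoire, an old donor with concentrated clones):

```r
tr <- clonotype_truth(c(d1 = 300, d2 = 300), ages = c(d1 = 30, d2 = 85),
                      subtypes = "CD8_CTL", rate = c(0.9, 0.4), seed = 1)
rs <- repertoire_by_group(simulate_clonotypes(tr))
rs$indices[, c("sample", "age", "n_cells", "n_clones", "gini", "expansion")]
#>   sample age n_cells n_clones       gini   expansion
#> 1     d1  30     300      273 0.08285714 0.006362149
#> 2     d2  85     300      112 0.34779762 0.042198494
```

`run_pipeline(pipeline_config(seed = 1), "out/")` chains all stages —
simulate, preprocess, age model, trajectories, DE-SWAN, single-cell
statistics, repertoire — writing TSV outputs, a manifest and a log;
reruns with the same configuration are bit-identical.

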