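# pcsig

Principal-component gene signatures for confounded overexpression designs.

## The problem

A common microarray / bulk-expression design asks what a single
overexpressed gene (the motivating case is *ITGBL1*, a secreted EGF-repeat
protein studied in ovarian cancer) does to the transcriptome of cultured
cells. The experiment measures two cell lines, each in three variants —
wild type, empty-vector control, and overexpression — with a handful of
arrays per group. The difficulty is that the difference between the two
cell lines dwarfs the overexpression effect: the leading principal
component of the pooled data is the cell-line contrast, and any naive
analysis of "overexpressing vs control" is confounded by it.

`pcsig` implements the full decision workflow for this situation:

1. **Presence filtering** — keep genes with signal ≥ 5 (log2) in more than
   3 arrays (both constants and both inequalities configurable).
2. **PCA by SVD** — genes are variables, samples observations; each
   component is reported as unit-norm per-gene loadings `v` with per-sample
   scores, and a deterministic sign convention.
3. **Signature selection** — gene `g` belongs to the signature of component
   `k` when `|v_gk| > W / sqrt(N)`, with `N` the number of genes decomposed
   and weight `W = 3.5` by default (recommended `W > 3`).
4. **Attribution** — each candidate component is judged by hierarchical
   clustering of samples on its signature genes: the *concordance* is the
   best achievable agreement between a k-cluster cut and the factor of
   interest (cell line, or overexpression status). A component is called
   overexpression-related when its overexpression concordance reaches 0.9
   and beats its cell-line concordance. Per-sample eta-squared summaries of
   the component scores are reported alongside.
5. **Over-representation analysis** — one-sided hypergeometric test of the
   signature against a GMT gene-set collection, universe = the filtered
   gene list; BH-adjusted p-values are reported but non-binding.
6. **Moderated t differential expression** — per cell line and per control
   type, the two-group t statistic with empirical-Bayes variance shrinkage
   `s2_post = (d0*s2_0 + d_g*s2_g) / (d0 + d_g)` on `d0 + d_g` degrees of
   freedom, BH correction, strict `adj_p < 1e-4` calls, and the cross-line
   set intersection. The prior `(d0, s2_0)` is estimated by moment matching
   on log variances with trigamma inversion.

Because the motivating study deposited no raw data, the package ships a
seeded generator (`generate_experiment()`) of the whole design — planted
cell-line offsets, a planted overexpression signature, scaled
inverse-chi-square gene variances, and planted pathways — so every stage is
verifiable against a known truth.

## Worked example

```r
library(pcsig)

exp    <- generate_experiment(sim_config(seed = 7))
report <- run_pipeline(exp$expr, exp$ann, exp$gene_sets)
print(report)
```

```
Variance-attribution workflow report
  Filter: 4749 of 5000 genes kept
  Pan-PCA: PC1 = 76.7%, PC2 = 6.8% of variance
  Cell-line factor: max eta^2 = 1.000 on PC1
  LINE_A: overexpression-related PC1, 149 signature genes, 1 significant pathway(s)
  LINE_B: overexpression-related PC1, 151 signature genes, 1 significant pathway(s)
  DE (vs empty vector), adj_p < 0.0001: 0 and 0 per line, 0 in both
```

Reading this: 4749 of 5000 genes pass the presence filter; the pan-analysis
puts 76.7% of variance on PC1, which separates the two cell lines perfectly
(eta² = 1) — the confounder. Within each line, the workflow attributes one
component to overexpression status and selects its ~150-gene signature,
which feeds the pathway screen:

```r
print(report$per_line$LINE_A$ora, n = 3)
```

```
Over-representation analysis: 51 gene sets tested, 1 significant at p < 0.05
 rank            pathway n_pathway n_overlap      p_value        adj_p
    1 PLANTED_PATHWAY_01        40        30 2.495878e-38 1.272898e-36
    2   DECOY_PATHWAY_25        40         3 9.558346e-02 1.000000e+00
    3   DECOY_PATHWAY_45        40         3 1.019867e-01 1.000000e+00
```

The planted pathway (30 of its 40 members inside the signature) ranks first
by a wide margin; the decoys sit at chance. The moderated-t fit reports its
empirical-Bayes prior alongside the calls:

```r
print(report$de$fits[["LINE_A.VECTOR"]])
```

```
Moderated t fit: 4749 genes, 3 vs 3 samples (d_g = 4)
EB prior: d0 = 4.182, s2_0 = 0.0509; df_total = 8.182
Significant at adj_p < 0.0001: 0 gene(s)
```

The recovered prior matches the generator's truth (`d0 = 4`,
`s2_0 = 0.05`). Note that with three replicates per group the strict
`adj_p < 1e-4` rule is extremely conservative — see the vignette for the
power analysis of this cutoff.

Individual stages are available as plain functions
(`filter_low_expression()`, `run_pca_svd()`, `select_signature()`,
`hierarchical_cluster()`, `cluster_concordance()`, `moderated_t_fit()`,
`run_ora()`), and readers/writers for the three text formats
(`read_expression_matrix()`, `read_sample_annotation()`, `read_gmt()`)
connect the workflow to external data.

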