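# ptrtkit

Identification of tumor-reactive T cells from paired single-cell expression
and TCR data.

## The problem

In bone-marrow malignancies such as AML, T cells that actually recognize
tumor antigen ("tumor-reactive" T cells) are a minority hidden inside a
large bystander repertoire, and — unlike in most solid tumors — they do not
carry a canonical exhaustion signature that would make them easy to gate.
`ptrtkit` implements a repertoire-driven alternative for paired
scRNA-seq + scV(D)J-seq data:

1. **pTRT cluster calling.** Every annotated T-cell cluster is scored with
   four indices:
   - *tumor enrichment* — Ro/e, the ratio of observed to chi-square-expected
     cell counts of the cluster in the tumor condition
     (`O_ij / (row_i · col_j / N)`);
   - *clonal expansion* — `1 − H/ln k`, where `H` is the Shannon entropy of
     the clone-size proportions of the cluster's tumor-condition cells and
     `k` the number of clonotypes (1 = monoclonal, 0 = fully even);
   - *proliferation* — fraction of cells detecting any cycling marker
     (MKI67, TOP2A, PCNA by default);
   - *TCR-signaling activation* — binned-control-pool gene-set scores for
     six TCR-signaling pathways, averaged per cluster and z-scored across
     clusters.
   A cluster passing all four thresholds (defaults: Ro/e ≥ 1.2,
   expansion ≥ 0.2, proliferation ≥ 0.05, median signaling z > 0) is called
   a *potentially tumor-reactive T cell* (pTRT) cluster.
2. **TCR tracing.** Clonotypes are defined by the paired productive TRA/TRB
   chains (V, J, CDR3). Any cell outside pTRT clusters whose clonotype also
   occurs on a pTRT cell is labeled *pTRT-relevant*; pTRT ∪ pTRT-relevant
   are the tumor-reactive cells, all others are bystanders.
3. **Marker discovery.** Genes with bystander mean expression < 0.5 (on the
   log-normalized scale) are ranked by the *delta value* — the difference in
   expressing-cell fractions between tumor-reactive and bystander cells —
   and for the top 100 the *reactive-cell precision* is computed: the share
   of all cells expressing the gene that are tumor-reactive. Virus-specific
   clonotypes can be excluded via exact CDR3β matching against a reference
   table.
4. **Bulk deconvolution.** A single-cell signature matrix (rank-sum top
   markers per state) and non-negative least squares estimate per-sample
   fractions of the labeled states — e.g. the marker⁺CD8⁺ share — in bulk
   RNA-seq.

A synthetic-cohort generator (`generate_dataset()`) plants all of this
structure — negative-binomial counts, power-law clone sizes, shared
clonotypes, a near-specific marker gene, viral clonotypes — with recorded
ground truth, so the entire pipeline is testable without any restricted
accession.

## Worked example

```r
library(ptrtkit)

sim <- generate_dataset(sim_config(seed = 1))   # 2,000 cells, 12 clusters
fit <- ptrt(sim$dataset, sim$contigs, seed = 1) # normalize -> clonotypes -> indices -> labels
fit
#> ptrt_fit: 2000 cells, 12 clusters, 2 pTRT cluster(s): CD8_Temra_P1, CD8_Temra_P2
#>   labels: pTRT=333  pTRT-irrelevant=1661  pTRT-relevant=6

coef(fit)["CD8_Temra_P1", ]
#> tumor_enrichment_index clonal_expansion_index    proliferation_index
#>                  1.518                  0.277                  0.743
#>     median_signaling_z
#>                  2.206

rk <- rank_marker_candidates(fit$dataset, fit$labels)
head(rk[!is.na(rk$rank), c("gene", "delta", "precision", "rank")][order(na.omit(rk$rank)), ], 3)
#>    gene     delta precision rank
#>  ADGRG1 0.896     0.909        1
#>   MKI67 0.332     0.848        2
#>    PCNA 0.316     0.796        3
```

The two planted Temra clusters are the only ones passing all four criteria
(Ro/e 1.52 vs ≈ 0.9 elsewhere; expansion 0.28–0.33 vs ≈ 0.15; proliferation
0.73–0.74; median signaling z ≈ 2), and the planted marker gene tops the
precision ranking: 90.9% of the cells expressing it are tumor-reactive,
matching the closed-form value implied by the planted expressing fractions
(`planted_marker_precision(sim$truth)` = 0.906) within sampling noise.

`run_pipeline(config, out_dir)` drives the same stages from a single YAML
configuration over on-disk inputs (10x-style MTX + contig CSV or AIRR TSV)
and writes `cluster_indices.tsv`, `reactivity_labels.tsv`,
`marker_ranking.tsv`, optional viral/deconvolution tables and a JSON run
report.

## Package layout

- `ptrt()` — the model-fitting entry point (class `ptrt_fit` with
  `print`/`summary`/`coef`/`fitted` methods); building blocks are exported
  individually (`call_clonotypes()`, `diversity()`, `roe_matrix()`,
  `score_gene_set()`, `rank_sum_markers()`, `compute_cluster_indices()`,
  `label_reactivity()`, `rank_marker_candidates()`,
  `flag_viral_clonotypes()`).
- `build_signature()` / `estimate_fractions()` — bulk deconvolution
  (class `FractionEstimates` with `coef`/`residuals`).
- `generate_dataset()` / `generate_bulk_mixtures()` — synthetic cohorts
  with ground truth; `write_simulation()` for the on-disk form.
- `vignettes/identifying-tumor-reactive-t-cells.Rmd` — the methods
  vignette: model assumptions, parameter choices, generator design and
  limitations.
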