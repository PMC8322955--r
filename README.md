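# scmeta

Cross-dataset meta-analysis of single-cell RNA-seq immune profiles.

## What problem this solves

Public scRNA-seq datasets of the same tissue — here, immune cells (CD45+)
from healthy human liver — are produced by different labs with different
enrichment strategies, chemistries and depths. Pooling them into a
*meta-atlas* is only defensible after quantifying how, and how much, they
disagree. `scmeta` implements that programme for analysts working with
multiple UMI-count datasets:

* **Ingest & filter** — Matrix Market / CSV readers, barcode-level tissue
  filtering and gene-positivity (CD45/PTPRC) selection, gene-axis
  harmonization across datasets.
* **Pipeline** — log normalization `ln(1 + 10^4 x/L)`, per-gene scaling,
  PCA (30 PCs), SNN-graph Leiden clustering, deterministic 2D embedding,
  and a simplified mutual-nearest-neighbor batch integration validated by
  kNN mixing entropy and a cluster-agreement metric.
* **Annotate** — marker-panel scoring (CD3D; KLRF1/FCGR3A; CD14/FCGR3A;
  CD19; SDC1) with an argmax-plus-margin rule, NK and T merged to NKT;
  proportion tables.
* **Concordance** — proportion chi-squared tests (overall and pairwise
  2×2), housekeeping-gene noise (ANOVA + Welch), pseudobulk Pearson /
  Spearman / linear / quadratic fits, rank-rank hypergeometric overlap
  (RRHO) grids, top-100 abundant-transcript agreement.
* **Differential expression** — per-gene Wilcoxon rank-sum on
  log-normalized values (exact by enumeration for small groups), with the
  dual gate: expression ratio `exp(logfc) >= 1.25` or `<= 0.8` *and*
  Bonferroni-adjusted `p < 0.05`.
* **Difference of differences (DoD)** — the interaction statistic

  `DoD = (m_pop1 − m_rest1) − (m_pop2 − m_rest2)`

  tested as a Welch four-group contrast. It partitions between-dataset DE
  into uniform dataset shifts (DoD ≈ 0) versus subpopulation-specific
  effects (DoD gene = between-dataset DE **and** DoD `p_adj < 0.05`),
  summarized as the percentage of DE genes that are DoD genes.
* **Signatures** — an integrated meta-atlas, per-subpopulation DE against a
  reference compartment (e.g. PBMC), and gene↔function chord edge-list
  export.
* **Simulator** — a negative-binomial multi-dataset generator with known
  ground truth (marker structure, uniform and subpopulation-specific batch
  effects, ambient ALB-like contamination, housekeeping baselines, a
  shiftable reference compartment) so every stage is testable offline.

See `vignettes/scmeta-methods.Rmd` for the full model description and the
reasoning behind every numerical convention.

## Worked example

Two synthetic datasets sharing subpopulation structure but separated by a
uniform batch effect (sdlog 0.3):

```r
library(scmeta)

cfg <- sim_config(n_datasets = 2, cells_per_dataset = c(600, 500),
                  n_genes = 500, batch_sigma_uniform = 0.3, seed = 1)
coll <- generate_collection(cfg)

anns <- list(); nms <- list()
for (d in names(coll$counts)) {
  pr <- process_dataset(coll$counts[[d]], hvg_n = 300, embed = FALSE)
  nms[[d]] <- pr$nm
  anns[[d]] <- annotate_dataset(pr, coll$cells[coll$cells$dataset_id == d, ])
}
pt <- proportions_table(do.call(rbind, anns))
print(pt)
#> <proportion_table> percentages:
#>       NKT Myeloid Plasma    B
#> DS1 59.33   23.83   11.5 5.33
#> DS2 53.00   26.40   13.4 7.20

chi <- proportion_chisq(pt, "overall")
#> chi-squared = 4.99 (df 3), p = 0.173

correlate_pairwise(pseudobulk(nms$DS1), pseudobulk(nms$DS2))
#> <pairwise_correlation> n=500 R=0.8820 rho=0.8852 slope=0.8815 intercept=0.2477

deb <- de_between_datasets(nms$DS1, nms$DS2, anns$DS1, anns$DS2, "NKT")
dd  <- dod(nms$DS1, nms$DS2, anns$DS1, anns$DS2, "NKT", de_between = deb)
dod_explained_summary(deb, dd)
#> NKT, DS1 vs DS2: 236 DE genes, 0 DoD genes (0.0% of DE)
```

Reading the output: annotation recovers the planted subpopulation
proportions (ranking NKT > Myeloid > Plasma > B in both datasets) and the
composition difference is not significant (p = 0.17). The batch effect
depresses the pseudobulk correlation to R = 0.88 and produces 236
between-dataset DE genes in NKT cells — yet **zero** of them are DoD genes:
every one is a uniform dataset shift, not an NKT-specific difference. That
separation is exactly what the DoD statistic is for.

## Command line

```sh
scmeta all --config run.json --seed 7 --out results/
# stages: simulate | ingest | pipeline | concord | de | dod | signature | all
```

Each stage writes its outputs (TSV/JSON) plus a `manifest_<stage>.json`
recording parameters, seed and md5 checksums; deterministic stages checksum
identically on reruns.

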