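# gcrepertoire

Paired single-cell transcriptome + immunoglobulin repertoire analysis of
germinal center (GC) B cells.

During the GC reaction, B cells diversify their B-cell receptors (BCR) by
somatic hypermutation (SHM) of the immunoglobulin variable (V) regions and
change antibody effector class by class switch recombination (CSR), while
transitioning through transcriptionally distinct states — dark zone (DZ),
light zone (LZ), intermediate states, and precursors of memory B cells
(PreM) and plasmablasts (PBL). `gcrepertoire` is for analysts who have
paired 10x-style single-cell gene expression and V(D)J data with a prior
transcriptome clustering and want to track SHM load and isotype class
composition across those states: it pairs heavy and light chains under
strict quality rules, quantifies and bins V-region germline identity,
calls clonotypes, scores intraclonal isotype heterogeneity, tests
per-cluster enrichment and depletion, and computes expression summary
statistics. A calibrated synthetic cohort generator reproduces the
statistical structure of a large GC dataset so the entire pipeline is
testable without any external download.

## Core statistics

* **Cell filter**: keep barcodes with expression data and exactly one
  eligible heavy and one eligible light contig (productive, full length,
  high confidence, UMI count > 3), excluding IGHD-expressing cells.
* **Germline identity**: per cell, the unweighted mean of heavy and light
  V-region identity, binned into 100%, [98,100), [96,98), [94,96), <94%.
* **Clonotypes**: per donor, identical heavy V/D/J + light V/J gene calls
  and identical concatenated heavy+light CDR3 nucleotide sequence.
* **Enrichment/depletion**: for a cluster of size *n* with *k* cells of a
  category totalling *K* in a background of *N*,
  *p*<sub>enrich</sub> = P(X ≥ k) and *p*<sub>deplete</sub> = P(X ≤ k)
  with X ~ Hypergeom(N, K, n), exact log-space tails, Benjamini–Hochberg
  correction per direction, flags at q ≤ 0.05. The same upper tail drives
  gene-set over-representation.
* **Expression**: library-size normalization; two-sided Wilcoxon rank-sum
  differential expression with fold-change ≥ 1.2 and ≥ 25% detection
  reporting filters; dot-plot statistics (percent detected, z-scored mean
  log2 normalized expression).

## Worked example

```r
library(gcrepertoire)

cohort <- generate_cohort(default_profile(), seed = 1)   # 40,000 cells, 3 donors
expressed <- unlist(lapply(cohort$expression, rownames))
cells <- filter_paired_cells(cohort$contigs, expressed,
                             annotations = cohort$annotations)

qc_audit(cells)
#>          input_barcodes      missing_expression       no_eligible_heavy
#>                   40000                       0                     398
#> multiple_eligible_heavy       no_eligible_light multiple_eligible_light
#>                     200                       0                       0
#>      empty_heavy_c_gene              ighd_heavy                    kept
#>                       0                     203                   39199

median(cells$germline_identity_pct)
#> [1] 95.51685
round(100 * prop.table(table(cells$identity_bin)), 1)
#>   B100    B98    B96    B94 B_LT94
#>    2.0   13.1   29.3   23.6   32.1
round(100 * prop.table(table(cells$isotype_class)), 1)
#> IGHA IGHG IGHM
#> 33.0 42.9 24.1
```

801 of the 40,000 simulated cells are dropped (the 2% injected QC
contaminants, each under its audit rule). Among the kept cells the median
V-region germline identity is 95.5%, 2% are unmutated, 32% heavily mutated
(< 94%), and the isotype classes split 43/33/24% IGHG/IGHA/IGHM.

```r
clones <- call_clonotypes(cells)
het <- clone_isotype_heterogeneity(clones, min_size = 5)
c(het$n_heterogeneous, het$n_eligible, round(100 * het$fraction, 1))
#> [1] 119.0 536.0  22.2

enr <- categorical_enrichment_by_cluster(cells, "identity_bin")
subset(enr$enrichment, flag != "none" & category == "B_LT94",
       select = c(cluster, k, n, q_enrich, q_deplete, flag))
#>   cluster    k    n q_enrich q_deplete     flag
#>     INT-2 1378 3486 1.01e-21  1.00e+00 enriched
#>      LZ-1 2009 5170 9.73e-28  1.00e+00 enriched
#>      DZ-1 1892 4681 8.14e-37  1.00e+00 enriched
#>     PBL-1  191 1222 1.00e+00  2.18e-39 depleted
#>     INT-3   17  764 1.00e+00  1.29e-99 depleted
#>   FCRL2/3   86  773 1.00e+00  7.47e-42 depleted
#>      PreM  270 1555 1.00e+00  1.18e-39 depleted
#>     PBL-2  145  804 1.00e+00  4.31e-19 depleted
```

22% of clonotypes with at least 5 cells contain mixed isotype classes —
evidence of class switching within clones. The enrichment stage flags the
heavier-mutated DZ/LZ clusters (DZ-1, INT-2, LZ-1) as enriched for
heavily mutated BCRs and the memory-precursor and plasmablast clusters as
depleted, exactly the structure planted by the generator.

`run_pipeline(out_dir)` executes the full chain (simulate → QC →
clonotypes → enrichment → differential expression → dot-plot → report)
and writes every stage output as TSV plus a JSON run manifest with seeds,
audit counters and file digests.

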