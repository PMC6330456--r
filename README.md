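# exdiv

Domestication reshapes not just *which* genes are expressed but *how
variably* they are expressed. Across domestic animals and crops, domestic
populations tend to show lower **gene expression diversity** than their wild
progenitors, and the loss is strongest in genes under artificial selection.
`exdiv` implements that comparison as a tested, reusable R pipeline for
anyone with paired domestic/wild RNA-seq count matrices and (optionally) a
two-population variant panel: population geneticists, crop and livestock
genomicists, and methods developers who want planted-truth simulations to
validate against.

## The statistics

* **Expression diversity** of a gene in a group is its coefficient of
  variation across replicate samples, CV = SD/mean, computed on
  median-of-ratios-normalized counts; a group's diversity is the mean CV
  over genes.
* The headline comparison statistic is the **decrease of expression
  diversity**

  D<sub>cv</sub> = 1 − CV<sub>dome</sub> / CV<sub>wild</sub>,

  with a one-sided Student's *t*-test on the per-gene CV vectors
  (alternative: domestic lower).
* **Candidate selected genes** (CSGS) are genes overlapping selective-sweep
  regions: windows (100 kb, 10 kb step) in the top 5% of either
  Weir–Cockerham/Hudson **F**<sub>ST</sub> or the diversity ratio
  π<sub>wild</sub>/π<sub>dome</sub> (Nei's per-site nucleotide diversity),
  merged into maximal intervals. PCSGS = 100·|CSGS|/|WGGS|.
* **Enhancer–gene synchrony** classifies one-to-one enhancer–gene pairs by
  the joint sign of the enhancer's genetic-diversity change and the gene's
  expression-diversity change (3×3 grid with a relative-change dead zone ε).

A calibrated negative-binomial simulator (`simulate_expression_pair()`,
`simulate_genotypes()`, `simulate_annotation()`,
`simulate_enhancer_pairs()`) plants known D<sub>cv</sub> effects, sweep
intervals, and synchrony classes so every stage can be checked against
ground truth.

## Worked example

```r
library(exdiv)
library(dplyr)

cfg <- sim_config(n_genes = 2000, n_samples_per_group = 10,
                  selected_fraction = 0.1, selected_cv_reduction = 0.2,
                  seed = 42)
sim <- simulate_expression_pair(cfg)
cvs <- cv_table(normalize_counts(sim$counts), sim$metadata)

sel <- sim$truth$selected_gene_ids
compare_diversity(cvs$cv[cvs$group == "domestic"],
                  cvs$cv[cvs$group == "wild"])
#> <diversity_comparison> WGGS: CV dome 0.922 vs wild 0.928, D_cv = 0.6%  (t = -0.70, less p = 0.241)

sub <- filter(cvs, gene_id %in% sel)
compare_diversity(sub$cv[sub$group == "domestic"],
                  sub$cv[sub$group == "wild"], gene_set_label = "CSGS")
#> <diversity_comparison> CSGS: CV dome 0.758 vs wild 0.900, D_cv = 15.8%  (t = -6.61, less p = 6.26e-11 ***)
```

Only 10% of genes carry the planted 20% CV reduction, so the whole-genome
set moves little (0.6%, not significant) while the planted set shows a
strong, highly significant decrease — the CSGS-versus-WGGS contrast the
pipeline is built to measure. The estimate (15.8%) sits below the planted
20% because sample CVs at n = 10 are slightly attenuated; at n = 20 the
recovery is within ±0.04 (see the acceptance tests).

`run_pipeline()` chains the full analysis from files (counts + metadata +
GFF3/BED annotation + VCF + population map) to a report table, sweep BED,
window-score TSV, synchrony summary, and a manifest with file hashes;
`inst/scripts/exdiv-pipeline.R` is a shell wrapper around it. Plots:
`plot_cv_distribution()`, `plot_window_scores()`,
`plot_diversity_report()`, `autoplot()` on synchrony summaries; `tidy()` /
`glance()` on comparison objects.

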