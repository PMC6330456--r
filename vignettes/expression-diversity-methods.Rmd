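---
title: "Measuring the loss of gene expression diversity under domestication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the loss of gene expression diversity under domestication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exdiv)
```

## The question and the model

Artificial selection narrows genetic diversity; this package quantifies the
companion effect at the transcriptome level. For each gene $g$ and group
(domestic or wild) with $n$ replicate samples of normalized expression
$x_{g1},\dots,x_{gn}$, expression diversity is the coefficient of variation

$$\mathrm{CV}_g = \frac{s_g}{\bar x_g},$$

with the sample ($n-1$) standard deviation. A group's diversity is the mean
CV over analyzed genes, and the comparison statistic between a domestic
group and its wild progenitor is the decrease of expression diversity

$$D_{cv} = 1 - \frac{\overline{\mathrm{CV}}_{dome}}{\overline{\mathrm{CV}}_{wild}},$$

a relative (ratio) decrease: $D_{cv}=0.125$ means the domestic group's mean
CV is 12.5% below the wild one. Negative values (a diversity increase) are
legal and preserved. Significance uses Student's *t* on the per-gene CV
vectors, one-sided by default (alternative: domestic lower), because the
scientific claim is directional. The pooled-variance unpaired test is the
default; Welch and gene-paired variants are exposed via
`compare_diversity(method = )`, since published descriptions of such tests
rarely say which was used and CV vectors over the same genes are arguably
paired. Genes with zero mean in either group have no defined CV and are
excluded before any mean is formed; the analyzed-gene universe ("WGGS") is
whatever survives that rule, and the package reports its own counts rather
than forcing agreement with any published gene census.

Two deliberate reading choices are baked in and tested:

* The decrease statistic is the **ratio** form above, not the difference
  $1-(\mathrm{CV}_{dome}-\mathrm{CV}_{wild})$ that a well-known table
  legend's typography suggests: only the ratio form reproduces the printed
  worked pair (1.054 vs 1.205 → 12.5% decrease).
* "Expressed gene" uses the **strict** inequality FPKM > threshold, with
  the conventional threshold ladder 0, 0.1, 0.5, 1, 5.

## Normalization

Counts are normalized by median-of-ratios size factors: factor $j$ is the
median over genes (restricted to genes with all-positive counts) of
$c_{ij}/(\prod_k c_{ik})^{1/m}$. This makes per-gene CVs invariant to
per-sample sequencing depth, which the test suite asserts on random
matrices. FPKM is computed directly from the count matrix and annotation
gene lengths ($c_{ij}\times 10^9 / (L_i T_j)$ with $T_j$ the column total);
no alignment-level "mapped reads" figure enters, because the package never
sees BAMs. Because dispersion statistics are biased by unequal group sizes,
`balance_samples()` cuts every group to the smallest group's size, keeping
the samples with the most clean reads and breaking ties toward the
lexicographically smaller sample id (the tie rule is our choice; published
descriptions are silent).

## Sweep scanning and gene-set partitioning

From a two-population biallelic panel the package applies the standard
transcriptome-SNP filtering cascade, in order: site depth ≥ 30 and site
quality ≥ 30; biallelic SNPs only; genotypes with < 3 supporting reads or
genotype quality < 20 masked missing; pooled minor-allele frequency > 0.05
computed **after** masking; missingness ≤ 20% (30% is the conventional
relaxation for whole-genome panels and is a single argument away). Whether
the allele-frequency rule should be pooled or per-population is genuinely
ambiguous; pooled is the default and `filter_config(allele_freq_scope =
"per_population")` the alternative, and the choice is logged.

Nucleotide diversity is Nei's mean pairwise difference per site,
$\pi = L^{-1}\sum_s \frac{n_s}{n_s-1} 2p_s(1-p_s)$, with unphased diploid
genotypes contributing two allele calls. Scans use 100-kb windows sliding
by 10 kb from coordinate 0; full windows only, plus one terminal truncated
window so every base is covered (disable with `keep_truncated = FALSE` for
strict fixed-length scans). Window F~ST~ is the ratio-of-sums
("weighted") combination of per-site Weir–Cockerham variance components
(Hudson's estimator and per-site averaging are flags). The diversity-ratio
scan scores $(\pi_{wild}+\epsilon)/(\pi_{dome}+\epsilon)$ with a
pseudocount defaulting to the smallest nonzero windowed $\pi$ in either
population — a repair for windows with zero domestic diversity, recorded
as an attribute and echoed in run logs, since how published scans treated
such windows is unstated.

Candidate sweep regions are the top 5% of defined window scores (ties at
the threshold all included — deterministic and conservative toward
inclusion), merged across overlaps and book-ends. Genes overlapping a
region by ≥ 1 bp form the candidate selected gene set; interval work uses
0-based half-open coordinates internally, converting at the GFF3/VCF/BED
boundaries. Externally computed window scores (e.g. a composite-likelihood
scan, which this package deliberately does not re-implement) enter the same
thresholding path through `ingest_external_scores()`, with the coordinate
convention declared in a header pragma.

## Enhancer–gene synchrony

For one-to-one enhancer–gene pairs, each axis (enhancer $\pi$, gene CV)
gets the relative change $1-\text{dome}/\text{wild}$ and a three-way label:
decreased when the change exceeds $\varepsilon$, increased below
$-\varepsilon$, else unchanged (wild 0/dome 0 is unchanged; wild 0 with
dome > 0 is increased). No published definition of "unchanged" exists, so
the dead zone $\varepsilon = 0.05$ per axis is an explicit, configurable
repair surfaced in the output attributes. Growing $\varepsilon$ can only
move pairs toward "unchanged", which the suite tests as a property.

## What the simulator emulates

The generators exist so every stage can be validated against planted truth;
their defaults are fixed study conditions, not tuning knobs.

* **Expression**: gene means are log-normal (location 5, scale 1.5 on the
  natural-log scale, i.e. typical counts of tens to thousands); counts are
  negative binomial with group-wise size $k$ (default 1, a realistic bulk
  RNA-seq overdispersion giving CVs near 1); per-sample library sizes are
  log-normal ($\sigma=0.15$) so normalization is non-trivially exercised.
  Because $\mathrm{CV}^2 = 1/\mu + 1/k$ for the NB law, a planted relative
  CV reduction $r$ on a selected gene is imposed analytically by solving
  for the domestic $k$; targets below the Poisson floor $1/\mu$ are capped
  near-Poisson. Two groups of ≥ 4 replicates mirror the replication floor
  of real domestication transcriptome panels (default 5).
* **Genotypes**: neutral allele frequencies are Beta(0.5, 0.5) per
  population (expected per-site heterozygosity $a/(2a+1) = 0.25$, the
  closed form the calibration test uses); inside planted sweep intervals
  the domestic frequency is shrunk toward 0/1 by the deterministic
  transform $2p'(1-p') = f\cdot 2p(1-p)$, so expected domestic diversity
  scales by exactly the sweep factor $f$ and monotonically in it.
* **Annotation** is a deterministic even tiling (ids shared with the
  expression generator); **enhancer pairs** plant class labels with a
  ±20% margin so classification at any $\varepsilon < 0.2$ recovers them
  exactly.

All randomness derives from one integer seed, one derived stream per
artifact; identical configs are byte-identical.

What the simulator does **not** emulate: linkage disequilibrium and
haplotype structure, demographic history (so it cannot separate bottleneck
from selection), mapping bias between reference genomes, isoform-level
effects, and gene-gene expression correlation. Passing tests therefore
demonstrate correctness of the estimators and recovery under the stated
generative model, not robustness to those real-data features.

## Numerical choices and problem sizes

* Quantile thresholds use R's default (type 7) empirical quantile;
  all-equal scores select every window.
* Degenerate t-test input (all CVs identical) is flagged, not an error.
* The type-I-error calibration runs 2,000 replicates of 300 genes × 5+5
  samples — the smallest size at which the pooled *t* on per-gene CVs is
  comfortably in its asymptotic regime while keeping the suite fast.
* Planted-D~cv~ recovery runs at 5,000 genes and 20+20 samples; sample CVs
  at n = 20 are mildly attenuated, which is why the recovery tolerance is
  ±0.04 rather than exact.
* The sweep-recovery experiment uses 4 × 3 Mb chromosomes, 24,000 sites
  (≈ 200 per 100-kb window, so window $\pi$ has ≈ 7% relative Monte-Carlo
  error), one 500-kb sweep at factor 0.2, and 10 diploids per population:
  sweeps must occupy well under 5% of windows for a top-5% rule to be able
  to recover them, and partial-overlap edge windows dilute the signal, so
  genome size and sweep width were fixed once on those analytic grounds.

## Known limitations

* CV is a biased estimator at small $n$; the package reports the plain
  sample CV (as the field does) rather than a bias-corrected variant, so
  cross-study comparisons should hold $n$ fixed — which is exactly what
  `balance_samples()` enforces within a study.
* The pipeline ingests counts and VCFs; upstream read QC, mapping,
  quantification, and SNP calling are out of scope, as are XP-CLR-style
  composite-likelihood scans (ingested externally instead).
* Published whole-genome gene-set counts are treated as inputs for worked
  examples, not targets the pipeline must re-derive: they depend on
  annotations and pooling rules that are not recoverable from summary
  tables.
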