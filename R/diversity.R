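#' Coefficient of variation of one gene's expression values
#'
#' `sd(x) / mean(x)` with the sample (n-1) standard deviation. A gene whose
#' mean is 0 has no defined CV and is reported `NA` (callers exclude it).
#'
#' @param values Numeric vector of normalized expression values for one gene
#'   in one group; at least 2 samples.
#' @return CV (>= 0), or `NA` when the mean is 0.
#' @examples
#' gene_cv(c(1, 2, 3))  # sd 1, mean 2 -> 0.5
#' @export
gene_cv <- function(values) {
  if (length(values) < 2) abort("gene_cv needs at least 2 samples.")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sd(values) / m
}

#' Per-gene, per-group CV table
#'
#' Computes mean, SD and CV of each gene's normalized expression separately
#' in each group. Genes whose mean is 0 in *either* group are excluded from
#' the table (their ids are recorded in attribute `"excluded_genes"`): the
#' CV of an unexpressed gene is undefined and would poison the group mean.
#'
#' @param normalized Normalized expression tibble (first column `gene_id`).
#' @param meta Sample metadata tibble (`sample_id`, `group`).
#' @return Tibble with `gene_id`, `group`, `mean_expression`,
#'   `sd_expression`, `cv`, `n_samples`.
#' @export
cv_table <- function(normalized, meta) {
  m <- counts_matrix(normalized)
  stopifnot(all(colnames(m) %in% meta$sample_id))
  groups <- setNames(meta$group, meta$sample_id)[colnames(m)]
  per_group <- lapply(unique(groups), function(g) {
    sub <- m[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) abort(sprintf("group '%s' has fewer than 2 samples.", g))
    tibble(gene_id = rownames(m), group = g,
           mean_expression = rowMeans(sub),
           sd_expression = apply(sub, 1, sd),
           n_samples = ncol(sub))
  })
  out <- bind_rows(per_group)
  zero_genes <- unique(out$gene_id[out$mean_expression == 0])
  out <- out %>%
    filter(!(.data$gene_id %in% zero_genes)) %>%
    mutate(cv = .data$sd_expression / .data$mean_expression) %>%
    select(all_of(c("gene_id", "group", "mean_expression", "sd_expression",
                    "cv", "n_samples")))
  attr(out, "excluded_genes") <- zero_genes
  out
}

#' Group expression diversity: mean per-gene CV
#'
#' @param cvs A [cv_table()] restricted to one group (or with `group`
#'   column, then filtered by `group`).
#' @param genes Optional gene-id subset; default all.
#' @param group Optional group label to filter on.
#' @return Arithmetic mean CV over the subset.
#' @export
expression_diversity <- function(cvs, genes = NULL, group = NULL) {
  if (!is.null(group)) cvs <- filter(cvs, .data$group == !!group)
  if (!is.null(genes)) cvs <- filter(cvs, .data$gene_id %in% genes)
  if (nrow(cvs) == 0) abort("empty gene subset after exclusions.")
  mean(cvs$cv)
}

#' Decrease of expression diversity
#'
#' `d_cv = 1 - mean_cv_dome / mean_cv_wild`. Positive values mean the
#' domestic group is less diverse; negative values (an increase) are allowed.
#'
#' @param mean_cv_dome,mean_cv_wild Group mean CVs; `mean_cv_wild` must be
#'   strictly positive.
#' @return Proportion (<= 1).
#' @examples
#' d_cv(1.054, 1.205)  # 0.1253 -> "12.5% decrease"
#' @export
d_cv <- function(mean_cv_dome, mean_cv_wild) {
  if (any(mean_cv_wild <= 0)) abort("`mean_cv_wild` must be > 0.")
  1 - mean_cv_dome / mean_cv_wild
}

#' Compare per-gene CV vectors between domestic and wild groups
#'
#' Student's t-test on the per-gene CVs, by default unpaired with pooled
#' variance and the one-sided alternative that the domestic group's
#' diversity is lower. Welch and gene-paired variants are available.
#'
#' @param cvs_dome,cvs_wild Numeric per-gene CV vectors; for
#'   `method = "paired"` they must align gene-wise and have equal length.
#' @param alternative `"less"` (domestic < wild, default) or `"two.sided"`.
#' @param method `"pooled"`, `"welch"` or `"paired"`.
#' @param gene_set_label Label stored on the result (`"WGGS"`, `"CSGS"`,
#'   `"non-CSGS"`, ...).
#' @return Object of class `diversity_comparison` with fields
#'   `gene_set_label`, `mean_cv_dome`, `mean_cv_wild`, `d_cv`,
#'   `t_statistic`, `p_value`, `n_genes` (dome/wild), `alternative`,
#'   `method`, `degenerate`.
#' @export
compare_diversity <- function(cvs_dome, cvs_wild,
                              alternative = c("less", "two.sided"),
                              method = c("pooled", "welch", "paired"),
                              gene_set_label = "WGGS") {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  stopifnot(length(cvs_dome) >= 2, length(cvs_wild) >= 2)
  if (method == "paired" && length(cvs_dome) != length(cvs_wild)) {
    abort("paired comparison needs aligned, equal-length CV vectors.")
  }
  tt <- tryCatch(
    t.test(cvs_dome, cvs_wild, alternative = alternative,
           var.equal = (method == "pooled"), paired = (method == "paired")),
    error = function(e) NULL)
  degenerate <- is.null(tt)
  structure(list(
    gene_set_label = gene_set_label,
    mean_cv_dome = mean(cvs_dome),
    mean_cv_wild = mean(cvs_wild),
    d_cv = d_cv(mean(cvs_dome), mean(cvs_wild)),
    t_statistic = if (degenerate) NA_real_ else unname(tt$statistic),
    p_value = if (degenerate) NA_real_ else tt$p.value,
    n_genes = c(dome = length(cvs_dome), wild = length(cvs_wild)),
    alternative = alternative,
    method = method,
    degenerate = degenerate
  ), class = "diversity_comparison")
}

#' @export
print.diversity_comparison <- function(x, ...) {
  cat(sprintf("<diversity_comparison> %s: CV dome %.3f vs wild %.3f, D_cv = %.1f%%",
              x$gene_set_label, x$mean_cv_dome, x$mean_cv_wild, 100 * x$d_cv))
  if (x$degenerate) {
    cat("  (degenerate input: p undefined)\n")
  } else {
    cat(sprintf("  (t = %.2f, %s p = %.3g%s)\n", x$t_statistic, x$alternative,
                x$p_value, significance_stars(x$p_value, prefix = " ")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a diversity comparison into a one-row tibble
#'
#' @param x A `diversity_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `gene_set`, `n_genes_dome`, `n_genes_wild`,
#'   `mean_cv_dome`, `mean_cv_wild`, `d_cv`, `statistic`, `p.value`,
#'   `alternative`, `method`.
#' @export
tidy.diversity_comparison <- function(x, ...) {
  tibble(gene_set = x$gene_set_label,
         n_genes_dome = unname(x$n_genes["dome"]),
         n_genes_wild = unname(x$n_genes["wild"]),
         mean_cv_dome = x$mean_cv_dome,
         mean_cv_wild = x$mean_cv_wild,
         d_cv = x$d_cv,
         statistic = x$t_statistic,
         p.value = x$p_value,
         alternative = x$alternative,
         method = x$method)
}

#' @rdname tidy.diversity_comparison
#' @export
glance.diversity_comparison <- function(x, ...) {
  tibble(d_cv = x$d_cv, statistic = x$t_statistic, p.value = x$p_value,
         n_genes = sum(x$n_genes), degenerate = x$degenerate)
}

#' Partition analyzed genes into candidate-selected and background sets
#'
#' Genes whose annotated interval overlaps any candidate sweep region by at
#' least 1 bp form the candidate selected gene set (CSGS); the rest of the
#' analyzed genes are the non-CSGS, and their union is the whole-genome gene
#' set (WGGS). Analyzed genes absent from the annotation are dropped with a
#' warning and listed in attribute `"missing_genes"`.
#'
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param sweeps Sweep regions: tibble with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [merge_regions()].
#' @param analyzed_genes Character vector of gene ids under analysis
#'   (typically the genes retained by [cv_table()]).
#' @return List of class `gene_set_partition` with character vectors `wggs`,
#'   `csgs`, `non_csgs`.
#' @export
partition_gene_sets <- function(annotation, sweeps, analyzed_genes) {
  missing <- setdiff(analyzed_genes, annotation$gene_id)
  if (length(missing) > 0) {
    warn(sprintf("%d analyzed gene(s) missing from annotation (e.g. %s); excluded.",
                 length(missing), missing[1]))
  }
  wggs <- intersect(analyzed_genes, annotation$gene_id)
  ann <- filter(annotation, .data$gene_id %in% wggs)
  if (nrow(ann) == 0 || nrow(sweeps) == 0) {
    csgs <- character()
  } else {
    gr_genes <- GenomicRanges::GRanges(
      ann$chrom, IRanges::IRanges(ann$start + 1, ann$end))
    gr_sweeps <- GenomicRanges::GRanges(
      sweeps$chrom, IRanges::IRanges(sweeps$start + 1, sweeps$end))
    hit <- GenomicRanges::countOverlaps(gr_genes, gr_sweeps, minoverlap = 1) > 0
    csgs <- ann$gene_id[hit]
  }
  out <- structure(list(wggs = wggs, csgs = csgs,
                        non_csgs = setdiff(wggs, csgs)),
                   class = "gene_set_partition")
  attr(out, "missing_genes") <- missing
  out
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf("<gene_set_partition> WGGS %d = CSGS %d + non-CSGS %d (PCSGS %.2f%%)\n",
              length(x$wggs), length(x$csgs), length(x$non_csgs),
              pcsgs(length(x$csgs), length(x$wggs))))
  invisible(x)
}

#' Percentage of candidate selected genes
#'
#' `100 * n_csgs / n_wggs`, reported to two decimals by default.
#'
#' @param n_csgs,n_wggs Gene counts with `0 <= n_csgs <= n_wggs` and
#'   `n_wggs > 0`.
#' @param digits Decimal places (`NULL` for full precision).
#' @return Percentage.
#' @examples
#' pcsgs(294, 24580)  # 1.20
#' @export
pcsgs <- function(n_csgs, n_wggs, digits = 2) {
  if (any(n_wggs <= 0)) abort("`n_wggs` must be > 0.")
  if (any(n_csgs < 0 | n_csgs > n_wggs)) abort("need 0 <= n_csgs <= n_wggs.")
  out <- 100 * n_csgs / n_wggs
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Significance stars for p-values
#'
#' `***`, `**`, `*` for p below 0.001, 0.01 and 0.05; empty otherwise.
#'
#' @param p Numeric p-values.
#' @param prefix String prepended to non-empty stars.
#' @return Character vector.
#' @export
significance_stars <- function(p, prefix = "") {
  out <- dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
  ifelse(out == "", out, paste0(prefix, out))
}
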