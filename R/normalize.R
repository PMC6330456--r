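#' Median-of-ratios size factors
#'
#' The classic count-normalization estimator: for sample *j*, the factor is
#' the median over eligible genes of `counts[i, j]` divided by the geometric
#' mean of gene *i* across all samples. Eligible genes are those with
#' strictly positive counts in every sample (the geometric mean is otherwise
#' zero).
#'
#' @param counts Count tibble: first column `gene_id`, remaining columns one
#'   per sample, non-negative integers.
#' @return Named numeric vector of positive per-sample factors.
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                          s1 = c(10, 30, 50), s2 = c(20, 60, 100))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  eligible <- rowSums(m > 0) == ncol(m)
  if (!any(eligible)) {
    abort("no gene has strictly positive counts in every sample; size factors are undefined.")
  }
  loggeo <- rowMeans(log(m[eligible, , drop = FALSE]))
  factors <- apply(m[eligible, , drop = FALSE], 2,
                   function(col) exp(median(log(col) - loggeo)))
  setNames(factors, colnames(m))
}

#' Divide counts by per-sample size factors
#'
#' @param counts Count tibble (see [size_factors()]).
#' @param factors Positive numeric vector, one per sample, in column order or
#'   named by sample id.
#' @return Tibble of the same shape with normalized values; attribute
#'   `"unit"` is `"size-factor-normalized count"`.
#' @export
normalize_counts <- function(counts, factors = size_factors(counts)) {
  m <- counts_matrix(counts)
  if (length(factors) != ncol(m)) {
    abort(sprintf("got %d size factors for %d samples.", length(factors), ncol(m)))
  }
  if (!is.null(names(factors))) factors <- factors[colnames(m)]
  if (any(!is.finite(factors) | factors <= 0)) abort("size factors must be positive.")
  out <- sweep(m, 2, factors, "/")
  structure(bind_cols_counts(counts$gene_id, out),
            unit = "size-factor-normalized count")
}

#' Fragments per kilobase per million (FPKM)
#'
#' `fpkm[i, j] = counts[i, j] * 1e9 / (length_i * total_j)`, where `total_j`
#' is the column sum of the supplied count matrix (the panel's own mapped
#' fragments; no external depth figure enters).
#'
#' @param counts Count tibble (see [size_factors()]).
#' @param lengths_bp Named numeric vector of gene lengths in bp covering
#'   every gene, e.g. from [gene_lengths()].
#' @return Tibble of the same shape; attribute `"unit"` is `"FPKM"`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g", s1 = 100)
#' fpkm(counts, c(g = 1000))  # against a 100-count library this is 1e6 FPKM
#' @export
fpkm <- function(counts, lengths_bp) {
  m <- counts_matrix(counts)
  missing <- setdiff(rownames(m), names(lengths_bp))
  if (length(missing) > 0) {
    abort(sprintf("missing gene length for %d gene(s), e.g. %s.",
                  length(missing), missing[1]))
  }
  len <- lengths_bp[rownames(m)]
  if (any(len <= 0)) abort("gene lengths must be > 0.")
  totals <- colSums(m)
  if (any(totals <= 0)) abort("every sample must have a positive column total.")
  out <- sweep(m * 1e9 / len, 2, totals, "/")
  structure(bind_cols_counts(counts$gene_id, out), unit = "FPKM")
}

#' Expressed-gene census across FPKM thresholds
#'
#' A gene counts as expressed in a sample when its FPKM is strictly greater
#' than the threshold. The default threshold ladder is 0, 0.1, 0.5, 1 and 5.
#'
#' @param fpkm_tbl FPKM tibble from [fpkm()].
#' @param thresholds Non-negative thresholds.
#' @param meta Optional sample metadata; when given, a per-group mean is
#'   appended.
#' @return Tibble with `sample_id`, `threshold`, `n_expressed` (and `group`
#'   if `meta` was supplied).
#' @export
count_expressed <- function(fpkm_tbl, thresholds = c(0, 0.1, 0.5, 1, 5),
                            meta = NULL) {
  stopifnot(all(thresholds >= 0))
  m <- counts_matrix(fpkm_tbl)
  out <- tidyr::expand_grid(sample_id = colnames(m), threshold = thresholds) %>%
    mutate(n_expressed = purrr::map2_int(
      .data$sample_id, .data$threshold,
      function(s, t) sum(m[, s] > t)))
  if (!is.null(meta)) {
    out <- left_join(out, select(meta, all_of(c("sample_id", "group"))),
                     by = "sample_id")
  }
  out
}

#' Equalize group sizes by sequencing depth
#'
#' Comparing dispersion-based statistics between groups of unequal size is
#' biased, so every group is cut down to the smallest group size, keeping the
#' samples with the most clean reads. Ties on `clean_reads` are broken toward
#' the lexicographically smaller sample id.
#'
#' @param meta Tibble with at least `sample_id`, `group`, `clean_reads`.
#' @return Character vector of retained sample ids.
#' @examples
#' meta <- tibble::tibble(sample_id = c("d1", "w1", "w2"),
#'                        group = c("domestic", "wild", "wild"),
#'                        clean_reads = c(10, 30, 20))
#' balance_samples(meta)
#' @export
balance_samples <- function(meta) {
  stopifnot(all(c("sample_id", "group", "clean_reads") %in% names(meta)))
  sizes <- table(meta$group)
  if (length(sizes) < 2) abort("balance_samples needs two or more groups.")
  if (any(sizes == 0)) abort("empty group.")
  k <- min(sizes)
  meta %>%
    group_by(.data$group) %>%
    arrange(desc(.data$clean_reads), .data$sample_id, .by_group = TRUE) %>%
    slice_head(n = k) %>%
    ungroup() %>%
    pull("sample_id")
}

# count tibble -> numeric matrix with gene_id rownames
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "gene_id")
  if (anyDuplicated(counts$gene_id)) abort("duplicate gene ids.")
  if (anyDuplicated(names(counts))) abort("duplicate sample ids.")
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0)) {
    abort("counts must be finite, non-negative numbers.")
  }
  rownames(m) <- counts$gene_id
  m
}
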