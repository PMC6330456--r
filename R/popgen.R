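#' Nei's nucleotide diversity over an interval
#'
#' Per-site unbiased heterozygosity summed over callable sites and divided by
#' the interval length:
#' \deqn{\pi = \frac{1}{L} \sum_s \frac{n_s}{n_s - 1} 2 p_s (1 - p_s)}
#' where \eqn{n_s} is the number of non-missing allele calls in the
#' population at site *s* and \eqn{p_s} the alt-allele frequency. This equals
#' the mean pairwise difference per site among the population's allele calls.
#' Sites with fewer than 2 called alleles are skipped.
#'
#' @param v A [variant_table()].
#' @param pop Population label (`"domestic"` or `"wild"`).
#' @param chrom Chromosome id.
#' @param start,end Interval in 0-based half-open coordinates; `L = end -
#'   start`.
#' @return Nucleotide diversity per bp; attribute `"n_sites"` counts the
#'   callable sites used (0 sites gives pi = 0).
#' @export
nucleotide_diversity <- function(v, pop, chrom, start, end) {
  stopifnot(inherits(v, "variant_table"), end > start)
  h <- site_heterozygosity(v, pop)
  q <- v$sites$pos - 1L  # 0-based site coordinate
  use <- v$sites$chrom == chrom & q >= start & q < end & !is.na(h)
  structure(sum(h[use]) / (end - start), n_sites = sum(use))
}

# per-site unbiased heterozygosity n/(n-1) * 2p(1-p); NA when < 2 allele calls
site_heterozygosity <- function(v, pop) {
  g <- v$geno[, pop_columns(v, pop), drop = FALSE]
  n <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / ifelse(n > 0, n, NA_real_)
  ifelse(n >= 2, n / (n - 1) * 2 * p * (1 - p), NA_real_)
}

#' Sliding windows over a genome
#'
#' Windows of `window_bp` starting every `step_bp` from coordinate 0; full
#' windows only (`start + window_bp <= length`), plus one terminal truncated
#' window starting one step after the last full window whenever the
#' chromosome end would otherwise be uncovered.
#'
#' @param chrom_lengths Named numeric vector (chrom -> length in bp) or a
#'   tibble with columns `chrom`, `length`.
#' @param window_bp,step_bp Window and step sizes; `window_bp >= step_bp >
#'   0`.
#' @param keep_truncated Emit the terminal truncated window (default TRUE).
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' make_windows(c(chr1 = 250000))  # 16 full 100-kb windows, 10-kb step
#' @export
make_windows <- function(chrom_lengths, window_bp = 100000, step_bp = 10000,
                         keep_truncated = TRUE) {
  stopifnot(window_bp >= step_bp, step_bp > 0)
  if (is.data.frame(chrom_lengths)) {
    chrom_lengths <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  }
  purrr::imap_dfr(chrom_lengths, function(len, ch) {
    if (len >= window_bp) {
      starts <- seq(0, len - window_bp, by = step_bp)
      ends <- starts + window_bp
    } else {
      starts <- ends <- numeric(0)
    }
    covered <- if (length(ends)) max(ends) else 0
    if (keep_truncated && covered < len) {
      nxt <- if (length(starts)) max(starts) + step_bp else 0
      starts <- c(starts, nxt)
      ends <- c(ends, len)
    }
    tibble(chrom = ch, start = as.integer(starts), end = as.integer(ends))
  })
}

# sum per-site values (NA = unusable) over 0-based half-open intervals;
# returns list(sum = ..., n_sites = ...) aligned with `intervals` rows
sum_in_intervals <- function(chrom, pos0, values, intervals) {
  out_sum <- numeric(nrow(intervals))
  out_n <- integer(nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    sel <- which(chrom == ch & !is.na(values))
    sel <- sel[order(pos0[sel])]
    q <- pos0[sel]
    cs <- c(0, cumsum(values[sel]))
    rows <- which(intervals$chrom == ch)
    hi <- findInterval(intervals$end[rows] - 1L, q)
    lo <- findInterval(intervals$start[rows] - 1L, q)
    out_sum[rows] <- cs[hi + 1] - cs[lo + 1]
    out_n[rows] <- hi - lo
  }
  list(sum = out_sum, n_sites = out_n)
}

#' Windowed nucleotide diversity
#'
#' @param v A [variant_table()].
#' @param windows Window tibble from [make_windows()].
#' @param pop Population label.
#' @return `windows` with `pi` (per bp) and `n_sites` columns.
#' @export
pi_windowed <- function(v, windows, pop) {
  h <- site_heterozygosity(v, pop)
  acc <- sum_in_intervals(v$sites$chrom, v$sites$pos - 1L, h, windows)
  windows %>%
    mutate(pi = acc$sum / (.data$end - .data$start), n_sites = acc$n_sites)
}

#' Windowed Fst between the domestic and wild populations
#'
#' Per-site variance components are combined per window as a ratio of sums
#' (the "weighted" window estimator); per-site averaging is available via
#' `combine = "mean"`. Sites require at least one called genotype in each
#' population; windows with no usable site or a zero denominator get an `NA`
#' score (excluded from downstream quantiles).
#'
#' @param v A [variant_table()].
#' @param windows Window tibble from [make_windows()].
#' @param estimator `"weir-cockerham"` (default; diploid two-population
#'   variance components with observed heterozygosity) or `"hudson"`.
#' @param combine `"ratio-of-sums"` (default) or `"mean"` of per-site
#'   ratios.
#' @return `windows` with `score` (Fst) and `n_sites` columns.
#' @export
fst_windowed <- function(v, windows,
                         estimator = c("weir-cockerham", "hudson"),
                         combine = c("ratio-of-sums", "mean")) {
  estimator <- match.arg(estimator)
  combine <- match.arg(combine)
  comp <- if (estimator == "weir-cockerham") wc_site_components(v) else
    hudson_site_components(v)
  if (combine == "ratio-of-sums") {
    num <- sum_in_intervals(v$sites$chrom, v$sites$pos - 1L, comp$num, windows)
    den <- sum_in_intervals(v$sites$chrom, v$sites$pos - 1L, comp$den, windows)
    score <- ifelse(den$sum > 0, num$sum / den$sum, NA_real_)
    n_sites <- num$n_sites
  } else {
    ratio <- ifelse(comp$den > 0, comp$num / comp$den, NA_real_)
    acc <- sum_in_intervals(v$sites$chrom, v$sites$pos - 1L, ratio, windows)
    score <- ifelse(acc$n_sites > 0, acc$sum / acc$n_sites, NA_real_)
    n_sites <- acc$n_sites
  }
  n_empty <- sum(is.na(score))
  if (n_empty > 0) {
    message(sprintf("fst_windowed: %d window(s) without usable sites (score NA).",
                    n_empty))
  }
  windows %>% mutate(score = score, n_sites = n_sites)
}

# Weir-Cockerham (1984) two-population diploid variance components a and
# a + b + c per site; NA when either population lacks a called genotype or
# nbar <= 1
wc_site_components <- function(v) {
  g1 <- v$geno[, pop_columns(v, "domestic"), drop = FALSE]
  g2 <- v$geno[, pop_columns(v, "wild"), drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * pmax(n1, 1))
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * pmax(n2, 1))
  h1 <- rowSums(g1 == 1, na.rm = TRUE) / pmax(n1, 1)
  h2 <- rowSums(g2 == 1, na.rm = TRUE) / pmax(n2, 1)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  bad <- n1 < 1 | n2 < 1 | nbar <= 1 | nc <= 0
  list(num = ifelse(bad, NA_real_, a),
       den = ifelse(bad, NA_real_, a + b + cc))
}

# Hudson estimator components on allele counts; NA when < 2 allele calls in
# either population
hudson_site_components <- function(v) {
  g1 <- v$geno[, pop_columns(v, "domestic"), drop = FALSE]
  g2 <- v$geno[, pop_columns(v, "wild"), drop = FALSE]
  n1 <- 2 * rowSums(!is.na(g1)); n2 <- 2 * rowSums(!is.na(g2))
  p1 <- rowSums(g1, na.rm = TRUE) / pmax(n1, 1)
  p2 <- rowSums(g2, na.rm = TRUE) / pmax(n2, 1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
    p2 * (1 - p2) / pmax(n2 - 1, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- n1 < 2 | n2 < 2
  list(num = ifelse(bad, NA_real_, num), den = ifelse(bad, NA_real_, den))
}

#' Windowed wild-to-domestic diversity ratio
#'
#' `score = (pi_wild + pseudocount) / (pi_dome + pseudocount)`; high scores
#' flag windows where the domestic population lost diversity. The default
#' pseudocount is the smallest strictly positive windowed pi observed in
#' either population across the genome (recorded in attribute
#' `"pseudocount"` so every run log can echo it); it keeps windows with zero
#' domestic diversity finite while preserving their top rank.
#'
#' @param v A [variant_table()].
#' @param windows Window tibble from [make_windows()].
#' @param pseudocount Non-negative; `NULL` for the data-driven default.
#' @return `windows` with `pi_wild`, `pi_dome`, `score`, `n_sites`.
#' @export
pi_ratio_windowed <- function(v, windows, pseudocount = NULL) {
  pw <- pi_windowed(v, windows, "wild")
  pd <- pi_windowed(v, windows, "domestic")
  if (is.null(pseudocount)) {
    pos <- c(pw$pi[pw$pi > 0], pd$pi[pd$pi > 0])
    pseudocount <- if (length(pos)) min(pos) else 1e-8
  }
  stopifnot(pseudocount >= 0)
  out <- windows %>%
    mutate(pi_wild = pw$pi, pi_dome = pd$pi,
           score = (pw$pi + pseudocount) / (pd$pi + pseudocount),
           n_sites = pw$n_sites + pd$n_sites)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Per-gene nucleotide diversity
#'
#' [nucleotide_diversity()] evaluated over every annotated gene interval.
#'
#' @param v A [variant_table()].
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param pop Population label.
#' @return Tibble with `gene_id`, `pi`, `n_sites`, `no_callable_site`.
#' @export
gene_genetic_diversity <- function(v, annotation, pop) {
  h <- site_heterozygosity(v, pop)
  acc <- sum_in_intervals(v$sites$chrom, v$sites$pos - 1L, h, annotation)
  tibble(gene_id = annotation$gene_id,
         pi = acc$sum / (annotation$end - annotation$start),
         n_sites = acc$n_sites,
         no_callable_site = acc$n_sites == 0)
}
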