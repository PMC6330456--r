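# shared fixture builders and independent oracles

# diploid panel from an explicit haplotype matrix (sites x haplotypes, 0/1);
# haplotypes are paired in order into unphased genotypes
panel_from_haplotypes <- function(hap, pops, chrom = "chr1") {
  stopifnot(ncol(hap) %% 2 == 0, length(pops) == ncol(hap) / 2)
  n_dip <- ncol(hap) / 2
  geno <- sapply(seq_len(n_dip), function(j) hap[, 2 * j - 1] + hap[, 2 * j])
  geno <- matrix(as.integer(geno), nrow(hap), n_dip)
  ids <- sprintf("s%02d", seq_len(n_dip))
  colnames(geno) <- ids
  variant_table(
    tibble::tibble(chrom = chrom, pos = seq_len(nrow(hap)),
                   ref = "A", alt = "T"),
    geno,
    tibble::tibble(sample_id = ids, population = pops)
  )
}

# brute-force mean pairwise difference per site over all allele-call pairs;
# independent of the 2p(1-p) algebra used by the package
oracle_pi <- function(geno_pop, L) {
  total <- 0
  for (s in seq_len(nrow(geno_pop))) {
    d <- geno_pop[s, !is.na(geno_pop[s, ])]
    alleles <- unname(unlist(lapply(d, function(x) c(rep(1, x), rep(0, 2 - x)))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0
    pairs <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      diffs <- diffs + (alleles[i] != alleles[j])
      pairs <- pairs + 1
    }
    total <- total + diffs / pairs
  }
  total / L
}

# textbook Weir-Cockerham (1984) per-site components, written as an explicit
# scalar loop so it stays independent of the vectorized implementation
oracle_wc_fst <- function(geno, pops) {
  a_sum <- d_sum <- 0
  for (s in seq_len(nrow(geno))) {
    g1 <- geno[s, pops == "domestic"]; g1 <- g1[!is.na(g1)]
    g2 <- geno[s, pops == "wild"]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1 || (n1 + n2) / 2 <= 1) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    a_sum <- a_sum + a
    d_sum <- d_sum + a + b + cc
  }
  a_sum / d_sum
}

# random diploid two-population panel (may contain missing genotypes)
random_panel <- function(n_sites, n_dip_per_pop, miss_rate = 0, chrom = "chr1") {
  n_dip <- 2 * n_dip_per_pop
  geno <- matrix(rbinom(n_sites * n_dip, 2, runif(n_sites)), n_sites, n_dip)
  if (miss_rate > 0) {
    geno[runif(length(geno)) < miss_rate] <- NA_integer_
  }
  ids <- sprintf("s%02d", seq_len(n_dip))
  colnames(geno) <- ids
  variant_table(
    tibble::tibble(chrom = chrom, pos = seq_len(n_sites), ref = "A", alt = "C"),
    geno,
    tibble::tibble(sample_id = ids,
                   population = rep(c("domestic", "wild"), each = n_dip_per_pop))
  )
}

# toy count tibble
toy_counts <- function(m, gene_ids = sprintf("g%d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("s%d", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = gene_ids),
                   tibble::as_tibble(as.data.frame(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# class-fraction matrix with named cells, rows = genetic, cols = expression
fraction_matrix <- function(dec_dec = 0, unch_dec = 0, fill_rest = TRUE) {
  fr <- matrix(0, 3, 3,
               dimnames = list(c("decreased", "unchanged", "increased"),
                               c("decreased", "unchanged", "increased")))
  fr["decreased", "decreased"] <- dec_dec
  fr["unchanged", "decreased"] <- unch_dec
  if (fill_rest) fr[fr == 0] <- (1 - sum(fr)) / sum(fr == 0)
  fr
}
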