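make_filter_panel <- function() {
  sites <- tibble::tibble(
    chrom = "chr1", pos = 1:5,
    ref = c("A", "A", "A", "A", "A"),
    alt = c("T", "T,G", "T", "T", "T"),   # site 2 is triallelic
    qual = c(100, 100, 100, 100, 10),     # site 5 fails quality
    depth = c(50L, 50L, 50L, 50L, 50L))
  geno <- matrix(1L, 5, 10, dimnames = list(NULL, sprintf("s%02d", 1:10)))
  geno[3, ] <- c(1L, rep(0L, 9))          # site 3: MAF 0.05, not > 0.05
  gt_depth <- matrix(20L, 5, 10)
  gt_depth[4, 1:3] <- 2L                  # site 4: 3/10 genotypes under-read
  gt_qual <- matrix(60L, 5, 10)
  variant_table(sites, geno,
                tibble::tibble(sample_id = sprintf("s%02d", 1:10),
                               population = rep(c("domestic", "wild"), each = 5)),
                gt_depth = gt_depth, gt_qual = gt_qual)
}

test_that("variant filtering applies the cascade in order", {
  v <- make_filter_panel()
  out <- filter_variants(v, filter_config())
  # survivors: only site 1 (site 2 triallelic, 3 low MAF, 4 missingness 30%,
  # 5 low quality)
  expect_equal(out$sites$pos, 1L)
  log <- attr(out, "filter_log")
  expect_equal(log$n_removed[log$rule == "biallelic"], 1L)
  expect_equal(log$n_removed[log$rule == "site_quality"], 1L)
  expect_equal(log$n_removed[log$rule == "allele_freq"], 1L)
  expect_equal(log$n_removed[log$rule == "missingness"], 1L)

  # the 30%-missing site survives under the relaxed whole-genome cap
  relaxed <- filter_variants(v, filter_config(max_missing_fraction = 0.30))
  expect_true(4L %in% relaxed$sites$pos)
})

test_that("a panel without ancillary fields skips those rules with a warning", {
  v <- make_filter_panel()
  bare <- variant_table(dplyr::select(v$sites, -"qual", -"depth"),
                        v$geno, v$samples)
  warns <- testthat::capture_warnings(
    out <- filter_variants(bare, filter_config()))
  expect_true(any(grepl("skipping", warns)))
  expect_true(5L %in% out$sites$pos)  # quality rule skipped
})

test_that("nucleotide diversity matches hand-worked toys", {
  # monomorphic interval
  v0 <- panel_from_haplotypes(matrix(0L, 3, 4), c("wild", "wild"))
  expect_equal(as.numeric(nucleotide_diversity(v0, "wild", "chr1", 0, 100)), 0)

  # 2 haplotypes, 1 differing site, L = 100: one pair, one difference
  v1 <- panel_from_haplotypes(matrix(c(0L, 1L), 1, 2), "wild")
  expect_equal(as.numeric(nucleotide_diversity(v1, "wild", "chr1", 0, 100)), 0.01)

  # 4 haplotypes, allele counts 2/2, L = 1: 4 of 6 pairs differ
  v2 <- panel_from_haplotypes(matrix(c(1L, 1L, 0L, 0L), 1, 4),
                              c("wild", "wild"))
  expect_equal(as.numeric(nucleotide_diversity(v2, "wild", "chr1", 0, 1)), 2 / 3)
})

test_that("pi equals exhaustive mean pairwise differences on random panels", {
  withr::with_seed(31, {
    for (rep in 1:40) {
      n_dip <- sample(2:4, 1)  # up to 8 haplotypes
      v <- random_panel(n_sites = sample(3:10, 1), n_dip_per_pop = n_dip,
                        miss_rate = 0.1)
      L <- max(v$sites$pos)
      got <- as.numeric(nucleotide_diversity(v, "wild", "chr1", 0, L))
      want <- oracle_pi(v$geno[, v$samples$population == "wild", drop = FALSE], L)
      expect_equal(got, want, tolerance = 1e-12)
      expect_gte(got, 0)
    }
  })
})

test_that("sliding windows tile the genome as specified", {
  expect_equal(nrow(make_windows(c(chr1 = 250000))), 16)  # starts 0..150 kb
  w1 <- make_windows(c(chr1 = 100000))
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$start, w1$end), c(0L, 100000L))

  # terminal truncated window appears only when the tail is uncovered
  w2 <- make_windows(c(chr1 = 105000))
  expect_equal(nrow(w2), 2)
  expect_equal(w2$end[2], 105000L)
  expect_equal(nrow(make_windows(c(chr1 = 105000), keep_truncated = FALSE)), 1)

  # coverage oracle on a toy chromosome: every base in >= 1 window
  w3 <- make_windows(c(chr1 = 1000), window_bp = 300, step_bp = 100)
  covered <- rep(FALSE, 1000)
  for (i in seq_len(nrow(w3))) {
    covered[(w3$start[i] + 1):w3$end[i]] <- TRUE
  }
  expect_true(all(covered))
})

test_that("both Fst estimators hit the boundary cases", {
  # fixed difference, equal sample sizes -> Fst = 1
  hap <- matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), 1)
  v_fix <- panel_from_haplotypes(hap, c("domestic", "domestic", "wild", "wild"))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  expect_equal(fst_windowed(v_fix, w, "weir-cockerham")$score, 1)
  expect_equal(fst_windowed(v_fix, w, "hudson")$score, 1)

  # identical allele frequencies at every site -> at most ~0
  geno_eq <- matrix(rep(c(0L, 1L, 2L, 1L), 2 * 5), 5, 8, byrow = TRUE,
                    dimnames = list(NULL, sprintf("s%02d", 1:8)))
  v_eq <- variant_table(
    tibble::tibble(chrom = "chr1", pos = 1:5, ref = "A", alt = "T"),
    geno_eq,
    tibble::tibble(sample_id = sprintf("s%02d", 1:8),
                   population = rep(c("domestic", "wild"), each = 4)))
  expect_lte(fst_windowed(v_eq, w, "weir-cockerham")$score, 0.05)
  expect_lte(fst_windowed(v_eq, w, "hudson")$score, 0.05)
})

test_that("window Fst equals an independently coded textbook evaluation", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      v <- random_panel(n_sites = 20, n_dip_per_pop = 6, miss_rate = 0.05)
      w <- tibble::tibble(chrom = "chr1", start = 0L, end = 25L)
      got <- fst_windowed(v, w, "weir-cockerham")$score
      want <- oracle_wc_fst(v$geno, rep(c("domestic", "wild"), each = 6))
      expect_equal(got, want, tolerance = 1e-12)
      expect_lte(got, 1)
      expect_lte(fst_windowed(v, w, "hudson")$score, 1)
    }
  })
})

test_that("windows without usable sites get NA scores", {
  v <- random_panel(n_sites = 5, n_dip_per_pop = 3)
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(50L, 200L))
  suppressMessages(out <- fst_windowed(v, w))
  expect_true(is.na(out$score[2]))
  expect_false(is.na(out$score[1]))
})

test_that("pi-ratio handles equal diversity and zero-domestic windows", {
  hap <- matrix(c(1L, 0L, 1L, 0L), 2, 4, byrow = FALSE)
  v <- panel_from_haplotypes(rbind(c(1L, 0L, 1L, 0L)),
                             c("domestic", "wild"))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 10L)
  expect_equal(pi_ratio_windowed(v, w, pseudocount = 0)$score, 1)

  # domestic monomorphic: finite score, monotone decreasing in pseudocount
  v0 <- panel_from_haplotypes(rbind(c(0L, 0L, 1L, 0L)),
                              c("domestic", "wild"))
  s1 <- pi_ratio_windowed(v0, w, pseudocount = 1e-4)$score
  s2 <- pi_ratio_windowed(v0, w, pseudocount = 1e-3)$score
  expect_true(is.finite(s1) && is.finite(s2))
  expect_gt(s1, s2)

  # default pseudocount is recorded
  out <- pi_ratio_windowed(v0, w)
  expect_gt(attr(out, "pseudocount"), 0)
})

test_that("top-quantile selection keeps threshold ties", {
  w <- tibble::tibble(chrom = "chr1", start = 0:99, end = 1:100,
                      score = 1:100)
  expect_equal(sort(top_quantile_regions(w, 0.05)$score), 96:100)
  expect_equal(nrow(top_quantile_regions(w, 1)), 100)
  w$score <- 7
  expect_equal(nrow(top_quantile_regions(w, 0.05)), 100)
  w$score <- NA_real_
  expect_error(top_quantile_regions(w), "undefined")
})

test_that("region merging is a disjoint union of its inputs", {
  w <- tibble::tibble(chrom = "chr1",
                      start = c(0L, 50000L, 200000L),
                      end = c(100000L, 150000L, 300000L))
  out <- merge_regions(w)
  expect_equal(out$start, c(0L, 200000L))
  expect_equal(out$end, c(150000L, 300000L))

  expect_equal(nrow(merge_regions(w[0, ])), 0)
  expect_equal(as.data.frame(merge_regions(out)), as.data.frame(out))  # idempotent

  # measure preservation against a brute-force position scan
  withr::with_seed(41, {
    for (rep in 1:5) {
      starts <- sample.int(5000, 20)
      win <- tibble::tibble(chrom = sample(c("c1", "c2"), 20, TRUE),
                            start = starts, end = starts + sample.int(500, 20))
      merged <- merge_regions(win)
      for (ch in c("c1", "c2")) {
        hit <- rep(FALSE, 6000)
        sub <- win[win$chrom == ch, ]
        for (i in seq_len(nrow(sub))) hit[(sub$start[i] + 1):sub$end[i]] <- TRUE
        msub <- merged[merged$chrom == ch, ]
        mhit <- rep(FALSE, 6000)
        for (i in seq_len(nrow(msub))) mhit[(msub$start[i] + 1):msub$end[i]] <- TRUE
        expect_identical(mhit, hit)
        if (nrow(msub) > 1) {
          expect_true(all(msub$start[-1] > msub$end[-nrow(msub)]))
        }
      }
    }
  })
})

test_that("external window scores round-trip and reject malformed input", {
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                      end = c(100000L, 110000L), score = c(1.5, 2.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_window_scores(w, path)
  back <- ingest_external_scores(path)
  expect_equal(back[, c("chrom", "start", "end", "score")], w)

  # 1-based closed input shifts starts down by one
  lines <- c("# coordinates=1-based-closed",
             "chrom\tstart\tend\tscore", "chr1\t1\t100000\t3.2")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, p2)
  one <- ingest_external_scores(p2)
  expect_equal(c(one$start, one$end), c(0L, 100000L))

  bad <- c("chrom\tstart\tend\tscore", "chr1\t0\t100\thigh")
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(bad, p3)
  expect_error(ingest_external_scores(p3), "line 2")
})

test_that("per-gene diversity is additive over disjoint genes", {
  withr::with_seed(51, v <- random_panel(n_sites = 200, n_dip_per_pop = 4))
  ann <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                        start = c(0L, 100L), end = c(100L, 200L))
  per_gene <- gene_genetic_diversity(v, ann, "wild")
  combined <- gene_genetic_diversity(
    v, tibble::tibble(gene_id = "all", chrom = "chr1",
                      start = 0L, end = 200L), "wild")
  expect_equal(combined$pi, sum(per_gene$pi * 100) / 200)

  empty <- gene_genetic_diversity(
    v, tibble::tibble(gene_id = "void", chrom = "chr2",
                      start = 0L, end = 100L), "wild")
  expect_equal(empty$pi, 0)
  expect_true(empty$no_callable_site)
})

test_that("a simulated panel survives a VCF round trip", {
  sim <- simulate_genotypes(sim_config(n_variant_sites = 100,
                                       n_chromosomes = 1, seed = 9))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$variants, path, chrom_lengths = c(chr1 = 1e6))
  back <- read_vcf(path, sim$variants$samples)
  expect_equal(back$geno, sim$variants$geno)
  expect_equal(back$sites$pos, sim$variants$sites$pos)
  expect_equal(back$sites$depth, sim$variants$sites$depth)
  expect_equal(unname(back$gt_qual), unname(sim$variants$gt_qual))
})
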