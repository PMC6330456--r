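test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_samples_per_group = 3), ">= 4")
  expect_error(sim_config(selected_cv_reduction = 1), "\\[0, 1\\)")
  expect_error(sim_config(sweep_diversity_factor = 0), "\\(0, 1\\]")
  expect_error(sim_config(n_haplotypes_per_pop = 7), "even")
  expect_error(sim_config(sweep_intervals = tibble::tibble(
    chrom = "chr1", start = 0L, end = 2e6), chrom_length_bp = 1e6),
    "chromosome bounds")
  expect_error(sim_config(sweep_intervals = tibble::tibble(
    chrom = "chr9", start = 0L, end = 100L)), "unknown chromosome")
})

test_that("all four generators are deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 60, n_variant_sites = 300, seed = 17,
                    sweep_intervals = tibble::tibble(chrom = "chr1",
                                                     start = 0L, end = 2e5))
  expect_identical(simulate_expression_pair(cfg), simulate_expression_pair(cfg))
  expect_identical(simulate_genotypes(cfg), simulate_genotypes(cfg))
  expect_identical(simulate_annotation(cfg), simulate_annotation(cfg))
  fr <- fraction_matrix(0.4, 0.2)
  expect_identical(simulate_enhancer_pairs(cfg, fr, 50),
                   simulate_enhancer_pairs(cfg, fr, 50))
  # different seeds give different draws
  cfg2 <- sim_config(n_genes = 60, seed = 18)
  expect_false(identical(simulate_expression_pair(cfg2)$counts,
                         simulate_expression_pair(cfg)$counts))
})

test_that("no planting is requested when selected_fraction is zero", {
  sim <- simulate_expression_pair(sim_config(n_genes = 40,
                                             selected_fraction = 0, seed = 2))
  expect_length(sim$truth$selected_gene_ids, 0)
})

test_that("expression matrix has the documented shape and metadata", {
  cfg <- sim_config(n_genes = 30, n_samples_per_group = 6, seed = 5)
  sim <- simulate_expression_pair(cfg)
  expect_equal(dim(sim$counts), c(30, 13))  # gene_id + 12 samples
  expect_equal(sort(unique(sim$metadata$group)), c("domestic", "wild"))
  expect_equal(sim$metadata$clean_reads,
               as.integer(colSums(as.matrix(sim$counts[, -1]))))
})

test_that("empirical CVs converge to the analytic NB calibration", {
  # with many samples the per-gene sample CV approaches sqrt(1/mu + 1/k),
  # and planted genes approach (1 - reduction) x wild CV
  cfg <- sim_config(n_genes = 400, n_samples_per_group = 400,
                    selected_fraction = 0.5, selected_cv_reduction = 0.3,
                    libsize_sigma = 0, seed = 23)
  sim <- simulate_expression_pair(cfg)
  cvs <- cv_table(sim$counts, sim$metadata)
  sel <- sim$truth$selected_gene_ids
  mean_cv <- function(g, ids) expression_diversity(cvs, genes = ids, group = g)
  ratio_sel <- mean_cv("domestic", sel) / mean_cv("wild", sel)
  expect_equal(ratio_sel, 1 - 0.3, tolerance = 0.02)
  bg <- setdiff(unique(cvs$gene_id), sel)
  ratio_bg <- mean_cv("domestic", bg) / mean_cv("wild", bg)
  expect_equal(ratio_bg, 1, tolerance = 0.02)
})

test_that("annotation tiles chromosomes with disjoint, in-bounds genes", {
  cfg <- sim_config(n_genes = 10, n_chromosomes = 1, chrom_length_bp = 1e5,
                    gene_length_bp = 2000, seed = 1)
  ann <- simulate_annotation(cfg)
  expect_lte(max(ann$end), 1e5)
  expect_true(all(ann$end - ann$start == 2000))
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))

  # ids match the expression generator for the same config
  sim <- simulate_expression_pair(cfg)
  expect_identical(ann$gene_id, sim$counts$gene_id)

  # disjointness via interval arithmetic: merged length equals summed length
  merged <- merge_regions(ann)
  expect_equal(sum(merged$end - merged$start), sum(ann$end - ann$start))

  expect_error(simulate_annotation(
    sim_config(n_genes = 100, n_chromosomes = 1, chrom_length_bp = 1e4,
               gene_length_bp = 2000)), "cannot place")
})

test_that("neutral genotypes match the Beta-law heterozygosity in both populations", {
  cfg <- sim_config(n_variant_sites = 6000, n_chromosomes = 1,
                    beta_shape = 0.5, seed = 29)
  sim <- simulate_genotypes(cfg)
  w <- tibble::tibble(chrom = "chr1", start = 0L,
                      end = as.integer(cfg$chrom_length_bp))
  # closed form: E[2p(1-p)] = a/(2a+1) = 0.25 per segregating site
  for (pop in c("domestic", "wild")) {
    pw <- pi_windowed(sim$variants, w, pop)
    mean_site_het <- pw$pi * cfg$chrom_length_bp / pw$n_sites
    expect_equal(mean_site_het, 0.25, tolerance = 0.02)
  }
  # expected windowed ratio ~ 1 genome-wide without sweeps
  scored <- pi_ratio_windowed(sim$variants, make_windows(c(chr1 = 1e6)))
  expect_equal(mean(scored$score), 1, tolerance = 0.1)
})

test_that("planted sweeps depress domestic diversity in nearly all replicates", {
  sweep <- tibble::tibble(chrom = "chr1", start = 400000L, end = 600000L)
  hits <- vapply(1:50, function(i) {
    cfg <- sim_config(n_chromosomes = 1, n_variant_sites = 2000,
                      sweep_intervals = sweep, sweep_diversity_factor = 0.2,
                      seed = 1000 + i)
    sim <- simulate_genotypes(cfg)
    scored <- pi_ratio_windowed(sim$variants, make_windows(c(chr1 = 1e6)))
    ov <- scored$start < 600000 & scored$end > 400000
    mean(scored$score[ov]) > mean(scored$score[!ov])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("frequency compression scales heterozygosity by the sweep factor", {
  p <- seq(0.01, 0.99, by = 0.01)
  for (f in c(0.2, 0.5, 0.9)) {
    pc <- exdiv:::compress_frequency(p, f)
    expect_equal(2 * pc * (1 - pc), f * 2 * p * (1 - p), tolerance = 1e-12)
  }
  # monotone in the factor: smaller factor, less heterozygosity
  h <- function(f) 2 * exdiv:::compress_frequency(0.3, f) *
    (1 - exdiv:::compress_frequency(0.3, f))
  expect_true(h(0.1) < h(0.5) && h(0.5) < h(1))
})

test_that("enhancer-pair planting honours the class fractions", {
  cfg <- sim_config(seed = 3)
  all_dec <- fraction_matrix(1, 0, fill_rest = FALSE)
  pairs <- simulate_enhancer_pairs(cfg, all_dec, n_pairs = 20)
  expect_true(all(pairs$pi_dome < pairs$pi_wild))
  expect_true(all(pairs$cv_dome < pairs$cv_wild))

  expect_equal(nrow(simulate_enhancer_pairs(cfg, all_dec, n_pairs = 0)), 0)
  bad <- fraction_matrix(0.5, 0.2, fill_rest = FALSE)
  expect_error(simulate_enhancer_pairs(cfg, bad), "sum to 1")
})

test_that("simulation truth survives a JSON round trip", {
  cfg <- sim_config(n_genes = 30, seed = 13,
                    sweep_intervals = tibble::tibble(chrom = "chr1",
                                                     start = 0L, end = 1e5))
  sim <- simulate_expression_pair(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(sim$truth, path)
  back <- read_sim_truth(path)
  expect_equal(back$selected_gene_ids, sim$truth$selected_gene_ids)
  expect_equal(back$planted_dcv_selected, sim$truth$planted_dcv_selected)
  expect_equal(back$sweep_intervals, sim$truth$sweep_intervals)
})
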