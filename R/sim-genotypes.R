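#' Simulate a two-population biallelic genotype panel with planted sweeps
#'
#' Sites are placed uniformly over the simulated genome. Neutral alt-allele
#' frequencies are drawn independently per population from a symmetric
#' Beta(`beta_shape`, `beta_shape`) law, so the expected per-site
#' heterozygosity is `beta_shape / (2 * beta_shape + 1)` in both populations
#' and the expected windowed pi-ratio is 1 genome-wide. Inside each planted
#' sweep interval the domestic frequency is shrunk deterministically toward
#' the nearer of 0/1 so that its heterozygosity is exactly
#' `sweep_diversity_factor` times the neutral value:
#' \eqn{2p'(1-p') = f \cdot 2p(1-p)} solved on the same side of 1/2.
#' Unphased diploid genotypes are drawn Binomial(2, p); per-genotype
#' supporting reads and qualities plus site depth/quality are simulated so
#' the filtering cascade is exercised.
#'
#' @param config A [sim_config()].
#' @return A list with `variants` (a [variant_table()]) and `truth`
#'   (a `sim_truth` as in [simulate_expression_pair()]).
#' @examples
#' sim <- simulate_genotypes(sim_config(n_variant_sites = 200, seed = 1))
#' dim(sim$variants)
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  chroms <- sim_chrom_names(config$n_chromosomes)
  n_site <- config$n_variant_sites
  n_dip <- config$n_haplotypes_per_pop / 2

  withr::with_seed(derive_seed(config$seed, 2L), {
    chrom <- sort(sample(chroms, n_site, replace = TRUE))
    pos <- unlist(lapply(split(seq_len(n_site), chrom), function(idx) {
      sort(sample.int(config$chrom_length_bp, length(idx)))
    }), use.names = FALSE)
    ref_alt <- replicate(n_site, sample(c("A", "C", "G", "T"), 2))

    p_wild <- rbeta(n_site, config$beta_shape, config$beta_shape)
    p_dome <- rbeta(n_site, config$beta_shape, config$beta_shape)

    in_sweep <- rep(FALSE, n_site)
    iv <- config$sweep_intervals
    if (nrow(iv) > 0) {
      for (k in seq_len(nrow(iv))) {
        # intervals are 0-based half-open; pos is 1-based
        in_sweep <- in_sweep |
          (chrom == iv$chrom[k] & pos > iv$start[k] & pos <= iv$end[k])
      }
      p_dome[in_sweep] <- compress_frequency(p_dome[in_sweep],
                                             config$sweep_diversity_factor)
    }

    sample_ids <- c(sprintf("dome_%02d", seq_len(n_dip)),
                    sprintf("wild_%02d", seq_len(n_dip)))
    pops <- rep(c("domestic", "wild"), each = n_dip)
    geno <- matrix(NA_integer_, n_site, 2 * n_dip,
                   dimnames = list(NULL, sample_ids))
    for (j in seq_len(2 * n_dip)) {
      p <- if (pops[j] == "domestic") p_dome else p_wild
      geno[, j] <- rbinom(n_site, 2L, p)
    }

    gt_depth <- matrix(rpois(n_site * 2 * n_dip, 30) + 3L, n_site,
                       dimnames = list(NULL, sample_ids))
    gt_qual <- matrix(sample(20:99, n_site * 2 * n_dip, replace = TRUE),
                      n_site, dimnames = list(NULL, sample_ids))
    sites <- tibble(
      chrom = chrom, pos = pos,
      ref = ref_alt[1, ], alt = ref_alt[2, ],
      qual = round(runif(n_site, 40, 999), 1),
      depth = as.integer(rowSums(gt_depth))
    )
  })

  v <- variant_table(sites, geno,
                     tibble(sample_id = sample_ids, population = pops),
                     gt_depth = gt_depth, gt_qual = gt_qual)
  truth <- structure(list(
    selected_gene_ids = character(),
    planted_dcv_selected = NA_real_,
    planted_dcv_background = NA_real_,
    sweep_intervals = config$sweep_intervals,
    seed = config$seed
  ), class = "sim_truth")
  list(variants = v, truth = truth)
}

# deterministic shrink of allele frequency toward the nearer of 0/1 so that
# heterozygosity scales by exactly `factor`; monotone in `factor`
compress_frequency <- function(p, factor) {
  het <- pmin(4 * factor * p * (1 - p), 1)  # 4p'(1-p') after scaling by factor
  lower <- (1 - sqrt(1 - het)) / 2
  ifelse(p <= 0.5, lower, 1 - lower)
}
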