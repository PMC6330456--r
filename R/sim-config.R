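#' Simulation configuration for paired domestic/wild fixtures
#'
#' Bundles every tunable of the synthetic-data generators: a negative-binomial
#' expression simulator for two groups of replicate samples, a two-population
#' biallelic genotype simulator with planted low-diversity sweep intervals in
#' the domestic population, a deterministic gene-annotation layout, and an
#' enhancer--gene pair generator with planted joint diversity-change classes.
#'
#' The expression model draws a gene mean \eqn{\mu_g} from a log-normal law and
#' counts from NB(mean = \eqn{s_j \mu_g}, size = \eqn{k}), where \eqn{s_j} is a
#' per-sample log-normal library-size factor. Because for the NB law
#' \eqn{CV^2 = 1/\mu + 1/k}, the domestic size parameter of a planted
#' "selected" gene is solved so that its expected CV equals
#' \eqn{(1 - \code{selected_cv_reduction})} times the wild expected CV.
#'
#' @param n_genes Number of genes.
#' @param n_samples_per_group Replicates per group (domestic and wild); at
#'   least 4, mirroring typical replication in domestication transcriptome
#'   panels.
#' @param mean_log_expression Location of the log-normal gene-mean law
#'   (natural log of expected counts).
#' @param sd_log_expression Scale of the log-normal gene-mean law.
#' @param dispersion_wild,dispersion_dome Negative-binomial size parameter
#'   (`size` in [stats::rnbinom()]) for un-planted genes in each group.
#' @param selected_fraction Fraction of genes planted with a domestic CV
#'   reduction.
#' @param selected_cv_reduction Planted relative CV decrease (the expected
#'   D_cv) on selected genes; must be in `[0, 1)`.
#' @param extra_cv_reduction_background Planted relative CV decrease on
#'   non-selected genes (0 = none).
#' @param libsize_sigma Log-scale SD of the per-sample library-size factors.
#' @param n_chromosomes,chrom_length_bp Genome layout for annotation and
#'   genotypes.
#' @param n_variant_sites Total biallelic sites placed uniformly over the
#'   genome.
#' @param sweep_intervals Planted sweep intervals: a tibble/data frame with
#'   columns `chrom`, `start`, `end` (0-based half-open), or `NULL` for none.
#' @param sweep_diversity_factor Multiplier in `(0, 1]` applied to the
#'   expected domestic per-site heterozygosity inside sweep intervals.
#' @param beta_shape Shape of the symmetric Beta law for neutral allele
#'   frequencies; the expected per-site heterozygosity is
#'   `beta_shape / (2 * beta_shape + 1)`.
#' @param n_haplotypes_per_pop Haplotypes per population (even; genotypes are
#'   unphased diploid).
#' @param gene_length_bp Length of each simulated gene.
#' @param seed Integer seed; all four generators derive their streams from it.
#'
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes = 100, seed = 1)
#' cfg$n_samples_per_group
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_group = 5,
                       mean_log_expression = 5,
                       sd_log_expression = 1.5,
                       dispersion_wild = 1,
                       dispersion_dome = 1,
                       selected_fraction = 0.1,
                       selected_cv_reduction = 0.2,
                       extra_cv_reduction_background = 0,
                       libsize_sigma = 0.15,
                       n_chromosomes = 2,
                       chrom_length_bp = 1e6,
                       n_variant_sites = 4000,
                       sweep_intervals = NULL,
                       sweep_diversity_factor = 0.2,
                       beta_shape = 0.5,
                       n_haplotypes_per_pop = 20,
                       gene_length_bp = 2000,
                       seed = 1L) {
  cfg <- list(
    n_genes = n_genes,
    n_samples_per_group = n_samples_per_group,
    mean_log_expression = mean_log_expression,
    sd_log_expression = sd_log_expression,
    dispersion_wild = dispersion_wild,
    dispersion_dome = dispersion_dome,
    selected_fraction = selected_fraction,
    selected_cv_reduction = selected_cv_reduction,
    extra_cv_reduction_background = extra_cv_reduction_background,
    libsize_sigma = libsize_sigma,
    n_chromosomes = n_chromosomes,
    chrom_length_bp = chrom_length_bp,
    n_variant_sites = n_variant_sites,
    sweep_intervals = normalize_intervals(sweep_intervals),
    sweep_diversity_factor = sweep_diversity_factor,
    beta_shape = beta_shape,
    n_haplotypes_per_pop = n_haplotypes_per_pop,
    gene_length_bp = gene_length_bp,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

normalize_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  x %>%
    as_tibble() %>%
    select(all_of(c("chrom", "start", "end"))) %>%
    mutate(chrom = as.character(.data$chrom),
           start = as.integer(.data$start),
           end = as.integer(.data$end)) %>%
    arrange(.data$chrom, .data$start)
}

validate_sim_config <- function(cfg) {
  pos_count <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x == floor(x)
  if (!pos_count(cfg$n_genes)) abort("`n_genes` must be a positive integer.")
  if (!pos_count(cfg$n_samples_per_group) || cfg$n_samples_per_group < 4) {
    abort("`n_samples_per_group` must be an integer >= 4.")
  }
  for (f in c("dispersion_wild", "dispersion_dome", "sd_log_expression")) {
    if (!(is.finite(cfg[[f]]) && cfg[[f]] > 0)) abort(paste0("`", f, "` must be > 0."))
  }
  for (f in c("selected_fraction", "extra_cv_reduction_background")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0("`", f, "` must be in [0, 1]."))
  }
  if (cfg$selected_cv_reduction < 0 || cfg$selected_cv_reduction >= 1) {
    abort("`selected_cv_reduction` must be in [0, 1).")
  }
  if (cfg$sweep_diversity_factor <= 0 || cfg$sweep_diversity_factor > 1) {
    abort("`sweep_diversity_factor` must be in (0, 1].")
  }
  for (f in c("n_chromosomes", "chrom_length_bp", "n_variant_sites",
              "n_haplotypes_per_pop", "gene_length_bp")) {
    if (!pos_count(cfg[[f]])) abort(paste0("`", f, "` must be a positive integer."))
  }
  if (cfg$n_haplotypes_per_pop %% 2 != 0) {
    abort("`n_haplotypes_per_pop` must be even (unphased diploid genotypes).")
  }
  iv <- cfg$sweep_intervals
  if (nrow(iv) > 0) {
    ok_chrom <- iv$chrom %in% sim_chrom_names(cfg$n_chromosomes)
    if (!all(ok_chrom)) abort("sweep interval on unknown chromosome.")
    if (any(iv$start < 0 | iv$end > cfg$chrom_length_bp | iv$start >= iv$end)) {
      abort("sweep intervals must lie within chromosome bounds with start < end.")
    }
  }
  invisible(cfg)
}

sim_chrom_names <- function(n) sprintf("chr%d", seq_len(n))

sim_gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  expression: %d genes x 2x%d samples, planted D_cv %.2f on %.0f%% of genes\n",
              x$n_genes, x$n_samples_per_group, x$selected_cv_reduction,
              100 * x$selected_fraction))
  cat(sprintf("  genome: %d chrom x %s bp, %d sites, %d sweep interval(s), factor %.2f\n",
              x$n_chromosomes, format(x$chrom_length_bp, big.mark = ","),
              x$n_variant_sites, nrow(x$sweep_intervals), x$sweep_diversity_factor))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
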