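#' Deterministic gene annotation matching the simulated expression genes
#'
#' Lays out `n_genes` non-overlapping genes of length `gene_length_bp`,
#' distributed as evenly as possible over the simulated chromosomes: each
#' chromosome is divided into equal slots and one gene starts at the beginning
#' of each slot. Gene ids match [simulate_expression_pair()] for the same
#' config, so expression and coordinates join directly. No randomness is
#' involved.
#'
#' @param config A [sim_config()].
#' @return Tibble with `gene_id`, `chrom`, `start`, `end` (0-based half-open,
#'   sorted, pairwise disjoint).
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 10, seed = 1))
#' all(ann$end - ann$start == 2000)
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  n_g <- config$n_genes
  n_c <- config$n_chromosomes
  per_chrom <- rep(n_g %/% n_c, n_c) + c(rep(1, n_g %% n_c), rep(0, n_c - n_g %% n_c))
  slot <- config$chrom_length_bp %/% max(per_chrom)
  if (slot < config$gene_length_bp) {
    abort(sprintf(
      "cannot place %d genes of %d bp on %d chromosome(s) of %d bp.",
      n_g, config$gene_length_bp, n_c, config$chrom_length_bp))
  }
  chroms <- sim_chrom_names(n_c)
  ann <- purrr::map2_dfr(chroms, per_chrom, function(ch, k) {
    if (k == 0) return(tibble())
    start <- (seq_len(k) - 1L) * slot
    tibble(chrom = ch, start = as.integer(start),
           end = as.integer(start + config$gene_length_bp))
  })
  ann$gene_id <- sim_gene_ids(n_g)
  ann %>% select(all_of(c("gene_id", "chrom", "start", "end")))
}

#' Gene lengths from an annotation table
#'
#' @param annotation Tibble with `gene_id`, `start`, `end` (0-based
#'   half-open).
#' @return Named numeric vector of interval lengths in bp.
#' @export
gene_lengths <- function(annotation) {
  setNames(annotation$end - annotation$start, annotation$gene_id)
}
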