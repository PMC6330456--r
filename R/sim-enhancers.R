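#' Simulate one-to-one enhancer--gene pairs with planted synchrony classes
#'
#' Generates `n_pairs` enhancer intervals, each regulating exactly one gene,
#' with per-pair enhancer nucleotide diversity (`pi_wild`, `pi_dome`) and
#' gene expression CV (`cv_wild`, `cv_dome`) planted so that each pair
#' belongs to a known joint diversity-change class on the 3x3 grid
#' (genetic axis x expression axis, levels decreased/unchanged/increased).
#' Planted "decreased" values use `dome = wild * (1 - planted_margin)`,
#' "increased" uses `dome = wild * (1 + planted_margin)` and "unchanged" uses
#' `dome = wild` exactly, so [classify_pairs()] recovers the planted class
#' for every pair whenever its dead zone satisfies
#' `0 <= epsilon < planted_margin`.
#'
#' Class counts are apportioned from `class_fractions` by largest remainder
#' so they sum exactly to `n_pairs`.
#'
#' @param config A [sim_config()] (supplies genome layout and the seed).
#' @param class_fractions 3x3 numeric matrix of target class fractions, rows
#'   = genetic axis, columns = expression axis, both ordered
#'   (decreased, unchanged, increased); must sum to 1 within 1e-9.
#' @param n_pairs Number of pairs (0 allowed).
#' @param planted_margin Relative change planted on "decreased"/"increased"
#'   axes; must be > 0.
#' @return Tibble with `enh_chrom`, `enh_start`, `enh_end` (0-based
#'   half-open), `gene_id`, `pi_dome`, `pi_wild`, `cv_dome`, `cv_wild`,
#'   `class_genetic`, `class_expression` (the planted truth).
#' @examples
#' fr <- matrix(1/9, 3, 3)
#' pairs <- simulate_enhancer_pairs(sim_config(seed = 1), fr, n_pairs = 18)
#' nrow(pairs)
#' @export
simulate_enhancer_pairs <- function(config, class_fractions,
                                    n_pairs = 843, planted_margin = 0.2) {
  validate_sim_config(config)
  stopifnot(is.matrix(class_fractions), all(dim(class_fractions) == c(3, 3)),
            all(class_fractions >= 0), planted_margin > 0, n_pairs >= 0)
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    abort("`class_fractions` must sum to 1 (tolerance 1e-9).")
  }
  lev <- diversity_change_levels()
  if (n_pairs == 0) {
    return(tibble(enh_chrom = character(), enh_start = integer(),
                  enh_end = integer(), gene_id = character(),
                  pi_dome = double(), pi_wild = double(),
                  cv_dome = double(), cv_wild = double(),
                  class_genetic = factor(character(), lev),
                  class_expression = factor(character(), lev)))
  }

  counts <- apportion_counts(as.vector(class_fractions), n_pairs)
  class_genetic <- rep(rep(lev, 3), counts)
  class_expression <- rep(rep(lev, each = 3), counts)

  withr::with_seed(derive_seed(config$seed, 4L), {
    pi_wild <- rlnorm(n_pairs, log(0.005), 0.3)
    cv_wild <- rlnorm(n_pairs, log(0.7), 0.2)
  })
  plant <- function(wild, cls) {
    dplyr::case_match(cls,
                      "decreased" ~ wild * (1 - planted_margin),
                      "unchanged" ~ wild,
                      "increased" ~ wild * (1 + planted_margin))
  }

  chroms <- sim_chrom_names(config$n_chromosomes)
  per_chrom <- ceiling(n_pairs / config$n_chromosomes)
  slot <- config$chrom_length_bp %/% per_chrom
  enh_len <- min(1000L, max(1L, slot %/% 2))
  idx <- seq_len(n_pairs) - 1L
  tibble(
    enh_chrom = chroms[idx %% config$n_chromosomes + 1L],
    enh_start = as.integer((idx %/% config$n_chromosomes) * slot),
    enh_end = as.integer((idx %/% config$n_chromosomes) * slot + enh_len),
    gene_id = sprintf("PAIRGENE%05d", seq_len(n_pairs)),
    pi_dome = plant(pi_wild, class_genetic),
    pi_wild = pi_wild,
    cv_dome = plant(cv_wild, class_expression),
    cv_wild = cv_wild,
    class_genetic = factor(class_genetic, lev),
    class_expression = factor(class_expression, lev)
  )
}

diversity_change_levels <- function() c("decreased", "unchanged", "increased")

# largest-remainder apportionment of n among fractions
apportion_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
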