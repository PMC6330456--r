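#' Two-population variant panel
#'
#' Container for a filtered or raw biallelic genotype panel: a site table plus
#' per-sample genotype dosage, genotype supporting-read and genotype-quality
#' matrices, and a sample-to-population map. Sites are kept sorted by
#' `(chrom, pos)` with 1-based positions (the VCF convention); all interval
#' arithmetic elsewhere in the package is 0-based half-open and conversion
#' happens at this boundary.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   and optionally `qual` (site quality) and `depth` (total mapping depth).
#' @param geno Integer matrix sites x samples of alt-allele dosages (0, 1, 2)
#'   with `NA` for missing genotypes; column names are sample ids.
#' @param samples Tibble with `sample_id`, `population`
#'   (`"domestic"`/`"wild"`).
#' @param gt_depth,gt_qual Optional sites x samples matrices of per-genotype
#'   supporting reads and genotype qualities.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, geno, samples, gt_depth = NULL, gt_qual = NULL) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(geno), nrow(geno) == nrow(sites),
            all(c("sample_id", "population") %in% names(samples)),
            ncol(geno) == nrow(samples))
  if (is.null(colnames(geno))) colnames(geno) <- samples$sample_id
  if (!identical(colnames(geno), samples$sample_id)) {
    abort("genotype matrix columns must match `samples$sample_id` in order.")
  }
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, ]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(gt_depth)) gt_depth <- gt_depth[ord, , drop = FALSE]
    if (!is.null(gt_qual)) gt_qual <- gt_qual[ord, , drop = FALSE]
  }
  structure(list(sites = sites, geno = geno,
                 gt_depth = gt_depth, gt_qual = gt_qual,
                 samples = as_tibble(samples)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d sites x %d samples (%s)\n",
              nrow(x$sites), ncol(x$geno),
              paste(sprintf("%s: %d", names(table(x$samples$population)),
                            table(x$samples$population)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.variant_table <- function(x) c(nrow(x$sites), ncol(x$geno))

#' Long-format view of a variant panel
#'
#' @param x A [variant_table()].
#' @param ... Unused.
#' @return Tibble with one row per (site, sample): `chrom`, `pos`, `ref`,
#'   `alt`, `sample_id`, `population`, `dosage`.
#' @export
as_tibble.variant_table <- function(x, ...) {
  n_site <- nrow(x$sites)
  n_samp <- ncol(x$geno)
  tibble(
    chrom = rep(x$sites$chrom, n_samp),
    pos = rep(x$sites$pos, n_samp),
    ref = rep(x$sites$ref, n_samp),
    alt = rep(x$sites$alt, n_samp),
    sample_id = rep(x$samples$sample_id, each = n_site),
    population = rep(x$samples$population, each = n_site),
    dosage = as.vector(x$geno)
  )
}

subset_sites <- function(v, keep) {
  variant_table(v$sites[keep, , drop = FALSE],
                v$geno[keep, , drop = FALSE],
                v$samples,
                if (!is.null(v$gt_depth)) v$gt_depth[keep, , drop = FALSE],
                if (!is.null(v$gt_qual)) v$gt_qual[keep, , drop = FALSE])
}

pop_columns <- function(v, pop) {
  idx <- which(v$samples$population == pop)
  if (length(idx) == 0) abort(sprintf("no samples in population '%s'.", pop))
  idx
}

#' Variant filtering configuration
#'
#' Thresholds of the SNP-filtering cascade applied by [filter_variants()]:
#' sites with total mapping depth or site quality below 30 are excluded, only
#' biallelic SNPs are retained, genotypes with fewer than 3 supporting reads
#' or genotype quality below 20 are set missing, the (pooled) minor-allele
#' frequency computed after masking must exceed 0.05, and sites with more
#' than 20% missing genotypes are excluded (whole-genome rice panels
#' conventionally relax the missingness cap to 30%).
#'
#' @param min_site_depth,min_site_quality Site-level thresholds (kept if
#'   `>=`).
#' @param min_allele_freq Pooled minor-allele frequency; kept if strictly
#'   greater.
#' @param min_genotype_reads,min_genotype_quality Per-genotype thresholds;
#'   genotypes below either are masked missing.
#' @param max_missing_fraction Sites with a strictly larger missing fraction
#'   are removed.
#' @param allele_freq_scope `"pooled"` (default) computes the allele
#'   frequency over both populations together; `"per_population"` requires
#'   the rule to hold in each population.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_site_depth = 30,
                          min_site_quality = 30,
                          min_allele_freq = 0.05,
                          min_genotype_reads = 3,
                          min_genotype_quality = 20,
                          max_missing_fraction = 0.20,
                          allele_freq_scope = c("pooled", "per_population")) {
  stopifnot(min_allele_freq >= 0, min_allele_freq <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(
    min_site_depth = min_site_depth,
    min_site_quality = min_site_quality,
    min_allele_freq = min_allele_freq,
    min_genotype_reads = min_genotype_reads,
    min_genotype_quality = min_genotype_quality,
    max_missing_fraction = max_missing_fraction,
    allele_freq_scope = match.arg(allele_freq_scope)
  ), class = "filter_config")
}

#' Apply the SNP-filtering cascade to a variant panel
#'
#' Rules are applied in order: (1) site depth and site quality, (2) biallelic
#' SNPs only, (3) per-genotype masking (supporting reads, genotype quality),
#' (4) minor-allele frequency computed after masking, (5) missingness. A rule
#' whose supporting field is absent from the panel is skipped with a warning.
#'
#' @param v A [variant_table()].
#' @param f A [filter_config()].
#' @return The filtered [variant_table()]; attribute `"filter_log"` is a
#'   tibble with the number of sites removed by each rule.
#' @export
filter_variants <- function(v, f = filter_config()) {
  stopifnot(inherits(v, "variant_table"), inherits(f, "filter_config"))
  log <- list()
  note_skip <- function(rule, field) {
    warn(sprintf("filter_variants: panel has no %s; skipping the %s rule.",
                 field, rule))
  }

  # (1) site depth / quality
  if (!is.null(v$sites$depth)) {
    keep <- !is.na(v$sites$depth) & v$sites$depth >= f$min_site_depth
    log$site_depth <- sum(!keep)
    v <- subset_sites(v, keep)
  } else note_skip("site-depth", "per-site depth")
  if (!is.null(v$sites$qual)) {
    keep <- !is.na(v$sites$qual) & v$sites$qual >= f$min_site_quality
    log$site_quality <- sum(!keep)
    v <- subset_sites(v, keep)
  } else note_skip("site-quality", "site quality")

  # (2) biallelic SNPs only: single-base ref and a single single-base alt
  keep <- !grepl(",", v$sites$alt, fixed = TRUE) &
    nchar(v$sites$ref) == 1 & nchar(v$sites$alt) == 1 &
    v$sites$ref %in% c("A", "C", "G", "T") & v$sites$alt %in% c("A", "C", "G", "T")
  log$biallelic <- sum(!keep)
  v <- subset_sites(v, keep)

  # (3) genotype masking
  if (!is.null(v$gt_depth)) {
    v$geno[!is.na(v$gt_depth) & v$gt_depth < f$min_genotype_reads |
             is.na(v$gt_depth)] <- NA_integer_
  } else note_skip("genotype-read", "per-genotype supporting reads")
  if (!is.null(v$gt_qual)) {
    v$geno[!is.na(v$gt_qual) & v$gt_qual < f$min_genotype_quality |
             is.na(v$gt_qual)] <- NA_integer_
  } else note_skip("genotype-quality", "genotype quality")

  # (4) allele frequency after masking (minor allele, strictly greater)
  maf_of <- function(g) {
    p <- rowSums(g, na.rm = TRUE) / pmax(2 * rowSums(!is.na(g)), 1)
    pmin(p, 1 - p)
  }
  if (f$allele_freq_scope == "pooled") {
    keep <- maf_of(v$geno) > f$min_allele_freq
  } else {
    keep <- rep(TRUE, nrow(v$geno))
    for (pop in unique(v$samples$population)) {
      keep <- keep & maf_of(v$geno[, pop_columns(v, pop), drop = FALSE]) >
        f$min_allele_freq
    }
  }
  log$allele_freq <- sum(!keep)
  v <- subset_sites(v, keep)

  # (5) missingness
  miss <- rowMeans(is.na(v$geno))
  keep <- miss <= f$max_missing_fraction
  log$missingness <- sum(!keep)
  v <- subset_sites(v, keep)

  attr(v, "filter_log") <- tibble(rule = names(log),
                                  n_removed = as.integer(unlist(log)))
  v
}
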