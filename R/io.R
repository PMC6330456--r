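#' Read and write gene-level count matrices as TSV
#'
#' First column `gene_id`, header row of sample ids, integer or numeric
#' cells.
#'
#' @param path File path.
#' @return `read_count_matrix()`: a count tibble; `write_count_matrix()`:
#'   `path`, invisibly.
#' @export
read_count_matrix <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "gene_id"
  counts_matrix(out)  # validation only
  out
}

#' @rdname read_count_matrix
#' @param counts Count tibble (first column `gene_id`).
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write sample metadata as TSV
#'
#' Columns `sample_id`, `group`, `clean_reads` and optionally `tissue`.
#'
#' @param path File path.
#' @return A metadata tibble / `path` invisibly.
#' @export
read_sample_metadata <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "group", "clean_reads") %in% names(out)))
  out
}

#' @rdname read_sample_metadata
#' @param meta Metadata tibble.
#' @export
write_sample_metadata <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Write a gene annotation as GFF3 or BED
#'
#' GFF3 uses 1-based closed intervals and feature type `gene`; BED uses
#' 0-based half-open intervals (the package's internal convention).
#'
#' @param annotation Tibble with `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\texdiv\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                   annotation$chrom, annotation$start + 1L, annotation$end,
                   annotation$gene_id)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
write_annotation_bed <- function(annotation, path) {
  utils::write.table(
    data.frame(annotation$chrom, annotation$start, annotation$end,
               annotation$gene_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 rows with feature type `gene` are used; the `ID` attribute becomes
#' `gene_id`. Coordinates are converted to 0-based half-open.
#'
#' @param path File path ending in `.gff3`/`.gff` or `.bed`.
#' @return Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = c("character", "integer", "integer",
                                           "character"))
    names(df) <- c("chrom", "start", "end", "gene_id")
    return(as_tibble(df) %>%
             select(all_of(c("gene_id", "chrom", "start", "end"))) %>%
             arrange(.data$chrom, .data$start))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))
  f <- f[keep]
  tibble(
    gene_id = vapply(f, function(x) sub(".*ID=([^;]+).*", "\\1", x[9]),
                     character(1)),
    chrom = vapply(f, `[`, character(1), 1),
    start = as.integer(vapply(f, `[`, character(1), 4)) - 1L,
    end = as.integer(vapply(f, `[`, character(1), 5))
  ) %>% arrange(.data$chrom, .data$start)
}

#' Write a variant panel as VCF v4.2
#'
#' Emits `GT:DP:GQ` genotype fields (unphased diploid), per-site `QUAL` and
#' `INFO/DP`, and `##contig` headers. The companion population map
#' (`sample_id`, `population`) is written by [write_population_map()].
#'
#' @param v A [variant_table()].
#' @param path Output path (plain text).
#' @param chrom_lengths Optional named vector for `##contig` length headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(v, path, chrom_lengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=exdiv",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total mapping depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Supporting reads\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  ), con)
  for (ch in unique(v$sites$chrom)) {
    len <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else
      max(v$sites$pos[v$sites$chrom == ch])
    writeLines(sprintf("##contig=<ID=%s,length=%d>", ch, as.integer(len)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", v$samples$sample_id), collapse = "\t"),
             con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[v$geno + 1L], nrow(v$geno))
  gt_str[is.na(v$geno)] <- "./."
  dp <- if (!is.null(v$gt_depth)) v$gt_depth else
    matrix(".", nrow(v$geno), ncol(v$geno))
  gq <- if (!is.null(v$gt_qual)) v$gt_qual else
    matrix(".", nrow(v$geno), ncol(v$geno))
  cells <- matrix(paste(gt_str, dp, gq, sep = ":"), nrow(v$geno))
  qual <- if (!is.null(v$sites$qual)) v$sites$qual else rep(".", nrow(v$sites))
  info <- if (!is.null(v$sites$depth)) sprintf("DP=%d", v$sites$depth) else "."
  lines <- paste(v$sites$chrom, v$sites$pos, ".", v$sites$ref, v$sites$alt,
                 qual, "PASS", info, "GT:DP:GQ",
                 apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF into a variant panel
#'
#' Parses GT (dosage of the first alt allele; any missing allele call masks
#' the genotype), per-genotype DP and GQ when present, site QUAL and
#' INFO/DP.
#'
#' @param path VCF path (plain or gzipped).
#' @param popmap Tibble (`sample_id`, `population`) or path to a two-column
#'   TSV population map.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_population_map(popmap)
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(x, "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = list(NULL, colnames(gt)))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  gt_depth <- tryCatch(
    suppressWarnings(vcfR::extract.gt(x, "DP", as.numeric = TRUE)),
    error = function(e) NULL)
  gt_qual <- tryCatch(
    suppressWarnings(vcfR::extract.gt(x, "GQ", as.numeric = TRUE)),
    error = function(e) NULL)
  if (!is.null(gt_depth)) rownames(gt_depth) <- NULL
  if (!is.null(gt_qual)) rownames(gt_qual) <- NULL
  info_dp <- suppressWarnings(as.integer(vcfR::extract.info(x, "DP")))
  sites <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    depth = info_dp
  )
  stopifnot(all(colnames(dosage) %in% popmap$sample_id))
  popmap <- popmap[match(colnames(dosage), popmap$sample_id), ]
  variant_table(sites, dosage, popmap, gt_depth = gt_depth, gt_qual = gt_qual)
}

#' Read and write the sample-to-population map
#'
#' Two-column TSV (`sample_id`, `population`).
#'
#' @param path File path.
#' @return Tibble / `path` invisibly.
#' @export
read_population_map <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "population") %in% names(out)))
  out
}

#' @rdname read_population_map
#' @param popmap Tibble (`sample_id`, `population`).
#' @export
write_population_map <- function(popmap, path) {
  readr::write_tsv(popmap[, c("sample_id", "population")], path)
  invisible(path)
}

#' Write simulation ground truth as JSON
#'
#' @param truth A `sim_truth` from the simulators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  out$selected_gene_ids <- as.character(out$selected_gene_ids %||% character())
  out$sweep_intervals <- normalize_intervals(out$sweep_intervals)
  structure(out, class = "sim_truth")
}

#' Reported gene-set sizes from published domestication scans
#'
#' Whole-genome and candidate-selected gene counts reported for seven
#' domestic/wild pairs (dog, silkworm, chicken, rice, soybean landrace and
#' improved, cotton whole genome and both subgenomes, maize ear), together
#' with the percentage each source printed. These are inputs for worked
#' examples and checks of [pcsgs()]; the package does not re-derive them.
#'
#' @return Tibble with `pair`, `n_wggs`, `n_csgs`, `printed_pcsgs`.
#' @export
reported_gene_set_counts <- function() {
  path <- system.file("extdata", "reported_gene_set_counts.tsv",
                      package = "exdiv", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
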