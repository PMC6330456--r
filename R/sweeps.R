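#' Select the top-quantile scored windows
#'
#' Windows whose score is at or above the empirical `1 - q` quantile of the
#' defined scores. Ties at the threshold are all included, which is
#' deterministic and conservative toward inclusion. Windows with `NA` scores
#' never enter the quantile.
#'
#' @param windows Scored window tibble (column `score`).
#' @param q Upper tail mass (default 0.05: the top 5%).
#' @return The selected window rows; attribute `"threshold"` records the cut
#'   value.
#' @export
top_quantile_regions <- function(windows, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  scores <- windows$score[!is.na(windows$score)]
  if (length(scores) == 0) abort("all window scores are undefined.")
  thr <- unname(quantile(scores, 1 - q))
  out <- filter(windows, !is.na(.data$score), .data$score >= thr)
  attr(out, "threshold") <- thr
  out
}

#' Merge overlapping or book-ended windows into sweep regions
#'
#' Maximal disjoint intervals covering the union of the input windows;
#' book-ended windows (end of one equals start of the next) are merged.
#'
#' @param windows Tibble with `chrom`, `start`, `end` (0-based half-open);
#'   typically the output of [top_quantile_regions()].
#' @param method Label recorded on the result (`"fst"`, `"pi_ratio"`,
#'   `"external"`, ...).
#' @param quantile_used Quantile recorded on the result.
#' @return Tibble of class `sweep_regions` with `chrom`, `start`, `end`,
#'   sorted and pairwise disjoint; attributes `"method"` and `"quantile"`.
#' @examples
#' w <- tibble::tibble(chrom = "chr1", start = c(0, 50e3, 200e3),
#'                     end = c(100e3, 150e3, 300e3))
#' merge_regions(w)
#' @export
merge_regions <- function(windows, method = "unspecified", quantile_used = NA_real_) {
  if (nrow(windows) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
  } else {
    gr <- GenomicRanges::GRanges(
      windows$chrom, IRanges::IRanges(windows$start + 1, windows$end))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
    red <- GenomicRanges::sort(red)
    out <- tibble(chrom = as.character(GenomicRanges::seqnames(red)),
                  start = as.integer(GenomicRanges::start(red) - 1L),
                  end = as.integer(GenomicRanges::end(red)))
  }
  structure(out, class = c("sweep_regions", class(out)),
            method = method, quantile = quantile_used)
}

#' One call from scored windows to merged sweep regions
#'
#' Convenience wrapper: [top_quantile_regions()] then [merge_regions()].
#'
#' @inheritParams top_quantile_regions
#' @inheritParams merge_regions
#' @return A `sweep_regions` tibble.
#' @export
call_sweeps <- function(windows, q = 0.05, method = "unspecified") {
  merge_regions(top_quantile_regions(windows, q), method = method,
                quantile_used = q)
}

#' Read externally computed per-window scores
#'
#' Tab-separated file with columns `chrom`, `start`, `end`, `score` and an
#' optional leading pragma line declaring the coordinate convention, e.g.
#' `# coordinates=1-based-closed` or `# coordinates=0-based-half-open`.
#' Coordinates are normalized to the package's internal 0-based half-open
#' convention, so scan scores computed by external sweep methods (e.g. a
#' composite-likelihood scan) can enter the same thresholding path.
#'
#' @param path File path.
#' @param coordinates Convention when the file carries no pragma:
#'   `"0-based-half-open"` (default) or `"1-based-closed"`.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open), `score`.
#' @export
ingest_external_scores <- function(path,
                                   coordinates = c("0-based-half-open",
                                                   "1-based-closed")) {
  coordinates <- match.arg(coordinates)
  lines <- readLines(path)
  data_start <- 1L
  if (length(lines) > 0 && grepl("^#", lines[1])) {
    pragma <- sub("^#+\\s*", "", lines[1])
    if (grepl("coordinates\\s*=", pragma)) {
      decl <- trimws(sub(".*coordinates\\s*=\\s*", "", pragma))
      if (!decl %in% c("0-based-half-open", "1-based-closed")) {
        abort(sprintf("line 1: unknown coordinate convention '%s'.", decl))
      }
      coordinates <- decl
    }
    data_start <- 2L
  }
  body <- lines[data_start:length(lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("chrom", "start", "end", "score")
  if (!all(need %in% header)) {
    abort(sprintf("line %d: header must contain chrom, start, end, score.",
                  data_start))
  }
  rows <- lapply(seq_along(body[-1]), function(i) {
    f <- strsplit(body[i + 1], "\t", fixed = TRUE)[[1]]
    line_no <- data_start + i
    if (length(f) != length(header)) {
      abort(sprintf("line %d: expected %d fields, got %d.",
                    line_no, length(header), length(f)))
    }
    rec <- setNames(as.list(f), header)
    num <- suppressWarnings(lapply(rec[c("start", "end", "score")], as.numeric))
    if (any(vapply(num, is.na, logical(1)))) {
      abort(sprintf("line %d: non-numeric start/end/score.", line_no))
    }
    tibble(chrom = rec$chrom, start = num$start, end = num$end,
           score = num$score)
  })
  out <- bind_rows(rows)
  if (coordinates == "1-based-closed") {
    out$start <- out$start - 1
  }
  out %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
    arrange(.data$chrom, .data$start)
}

#' Write per-window scores as TSV
#'
#' Emits the pragma `# coordinates=0-based-half-open` followed by a header
#' and one row per window, so [ingest_external_scores()] round-trips.
#'
#' @param windows Scored window tibble (`chrom`, `start`, `end`, `score`,
#'   optionally `n_sites`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_scores <- function(windows, path) {
  cols <- intersect(c("chrom", "start", "end", "score", "n_sites"),
                    names(windows))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates=0-based-half-open", con)
  utils::write.table(windows[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write sweep regions as BED
#'
#' Three-column BED (0-based half-open), the package's external form of a
#' sweep-region set.
#'
#' @param regions A `sweep_regions` tibble (or any `chrom`/`start`/`end`
#'   tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' @param path Path to a 3+ column BED file (0-based half-open).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  as_tibble(df) %>% arrange(.data$chrom, .data$start)
}
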