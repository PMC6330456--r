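#' Run the full expression-diversity pipeline from files to reports
#'
#' Orchestrates every stage on documented file formats: sample balancing by
#' clean reads, median-of-ratios normalization, per-gene CV computation,
#' variant filtering, a windowed sweep scan (pi-ratio or Fst, or externally
#' computed window scores), top-quantile thresholding and region merging,
#' WGGS/CSGS/non-CSGS partitioning, per-set domestic-vs-wild comparisons,
#' and (optionally) the enhancer--gene synchrony summary.
#'
#' @param config Named list or path to a YAML/JSON file with entries:
#'   * `counts`, `metadata`, `annotation` — input paths (TSV / GFF3 or BED);
#'   * `vcf`, `popmap` — variant panel and population map paths (required
#'     for sweep methods `"pi_ratio"`/`"fst"`);
#'   * `external_scores` — per-window score TSV (required for method
#'     `"external"`);
#'   * `pairs` — optional enhancer--gene pair TSV (`enh_chrom`, `enh_start`,
#'     `enh_end`, `gene_id`);
#'   * `sweep_method` (`"pi_ratio"` default, `"fst"`, `"external"`),
#'     `quantile` (0.05), `window_bp` (1e5), `step_bp` (1e4), `filter`
#'     (list of [filter_config()] arguments), `epsilon_pi`/`epsilon_cv`
#'     (0.05), `alternative` (`"less"`), `test_method` (`"pooled"`),
#'     `seed` (1), `out_dir` (required).
#' @return Invisibly, a list with `report` (the diversity report tibble),
#'   `partition`, `regions`, `windows`, `synchrony` (or `NULL`) and
#'   `manifest`. All tables are also written under `out_dir` together with
#'   `manifest.json` and `run.log`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(list(
    sweep_method = "pi_ratio", quantile = 0.05,
    window_bp = 1e5, step_bp = 1e4, filter = list(),
    epsilon_pi = 0.05, epsilon_cv = 0.05,
    alternative = "less", test_method = "pooled", seed = 1L
  ), config)
  if (is.null(cfg$out_dir)) abort("config must name `out_dir`.")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  log_msg <- function(...) {
    line <- sprintf(...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  need_input <- function(field) {
    if (is.null(cfg[[field]]) || !file.exists(cfg[[field]])) {
      abort(sprintf("pipeline stage 'inputs' failed: missing input `%s`%s.",
                    field,
                    if (is.null(cfg[[field]])) "" else
                      sprintf(" (file '%s' not found)", cfg[[field]])))
    }
    cfg[[field]]
  }

  # --- expression side ------------------------------------------------
  counts <- stage("read_counts", read_count_matrix(need_input("counts")))
  meta <- stage("read_metadata", read_sample_metadata(need_input("metadata")))
  annotation <- stage("read_annotation", read_annotation(need_input("annotation")))

  kept <- stage("balance", balance_samples(meta))
  log_msg("balance: retained %d of %d samples.", length(kept), nrow(meta))
  counts <- counts[, c("gene_id", kept)]
  meta <- filter(meta, .data$sample_id %in% kept)

  normalized <- stage("normalize", normalize_counts(counts))
  cvs <- stage("cv", cv_table(normalized, meta))
  log_msg("cv: %d genes retained, %d excluded (zero mean in a group).",
          length(unique(cvs$gene_id)), length(attr(cvs, "excluded_genes")))

  # --- sweep side -----------------------------------------------------
  if (cfg$sweep_method %in% c("pi_ratio", "fst")) {
    v <- stage("read_vcf", read_vcf(need_input("vcf"), need_input("popmap")))
    v <- stage("filter_variants",
               filter_variants(v, do.call(filter_config, cfg$filter)))
    flog <- attr(v, "filter_log")
    log_msg("filter: removed %s.",
            paste(sprintf("%s=%d", flog$rule, flog$n_removed), collapse = ", "))
    chrom_lengths <- stage("windows", {
      tapply(c(annotation$end, v$sites$pos), c(annotation$chrom, v$sites$chrom),
             max)
    })
    windows <- make_windows(chrom_lengths, cfg$window_bp, cfg$step_bp)
    scored <- if (cfg$sweep_method == "pi_ratio") {
      w <- stage("pi_ratio", pi_ratio_windowed(v, windows))
      log_msg("pi_ratio: pseudocount = %g.", attr(w, "pseudocount"))
      w
    } else {
      stage("fst", fst_windowed(v, windows))
    }
  } else if (cfg$sweep_method == "external") {
    scored <- stage("external_scores",
                    ingest_external_scores(need_input("external_scores")))
    v <- NULL
  } else {
    abort(sprintf("unknown sweep_method '%s'.", cfg$sweep_method))
  }
  top <- stage("top_quantile", top_quantile_regions(scored, cfg$quantile))
  log_msg("top_quantile: %d of %d windows at threshold %g (ties included).",
          nrow(top), sum(!is.na(scored$score)), attr(top, "threshold"))
  regions <- stage("merge", merge_regions(top, method = cfg$sweep_method,
                                          quantile_used = cfg$quantile))

  # --- partition + comparisons ---------------------------------------
  part <- stage("partition",
                partition_gene_sets(annotation, regions,
                                    unique(cvs$gene_id)))
  groups <- unique(cvs$group)
  dome_lab <- if ("domestic" %in% groups) "domestic" else groups[1]
  wild_lab <- if ("wild" %in% groups) "wild" else groups[2]
  cmp_for <- function(ids, label) {
    sub <- filter(cvs, .data$gene_id %in% ids)
    compare_diversity(sub$cv[sub$group == dome_lab],
                      sub$cv[sub$group == wild_lab],
                      alternative = cfg$alternative,
                      method = cfg$test_method,
                      gene_set_label = label)
  }
  comparisons <- stage("compare", list(
    WGGS = cmp_for(part$wggs, "WGGS"),
    CSGS = if (length(part$csgs) >= 2) cmp_for(part$csgs, "CSGS"),
    `non-CSGS` = if (length(part$non_csgs) >= 2)
      cmp_for(part$non_csgs, "non-CSGS")
  ))
  comparisons <- comparisons[!vapply(comparisons, is.null, logical(1))]
  report <- report_diversity_table(
    comparisons, pair = cfg$pair_label %||% paste0(dome_lab, "-", wild_lab),
    n_csgs = length(part$csgs), n_wggs = length(part$wggs))

  # --- enhancers (optional) ------------------------------------------
  synchrony <- NULL
  if (!is.null(cfg$pairs)) {
    synchrony <- stage("enhancers", {
      pairs <- readr::read_tsv(need_input("pairs"), show_col_types = FALSE)
      if (!all(c("pi_dome", "pi_wild") %in% names(pairs))) {
        if (is.null(v)) abort("enhancer pi needs a VCF-backed sweep method.")
        enh_iv <- pairs %>%
          rename(chrom = "enh_chrom", start = "enh_start", end = "enh_end")
        for (popn in c("domestic", "wild")) {
          piv <- gene_genetic_diversity(v, enh_iv, popn)
          pairs[[if (popn == "domestic") "pi_dome" else "pi_wild"]] <- piv$pi
        }
      }
      if (!all(c("cv_dome", "cv_wild") %in% names(pairs))) {
        cv_wide <- cvs %>%
          select(all_of(c("gene_id", "group", "cv"))) %>%
          tidyr::pivot_wider(names_from = "group", values_from = "cv")
        pairs <- pairs %>%
          left_join(cv_wide, by = "gene_id") %>%
          rename(cv_dome = all_of(dome_lab), cv_wild = all_of(wild_lab))
      }
      cls <- classify_pairs(pairs, cfg$epsilon_pi, cfg$epsilon_cv)
      log_msg("enhancers: %d pairs classified, %d excluded (epsilon pi=%g cv=%g).",
              nrow(cls), attr(cls, "n_excluded"), cfg$epsilon_pi, cfg$epsilon_cv)
      synchrony_summary(cls)
    })
  }

  # --- outputs --------------------------------------------------------
  out <- function(f) file.path(cfg$out_dir, f)
  readr::write_tsv(cvs, out("cv_table.tsv"))
  write_window_scores(scored, out("window_scores.tsv"))
  write_regions_bed(regions, out("sweep_regions.bed"))
  readr::write_tsv(report, out("diversity_report.tsv"))
  files <- c("cv_table.tsv", "window_scores.tsv", "sweep_regions.bed",
             "diversity_report.tsv")
  if (!is.null(synchrony)) {
    readr::write_tsv(synchrony, out("synchrony.tsv"))
    files <- c(files, "synchrony.tsv")
  }
  manifest <- list(
    package = "exdiv",
    version = as.character(utils::packageVersion("exdiv")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    sweep_method = cfg$sweep_method,
    quantile = cfg$quantile,
    files = as.list(tools::md5sum(vapply(files, out, character(1))))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  writeLines(log_lines, out("run.log"))

  invisible(list(report = report, partition = part, regions = regions,
                 windows = scored, synchrony = synchrony,
                 comparisons = comparisons, manifest = manifest))
}

#' Format diversity comparisons as the standard report table
#'
#' One row per gene set with the comparison's headline numbers: decrease of
#' expression diversity as a percentage at one decimal, candidate-selected
#' gene counts and their percentage at two decimals, the t-test p-value and
#' significance stars (`*`, `**`, `***` below 0.05, 0.01, 0.001).
#'
#' @param comparisons A `diversity_comparison` or list of them.
#' @param pair Label for the species pair.
#' @param n_csgs,n_wggs Candidate-selected and whole-genome gene counts for
#'   the PCSGS column (NA to omit).
#' @return Tibble with `pair`, `gene_set`, `n_genes`, `mean_cv_dome`,
#'   `mean_cv_wild`, `d_cv_percent`, `csgs_n`, `pcsgs_percent`, `p`,
#'   `stars`.
#' @export
report_diversity_table <- function(comparisons, pair = "dome-wild",
                                   n_csgs = NA_integer_, n_wggs = NA_integer_) {
  if (inherits(comparisons, "diversity_comparison")) {
    comparisons <- list(comparisons)
  }
  stopifnot(length(comparisons) >= 1)
  purrr::map_dfr(comparisons, function(x) {
    tibble(
      pair = pair,
      gene_set = x$gene_set_label,
      n_genes = unname(x$n_genes["dome"]),
      mean_cv_dome = x$mean_cv_dome,
      mean_cv_wild = x$mean_cv_wild,
      d_cv_percent = round(100 * x$d_cv, 1),
      csgs_n = n_csgs,
      pcsgs_percent = if (is.na(n_wggs)) NA_real_ else pcsgs(n_csgs, n_wggs),
      p = x$p_value,
      stars = significance_stars(x$p_value)
    )
  })
}
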