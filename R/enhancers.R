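#' Classify enhancer--gene pairs by joint diversity change
#'
#' Each pair carries enhancer nucleotide diversity and regulated-gene
#' expression CV in both populations. On each axis the relative change
#' `1 - dome/wild` is compared against a dead zone: `decreased` when the
#' change exceeds `epsilon`, `increased` when it is below `-epsilon`, else
#' `unchanged`. A wild value of 0 with a domestic value of 0 is `unchanged`;
#' wild 0 with domestic > 0 is `increased`. Pairs with any missing value are
#' excluded and counted in attribute `"n_excluded"`.
#'
#' @param pairs Tibble with columns `pi_dome`, `pi_wild`, `cv_dome`,
#'   `cv_wild` (e.g. from [simulate_enhancer_pairs()] or a join of
#'   [gene_genetic_diversity()] and [cv_table()] outputs).
#' @param epsilon_pi,epsilon_cv Non-negative relative-change dead zones
#'   (default 0.05). The "unchanged" category has no published definition;
#'   the dead zone is this package's explicit repair and is echoed in
#'   attribute `"epsilon"`.
#' @return `pairs` with factor columns `class_genetic`, `class_expression`
#'   (levels decreased/unchanged/increased), missing-value rows dropped.
#' @examples
#' p <- tibble::tibble(pi_dome = 0.004, pi_wild = 0.010,
#'                     cv_dome = 0.5, cv_wild = 0.8)
#' classify_pairs(p)
#' @export
classify_pairs <- function(pairs, epsilon_pi = 0.05, epsilon_cv = 0.05) {
  stopifnot(epsilon_pi >= 0, epsilon_cv >= 0)
  need <- c("pi_dome", "pi_wild", "cv_dome", "cv_wild")
  stopifnot(all(need %in% names(pairs)))
  complete <- stats::complete.cases(pairs[, need])
  n_excluded <- sum(!complete)
  out <- pairs[complete, ]
  out <- out %>%
    mutate(
      class_genetic = classify_axis(.data$pi_dome, .data$pi_wild, epsilon_pi),
      class_expression = classify_axis(.data$cv_dome, .data$cv_wild, epsilon_cv)
    )
  attr(out, "n_excluded") <- n_excluded
  attr(out, "epsilon") <- c(pi = epsilon_pi, cv = epsilon_cv)
  out
}

classify_axis <- function(dome, wild, eps) {
  rel <- ifelse(wild > 0, 1 - dome / wild, NA_real_)
  cls <- dplyr::case_when(
    wild == 0 & dome == 0 ~ "unchanged",
    wild == 0 & dome > 0 ~ "increased",
    rel > eps ~ "decreased",
    rel < -eps ~ "increased",
    TRUE ~ "unchanged"
  )
  factor(cls, diversity_change_levels())
}

#' 3x3 synchrony summary of classified pairs
#'
#' Counts and fractions of pairs in every joint (genetic, expression)
#' diversity-change class, with all 9 cells present (zero counts kept).
#'
#' @param classified Output of [classify_pairs()].
#' @return Tibble of class `synchrony_summary` with `class_genetic`,
#'   `class_expression`, `n`, `fraction` (fractions sum to 1).
#' @export
synchrony_summary <- function(classified) {
  stopifnot(all(c("class_genetic", "class_expression") %in% names(classified)))
  if (nrow(classified) == 0) abort("no classified pairs.")
  lev <- diversity_change_levels()
  out <- classified %>%
    dplyr::count(.data$class_genetic, .data$class_expression, .drop = FALSE) %>%
    tidyr::complete(class_genetic = factor(lev, lev),
                    class_expression = factor(lev, lev),
                    fill = list(n = 0L)) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    arrange(.data$class_genetic, .data$class_expression)
  structure(out, class = c("synchrony_summary", class(out)))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tile plot of the enhancer--gene synchrony grid
#'
#' @param object A [synchrony_summary()].
#' @param ... Unused.
#' @return A ggplot: 3x3 tiles shaded by fraction, labelled with percentages.
#' @export
autoplot.synchrony_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$class_genetic, y = .data$class_expression,
    fill = .data$fraction)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$fraction))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "Enhancer genetic diversity change",
                  y = "Gene expression diversity change",
                  fill = "Fraction") +
    ggplot2::theme_minimal()
}
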