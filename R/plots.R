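category_scale <- function() {
  ggplot2::scale_x_discrete(limits = c("UC", "EM", "MM"))
}

#' Plot a ChAs null distribution against the observed value
#'
#' Histogram of the null ChAs sample with the observed assortativity as a
#' vertical line; the gap between them, in null standard deviations, is
#' the reported z-score.
#'
#' @param object A `chas_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chas_result
#' @export
autoplot.chas_result <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_sample),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      title = paste0("ChAs: ", object$feature),
      subtitle = sprintf("observed %.3f, z = %.2f (%d randomizations)",
                         object$observed, object$z, object$n_rand),
      x = "ChAs under distance-matched null", y = "count"
    ) +
    ggplot2::theme_minimal()
}

#' Plot age-category ChAs z-scores
#'
#' @param chas_age Tibble (`category`, `z`), e.g. `report$chas_age` or the
#'   output of [chas_zscore_categorical()]; an optional `cell` or `run`
#'   column is used for dodging.
#' @return A ggplot with the conventional |z| = 2 significance line.
#' @export
plot_chas_age <- function(chas_age) {
  p <- ggplot2::ggplot(chas_age,
                       ggplot2::aes(x = .data$category, y = .data$z)) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed", colour = "grey50")
  if ("run" %in% names(chas_age)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$run),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  }
  p + category_scale() +
    ggplot2::labs(x = "gene age category", y = "ChAs z-score") +
    ggplot2::theme_minimal()
}

#' Plot normalized pausing-index distributions
#'
#' Boxplots of normalized pausing indices by age category, one panel per
#' cell state.
#'
#' @param pt A `pausing_table` from [pausing_pipeline()].
#' @param ages Age table.
#' @return A ggplot.
#' @export
plot_pausing <- function(pt, ages) {
  dat <- pt |>
    filter(.data$excluded_reason == "none") |>
    inner_join(ages |> select("gene_id", "category"), by = "gene_id") |>
    mutate(category = factor(.data$category, levels = c("UC", "EM", "MM")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$pi_norm,
                                    fill = .data$category)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~ .data$cell) +
    ggplot2::labs(x = "gene age category", y = "normalized pausing index") +
    ggplot2::theme_minimal()
}

#' Plot metagene profiles by age category
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot of mean signal vs position relative to the TSS.
#' @export
plot_metagene <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$signal,
                                        colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "position relative to TSS (bp)", y = "mean signal",
                  colour = "age category") +
    ggplot2::theme_minimal()
}
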