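#' Bar plot of replicate summaries
#'
#' Mean proportion of cap-positive and nucleoplasmic-FBL-positive cells
#' with SD error bars across replicates, the standard presentation of
#' per-sample phenotype scoring.
#'
#' @param summaries row-bound [summarize_sample()] outputs, optionally
#'   with a `sample` column to facet groups of replicates.
#' @return a ggplot object.
#' @export
plot_sample_summary <- function(summaries) {
  long <- summaries %>%
    tidyr::pivot_longer(c("prop_cap_positive",
                          "prop_nucleoplasmic_fbl_positive"),
                        names_to = "metric", values_to = "proportion")
  grp <- if ("sample" %in% names(long)) "sample" else "metric"
  agg <- long %>%
    group_by(dplyr::across(all_of(unique(c(grp, "metric"))))) %>%
    summarise(mean = mean(.data$proportion),
              sd = if (n() > 1) sd(.data$proportion) else NA_real_,
              .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data[[grp]], y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_y_continuous(limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = "proportion of scored cells") +
    ggplot2::theme_classic()
}

#' Line-profile plot
#'
#' Per-channel intensities along a sampled segment, normalized to each
#' channel's maximum along the line.
#'
#' @param profile a [extract_line_profile()] result.
#' @return a ggplot object.
#' @export
plot_line_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$distance_um, y = .data$normalized,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (µm)", y = "normalized intensity") +
    ggplot2::theme_classic()
}

#' @rdname plot_line_profile
#' @param object a `line_profile` object.
#' @param ... unused.
#' @export
autoplot.line_profile <- function(object, ...) plot_line_profile(object)

#' Enrichment bubble plot
#'
#' Rich factor on the x-axis, one term per row, bubble size giving the
#' overlap count and colour the -log10 p-value — the conventional
#' pathway-enrichment presentation.
#'
#' @param enrichment an [over_representation()] result.
#' @param top show the top `top` terms by adjusted p.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 20) {
  df <- utils::head(enrichment, top) %>%
    mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rich_factor, y = .data$term,
                                   size = .data$k,
                                   colour = -log10(.data$p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "rich factor", y = NULL, size = "genes",
                  colour = expression(-log[10] * " p")) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
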