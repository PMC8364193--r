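# ggplot2 views of the result tables, in the style of the usual cohort
# survey figures: stacked positive/negative prevalence bars and
# metabolite distributions split by gene presence with a mean diamond.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot prevalence fractions
#'
#' Stacked bars of the positive (red) and negative (gray) sample
#' fractions per group, with the group size printed above each bar.
#'
#' @param object a [prevalence()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.prevalence_df <- function(object, ...) {
  grp_col <- setdiff(names(object),
                     c("n", "n_positive", "frac_positive", "frac_negative"))
  df <- as_tibble(object)
  df$group <- if (length(grp_col) > 0) as.character(df[[grp_col[1]]]) else "all"
  long <- tidyr::pivot_longer(
    df[, c("group", "n", "frac_positive", "frac_negative")],
    cols = c("frac_positive", "frac_negative"),
    names_to = "status", values_to = "fraction")
  long$status <- factor(long$status, levels = c("frac_negative", "frac_positive"),
                        labels = c("negative", "positive"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$fraction,
                                     fill = .data$status)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_text(data = df,
                       ggplot2::aes(x = .data$group, y = 1.02,
                                    label = .data$n),
                       inherit.aes = FALSE, vjust = 0, size = 3) +
    ggplot2::scale_fill_manual(values = c(negative = "grey70",
                                          positive = "firebrick")) +
    ggplot2::labs(x = NULL, y = "fraction of samples", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.prevalence_df
#' @param prev a [prevalence()] result.
#' @export
plot_prevalence <- function(prev, ...) autoplot(prev, ...)

#' Plot metabolite levels by marker presence
#'
#' Boxplots of a metabolite split by gene presence, with jittered points
#' and the group mean as a yellow diamond.
#'
#' @param table cohort tibble.
#' @param metabolite metabolite column (unquoted).
#' @param col logical presence column (unquoted; default `gene_present`).
#' @return a ggplot.
#' @export
plot_metabolite_association <- function(table, metabolite,
                                        col = gene_present) {
  metabolite <- enquo(metabolite)
  col <- enquo(col)
  df <- tibble(value = dplyr::pull(table, !!metabolite),
               present = dplyr::pull(table, !!col))
  df <- df[!is.na(df$value) & !is.na(df$present), ]
  df$present <- factor(df$present, levels = c(FALSE, TRUE),
                       labels = c("negative", "positive"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$present, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 23, size = 3,
                          fill = "gold") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "marker gene", y = as_name(metabolite)) +
    ggplot2::theme_minimal()
}

#' Plot per-sample abundance estimates
#'
#' Genes-per-genome abundance of positive samples on a log scale.
#'
#' @param quant quantification tibble from [quantify_sample()].
#' @return a ggplot.
#' @export
plot_abundance <- function(quant) {
  df <- quant[quant$present & !is.na(quant$abundance) & quant$abundance > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = "samples", y = .data$abundance)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 23, size = 3,
                          fill = "gold") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "marker genes per microbial genome") +
    ggplot2::theme_minimal()
}
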