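# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.de_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' Per-comparison summary of a differential-expression result
#'
#' One row per stage pair: miRNAs tested, excluded, and the fraction in
#' each significance band among the non-excluded ones.
#'
#' @param x A `de_result` from [diff_expression()].
#' @param ... Unused.
#' @export
glance.de_result <- function(x, ...) {
  x %>%
    group_by(.data$control, .data$treatment) %>%
    summarise(
      n = dplyr::n(),
      n_excluded = sum(.data$excluded),
      frac_p_lt_0.01 = mean(.data$sig_class[!.data$excluded] == "p<0.01"),
      frac_p_0.01_0.05 = mean(.data$sig_class[!.data$excluded] == "0.01<=p<0.05"),
      frac_ns = mean(.data$sig_class[!.data$excluded] == "NS"),
      .groups = "drop")
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(mode = attr(x, "mode") %||% NA_character_,
         n_terms_tested = nrow(x),
         n_significant = sum(x$significant),
         min_p_adjusted = if (nrow(x)) min(x$p_adjusted) else NA_real_)
}

#' @export
tidy.fold_result <- function(x, ...) {
  tibble(position = seq_len(nchar(x$seq)),
         base = strsplit(x$seq, "")[[1]],
         partner = x$pair_table,
         paired = x$pair_table > 0)
}

#' @export
glance.fold_result <- function(x, ...) {
  tibble(length = nchar(x$seq), mfe = x$mfe,
         n_pairs = sum(x$pair_table > 0) / 2, backend = x$backend)
}

#' Expression scatter plot for one stage comparison
#'
#' The classic two-library scatter: each point is a miRNA, axes are
#' log10 normalised expression in control and treatment, coloured by
#' expression-ratio band (red ratio > 2, blue 1/2 < ratio <= 2, green
#' ratio <= 1/2).
#'
#' @param object A `de_result` from [diff_expression()].
#' @param ... Unused.
#' @return A ggplot object (facetted over stage pairs).
#' @export
autoplot.de_result <- function(object, ...) {
  df <- filter(as_tibble(object), !.data$excluded) %>%
    mutate(pair = paste(.data$treatment, "vs", .data$control))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tpm_control,
                                   y = .data$tpm_treatment,
                                   colour = .data$ratio_class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c("ratio>2" = "red",
                                            "1/2<ratio<=2" = "blue",
                                            "ratio<=1/2" = "darkgreen")) +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "control expression (TPM)",
                  y = "treatment expression (TPM)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.enrichment_result <- function(object, top = 15, ...) {
  df <- head(as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_adjusted),
                                   y = stats::reorder(.data$term,
                                                      -.data$p_adjusted),
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Clean-read length distribution plot
#'
#' Total (abundance-weighted) and distinct tag counts per insert length,
#' per library.
#'
#' @param lengths Output of [length_distribution()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(lengths) {
  df <- tidyr::pivot_longer(lengths, c("total", "distinct"),
                            names_to = "basis", values_to = "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$count,
                                   fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~basis, scales = "free_y") +
    ggplot2::labs(x = "insert length (nt)", y = "reads") +
    ggplot2::theme_minimal()
}
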