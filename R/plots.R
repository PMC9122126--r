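# ggplot2 views of the main result objects.

#' Plot arrangement frequencies
#'
#' Bar chart of the most abundant arrangements (share of all loci),
#' the bar-chart analogue of the published top-N pie summaries.
#'
#' @param object An `arrangement_table`.
#' @param top_n How many arrangements to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.arrangement_table <- function(object, top_n = 30, ...) {
  df <- tidy(object) |>
    mutate(label = purrr::map_chr(.data$cluster_tuple, function(tt) {
      if (length(tt) == 0) "(empty)" else paste(tt, collapse = "-")
    })) |>
    arrange(desc(.data$count)) |>
    head(top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, .data$count), y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of loci",
                  title = sprintf("Top %d arrangements (%d loci)",
                                  nrow(df), object$total_loci)) +
    ggplot2::theme_minimal()
}

#' Plot system prevalence across a mined hotspot
#'
#' @param object A `system_groups` tibble.
#' @param total_loci Locus count used as the denominator.
#' @param top_n How many systems to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.system_groups <- function(object, total_loci = sum(object$total_count),
                                   top_n = 30, ...) {
  df <- as_tibble(object) |>
    arrange(desc(.data$total_count)) |>
    head(top_n) |>
    mutate(proportion = .data$total_count / total_loci)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$system_id, .data$total_count),
    y = .data$proportion)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion of loci",
                  title = sprintf("Top %d systems", nrow(df))) +
    ggplot2::theme_minimal()
}

#' Histogram of hotspot locus spans
#'
#' @param loci Locus tibble from [extract_loci()].
#' @param binwidth Bin width in kb.
#' @return A ggplot.
#' @export
plot_locus_spans <- function(loci, binwidth = 0.25) {
  df <- mutate(loci, span_kb = .data$span_bp / 1000)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$span_kb)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::geom_vline(xintercept = mean(df$span_kb), linetype = 2) +
    ggplot2::labs(x = "locus span (kb)", y = "loci",
                  title = sprintf("Mean span %.2f kb", mean(df$span_kb))) +
    ggplot2::theme_minimal()
}
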