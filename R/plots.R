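# ggplot2 views of the main result types.

#' Plot the nucleotide profile around poly(A) cleavage sites
#'
#' Line plot of per-position base fractions from -flank to +flank around the
#' cleavage site (position 0 = last transcribed base); the canonical view
#' shows a U-rich upstream and A-rich downstream bias.
#'
#' @param object `polya_profile` matrix from [polya_profile()].
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.polya_profile <- function(object, ...) {
  df <- as_tibble(unclass(object), rownames = "base") |>
    pivot_longer(-"base", names_to = "position", values_to = "fraction") |>
    mutate(position = as.integer(.data$position))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$fraction,
                                   colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to cleavage site (nt)",
                  y = "base fraction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of AS event counts by type
#'
#' @param as_result list from [enumerate_as_events()].
#' @return a ggplot.
#' @export
plot_as_counts <- function(as_result) {
  df <- as_result$counts |>
    mutate(type = factor(.data$type, levels = c("ES", "AA", "AD", "IR",
                                                "other")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "AS event type", y = "events") +
    ggplot2::theme_minimal()
}

#' Histogram of poly(A) sites per gene
#'
#' @param apa list from [call_apa_genes()].
#' @return a ggplot.
#' @export
plot_apa_histogram <- function(apa) {
  ggplot2::ggplot(apa$histogram,
                  ggplot2::aes(x = factor(.data$n_sites),
                               y = .data$n_genes)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "poly(A) sites per gene", y = "genes") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression screen
#'
#' @param object `iso_screen` tibble from [deg_screen()].
#' @param ... unused.
#' @return a ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.iso_screen <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(status = if_else(.data$deg_up, "up",
                            if_else(.data$deg_down, "down", "ns")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$qvalue),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "navy", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Isoform length / locus length density plot
#'
#' @param results `iso_pipeline` from [run_pipeline()].
#' @return a ggplot comparing locus span length distributions.
#' @export
plot_locus_lengths <- function(results) {
  df <- results$loci |> mutate(length = .data$end - .data$start)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "locus span (nt)", y = "density") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
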