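#' Bar chart of TMD-count distributions by method
#'
#' Side-by-side bars of the fraction of transmembrane-protein groups per
#' TMD-count bin for each method, with standard-error bars over replicates
#' when replicate fractions are available, and significance stars from the
#' per-bin t-test (first two methods).
#'
#' @param x A `method_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_tmd_histogram <- function(x, ...) {
  stopifnot(inherits(x, "method_comparison"))
  bins <- x$proteome_histogram$bin
  df <- purrr::imap(x$replicate_fractions, function(fr, m) {
    tibble::as_tibble(fr) |>
      dplyr::mutate(method = m) |>
      tidyr::pivot_longer(-"method",
        names_to = "bin", values_to = "fraction"
      )
  }) |>
    dplyr::bind_rows() |>
    dplyr::group_by(.data$method, .data$bin) |>
    dplyr::summarise(
      mean = mean(.data$fraction),
      se = stats::sd(.data$fraction) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(bin = factor(.data$bin, levels = bins))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$bin, y = .data$mean, fill = .data$method
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(
      x = "TMDs per protein group",
      y = "fraction of TMP groups",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(x$ttest)) {
    stars <- dplyr::filter(x$ttest, .data$stars != "")
    if (nrow(stars) > 0L) {
      tops <- df |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(y = max(.data$mean + .data$se), .groups = "drop")
      lab <- dplyr::inner_join(
        stars, tops,
        by = "bin"
      ) |>
        dplyr::mutate(bin = factor(.data$bin, levels = bins))
      p <- p + ggplot2::geom_text(
        data = lab,
        ggplot2::aes(x = .data$bin, y = .data$y + 0.01,
                     label = .data$stars),
        inherit.aes = FALSE
      )
    }
  }
  p
}

#' @rdname plot_tmd_histogram
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(x, ...) {
  plot_tmd_histogram(x, ...)
}

#' Peptide-coverage map of one protein
#'
#' Draws the protein as a horizontal track with its predicted TMDs and the
#' matched peptide spans, a text-free stand-in for membrane-topology coverage
#' cartoons.
#'
#' @param map A `tmd_map` from [map_peptides()].
#' @param tmds TMD interval tibble used for the mapping.
#' @param accession Protein to draw.
#' @param protein_length Optional protein length (extends the backbone).
#' @return A ggplot object.
#' @export
plot_protein_coverage <- function(map, tmds, accession,
                                  protein_length = NULL) {
  stopifnot(inherits(map, "tmd_map"))
  cov <- dplyr::filter(map$coverage, .data$accession == !!accession)
  td <- dplyr::filter(tmds, .data$accession == !!accession)
  xmax <- protein_length %||% max(cov$end, td$end, 1L)
  ggplot2::ggplot() +
    ggplot2::annotate("segment",
      x = 1, xend = xmax, y = 0, yend = 0, linewidth = 0.8
    ) +
    ggplot2::geom_rect(
      data = td,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -0.25, ymax = 0.25, fill = "grey55", alpha = 0.8
    ) +
    ggplot2::geom_segment(
      data = cov,
      ggplot2::aes(x = .data$start, xend = .data$end),
      y = 0.5, yend = 0.5, linewidth = 2, colour = "steelblue"
    ) +
    ggplot2::scale_y_continuous(limits = c(-0.6, 0.9), breaks = NULL) +
    ggplot2::labs(
      title = accession, x = "residue position", y = NULL,
      subtitle = "grey: predicted TMDs; blue: matched peptides"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
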