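#' Manhattan plot of the ROH-status scan
#'
#' Plots -log10 p for the ROH-with-minor-allele test (and optionally the
#' major-allele test) along the genome, with the genome-wide threshold.
#'
#' @param scan Tibble from [gwas_scan()].
#' @param threshold Significance threshold from [significance_threshold()]
#'   (optional).
#' @param test Which ROH test to plot: `"a"` (minor homozygote), `"b"`, or
#'   `"both"`.
#' @return A ggplot.
#' @export
plot_manhattan <- function(scan, threshold = NULL, test = c("a", "b", "both")) {
  test <- match.arg(test)
  df <- scan |>
    dplyr::mutate(chrom = as.integer(.data$chrom)) |>
    dplyr::arrange(.data$chrom, .data$pos_bp) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(offset = .data$pos_bp / 1e6) |>
    dplyr::ungroup()
  chrom_span <- df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(span = max(.data$offset), .groups = "drop") |>
    dplyr::mutate(start = cumsum(dplyr::lag(.data$span, default = 0)))
  df <- dplyr::left_join(df, chrom_span, by = "chrom") |>
    dplyr::mutate(x = .data$start + .data$offset)
  long <- dplyr::bind_rows(
    if (test %in% c("a", "both"))
      dplyr::transmute(df, x = .data$x, chrom = .data$chrom,
                       p = .data$p_a, which = "ROH + minor hom"),
    if (test %in% c("b", "both"))
      dplyr::transmute(df, x = .data$x, chrom = .data$chrom,
                       p = .data$p_b, which = "ROH + major hom")) |>
    dplyr::filter(!is.na(.data$p))
  gg <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$x, y = -log10(.data$p),
    colour = factor(.data$chrom %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue")) +
    ggplot2::labs(x = "genome position (Mb, concatenated)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (test == "both") gg <- gg + ggplot2::facet_wrap(~which, ncol = 1)
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' Plot the ROH landscape
#'
#' Per-SNP fraction of samples in a ROH along the genome, exposing
#' hotspots and coldspots.
#'
#' @param landscape Tibble from [roh_landscape()].
#' @return A ggplot.
#' @export
plot_roh_landscape <- function(landscape) {
  ggplot2::ggplot(landscape,
                  ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$roh_freq)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "fraction of samples in ROH") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot predicted racing probability against inbreeding
#'
#' @param predictions Tibble from [prediction_table()].
#' @param froh_var Name of the inbreeding column.
#' @return A ggplot with the prediction curve and its confidence band.
#' @export
plot_prediction <- function(predictions, froh_var = "f_roh") {
  ggplot2::ggplot(predictions, ggplot2::aes(x = .data[[froh_var]],
                                            y = .data$p_hat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = expression(F[ROH]), y = "Pr(raced)") +
    ggplot2::theme_minimal()
}
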