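#' Plot a calibration curve with its fitted line
#'
#' @param object A `calibration_curve` from [fit_calibration()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method
autoplot.calibration_curve <- function(object, ...) {
  df <- tibble(
    concentration = object$model$model$concentration,
    response = object$model$model$response
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                   y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$gain, linetype = 2) +
    ggplot2::labs(
      x = "standard concentration (units)",
      y = "kinetic slope (absorbance/min)",
      title = sprintf("Calibration: gain %.3g, R² %.4f",
                      object$gain, object$r_squared)
    )
}

#' Plot relative protein abundance across strains
#'
#' Bar-and-errorbar view of a protein's relative abundance (mean +/- SD of
#' the per-replicate fractions) in each strain.
#'
#' @param summary Abundance summary from [abundance_summary()].
#' @param protein Protein accession to show; default all.
#' @return A ggplot.
#' @export
plot_relative_abundance <- function(summary, protein = NULL) {
  check_columns(summary, c("protein_id", "strain_id", "mean_fraction"),
                "summary")
  if (!is.null(protein)) {
    summary <- dplyr::filter(summary, .data$protein_id %in% protein)
  }
  p <- ggplot2::ggplot(summary, ggplot2::aes(x = .data$strain_id,
                                             y = .data$mean_fraction)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "strain", y = "relative abundance (fraction)")
  if ("sd_fraction" %in% names(summary)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fraction - .data$sd_fraction,
                   ymax = .data$mean_fraction + .data$sd_fraction),
      width = 0.2
    )
  }
  if (length(unique(summary$protein_id)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$protein_id),
                                 scales = "free_y")
  }
  p
}

#' Plot a relative-yield table
#'
#' Tile view of the mean relative yields with significance marks:
#' `*` for significant cells, `.` for marginal ones.
#'
#' @param object A `yield_table` from [relative_yield_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @exportS3Method
autoplot.yield_table <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(mark = dplyr::case_when(
      !is.na(.data$class) & .data$class == "significant" ~ "*",
      !is.na(.data$class) & .data$class == "marginal" ~ ".",
      TRUE ~ ""
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prsA, y = .data$amylase,
                                   fill = .data$mean_ratio)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%s", .data$mean_ratio, .data$mark)
    )) +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "steelblue",
                                  mid = "white", high = "firebrick") +
    ggplot2::labs(x = "added chaperone gene", y = "amylase",
                  fill = "relative\nyield")
}
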