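#' Plot a genome-wide contact map
#'
#' Renders the binned contact matrix on the whole-genome concatenated
#' axis, annotated with the contact total and cis/trans breakdown in the
#' caption style of per-cell map figures.
#'
#' @param object A `contact_matrix` from [bin_contacts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contact_matrix <- function(object, ...) {
  bins <- attr(object, "chrom_offsets")
  d <- dplyr::bind_rows(
    tibble::tibble(x = object$bin1, y = object$bin2, count = object$count),
    tibble::tibble(x = object$bin2, y = object$bin1, count = object$count) |>
      dplyr::filter(.data$x != .data$y))
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::scale_fill_gradient(low = "#c6dbef", high = "#08306b") +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_hline(yintercept = bins$offset[-1] - 0.5,
                        colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = bins$offset[-1] - 0.5,
                        colour = "grey70", linewidth = 0.2) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = paste0(format(attr(object, "n_contacts"), big.mark = ","),
                     " contacts, ",
                     format(attr(object, "bin_size") / 1e6), " Mb bins")) +
    ggplot2::theme_minimal()
}

#' Plot a contact-probability versus separation curve
#'
#' Log-log plot with dashed grey reference lines at the polymer slopes
#' -1.0 (fractal globule) and -1.5 (equilibrium globule), anchored at
#' the first occupied bin.
#'
#' @param object A `separation_curve`.
#' @param ref_slopes Reference exponents to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.separation_curve <- function(object, ref_slopes = c(-1.0, -1.5), ...) {
  d <- object[object$n > 0 & object$probability > 0, ]
  anchor <- d[1, ]
  refs <- purrr::map_dfr(ref_slopes, function(a) {
    tibble::tibble(alpha = factor(a), bin_mid = d$bin_mid,
                   probability = anchor$probability *
                     (d$bin_mid / anchor$bin_mid)^a)
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_mid, .data$probability)) +
    ggplot2::geom_line(data = refs,
                       ggplot2::aes(group = .data$alpha,
                                    linetype = .data$alpha),
                       colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sequence separation (bp)",
                  y = "contact probability",
                  linetype = "reference slope") +
    ggplot2::theme_minimal()
}

#' Plot a 2D projection of a genome structure
#'
#' X-Y projection of one or more models, coloured by chromosome, with
#' the backbone drawn as a path.
#'
#' @param object A `genome_structure`.
#' @param models Which models to draw (default first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genome_structure <- function(object, models = 1, ...) {
  d <- tidy.genome_structure(object)
  d <- d[d$model %in% models, ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, colour = .data$chrom,
                                  group = interaction(.data$model, .data$chrom))) +
    ggplot2::geom_path(alpha = 0.8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (particle radii)", y = "y (particle radii)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
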