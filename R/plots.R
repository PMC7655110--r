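# ggplot2 visualisations.

#' Plot a contact matrix
#'
#' log10 heat map of the (balanced, if available) contact matrix, white
#' to dark red, the standard contact-map colouring.
#'
#' @param object A `contact_matrix`.
#' @param max_bins Downsample to at most this many bins per side before
#'   plotting (keeps the raster desk-sized).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, max_bins = 800L, ...) {
  m <- object
  while (m$n_bins > max_bins) m <- rebin(m, m$bin_size * 2L)
  df <- tidy.contact_matrix(m, upper_only = FALSE)
  df$mb <- (df$bin_i - 0.5) * m$bin_size / 1000
  df$mb2 <- (df$bin_j - 0.5) * m$bin_size / 1000
  ggplot2::ggplot(df, ggplot2::aes(.data$mb, .data$mb2,
                                   fill = log10(.data$count + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 name = "log10 contacts") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "position (kb)", y = "position (kb)") +
    ggplot2::theme_minimal()
}

#' Plot a pile-up
#'
#' Diverging log2 heat map of an aggregate window, centre marked by the
#' enrichment ratio when available.
#'
#' @param object A `pileup`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pileup
#' @export
autoplot.pileup <- function(object, ...) {
  df <- tidy.pileup(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$offset_j / 1000, .data$offset_i / 1000,
                                   fill = log2(.data$value))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  name = "log2 enrichment") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "offset (kb)", y = "offset (kb)",
                  title = if (is.finite(object$enrichment_ratio))
                    sprintf("centre/corner ratio %.2f", object$enrichment_ratio)
                  else NULL) +
    ggplot2::theme_minimal()
}

#' Plot a contact-decay curve
#'
#' @param object A `decay_curve`.
#' @param ... Unused.
#' @return A ggplot of density against distance, both log-scaled.
#' @method autoplot decay_curve
#' @export
autoplot.decay_curve <- function(object, ...) {
  df <- object[object$density > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$mid, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance (bp)", y = "contact density") +
    ggplot2::theme_minimal()
}

#' Plot an insulation profile
#'
#' Normalised insulation score along the chromosome with boundary calls
#' marked.
#'
#' @param object An `insulation_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot insulation_profile
#' @export
autoplot.insulation_profile <- function(object, ...) {
  df <- object$scores[!object$scores$masked, ]
  gg <- ggplot2::ggplot(df, ggplot2::aes((.data$start + object$res / 2) / 1000,
                                         .data$score)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (kb)", y = "insulation (log2 vs mean)") +
    ggplot2::theme_minimal()
  if (nrow(object$boundaries) > 0) {
    gg <- gg + ggplot2::geom_vline(xintercept = object$boundaries$pos / 1000,
                                   linetype = "dashed", colour = "red",
                                   alpha = 0.5)
  }
  gg
}

#' Plot the CAR-interval enrichment series
#'
#' @param series An `interval_series` tibble from
#'   [interval_pileup_series()], or a named list of them (names become
#'   the legend).
#' @return A ggplot of enrichment ratio against CAR interval k.
#' @export
plot_interval_series <- function(series) {
  if (inherits(series, "interval_series")) series <- list(series = series)
  df <- dplyr::bind_rows(
    purrr::imap(series, ~ tibble::tibble(k = .x$k, ratio = .x$ratio,
                                         scenario = .y)))
  ggplot2::ggplot(df[!is.na(df$ratio), ],
                  ggplot2::aes(.data$k, .data$ratio, colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = function(l) seq(ceiling(l[1]), floor(l[2]))) +
    ggplot2::labs(x = "CAR interval (+k)", y = "centre/corner enrichment") +
    ggplot2::theme_minimal()
}

#' Plot a loop-span histogram
#'
#' @param sh The tibble returned by [span_histogram()].
#' @return A ggplot of span probability against CAR interval.
#' @export
plot_span_histogram <- function(sh) {
  ggplot2::ggplot(sh, ggplot2::aes(.data$k, .data$prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "span (CAR intervals)", y = "probability") +
    ggplot2::theme_minimal()
}
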