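# broom-style tidiers for the non-tabular result objects.

#' Tidy a contact matrix into long format
#'
#' @param x A `contact_matrix`.
#' @param upper_only Keep only the upper triangle (including the
#'   diagonal).
#' @param ... Unused.
#' @return Tibble with `bin_i`, `bin_j` (1-based), `distance` (bp),
#'   `count`.
#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, upper_only = TRUE, ...) {
  n <- x$n_bins
  df <- tibble::tibble(
    bin_i = rep(seq_len(n), times = n),
    bin_j = rep(seq_len(n), each = n),
    count = as.vector(x$counts))
  if (upper_only) df <- df[df$bin_j >= df$bin_i, ]
  df$distance <- (df$bin_j - df$bin_i) * x$bin_size
  df[, c("bin_i", "bin_j", "distance", "count")]
}

#' @rdname tidy.contact_matrix
#' @method glance contact_matrix
#' @export
glance.contact_matrix <- function(x, ...) {
  tibble::tibble(n_bins = x$n_bins, bin_size = x$bin_size,
                 chrom_length = x$chrom_length,
                 total_contacts = sum(x$counts),
                 balanced = !is.null(x$weights),
                 n_masked = if (is.null(x$weights)) NA_integer_
                            else sum(is.na(x$weights)))
}

#' Tidy a pile-up into long format
#'
#' @param x A `pileup`.
#' @param ... Unused.
#' @return Tibble with `offset_i`, `offset_j` (bp from the centre) and
#'   `value`.
#' @method tidy pileup
#' @export
tidy.pileup <- function(x, ...) {
  side <- nrow(x$mat)
  off <- (seq_len(side) - (side + 1L) / 2) * x$res
  tibble::tibble(offset_i = rep(off, times = side),
                 offset_j = rep(off, each = side),
                 value = as.vector(x$mat))
}

#' @rdname tidy.pileup
#' @method glance pileup
#' @export
glance.pileup <- function(x, ...) {
  tibble::tibble(n_stacked = x$n_stacked, n_dropped = x$n_dropped,
                 res = x$res, half_width = x$half_width, norm = x$norm,
                 enrichment_ratio = x$enrichment_ratio)
}

#' Tidy an insulation profile
#'
#' @param x An `insulation_profile`.
#' @param ... Unused.
#' @return The per-bin score tibble.
#' @method tidy insulation_profile
#' @export
tidy.insulation_profile <- function(x, ...) x$scores

#' @rdname tidy.insulation_profile
#' @method glance insulation_profile
#' @export
glance.insulation_profile <- function(x, ...) {
  tibble::tibble(res = x$res, window = x$window,
                 n_bins = nrow(x$scores),
                 n_masked = sum(x$scores$masked),
                 n_boundaries = nrow(x$boundaries))
}

#' Tidy a population of loops
#'
#' @param x A `population_loops`.
#' @param ... Unused.
#' @return The positioned-loop frequency tibble with a `span` column
#'   (CAR intervals).
#' @method tidy population_loops
#' @export
tidy.population_loops <- function(x, ...) {
  dplyr::mutate(x$loops, span = .data$right_car - .data$left_car)
}

#' @rdname tidy.population_loops
#' @method glance population_loops
#' @export
glance.population_loops <- function(x, ...) {
  sh <- span_histogram(x)
  tibble::tibble(n_cells = x$n_cells, mode = x$mode,
                 n_distinct_loops = nrow(x$loops),
                 n_unpositioned = nrow(x$unpositioned),
                 mean_span = attr(sh, "mean_span"))
}
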