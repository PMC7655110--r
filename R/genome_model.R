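#' Build a synthetic chromosome of cohesin associated regions (CARs)
#'
#' Generates the chromosome model at the heart of the simulator: a set of
#' CAR centres along a single yeast-like chromosome, each carrying an
#' occupancy probability -- the per-cell probability that the CAR holds
#' stably bound cohesin.  Inter-CAR spacings are drawn from a right-skewed
#' log-normal distribution with the requested median (yeast CARs sit a
#' median of ~8 kb apart, ranging from ~3 kb to tens of kb), resampled
#' until they fall inside `spacing_range`.  Occupancies are i.i.d.
#' Beta-distributed so that a top decile of "high-residency" CARs is
#' clearly separated from the bulk.
#'
#' When a centromere coordinate is supplied the CAR nearest to it is
#' flagged centromeric and assigned the maximum occupancy of the map,
#' mirroring the single high-residency cohesin peak observed at yeast
#' centromeres.
#'
#' @param n_cars Number of CARs to place.
#' @param chrom_length Chromosome length in bp.
#' @param spacing_median Target median inter-CAR spacing in bp.
#' @param spacing_range Length-2 numeric; spacings are resampled until they
#'   fall inside this range (bp).
#' @param spacing_sdlog Log-scale standard deviation of the spacing
#'   distribution.
#' @param occupancy_shape Occupancy distribution.  Either a length-2
#'   numeric, the `(alpha, beta)` parameters of a single Beta law, or a
#'   list `list(bulk = c(a, b), high = c(a, b), prop_high = p)` for a
#'   two-component Beta mixture.  The default mixture (90% of CARs from
#'   Beta(2.5, 3) with mean 0.45; 10% from Beta(10, 2) with mean 0.83;
#'   overall mean ~0.5) keeps the top occupancy decile clearly separated
#'   from the bulk, so that high-residency CARs behave as qualitatively
#'   distinct barriers.
#' @param centromere Optional centromere coordinate (bp), or `NULL`.
#' @param chrom_name Chromosome label carried into exported files.
#' @param seed Integer seed; the map is deterministic given it.
#' @return A `car_map`: a tibble with one row per CAR and columns `car`
#'   (1-based index), `pos` (centre, bp, 0-based), `occupancy`,
#'   `high_residency` (all `FALSE` until [classify_high_residency()] is
#'   applied) and `centromere` (logical), with attributes `chrom_name`,
#'   `chrom_length` and `centromere_index`.
#' @examples
#' cm <- build_car_map(n_cars = 50, chrom_length = 5e5, seed = 1)
#' median(diff(cm$pos))
#' @export
build_car_map <- function(n_cars,
                          chrom_length,
                          spacing_median = 8000,
                          spacing_range = c(3000, 40000),
                          spacing_sdlog = 0.45,
                          occupancy_shape = list(bulk = c(2.5, 3),
                                                 high = c(10, 2),
                                                 prop_high = 0.1),
                          centromere = NULL,
                          chrom_name = "chrSim",
                          seed = 1L) {
  stopifnot_scalar_number(n_cars, "n_cars", lower = 0)
  stopifnot_scalar_number(chrom_length, "chrom_length", lower = 1)
  min_gap <- spacing_range[1]
  if (min_gap < 2000) abort("minimum spacing must be at least 2 kb")
  if (spacing_median < min_gap) {
    abort("`spacing_median` is below the minimum inter-CAR gap")
  }
  if (n_cars > 0 && chrom_length < n_cars * min_gap) {
    abort(sprintf(
      "chromosome of %d bp too short to host %d CARs at >= %d bp spacing",
      chrom_length, n_cars, min_gap))
  }

  if (n_cars == 0) {
    return(new_car_map(tibble::tibble(
      car = integer(), pos = numeric(), occupancy = numeric(),
      high_residency = logical(), centromere = logical()),
      chrom_name, chrom_length, NA_integer_))
  }

  with_seed(seed, {
    spacings <- draw_clipped_lognormal(n_cars - 1L, spacing_median,
                                       spacing_sdlog, spacing_range)
    # first CAR offset from the chromosome start, same law as a spacing
    offset <- draw_clipped_lognormal(1L, spacing_median / 2, spacing_sdlog,
                                     c(500, spacing_range[2]))
    pos <- round(cumsum(c(offset, spacings)))
    # rescale into the chromosome if the draw overshoots the right end
    if (pos[n_cars] >= chrom_length - 500) {
      pos <- round(pos * (chrom_length - 1000) / pos[n_cars])
    }
    occ <- draw_occupancy(n_cars, occupancy_shape)

    cen_idx <- NA_integer_
    if (!is.null(centromere)) {
      cen_idx <- which.min(abs(pos - centromere))
      occ[cen_idx] <- max(occ)
    }

    new_car_map(tibble::tibble(
      car = seq_len(n_cars),
      pos = as.numeric(pos),
      occupancy = occ,
      high_residency = FALSE,
      centromere = seq_len(n_cars) == cen_idx & !is.na(cen_idx)),
      chrom_name, chrom_length, cen_idx)
  })
}

draw_occupancy <- function(n, shape) {
  if (is.numeric(shape) && length(shape) == 2L) {
    return(rbeta(n, shape[1], shape[2]))
  }
  if (is.list(shape) && all(c("bulk", "high", "prop_high") %in% names(shape))) {
    hi <- runif(n) < shape$prop_high
    out <- numeric(n)
    out[!hi] <- rbeta(sum(!hi), shape$bulk[1], shape$bulk[2])
    out[hi] <- rbeta(sum(hi), shape$high[1], shape$high[2])
    return(out)
  }
  abort("`occupancy_shape` must be c(alpha, beta) or list(bulk, high, prop_high)")
}

draw_clipped_lognormal <- function(n, med, sdlog, range) {
  if (n <= 0) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2L * (n - length(out)) + 8L, meanlog = log(med), sdlog = sdlog)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

new_car_map <- function(df, chrom_name, chrom_length, centromere_index) {
  structure(df,
            chrom_name = chrom_name,
            chrom_length = as.numeric(chrom_length),
            centromere_index = centromere_index,
            class = c("car_map", class(df)))
}

#' @export
print.car_map <- function(x, ...) {
  cat(sprintf("# CAR map: %d CARs on %s (%s bp)%s\n",
              nrow(x), attr(x, "chrom_name"),
              format(attr(x, "chrom_length"), big.mark = ","),
              if (!is.na(attr(x, "centromere_index") %||% NA))
                sprintf(", centromere at CAR %d", attr(x, "centromere_index"))
              else ""))
  NextMethod()
}

validate_car_map <- function(map) {
  if (!inherits(map, "car_map")) abort("expected a `car_map`")
  if (nrow(map) > 0) {
    if (is.unsorted(map$pos, strictly = TRUE)) {
      abort("CAR positions must be strictly increasing")
    }
    if (any(map$pos < 0) || any(map$pos >= attr(map, "chrom_length"))) {
      abort("CAR positions must lie inside [0, chrom_length)")
    }
    if (any(map$occupancy < 0 | map$occupancy > 1)) {
      abort("occupancy probabilities must lie in [0, 1]")
    }
  }
  invisible(map)
}

#' Flag the highest-residency entries of a CAR map or peak set
#'
#' Cohesin ChIP peaks span a wide range of heights; the top decile
#' ("high-residency" CARs) act as barriers to loop expansion and as
#' domain boundaries.  This classifier flags the `ceiling(fraction * n)`
#' entries with the largest occupancy (for a `car_map`) or peak height
#' (for a `peak_set`).  Ties are broken toward the leftmost coordinate,
#' so the result is deterministic and permutation-invariant.
#'
#' @param x A `car_map` or `peak_set`.
#' @param fraction Fraction to flag, in (0, 1]; default the top 10%.
#' @return For a `car_map`, the map with its `high_residency` column set;
#'   for a `peak_set`, the peak set with a `high_residency` column.
#' @export
classify_high_residency <- function(x, fraction = 0.10) {
  stopifnot_scalar_number(fraction, "fraction", lower = 1e-12, upper = 1)
  score <- if (inherits(x, "car_map")) x$occupancy
           else if (inherits(x, "peak_set")) x$height
           else abort("`x` must be a `car_map` or `peak_set`")
  coord <- if (inherits(x, "car_map")) x$pos else x$summit
  n <- length(score)
  flags <- logical(n)
  if (n > 0) {
    k <- ceiling(fraction * n)
    ord <- order(-score, coord)
    flags[ord[seq_len(k)]] <- TRUE
  }
  x$high_residency <- flags
  x
}
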