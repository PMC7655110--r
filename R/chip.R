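#' Emulate a cohesin ChIP-seq coverage track from a CAR map
#'
#' The intensity of a cohesin ChIP peak is taken to reflect the
#' probability that the CAR is occupied in a given cell, so the track is
#' built as a flat count-sampled background plus one Gaussian bump per
#' CAR whose expected area is `peak_gain * occupancy`.  The bump
#' full-width at half maximum is `peak_width` (~1 kb, the observed width
#' of Mcd1p peaks).
#'
#' @param map A `car_map`.
#' @param depth Mean background signal per bin; Poisson-sampled when
#'   `noise = TRUE`, added as a constant otherwise.
#' @param peak_width Full-width at half maximum of each peak, bp.
#' @param peak_gain Expected bump area (signal x bp summed over bins)
#'   per unit occupancy.
#' @param bin_size Track bin size in bp (>= 10).
#' @param noise Sample the background from a Poisson law (`TRUE`) or
#'   return the noise-free expectation (`FALSE`).
#' @param seed Integer seed controlling the background sampling.
#' @return A `chip_track`: tibble with `bin` (0-based), `start`, `end`
#'   and `score`, with attributes `bin_size` and `chrom_length`.
#' @export
synthesize_chip <- function(map,
                            depth = 20,
                            peak_width = 1000,
                            peak_gain = 2000,
                            bin_size = 20,
                            noise = TRUE,
                            seed = 1L) {
  validate_car_map(map)
  if (bin_size < 10) abort("`bin_size` must be at least 10 bp")
  stopifnot_scalar_number(depth, "depth", lower = 0)
  chrom_length <- attr(map, "chrom_length")
  n_bins <- ceiling(chrom_length / bin_size)
  centers <- (seq_len(n_bins) - 0.5) * bin_size

  cov <- numeric(n_bins)
  if (nrow(map) > 0) {
    sigma <- peak_width / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    for (i in seq_len(nrow(map))) {
      lo <- max(1L, floor((map$pos[i] - 5 * sigma) / bin_size))
      hi <- min(n_bins, ceiling((map$pos[i] + 5 * sigma) / bin_size))
      idx <- lo:hi
      cov[idx] <- cov[idx] +
        map$occupancy[i] * peak_gain * dnorm(centers[idx], map$pos[i], sigma) * bin_size
    }
  }
  if (depth > 0) {
    bg <- if (noise) with_seed(seed, rpois(n_bins, depth)) else rep(depth, n_bins)
    cov <- cov + bg
  }

  structure(tibble::tibble(
    bin = seq_len(n_bins) - 1L,
    start = (seq_len(n_bins) - 1L) * bin_size,
    end = pmin(seq_len(n_bins) * bin_size, chrom_length),
    score = cov),
    bin_size = bin_size,
    chrom_length = chrom_length,
    chrom_name = attr(map, "chrom_name"),
    class = c("chip_track", "tbl_df", "tbl", "data.frame"))
}

#' Call peaks on a ChIP track by thresholded local maxima
#'
#' A deliberately simple detector for synthetic tracks (real data would
#' go through a dedicated peak caller): the track is smoothed with a
#' running mean, local maxima above `min_height` are collected, and
#' maxima are greedily accepted in decreasing height order subject to a
#' minimum mutual separation (ties go to the leftmost).  Peak width is
#' the span of the smoothed profile above half of the peak height.
#'
#' @param track A `chip_track`.
#' @param min_height Minimum smoothed height for a summit.
#' @param min_separation Minimum distance between summits, bp (>= one bin).
#' @param smooth_bins Odd running-mean window in bins (1 = no smoothing).
#' @param baseline Background level subtracted from reported heights
#'   (e.g. the sequencing depth); reported heights are `max - baseline`,
#'   floored at 0.  The `min_height` threshold applies before
#'   subtraction.
#' @return A `peak_set`: tibble with `summit` (bp), `height` and
#'   `width` (bp), sorted by summit.
#' @export
call_peaks <- function(track,
                       min_height,
                       min_separation = 2000,
                       smooth_bins = 5L,
                       baseline = 0) {
  bin_size <- attr(track, "bin_size")
  if (min_separation < bin_size) abort("`min_separation` must be >= one bin")
  y <- running_mean(track$score, smooth_bins)
  n <- length(y)
  if (n < 3L) return(new_peak_set(numeric(0), numeric(0), numeric(0)))

  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  cand <- which(is_max & y >= min_height)
  if (length(cand) == 0) return(new_peak_set(numeric(0), numeric(0), numeric(0)))

  # greedy acceptance: tallest first, leftmost on ties
  ord <- cand[order(-y[cand], cand)]
  sep_bins <- min_separation / bin_size
  kept <- integer(0)
  for (b in ord) {
    if (all(abs(kept - b) >= sep_bins)) kept <- c(kept, b)
  }
  kept <- sort(kept)

  centers <- (track$start + track$end) / 2
  widths <- vapply(kept, function(b) {
    half <- y[b] / 2
    lo <- b
    while (lo > 1L && y[lo - 1L] >= half) lo <- lo - 1L
    hi <- b
    while (hi < n && y[hi + 1L] >= half) hi <- hi + 1L
    (hi - lo + 1L) * bin_size
  }, numeric(1))

  new_peak_set(centers[kept], pmax(y[kept] - baseline, 0), widths)
}

new_peak_set <- function(summit, height, width) {
  structure(tibble::tibble(summit = summit, height = height, width = width),
            class = c("peak_set", "tbl_df", "tbl", "data.frame"))
}

#' Estimate per-CAR occupancy from ChIP peak heights
#'
#' The inverse of [synthesize_chip()]: peak heights divided by a
#' calibration factor (expected peak height per unit occupancy) give
#' occupancy estimates, clipped to `[0, 1]`.  Peaks are matched to CARs
#' by nearest summit; peaks further than `max_match` from any CAR are
#' reported as orphans and excluded.
#'
#' @param peaks A `peak_set`.
#' @param map The `car_map` the peaks are matched against.
#' @param calibration Expected peak height per unit occupancy (> 0); see
#'   [chip_peak_height()] for the value implied by the synthesis
#'   parameters.
#' @param max_match Maximum summit-to-CAR distance for a match, bp.
#' @return A tibble with one row per CAR: `car`, `pos`, `estimate`
#'   (`NA` when no peak matched), plus attribute `orphans` (summits of
#'   unmatched peaks).
#' @export
estimate_occupancy <- function(peaks, map, calibration, max_match = 2000) {
  validate_car_map(map)
  stopifnot_scalar_number(calibration, "calibration", lower = 1e-300)
  est <- rep(NA_real_, nrow(map))
  orphans <- numeric(0)
  if (nrow(peaks) > 0 && nrow(map) > 0) {
    for (i in seq_len(nrow(peaks))) {
      j <- which.min(abs(map$pos - peaks$summit[i]))
      if (abs(map$pos[j] - peaks$summit[i]) <= max_match) {
        h <- peaks$height[i] / calibration
        est[j] <- min(max(h, 0), 1)
      } else {
        orphans <- c(orphans, peaks$summit[i])
      }
    }
  } else {
    orphans <- peaks$summit
  }
  structure(tibble::tibble(car = map$car, pos = map$pos, estimate = est),
            orphans = orphans)
}

#' Expected ChIP peak height per unit occupancy
#'
#' The summit height implied by the [synthesize_chip()] bump model for a
#' CAR with occupancy 1: the centre-bin value of a Gaussian of area
#' `peak_gain` and FWHM `peak_width`, optionally attenuated by the
#' running-mean smoothing applied in [call_peaks()].
#'
#' @inheritParams synthesize_chip
#' @param smooth_bins Smoothing window that will be used at peak calling.
#' @return Expected summit height (signal units) per unit occupancy.
#' @export
chip_peak_height <- function(peak_gain = 2000, peak_width = 1000,
                             bin_size = 20, smooth_bins = 1L) {
  sigma <- peak_width / (2 * sqrt(2 * log(2)))
  half <- (smooth_bins - 1) %/% 2
  offs <- (-half:half) * bin_size
  mean(dnorm(offs, 0, sigma)) * bin_size * peak_gain
}

#' Estimate occupancy from adjacent-loop frequencies
#'
#' Under the consecutive-occupancy loop model an adjacent (span-1) loop
#' between CARs i and i+1 forms exactly when both are occupied, so its
#' population frequency is `p_i * p_(i+1)`.  For each CAR the geometric
#' mean of the square roots of its flanking adjacent-loop frequencies is
#' an occupancy estimate that is exact for uniform occupancy.
#'
#' @param pop A `population_loops` object from [simulate_population()].
#' @param map The `car_map` the population was simulated from.
#' @return Tibble with `car`, `pos`, `estimate` (`NA` where no flanking
#'   adjacent loop was observed).
#' @export
occupancy_from_adjacent_loops <- function(pop, map) {
  validate_car_map(map)
  adj <- dplyr::filter(pop$loops, .data$right_car - .data$left_car == 1L)
  f <- rep(NA_real_, max(nrow(map) - 1L, 0L))
  if (nrow(adj) > 0) f[adj$left_car] <- adj$frequency
  est <- vapply(seq_len(nrow(map)), function(i) {
    fl <- if (i > 1L) f[i - 1L] else NA_real_
    fr <- if (i <= length(f)) f[i] else NA_real_
    v <- sqrt(c(fl, fr))
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else exp(mean(log(pmax(v, 1e-12))))
  }, numeric(1))
  tibble::tibble(car = map$car, pos = map$pos, estimate = pmin(est, 1))
}
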