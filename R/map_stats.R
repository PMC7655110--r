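#' Contact-decay curve
#'
#' Histograms intra-chromosomal contacts into distance bins with
#' exponentially increasing widths (default 100 bp to 1 Mb), after
#' removing contacts closer than `min_dist` (self-ligation range).  Two
#' normalisations are reported per bin: `prob`, the fraction of retained
#' contacts (sums to 1), and `density`, a probability density over
#' distance.  For a `contact_matrix` input the density is computed from
#' the *per-locus-pair* mean contact at each distance, which removes the
#' finite-chromosome edge effect (fewer pairs exist at large distances);
#' for a raw pair list it is the histogram mass divided by bin width and
#' total.
#'
#' @param x A `contact_matrix`, or a numeric vector of pair distances
#'   (bp), or a data frame with a `distance` column.
#' @param min_dist Minimum retained distance, bp.
#' @param range Length-2 distance range of the binning, bp.
#' @param bins_per_decade Number of log-spaced bins per decade.
#' @return A `decay_curve` tibble: `bin_lo`, `bin_hi`, `mid` (geometric
#'   midpoint), `n` (contact mass), `prob`, `density`.
#' @export
contact_decay <- function(x, min_dist = 100, range = c(100, 1e6),
                          bins_per_decade = 8) {
  edges <- 10^seq(log10(range[1]), log10(range[2]),
                  by = 1 / bins_per_decade)
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  mid <- sqrt(lo * hi)

  if (inherits(x, "contact_matrix")) {
    n_bins <- x$n_bins
    dists <- (seq_len(n_bins - 1L)) * x$bin_size  # off-diagonal distances
    diag_sums <- vapply(seq_len(n_bins - 1L), function(d) {
      sum(x$counts[cbind(seq_len(n_bins - d), seq_len(n_bins - d) + d)])
    }, numeric(1))
    keep <- dists >= min_dist
    if (!any(keep) || sum(diag_sums[keep]) == 0) {
      abort("no contacts remain after the minimum-distance filter")
    }
    dists <- dists[keep]
    diag_sums <- diag_sums[keep]
    n_pairs <- n_bins - dists / x$bin_size
    per_pair <- diag_sums / n_pairs  # finite-size-corrected mean contact
    idx <- findInterval(dists, edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= length(lo)
    mass <- vapply(seq_along(lo), function(b) sum(diag_sums[ok & idx == b]),
                   numeric(1))
    dens <- vapply(seq_along(lo), function(b) {
      s <- per_pair[ok & idx == b]
      if (length(s) == 0) 0 else mean(s)
    }, numeric(1))
    total <- sum(mass)
    dens <- dens / sum(dens * (hi - lo))  # pdf over distance
  } else {
    d <- if (is.data.frame(x)) x$distance else as.numeric(x)
    d <- d[d >= min_dist]
    if (length(d) == 0) abort("no contacts remain after the minimum-distance filter")
    idx <- findInterval(d, edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= length(lo)
    mass <- tabulate(idx[ok], nbins = length(lo))
    total <- sum(mass)
    dens <- mass / (hi - lo) / total
  }

  structure(tibble::tibble(bin_lo = lo, bin_hi = hi, mid = mid,
                           n = mass, prob = mass / total, density = dens),
            min_dist = min_dist,
            class = c("decay_curve", "tbl_df", "tbl", "data.frame"))
}

#' Sliding-window slopes of a decay curve
#'
#' Fits a least-squares line to `log10(density)` versus `log10(distance)`
#' inside every fixed-width window of bins and assigns the slope to the
#' window centre, giving the derivative track commonly plotted next to
#' contact-decay curves.
#'
#' @param curve A `decay_curve`.
#' @param window Window width in bins (>= 2).
#' @return Tibble with `mid` (window-centre distance, bp) and `slope`.
#' @export
decay_slope <- function(curve, window = 5L) {
  if (window < 2L) abort("`window` must be >= 2 bins")
  keep <- curve$density > 0 & is.finite(curve$density)
  lx <- log10(curve$mid[keep])
  ly <- log10(curve$density[keep])
  nb <- length(lx)
  if (window > nb) abort("`window` exceeds the number of usable bins")
  n_win <- nb - window + 1L
  slopes <- vapply(seq_len(n_win), function(i) {
    xs <- lx[i:(i + window - 1L)]
    ys <- ly[i:(i + window - 1L)]
    sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  }, numeric(1))
  centers <- vapply(seq_len(n_win), function(i) {
    10^mean(lx[i:(i + window - 1L)])
  }, numeric(1))
  tibble::tibble(mid = centers, slope = slopes)
}

#' Pile up contact-map windows at anchor pairs (APA)
#'
#' Extracts, for every anchor pair, the square window of half-width
#' `half_width` centred on the pair's pixel, normalises it (`"balanced"`
#' uses the balanced counts as-is; `"distance"` divides every entry by
#' the genome-wide expected contact at its diagonal), and averages the
#' stack element-wise.  Pairs whose separation is smaller than
#' `half_width` (too close to the diagonal) and pairs whose window runs
#' off the matrix are dropped and counted.
#'
#' @param m A `contact_matrix` (balanced for `norm = "balanced"` or
#'   `"distance"` on balanced counts; raw counts are used when no
#'   weights are stored).
#' @param pairs Data frame with bp coordinates in columns `a5` and `a3`
#'   (or first two columns), one row per anchor pair.
#' @param half_width Window half-width, bp.
#' @param norm `"distance"` (default) or `"balanced"`.
#' @return A `pileup` object: list with `mat` (odd-sided aggregate),
#'   `res` (= matrix bin size), `half_width`, `n_stacked`, `n_dropped`,
#'   `norm`, `enrichment_ratio` (filled by [enrichment_ratio()], `NA`
#'   here).
#' @export
pileup_at_pairs <- function(m, pairs, half_width = 5000,
                            norm = c("distance", "balanced")) {
  norm <- match.arg(norm)
  if (!is.data.frame(pairs)) abort("`pairs` must be a data frame")
  a5 <- if ("a5" %in% names(pairs)) pairs$a5 else pairs[[1]]
  a3 <- if ("a3" %in% names(pairs)) pairs$a3 else pairs[[2]]

  x <- if (is.null(m$weights)) m$counts else balanced_counts(m)
  if (norm == "distance") {
    expd <- diagonal_means(x)
    d <- abs(row(x) - col(x)) + 1L
    x <- x / expd[d]
    dim(x) <- c(m$n_bins, m$n_bins)
  }

  hw <- round(half_width / m$bin_size)
  side <- 2L * hw + 1L
  n <- m$n_bins
  acc <- matrix(0, side, side)
  cnt <- matrix(0, side, side)
  n_stacked <- 0L
  n_dropped <- 0L
  for (p in seq_along(a5)) {
    bi <- floor(min(a5[p], a3[p]) / m$bin_size) + 1L
    bj <- floor(max(a5[p], a3[p]) / m$bin_size) + 1L
    if (abs(a3[p] - a5[p]) < half_width ||
        bi - hw < 1L || bj + hw > n || bi + hw > n || bj - hw < 1L) {
      n_dropped <- n_dropped + 1L
      next
    }
    win <- x[(bi - hw):(bi + hw), (bj - hw):(bj + hw)]
    fin <- is.finite(win)
    win[!fin] <- 0
    acc <- acc + win
    cnt <- cnt + fin
    n_stacked <- n_stacked + 1L
  }
  if (n_stacked == 0L) abort("no usable anchor pairs for the pile-up")
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  structure(list(mat = out, res = m$bin_size, half_width = half_width,
                 n_stacked = n_stacked, n_dropped = n_dropped, norm = norm,
                 enrichment_ratio = NA_real_),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("# Pile-up: %dx%d at %d bp (%d pairs stacked, %d dropped), %s-normalised\n",
              nrow(x$mat), ncol(x$mat), x$res, x$n_stacked, x$n_dropped, x$norm))
  if (is.finite(x$enrichment_ratio)) {
    cat(sprintf("# centre/corner enrichment ratio: %.3f\n", x$enrichment_ratio))
  }
  invisible(x)
}

#' Centre-over-corner enrichment ratio of a pile-up
#'
#' The aggregate loop strength: the value of the central pixel divided
#' by the mean over the four `corner_size` x `corner_size` corner
#' submatrices of the pile-up window (corners flush with the window
#' borders).
#'
#' @param p A `pileup`.
#' @param corner_size Corner submatrix side in pixels; `2 * corner_size`
#'   must be smaller than the pile-up side.
#' @return The ratio (a bare number); `NaN` with a warning when the
#'   corner mean is zero or undefined.
#' @export
enrichment_ratio <- function(p, corner_size = 14L) {
  side <- nrow(p$mat)
  if (2L * corner_size >= side) {
    abort("`corner_size` too large for this pile-up window")
  }
  c0 <- (side + 1L) %/% 2L
  center <- p$mat[c0, c0]
  ks <- seq_len(corner_size)
  corners <- c(p$mat[ks, ks], p$mat[ks, side - corner_size + ks],
               p$mat[side - corner_size + ks, ks],
               p$mat[side - corner_size + ks, side - corner_size + ks])
  cm <- mean(corners, na.rm = TRUE)
  if (!is.finite(cm) || cm == 0) {
    warn("corner mean is zero or undefined; enrichment ratio is NaN")
    return(NaN)
  }
  center / cm
}

#' Pile-up series over CAR intervals (+1 ... +k)
#'
#' For each interval k, pairs every peak with the peak k positions
#' further along the chromosome (pairs separated by more than
#' `max_separation` are dropped), piles up the contact map at those
#' pairs and reports the centre-over-corner enrichment ratio -- the
#' genome-wide quantification of loop expansion.
#'
#' @param m A balanced `contact_matrix`.
#' @param peaks A `peak_set` (or a `car_map`, whose CAR centres are
#'   used), sorted by coordinate.
#' @param k_range Integer vector of CAR intervals to evaluate.
#' @param half_width,norm Passed to [pileup_at_pairs()].
#' @param corner_size Passed to [enrichment_ratio()].
#' @param max_separation Pairs further apart than this are dropped, bp.
#' @return Tibble with `k`, `n_pairs`, `ratio`; attribute `pileups` is
#'   the named list of per-k `pileup` objects (`NULL` entries where no
#'   usable pairs existed).
#' @export
interval_pileup_series <- function(m, peaks, k_range = 1:10,
                                   half_width = 5000,
                                   norm = "distance",
                                   corner_size = 14L,
                                   max_separation = 1e5) {
  summits <- peak_coords(peaks)
  m <- precompute_norm(m, norm)  # one O/E pass shared across all k
  res <- purrr::map(k_range, function(k) {
    if (k >= length(summits)) return(NULL)
    i <- seq_len(length(summits) - k)
    prs <- tibble::tibble(a5 = summits[i], a3 = summits[i + k])
    prs <- prs[prs$a3 - prs$a5 <= max_separation, ]
    if (nrow(prs) == 0) return(NULL)
    p <- tryCatch(pileup_at_pairs(m, prs, half_width, norm = "balanced"),
                  error = function(e) NULL)
    if (is.null(p)) return(NULL)
    p$enrichment_ratio <- enrichment_ratio(p, corner_size)
    p
  })
  names(res) <- paste0("k", k_range)
  structure(tibble::tibble(
    k = k_range,
    n_pairs = vapply(res, function(p) if (is.null(p)) 0L else p$n_stacked, integer(1)),
    ratio = vapply(res, function(p) if (is.null(p)) NA_real_ else p$enrichment_ratio,
                   numeric(1))),
    pileups = res,
    class = c("interval_series", "tbl_df", "tbl", "data.frame"))
}

# Apply the requested pile-up normalisation once, returning a matrix
# object whose raw counts already carry it (so repeated pile-up calls
# skip the O/E recomputation).
precompute_norm <- function(m, norm) {
  x <- if (norm == "distance") observed_over_expected(m)
       else if (is.null(m$weights)) m$counts
       else balanced_counts(m)
  structure(list(counts = x, bin_size = m$bin_size, n_bins = m$n_bins,
                 chrom_length = m$chrom_length, chrom_name = m$chrom_name,
                 weights = NULL),
            class = "contact_matrix")
}

peak_coords <- function(peaks) {
  s <- if (inherits(peaks, "car_map")) peaks$pos
       else if (inherits(peaks, "peak_set")) peaks$summit
       else if (is.numeric(peaks)) peaks
       else abort("`peaks` must be a peak_set, car_map or numeric vector")
  if (is.unsorted(s)) abort("peak coordinates must be sorted")
  s
}

#' Barrier contrast at +2 CAR pairs
#'
#' Splits all (i, i+2) peak pairs by whether the intervening peak is
#' flagged high-residency and reports the pile-up enrichment ratio of
#' each class.  High-residency CARs acting as barriers show up as
#' `ratio_across_barrier < ratio_no_barrier`.
#'
#' @param m A balanced `contact_matrix`.
#' @param peaks A `peak_set` or `car_map` carrying a `high_residency`
#'   column (see [classify_high_residency()]).
#' @param half_width,norm,corner_size,max_separation As in
#'   [interval_pileup_series()].
#' @return Tibble with one row per class: `class`, `n_pairs`, `ratio`
#'   (`NA` when a class has no usable pairs).
#' @export
barrier_contrast <- function(m, peaks, half_width = 5000,
                             norm = "distance", corner_size = 14L,
                             max_separation = 1e5) {
  summits <- peak_coords(peaks)
  flags <- peaks$high_residency
  if (is.null(flags)) abort("`peaks` carries no high_residency flags")
  n <- length(summits)
  if (n < 3L) abort("need at least three peaks for +2 pairs")
  i <- seq_len(n - 2L)
  mid_hr <- flags[i + 1L]
  prs <- tibble::tibble(a5 = summits[i], a3 = summits[i + 2L], barrier = mid_hr)
  prs <- prs[prs$a3 - prs$a5 <= max_separation, ]
  m <- precompute_norm(m, norm)

  ratio_of <- function(sub) {
    if (nrow(sub) == 0) return(c(n = 0L, ratio = NA_real_))
    p <- tryCatch(pileup_at_pairs(m, sub, half_width, norm = "balanced"),
                  error = function(e) NULL)
    if (is.null(p)) return(c(n = 0L, ratio = NA_real_))
    c(n = p$n_stacked, ratio = enrichment_ratio(p, corner_size))
  }
  ab <- ratio_of(prs[prs$barrier, ])
  nb <- ratio_of(prs[!prs$barrier, ])
  tibble::tibble(class = c("across_barrier", "no_barrier"),
                 n_pairs = as.integer(c(ab["n"], nb["n"])),
                 ratio = c(ab["ratio"], nb["ratio"]))
}
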