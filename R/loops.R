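# Donut-filter loop calling and loop summary statistics.

# Summed-area table: S[i+1, j+1] = sum of M[1:i, 1:j]; box sums in O(1).
sat <- function(m) {
  n <- nrow(m)
  s <- matrix(0, n + 1L, n + 1L)
  s[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  s
}

sat_box <- function(s, i0, i1, j0, j1) {
  s[cbind(i1 + 1L, j1 + 1L)] - s[cbind(i0, j1 + 1L)] -
    s[cbind(i1 + 1L, j0)] + s[cbind(i0, j0)]
}

#' Call focal loops with a simplified donut filter
#'
#' A deliberately pared-down stand-in for HICCUPS-style callers, suited
#' to planted-truth synthetic maps: for every pixel in the distance band
#' `[min_dist, max_dist]`, the local background is the mean
#' observed/expected value in a square ring (donut) between Chebyshev
#' radii `donut_inner` and `donut_outer`, excluding the same-row and
#' same-column strips.  Pixels whose O/E exceeds `fold_min` times that
#' background are candidates; each gets a Poisson upper-tail p-value of
#' its raw count against the locally-adjusted expected count,
#' Benjamini-Hochberg correction is applied at `fdr` over all
#' candidates, and significant pixels are greedily merged to their local
#' maximum within `merge_radius` bins.
#'
#' @param m A balanced `contact_matrix` (raw counts are used to score
#'   significance; the O/E transform drives candidate selection).
#' @param min_dist,max_dist Distance band for calls, bp.
#' @param donut_inner,donut_outer Inner/outer Chebyshev radii of the
#'   donut, bins (`donut_outer > donut_inner >= 1`).
#' @param fold_min Minimum O/E fold over the donut background.
#' @param fdr Benjamini-Hochberg false-discovery level.
#' @param merge_radius Chebyshev radius (bins) within which significant
#'   pixels are merged to the strongest one.
#' @return A `loop_calls` tibble sorted by `(bin_i, bin_j)`: 1-based
#'   `bin_i`, `bin_j`, anchor bin centres `a5`, `a3` (bp), `observed`
#'   (raw count), `local_expected`, `fold`, `p_value`, `q_value`;
#'   attribute `bin_size`.
#' @export
call_loops <- function(m,
                       min_dist = 5000,
                       max_dist = 1e5,
                       donut_inner = 2L,
                       donut_outer = 6L,
                       fold_min = 2,
                       fdr = 0.1,
                       merge_radius = 3L) {
  if (donut_inner < 1L || donut_outer <= donut_inner) {
    abort("need donut_outer > donut_inner >= 1")
  }
  oe <- observed_over_expected(m)
  n <- m$n_bins
  bs <- m$bin_size

  fin <- is.finite(oe)
  oe0 <- ifelse(fin, oe, 0)
  s_val <- sat(oe0)
  s_cnt <- sat(fin * 1)
  rc_val <- t(apply(oe0, 1, cumsum))   # row cumsums for strip segments
  rc_cnt <- t(apply(fin * 1, 1, cumsum))
  cc_val <- apply(oe0, 2, cumsum)
  cc_cnt <- apply(fin * 1, 2, cumsum)

  dmin <- ceiling(min_dist / bs)
  dmax <- floor(max_dist / bs)
  cand <- which(upper.tri(oe) & (col(oe) - row(oe)) >= dmin &
                  (col(oe) - row(oe)) <= dmax & fin, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty_loop_calls(bs))
  i <- cand[, 1]; j <- cand[, 2]
  R <- donut_outer; r <- donut_inner

  clamp <- function(x) pmin(pmax(x, 1L), n)
  box <- function(svals, rad) {
    sat_box(svals, clamp(i - rad), clamp(i + rad), clamp(j - rad), clamp(j + rad))
  }
  rowseg <- function(rcm, rad) {
    hi <- rcm[cbind(i, clamp(j + rad))]
    lo <- ifelse(j - rad - 1L >= 1L, rcm[cbind(i, clamp(j - rad - 1L))], 0)
    hi - lo
  }
  colseg <- function(ccm, rad) {
    hi <- ccm[cbind(clamp(i + rad), j)]
    lo <- ifelse(i - rad - 1L >= 1L, ccm[cbind(clamp(i - rad - 1L), j)], 0)
    hi - lo
  }

  donut_sum <- box(s_val, R) - box(s_val, r) -
    (rowseg(rc_val, R) - rowseg(rc_val, r)) -
    (colseg(cc_val, R) - colseg(cc_val, r))
  donut_cnt <- box(s_cnt, R) - box(s_cnt, r) -
    (rowseg(rc_cnt, R) - rowseg(rc_cnt, r)) -
    (colseg(cc_cnt, R) - colseg(cc_cnt, r))

  ok <- donut_cnt > 0
  local_bg <- ifelse(ok, donut_sum / pmax(donut_cnt, 1), NA_real_)
  fold <- oe[cand] / local_bg

  # Poisson tail on raw counts integrated over the focal footprint (a
  # 3x3 box -- spots spread over a few pixels, single-pixel shot noise
  # does not): expected = donut O/E background times the genome-wide
  # raw expectation summed over the box distances.  BH runs over
  # *every* pixel of the distance band -- restricting the test pool to
  # pixels that already look enriched would bias the FDR.
  expd_raw <- diagonal_means(m$counts)
  s_raw <- sat(m$counts)
  obs_box <- sat_box(s_raw, clamp(i - 1L), clamp(i + 1L),
                     clamp(j - 1L), clamp(j + 1L))
  dgap <- j - i
  wts <- c(1, 2, 3, 2, 1)
  lam_unit <- rep(0, length(dgap))
  for (t in -2:2) {
    dd <- dgap + t
    v <- ifelse(dd >= 1 & dd <= length(expd_raw) - 1L, expd_raw[pmax(dd, 1) + 1L], 0)
    lam_unit <- lam_unit + wts[t + 3L] * v
  }
  lambda <- pmax(local_bg, 0) * lam_unit
  lambda_c <- pmax(local_bg, 0) * expd_raw[dgap + 1L]
  obs <- m$counts[cbind(i, j)]
  # a call must clear the FDR on both the integrated footprint and the
  # centre pixel alone: footprint kills single-pixel shot noise, centre
  # kills diffuse box-level fluctuations
  p_box <- ifelse(obs_box <= 0 | !ok, 1,
                  pgamma(lambda, shape = obs_box, lower.tail = TRUE))
  p_ctr <- ifelse(obs <= 0 | !ok, 1,
                  pgamma(lambda_c, shape = obs, lower.tail = TRUE))
  q <- pmax(p.adjust(p_box, method = "BH"), p.adjust(p_ctr, method = "BH"))
  p <- pmax(p_box, p_ctr)

  sig <- which(q <= fdr & is.finite(fold) & fold > fold_min)
  if (length(sig) == 0) return(empty_loop_calls(bs))
  i <- i[sig]; j <- j[sig]; fold <- fold[sig]; local_bg <- local_bg[sig]
  obs <- obs[sig]; p <- p[sig]; q <- q[sig]

  # greedy merge: strongest O/E first, suppress neighbours
  strength <- oe[cbind(i, j)]
  ord <- order(-strength, i, j)
  keep <- logical(length(ord))
  taken_i <- integer(0); taken_j <- integer(0)
  for (idx in ord) {
    if (length(taken_i) == 0 ||
        all(pmax(abs(taken_i - i[idx]), abs(taken_j - j[idx])) > merge_radius)) {
      keep[idx] <- TRUE
      taken_i <- c(taken_i, i[idx]); taken_j <- c(taken_j, j[idx])
    }
  }

  out <- tibble::tibble(
    bin_i = i[keep], bin_j = j[keep],
    a5 = (i[keep] - 0.5) * bs, a3 = (j[keep] - 0.5) * bs,
    observed = obs[keep], local_expected = local_bg[keep],
    fold = fold[keep], p_value = p[keep], q_value = q[keep])
  out <- dplyr::arrange(out, .data$bin_i, .data$bin_j)
  structure(out, bin_size = bs,
            class = c("loop_calls", "tbl_df", "tbl", "data.frame"))
}

empty_loop_calls <- function(bin_size) {
  structure(tibble::tibble(
    bin_i = integer(), bin_j = integer(), a5 = numeric(), a3 = numeric(),
    observed = numeric(), local_expected = numeric(), fold = numeric(),
    p_value = numeric(), q_value = numeric()),
    bin_size = bin_size,
    class = c("loop_calls", "tbl_df", "tbl", "data.frame"))
}

#' Loops per anchor
#'
#' Clusters loop anchors that fall within `tol` bins of each other and
#' counts, for every anchor, how many distinct partners it pairs with in
#' the rightward direction.  Returns the percentage histogram of those
#' counts -- the statistic that increases when loop expansion produces
#' distal pairings.
#'
#' @param calls A `loop_calls` tibble.
#' @param tol Anchor clustering tolerance, bins.
#' @return Tibble with `partners`, `n_anchors`, `percent`; attribute
#'   `mean_partners`.
#' @export
loops_per_anchor <- function(calls, tol = 2L) {
  if (nrow(calls) == 0) {
    return(structure(tibble::tibble(partners = integer(),
                                    n_anchors = integer(),
                                    percent = numeric()),
                     mean_partners = NA_real_))
  }
  bins <- sort(unique(c(calls$bin_i, calls$bin_j)))
  cl <- cumsum(c(1L, diff(bins) > tol))
  cluster_of <- setNames(cl, bins)
  li <- cluster_of[as.character(calls$bin_i)]
  ri <- cluster_of[as.character(calls$bin_j)]
  per <- tapply(ri, li, function(x) length(unique(x)))
  tab <- table(per)
  structure(tibble::tibble(
    partners = as.integer(names(tab)),
    n_anchors = as.integer(tab),
    percent = 100 * as.integer(tab) / sum(tab)),
    mean_partners = mean(per))
}

#' Compare loop sizes with adjacent-peak intervals
#'
#' Histograms the base-pair spans of called loops and of adjacent ChIP
#' peak intervals on a common 0-40 kb grid and reports both medians.
#' When loops form predominantly between adjacent CARs the two
#' distributions coincide.
#'
#' @param calls A `loop_calls` tibble.
#' @param peaks A `peak_set` or `car_map`.
#' @param breaks Histogram break points, bp.
#' @return List with `hist` (tibble `bin_lo`, `bin_hi`, `loop_prob`,
#'   `interval_prob`), `median_loop`, `median_interval`.
#' @export
loop_size_vs_interval <- function(calls, peaks,
                                  breaks = seq(0, 40000, by = 2000)) {
  summits <- peak_coords(peaks)
  spans <- calls$a3 - calls$a5
  intervals <- diff(summits)
  histo <- function(v) {
    h <- tabulate(findInterval(v[v >= breaks[1] & v < max(breaks)], breaks),
                  nbins = length(breaks) - 1L)
    if (sum(h) == 0) rep(0, length(h)) else h / sum(h)
  }
  list(hist = tibble::tibble(bin_lo = breaks[-length(breaks)],
                             bin_hi = breaks[-1],
                             loop_prob = histo(spans),
                             interval_prob = histo(intervals)),
       median_loop = if (length(spans)) median(spans) else NA_real_,
       median_interval = if (length(intervals)) median(intervals) else NA_real_)
}

#' Fraction of loop anchors that overlap a ChIP peak
#'
#' The anchor/CAR colocalisation statistic: the fraction of distinct
#' loop-anchor positions with a peak summit within `tol` (anchors and
#' peaks are both confined within ~1 kb in the data this emulates).
#'
#' @param calls A `loop_calls` tibble.
#' @param peaks A `peak_set`, `car_map` or numeric summit vector.
#' @param tol Matching tolerance, bp.
#' @return The overlapping fraction (0 when there are no peaks);
#'   attribute `n_anchors`.
#' @export
anchor_overlap <- function(calls, peaks, tol = 1000) {
  anchors <- unique(c(calls$a5, calls$a3))
  if (length(anchors) == 0) return(structure(NA_real_, n_anchors = 0L))
  summits <- tryCatch(peak_coords(peaks), error = function(e) numeric(0))
  if (length(summits) == 0) return(structure(0, n_anchors = length(anchors)))
  hit <- vapply(anchors, function(a) min(abs(summits - a)) <= tol, logical(1))
  structure(mean(hit), n_anchors = length(anchors))
}
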