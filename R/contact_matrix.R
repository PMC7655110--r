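# Contact-matrix container and balancing / normalisation transforms.

#' Construct a contact matrix
#'
#' Thin S3 wrapper around a dense symmetric count matrix with its bin
#' size and chromosome metadata.  Balancing weights (from
#' [ice_balance()]) are stored alongside; `NA` weights mark masked bins.
#'
#' @param counts Symmetric non-negative square matrix.
#' @param bin_size Bin size in bp.
#' @param chrom_length Chromosome length in bp; defaults to
#'   `nrow(counts) * bin_size`.
#' @param chrom_name Chromosome label.
#' @param weights Optional per-bin balancing weights.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(counts, bin_size,
                           chrom_length = nrow(counts) * bin_size,
                           chrom_name = "chrSim",
                           weights = NULL) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    abort("`counts` must be a square matrix")
  }
  if (any(counts < 0, na.rm = TRUE)) abort("contact counts must be >= 0")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8 * (1 + max(abs(counts)))) {
    abort("`counts` must be symmetric")
  }
  if (nrow(counts) != ceiling(chrom_length / bin_size)) {
    abort("`counts` dimension does not match ceiling(chrom_length / bin_size)")
  }
  structure(list(counts = counts,
                 bin_size = bin_size,
                 n_bins = nrow(counts),
                 chrom_length = chrom_length,
                 chrom_name = chrom_name,
                 weights = weights),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("# Contact matrix: %d x %d bins of %d bp on %s (%s contacts)%s\n",
              x$n_bins, x$n_bins, x$bin_size, x$chrom_name,
              format(round(sum(x$counts)), big.mark = ","),
              if (is.null(x$weights)) "" else ", balanced"))
  invisible(x)
}

#' Coarsen a contact matrix to a larger bin size
#'
#' Sums counts into bins of `new_bin_size`, which must be a multiple of
#' the current bin size.  Balancing weights are dropped (re-balance
#' after rebinning).
#'
#' @param m A `contact_matrix`.
#' @param new_bin_size Target bin size, a multiple of `m$bin_size`.
#' @return A `contact_matrix` at the coarser resolution.
#' @export
rebin <- function(m, new_bin_size) {
  if (new_bin_size %% m$bin_size != 0) {
    abort("`new_bin_size` must be a multiple of the current bin size")
  }
  f <- new_bin_size / m$bin_size
  if (f == 1) return(m)
  grp <- (seq_len(m$n_bins) - 1L) %/% f + 1L
  agg <- rowsum(m$counts, grp)
  agg <- t(rowsum(t(agg), grp))
  contact_matrix(agg, new_bin_size, chrom_length = m$chrom_length,
                 chrom_name = m$chrom_name)
}

#' Iterative-correction (ICE) balancing
#'
#' Computes multiplicative per-bin weights such that the row sums of the
#' weighted matrix `W[i] * counts[i, j] * W[j]` are equal over unmasked
#' bins, by the standard iterative-correction fixed point.  Bins whose
#' raw coverage falls below the `mask_low_coverage` quantile of nonzero
#' coverage (plus all-zero bins) are masked and receive `NA` weights.
#'
#' @param m A `contact_matrix`.
#' @param tol Convergence tolerance on the maximum relative row-sum
#'   deviation.
#' @param max_iter Iteration cap; non-convergence raises a warning that
#'   reports the iteration count.
#' @param mask_low_coverage Quantile of nonzero coverage below which a
#'   bin is masked.
#' @return The `contact_matrix` with `weights` set (normalised so the
#'   mean unmasked weight is 1).
#' @export
ice_balance <- function(m, tol = 1e-8, max_iter = 200L,
                        mask_low_coverage = 0.02) {
  cov <- rowSums(m$counts)
  if (all(cov == 0)) abort("cannot balance an all-zero matrix")
  thresh <- quantile(cov[cov > 0], mask_low_coverage)
  mask <- cov == 0 | cov < thresh
  keep <- which(!mask)

  a <- m$counts[keep, keep, drop = FALSE]
  b <- rep(1, length(keep))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.vector(a %*% b) * b
    s_rel <- s / mean(s)
    if (max(abs(s_rel - 1)) < tol) { converged <- TRUE; break }
    b <- b / sqrt(s_rel)
  }
  if (!converged) {
    warn(sprintf("ICE balancing did not converge in %d iterations", max_iter))
  }
  w <- rep(NA_real_, m$n_bins)
  w[keep] <- b / mean(b)
  m$weights <- w
  m
}

#' Balanced counts of a contact matrix
#'
#' Applies the stored ICE weights; masked bins become `NA` rows/columns.
#'
#' @param m A balanced `contact_matrix`.
#' @return A numeric matrix of balanced contacts.
#' @export
balanced_counts <- function(m) {
  if (is.null(m$weights)) abort("matrix has no balancing weights; run ice_balance() first")
  w <- m$weights
  m$counts * outer(w, w)
}

#' Observed-over-expected transform
#'
#' Divides every entry of the (balanced, if weights are present)
#' contact matrix by the mean of its diagonal -- the expected contact at
#' that genomic distance.  Diagonals whose mean is zero or undefined
#' are masked (`NA`).
#'
#' @param m A `contact_matrix`; balanced counts are used when weights
#'   are available, raw counts otherwise.
#' @return A numeric matrix of distance-normalised values.
#' @export
observed_over_expected <- function(m) {
  x <- if (is.null(m$weights)) m$counts else balanced_counts(m)
  expd <- diagonal_means(x)
  d <- abs(row(x) - col(x)) + 1L
  denom <- expd[d]
  out <- x / denom
  out[!is.finite(out)] <- NA_real_
  out[denom == 0 | is.na(denom)] <- NA_real_
  dim(out) <- dim(x)
  out
}
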