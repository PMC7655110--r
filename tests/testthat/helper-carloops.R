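# Shared fixture builders; everything is generated in code.

# A small deterministic CAR map with evenly spaced CARs.
even_car_map <- function(n_cars = 20, spacing = 8000, occupancy = 0.5,
                         chrom_pad = 10000, centromere = NULL) {
  pos <- chrom_pad + spacing * (seq_len(n_cars) - 1L)
  chrom_length <- max(pos) + chrom_pad
  occ <- rep_len(occupancy, n_cars)
  cen_idx <- NA_integer_
  if (!is.null(centromere)) {
    cen_idx <- which.min(abs(pos - centromere))
    occ[cen_idx] <- max(occ)
  }
  carloops:::new_car_map(
    tibble::tibble(car = seq_len(n_cars), pos = as.numeric(pos),
                   occupancy = occ, high_residency = FALSE,
                   centromere = seq_len(n_cars) == cen_idx & !is.na(cen_idx)),
    "chrTest", chrom_length, cen_idx)
}

# Occupancy state vector without sampling.
fixed_state <- function(pattern) {
  structure(as.logical(pattern), cell_id = 1L)
}

# Contact matrix from a raw symmetric matrix.
cm_from <- function(counts, bin_size = 1000) {
  contact_matrix(counts, bin_size)
}

# Random symmetric positive matrix.
random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n, 0.5, 2), n, n)
  (a + t(a)) / 2
}

# Independent loop-formation oracle: consecutive occupied CARs via rle
# bookkeeping rather than index pairing.
oracle_consecutive_loops <- function(state) {
  occ <- which(state)
  if (length(occ) < 2) return(matrix(numeric(0), ncol = 2))
  out <- NULL
  prev <- NULL
  for (i in seq_along(state)) {
    if (state[i]) {
      if (!is.null(prev)) out <- rbind(out, c(prev, i))
      prev <- i
    }
  }
  out
}

# Brute-force pile-up: naive double loop over pairs and window pixels.
oracle_pileup <- function(x, pairs_bins, hw) {
  side <- 2 * hw + 1
  acc <- matrix(0, side, side)
  k <- 0
  for (r in seq_len(nrow(pairs_bins))) {
    bi <- pairs_bins[r, 1]; bj <- pairs_bins[r, 2]
    win <- matrix(NA_real_, side, side)
    for (a in -hw:hw) for (b in -hw:hw) {
      win[a + hw + 1, b + hw + 1] <- x[bi + a, bj + b]
    }
    acc <- acc + win
    k <- k + 1
  }
  acc / k
}

# Hand-indexed centre/corner ratio.
oracle_enrichment <- function(mat, cs) {
  side <- nrow(mat)
  ctr <- mat[(side + 1) / 2, (side + 1) / 2]
  corners <- c(mat[1:cs, 1:cs], mat[1:cs, (side - cs + 1):side],
               mat[(side - cs + 1):side, 1:cs],
               mat[(side - cs + 1):side, (side - cs + 1):side])
  ctr / mean(corners)
}
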