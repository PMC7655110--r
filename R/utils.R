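# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a base seed and a stage/cell offset,
# kept strictly below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + as.double(offset) * 16807) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the state alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Running mean with odd window `w` (bins); edges use shrinking windows.
running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Mean of each diagonal |i-j| = d of a square matrix, d = 0..n-1.
# Returns a vector indexed by d + 1. NA entries are dropped from the mean.
diagonal_means <- function(m) {
  n <- nrow(m)
  d <- abs(row(m) - col(m))
  sums <- rowsum(as.vector(ifelse(is.na(m), 0, m)), as.vector(d))
  cnts <- rowsum(as.vector(!is.na(m)) * 1, as.vector(d))
  out <- as.vector(sums / pmax(cnts, 1))
  out[cnts == 0] <- NA_real_
  out
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
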