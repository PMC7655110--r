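#' Sample a per-cell cohesin occupancy state
#'
#' Each CAR is occupied independently with its occupancy probability.
#' The draw is reproducible given `(seed, cell_id)`: the two are folded
#' into a single sub-seed, so individual cells of a population can be
#' regenerated in isolation.
#'
#' @param map A `car_map`.
#' @param cell_id Integer cell index (>= 1).
#' @param seed Integer base seed.
#' @return Logical vector of length `nrow(map)` with attribute `cell_id`.
#' @export
sample_occupancy <- function(map, cell_id = 1L, seed = 1L) {
  validate_car_map(map)
  occ <- with_seed(derive_seed(seed, cell_id),
                  runif(nrow(map)) < map$occupancy)
  structure(occ, cell_id = as.integer(cell_id))
}

#' Form positioned loops between consecutive occupied CARs
#'
#' The core verbal model: extruding cohesin stops at the first occupied
#' CAR on either side, so in a given cell one positioned loop forms
#' between every pair of *consecutive* occupied CARs -- a loop spans k
#' CAR intervals exactly when its two endpoint CARs are occupied and the
#' k-1 CARs between them are not.
#'
#' @param state Logical occupancy vector from [sample_occupancy()].
#' @param map The parent `car_map`.
#' @return A `cell_loops` tibble: `left_anchor`, `right_anchor` (bp),
#'   `left_positioned`, `right_positioned` (all `TRUE` here),
#'   `left_car`, `right_car` (CAR indices).
#' @export
form_loops_consecutive <- function(state, map) {
  idx <- which(state)
  if (length(idx) < 2L) return(empty_cell_loops())
  li <- idx[-length(idx)]
  ri <- idx[-1]
  new_cell_loops(map$pos[li], map$pos[ri], TRUE, TRUE, li, ri)
}

empty_cell_loops <- function() {
  new_cell_loops(numeric(0), numeric(0), logical(0), logical(0),
                 integer(0), integer(0))
}

new_cell_loops <- function(la, ra, lp, rp, lc, rc) {
  structure(tibble::tibble(
    left_anchor = la, right_anchor = ra,
    left_positioned = rep_len(lp, length(la)),
    right_positioned = rep_len(rp, length(la)),
    left_car = rep_len(lc, length(la)),
    right_car = rep_len(rc, length(la))),
    class = c("cell_loops", "tbl_df", "tbl", "data.frame"))
}

#' Extrude loops in one cell with explicit extruders
#'
#' An alternative, mechanistic loop-formation mode.  `n_extruders`
#' cohesins load at uniform random positions and grow a loop
#' symmetrically; each side halts permanently when it reaches an
#' occupied CAR, and growth stops once the total extruded length
#' reaches `processivity` (or both sides have halted).  An anchor is
#' *positioned* when it sits at an occupied CAR, otherwise it is an
#' unpositioned anchor at the coordinate reached.  Extruders act
#' independently: no extruder-extruder collisions, and unoccupied CARs
#' do not impede them.
#'
#' @param state Logical occupancy vector.
#' @param map The parent `car_map`.
#' @param n_extruders Number of extruders loaded in this cell.
#' @param processivity Total extrudable length per extruder, bp.
#' @param seed Integer seed for the load positions.
#' @return A `cell_loops` tibble (degenerate zero-span loops from
#'   extruders that could not grow are dropped).
#' @export
extrude_cell <- function(state, map, n_extruders, processivity, seed = 1L) {
  if (n_extruders <= 0) return(empty_cell_loops())
  stopifnot_scalar_number(processivity, "processivity", lower = 1)
  chrom_length <- attr(map, "chrom_length")
  occ_pos <- map$pos[state]
  occ_idx <- which(state)

  loads <- with_seed(seed, runif(n_extruders, 0, chrom_length))

  # distance to nearest occupied CAR left/right of each load point
  k <- findInterval(loads, occ_pos)
  dl <- ifelse(k >= 1, loads - occ_pos[pmax(k, 1L)], Inf)
  dr <- ifelse(k < length(occ_pos), occ_pos[pmin(k + 1L, length(occ_pos))] - loads, Inf)

  L <- processivity
  dmin <- pmin(dl, dr)
  dmax <- pmax(dl, dr)
  near_left <- dl <= dr  # the nearer occupied CAR is on the left

  # symmetric growth: both sides grow at the same rate; after the first
  # halt (2*dmin consumed) the free side takes the remaining budget
  both_free <- 2 * dmin >= L        # budget exhausted before any halt
  ext_near <- ifelse(both_free, L / 2, dmin)
  ext_far <- ifelse(both_free, L / 2, pmin(dmax, dmin + (L - 2 * dmin)))
  near_positioned <- !both_free
  far_positioned <- !both_free & (ext_far >= dmax)

  left_ext <- ifelse(near_left, ext_near, ext_far)
  right_ext <- ifelse(near_left, ext_far, ext_near)
  lp <- ifelse(near_left, near_positioned, far_positioned)
  rp <- ifelse(near_left, far_positioned, near_positioned)

  la <- pmax(loads - left_ext, 0)
  ra <- pmin(loads + right_ext, chrom_length - 1)

  lc <- rep(NA_integer_, n_extruders)
  rc <- rep(NA_integer_, n_extruders)
  lc[lp] <- occ_idx[k[lp]]
  rc[rp] <- occ_idx[k[rp] + 1L]

  keep <- ra - la >= 1
  new_cell_loops(la[keep], ra[keep], lp[keep], rp[keep], lc[keep], rc[keep])
}

#' Simulate a population of cells and aggregate their loops
#'
#' Runs per-cell occupancy sampling and loop formation for `n_cells`
#' cells and aggregates positioned loops (both anchors at occupied
#' CARs) into a loop -> frequency table; loops with at least one
#' unpositioned anchor (extruder mode only) are kept as individual
#' records.  Deterministic given `seed`.
#'
#' @param map A `car_map`.
#' @param n_cells Number of cells (>= 1).
#' @param mode `"consecutive"` (default) or `"extruder"`.
#' @param n_extruders Extruders per cell (extruder mode); default one
#'   per 30 kb of chromosome.
#' @param processivity Extruder processivity in bp (extruder mode).
#' @param seed Integer seed.
#' @return A `population_loops` object: list with `loops` (tibble
#'   `left_car`, `right_car`, `left_pos`, `right_pos`, `n`,
#'   `frequency`), `unpositioned` (tibble of loop records with
#'   coordinates, positioned flags and `cell`), `n_cells`, `mode`.
#' @export
simulate_population <- function(map,
                                n_cells,
                                mode = c("consecutive", "extruder"),
                                n_extruders = NULL,
                                processivity = 30000,
                                seed = 1L) {
  validate_car_map(map)
  mode <- match.arg(mode)
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  n_cars <- nrow(map)
  chrom_length <- attr(map, "chrom_length")
  if (is.null(n_extruders)) n_extruders <- max(1L, round(chrom_length / 30000))

  pair_l <- vector("list", n_cells)
  unpos <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    state <- sample_occupancy(map, cell, seed)
    if (mode == "consecutive") {
      # same pairing rule as form_loops_consecutive(), without the
      # per-cell tibble overhead (this loop runs tens of thousands of
      # times at population scale)
      idx <- which(state)
      if (length(idx) >= 2L) {
        pair_l[[cell]] <- (n_cars + 1) * idx[-length(idx)] + idx[-1]
      }
    } else {
      loops <- extrude_cell(state, map, n_extruders, processivity,
                            seed = derive_seed(seed, 500000L + cell))
      if (nrow(loops) == 0) next
      pos <- loops$left_positioned & loops$right_positioned
      if (any(pos)) {
        pair_l[[cell]] <- (n_cars + 1) * loops$left_car[pos] + loops$right_car[pos]
      }
      if (any(!pos)) {
        u <- loops[!pos, ]
        u$cell <- cell
        unpos[[cell]] <- u
      }
    }
  }

  keys <- unlist(pair_l)
  if (length(keys) > 0) {
    tab <- table(keys)
    key <- as.numeric(names(tab))
    lc <- as.integer(key %/% (n_cars + 1))
    rc <- as.integer(key %% (n_cars + 1))
    loops <- tibble::tibble(
      left_car = lc, right_car = rc,
      left_pos = map$pos[lc], right_pos = map$pos[rc],
      n = as.integer(tab),
      frequency = as.integer(tab) / n_cells)
    loops <- dplyr::arrange(loops, .data$left_car, .data$right_car)
  } else {
    loops <- tibble::tibble(left_car = integer(), right_car = integer(),
                            left_pos = numeric(), right_pos = numeric(),
                            n = integer(), frequency = numeric())
  }

  structure(list(
    loops = loops,
    unpositioned = if (length(unpos)) dplyr::bind_rows(unpos)
                   else dplyr::mutate(empty_cell_loops(), cell = integer(0)),
    n_cells = n_cells,
    mode = mode,
    chrom_name = attr(map, "chrom_name"),
    chrom_length = chrom_length),
    class = "population_loops")
}

#' @export
print.population_loops <- function(x, ...) {
  cat(sprintf(
    "# Population loops: %d distinct positioned loops over %d cells (%s mode), %d unpositioned records\n",
    nrow(x$loops), x$n_cells, x$mode, nrow(x$unpositioned)))
  print(x$loops, ...)
  invisible(x)
}

#' Span distribution of a loop population
#'
#' Tabulates positioned loops by their span in CAR intervals (k = 1 for
#' adjacent CARs, k = 2 for loops skipping one CAR, ...), weighting each
#' distinct loop by its population count, and reports base-pair span
#' quantiles alongside.
#'
#' @param pop A `population_loops` object.
#' @param map The parent `car_map` (unused beyond validation; spans are
#'   taken from the loop table).
#' @return Tibble with `k`, `n`, `prob` (normalised over observed k) and
#'   attributes `bp_quantiles` (named vector) and `mean_span`.
#' @export
span_histogram <- function(pop, map = NULL) {
  loops <- pop$loops
  if (nrow(loops) == 0) {
    return(structure(tibble::tibble(k = integer(), n = integer(),
                                    prob = numeric()),
                     bp_quantiles = setNames(numeric(0), character(0)),
                     mean_span = NA_real_))
  }
  k <- loops$right_car - loops$left_car
  bp <- loops$right_pos - loops$left_pos
  tab <- rowsum(loops$n, k)
  ks <- as.integer(rownames(tab))
  n <- as.integer(tab)
  structure(tibble::tibble(k = ks, n = n, prob = n / sum(n)),
            bp_quantiles = quantile(rep(bp, loops$n), c(0.25, 0.5, 0.75)),
            mean_span = sum(ks * n) / sum(n))
}
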