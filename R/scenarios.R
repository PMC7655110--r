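#' Named depletion scenarios
#'
#' Each scenario encodes, as a transform of per-CAR occupancy (plus an
#' extruder-processivity override), the loop-pattern phenotype of one
#' protein depletion:
#'
#' * `WT` -- identity.
#' * `MCD1` -- cohesin core depleted: all occupancy 0, no positioned
#'   loops.
#' * `BRN1` -- condensin depleted: loops unaffected, identity.
#' * `WPL1` -- cohesin at CARs roughly halved, which lowers per-cell
#'   occupancy and lets loops expand further: occupancy x 0.5.
#' * `PDS5` -- cohesin lost from chromosome arms but retained near the
#'   centromere: occupancy x 0.05 beyond `pericentric_radius` of the
#'   centromere, x 0.7 within it, centromeric CAR untouched; extruder
#'   processivity raised tenfold so loops emanate from the centromere
#'   over long distances (the stripe phenotype).
#'
#' @param name One of `"WT"`, `"MCD1"`, `"BRN1"`, `"WPL1"`, `"PDS5"`.
#' @param pericentric_radius Distance from the centromere (bp) within
#'   which a CAR counts as pericentric in the PDS5 scenario.
#' @return A `scenario` object (list with `name`, `transform`,
#'   `processivity_scale`, `pericentric_radius`).
#' @export
scenario <- function(name = c("WT", "MCD1", "BRN1", "WPL1", "PDS5"),
                     pericentric_radius = 30000) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("WT", "MCD1", "BRN1", "WPL1", "PDS5")) {
    abort("unknown scenario; expected one of WT, MCD1, BRN1, WPL1, PDS5")
  }
  structure(list(name = name,
                 processivity_scale = if (name == "PDS5") 10 else 1,
                 pericentric_radius = pericentric_radius),
            class = "scenario")
}

#' Apply a depletion scenario to a CAR map
#'
#' Returns a new `car_map` with occupancies transformed according to the
#' scenario (see [scenario()]).  The PDS5 scenario requires a map with a
#' centromere.  The scenario's `processivity_scale` is attached to the
#' returned map as attribute `processivity_scale` so that downstream
#' extruder-mode simulation can honour it.
#'
#' @param map A `car_map`.
#' @param scen A `scenario` object or scenario name.
#' @return The transformed `car_map`.
#' @export
apply_scenario <- function(map, scen) {
  validate_car_map(map)
  if (is.character(scen)) scen <- scenario(scen)
  if (!inherits(scen, "scenario")) abort("`scen` must be a scenario")
  occ <- map$occupancy
  occ_new <- switch(scen$name,
    WT = occ,
    BRN1 = occ,
    MCD1 = rep(0, length(occ)),
    WPL1 = occ * 0.5,
    PDS5 = {
      cen <- attr(map, "centromere_index")
      if (is.na(cen %||% NA_integer_)) {
        abort("the PDS5 scenario needs a map with a centromere")
      }
      d <- abs(map$pos - map$pos[cen])
      out <- ifelse(d > scen$pericentric_radius, occ * 0.05, occ * 0.7)
      out[cen] <- occ[cen]
      out
    })
  map$occupancy <- occ_new
  attr(map, "processivity_scale") <- scen$processivity_scale
  attr(map, "scenario") <- scen$name
  map
}
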