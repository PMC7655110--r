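#' Default run configuration for the scenario pipeline
#'
#' Collects every tunable of the end-to-end pipeline with a desk-scale
#' default: a 750 kb chromosome carrying 90 CARs (median spacing 8 kb)
#' with a mid-chromosome centromere, 3,000 cells, 200 bp rendering
#' bins.  A serialised config plus the seed fully reproduces a run.
#'
#' @param scenario_name Scenario preset (see [scenario()]).
#' @param n_cars,chrom_length,spacing_median,centromere Genome model
#'   parameters (bp).
#' @param n_cells,mode Simulation parameters.
#' @param bin_size,render Render resolution (bp) and a
#'   [render_params()] list.
#' @param insulation_res,insulation_window Insulation settings, bp.
#' @param seed Integer master seed; stage seeds are derived from it by
#'   fixed offsets.
#' @param out_dir Output directory for standard-format files, or `NULL`
#'   to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario_name = "WT",
                       n_cars = 90,
                       chrom_length = 750000,
                       spacing_median = 8000,
                       centromere = 375000,
                       n_cells = 3000,
                       mode = "consecutive",
                       bin_size = 200,
                       render = render_params(),
                       insulation_res = 2000,
                       insulation_window = 15000,
                       seed = 1L,
                       out_dir = NULL) {
  structure(list(scenario_name = scenario_name, n_cars = n_cars,
                 chrom_length = chrom_length, spacing_median = spacing_median,
                 centromere = centromere, n_cells = n_cells, mode = mode,
                 bin_size = bin_size, render = render,
                 insulation_res = insulation_res,
                 insulation_window = insulation_window,
                 seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full scenario pipeline
#'
#' Wires the whole analysis together: build the CAR map, apply the
#' scenario transform, simulate the cell population, render and balance
#' the contact map, then compute the decay curve, the CAR-interval
#' pile-up series, loop calls with per-anchor and size statistics, the
#' insulation profile, and the boundary/CAR overlap.  When
#' `config$out_dir` is set, the standard-format files (BED, BEDPE,
#' bedGraph, matrix TSV, summary JSON) are written there.
#'
#' @param config A [run_config()] list.
#' @return A `scenario_report`: list with `scenario`, `map`, `pop`,
#'   `matrix`, `n_called_loops`, `calls`, `loops_per_anchor`,
#'   `size_vs_interval`, `interval_series`, `decay`, `insulation`,
#'   `boundary_car_overlap`, `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  seed <- config$seed

  map <- stage("build_car_map", {
    m <- build_car_map(config$n_cars, config$chrom_length,
                       spacing_median = config$spacing_median,
                       centromere = config$centromere,
                       seed = derive_seed(seed, 1L))
    classify_high_residency(m)
  })
  scen <- scenario(config$scenario_name)
  map_s <- stage("apply_scenario", apply_scenario(map, scen))

  pop <- stage("simulate_population", simulate_population(
    map_s, config$n_cells, mode = config$mode,
    processivity = 30000 * (attr(map_s, "processivity_scale") %||% 1),
    seed = derive_seed(seed, 2L)))

  rp <- config$render
  rp$seed <- derive_seed(seed, 3L)
  m <- stage("render_map", render_map(pop, map_s, rp, bin_size = config$bin_size))
  m <- stage("ice_balance", ice_balance(m))

  decay <- stage("contact_decay",
                 contact_decay(m, range = c(100, config$chrom_length)))
  # corner submatrices cover the same genomic area at any resolution
  corner <- max(2L, round(14L * 200 / config$bin_size))
  series <- stage("interval_pileup_series",
                  interval_pileup_series(m, map, k_range = 1:10,
                                         corner_size = corner))
  calls <- stage("call_loops", call_loops(m))
  lpa <- loops_per_anchor(calls)
  svi <- loop_size_vs_interval(calls, map)
  ins <- stage("insulation", insulation(m, config$insulation_res,
                                        config$insulation_window))

  bc_overlap <- if (nrow(ins$boundaries) > 0) {
    mean(vapply(ins$boundaries$pos,
                function(b) min(abs(map$pos - b)) <= 2000, logical(1)))
  } else NA_real_

  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_car_map(map_s, p("car_map.bed"))
    write_bedpe(pop, p("loops.bedpe"))
    write_matrix_tsv(m, p("contacts.tsv"))
    utils::write.table(decay, p("decay.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(series[, c("k", "n_pairs", "ratio")]),
                       p("interval_series.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(as.data.frame(calls), p("loop_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ins$scores), p("insulation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(scenario = config$scenario_name, seed = seed,
           n_called_loops = nrow(calls),
           boundary_car_overlap = bc_overlap,
           median_loop = svi$median_loop,
           median_interval = svi$median_interval),
      p("report.json"), auto_unbox = TRUE, digits = NA, null = "null")
    files <- list.files(config$out_dir, full.names = TRUE)
  }

  structure(list(scenario = config$scenario_name,
                 map = map_s, pop = pop, matrix = m,
                 n_called_loops = nrow(calls), calls = calls,
                 loops_per_anchor = lpa, size_vs_interval = svi,
                 interval_series = series, decay = decay,
                 insulation = ins, boundary_car_overlap = bc_overlap,
                 files = files, config = config),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("# Scenario %s: %d called loops, boundary/CAR overlap %s\n",
              x$scenario, x$n_called_loops,
              ifelse(is.na(x$boundary_car_overlap), "NA",
                     sprintf("%.2f", x$boundary_car_overlap))))
  invisible(x)
}
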