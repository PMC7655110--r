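# Plain-text interchange: BED, BEDPE, bedGraph, dense matrix TSV.
# All coordinates are 0-based, half-open.

check_intervals <- function(start, end, what) {
  bad <- which(end < start)
  if (length(bad)) {
    abort(sprintf("%s: end < start on line %d", what, bad[1]))
  }
}

#' Write / read a CAR map as BED plus a JSON sidecar
#'
#' The BED records each CAR as a 1 kb interval centred on the CAR
#' (`score = round(1000 * occupancy)`); exact occupancies, the
#' centromere index, high-residency flags and chromosome length go to a
#' JSON sidecar `<path>.meta.json` so the round trip is lossless.
#'
#' @param map A `car_map`.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_car_map <- function(map, path) {
  validate_car_map(map)
  df <- data.frame(chrom = attr(map, "chrom_name"),
                   start = pmax(map$pos - 500, 0),
                   end = map$pos + 500,
                   name = sprintf("CAR%04d", map$car),
                   score = round(1000 * map$occupancy))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  meta <- list(chrom_name = attr(map, "chrom_name"),
               chrom_length = attr(map, "chrom_length"),
               centromere_index = attr(map, "centromere_index"),
               pos = map$pos,
               occupancy = map$occupancy,
               high_residency = map$high_residency)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_car_map
#' @param path Path written by [write_car_map()].
#' @export
read_car_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  n <- length(meta$pos)
  cen <- meta$centromere_index
  cen <- if (is.null(cen) || length(cen) == 0) NA_integer_ else as.integer(cen)
  new_car_map(tibble::tibble(
    car = seq_len(n),
    pos = as.numeric(meta$pos),
    occupancy = as.numeric(meta$occupancy),
    high_residency = as.logical(meta$high_residency),
    centromere = seq_len(n) == cen & !is.na(cen)),
    meta$chrom_name, meta$chrom_length, cen)
}

#' Write / read population loops as BEDPE
#'
#' Positioned loops are written with 1 kb anchor windows and
#' `score = frequency`.  Reading returns a tibble (not a full
#' `population_loops`): `chrom`, anchor intervals, `name`, `frequency`.
#'
#' @param pop A `population_loops` object.
#' @param path Output BEDPE path.
#' @export
write_bedpe <- function(pop, path) {
  l <- pop$loops
  df <- data.frame(chrom1 = pop$chrom_name,
                   start1 = pmax(l$left_pos - 500, 0), end1 = l$left_pos + 500,
                   chrom2 = pop$chrom_name,
                   start2 = pmax(l$right_pos - 500, 0), end2 = l$right_pos + 500,
                   name = sprintf("loop_%d_%d", l$left_car, l$right_car),
                   score = l$frequency)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom1", "start1", "end1",
                                        "chrom2", "start2", "end2",
                                        "name", "score"))
  check_intervals(df$start1, df$end1, "BEDPE anchor 1")
  check_intervals(df$start2, df$end2, "BEDPE anchor 2")
  tibble::as_tibble(df)
}

#' Write / read a ChIP track as bedGraph
#'
#' @param track A `chip_track`.
#' @param path Output bedGraph path.
#' @export
write_bedgraph <- function(track, path) {
  df <- data.frame(chrom = attr(track, "chrom_name") %||% "chrSim",
                   start = track$start, end = track$end,
                   score = track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  check_intervals(df$start, df$end, "bedGraph")
  bin_size <- df$end[1] - df$start[1]
  structure(tibble::tibble(bin = seq_len(nrow(df)) - 1L,
                           start = df$start, end = df$end, score = df$score),
            bin_size = bin_size,
            chrom_length = max(df$end),
            chrom_name = df$chrom[1],
            class = c("chip_track", "tbl_df", "tbl", "data.frame"))
}

#' Write / read a contact matrix as a dense TSV
#'
#' Header comment lines carry the chromosome name, length and bin size;
#' the body is the dense count matrix.  Balancing weights, if present,
#' are stored on one further header line.  The round trip is
#' bit-faithful for integer counts.
#'
#' @param m A `contact_matrix`.
#' @param path Output TSV path.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom\t%s", m$chrom_name), con)
  writeLines(sprintf("#chrom_length\t%s", format(m$chrom_length, scientific = FALSE)), con)
  writeLines(sprintf("#bin_size\t%d", m$bin_size), con)
  if (!is.null(m$weights)) {
    writeLines(paste0("#weights\t",
                      paste(format(m$weights, digits = 17), collapse = "\t")), con)
  }
  utils::write.table(m$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (length(ln) == 0) return(NULL)
    strsplit(ln[1], "\t")[[1]][-1]
  }
  counts <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  weights <- get("weights")
  if (!is.null(weights)) {
    weights <- trimws(weights)
    weights <- ifelse(weights == "NA", NA_character_, weights)  # masked bins
    weights <- as.numeric(weights)
  }
  contact_matrix(counts,
                 bin_size = as.integer(get("bin_size")),
                 chrom_length = as.numeric(get("chrom_length")),
                 chrom_name = get("chrom")[1],
                 weights = weights)
}
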