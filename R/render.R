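#' Rendering parameters for synthetic contact maps
#'
#' Collects the free parameters of the map renderer.  The background
#' follows a softened power law `(s + s0)^-alpha`; each positioned loop
#' adds a focal bell at its anchor pair (spread `anchor_sigma`, so that
#' ~all of the focal mass is confined within ~1 kb of the anchors) and a
#' uniform "loop domain" square over the loop interior.
#'
#' @param alpha Background decay exponent (> 0).
#' @param s0 Background softening offset, bp.
#' @param background_weight Multiplier on the decay background (0 turns
#'   the background off, for focal-only test maps).
#' @param focal_weight Total focal mass per loop per cell, on the same
#'   scale as the background density integrated over bp^2 (the rendered
#'   enrichment is bin-size independent).  The default gives an
#'   adjacent-loop spot a few-fold over background at typical loop
#'   frequencies.
#' @param domain_weight Total intra-loop mass per loop per cell, spread
#'   uniformly over the loop square (so larger loops get fainter
#'   squares), same scale as `focal_weight`.
#' @param anchor_sigma Gaussian spread of the focal spot, bp.
#' @param total_reads Total contact count the sampled map is scaled to.
#' @param seed Integer seed for count sampling.
#' @return A `render_params` list.
#' @export
render_params <- function(alpha = 1.0,
                          s0 = 1000,
                          background_weight = 1,
                          focal_weight = 5000,
                          domain_weight = 15000,
                          anchor_sigma = 500,
                          total_reads = 1e7,
                          seed = 1L) {
  stopifnot_scalar_number(alpha, "alpha", lower = 1e-9)
  stopifnot_scalar_number(focal_weight, "focal_weight", lower = 0)
  stopifnot_scalar_number(domain_weight, "domain_weight", lower = 0)
  structure(list(alpha = alpha, s0 = s0,
                 background_weight = background_weight,
                 focal_weight = focal_weight,
                 domain_weight = domain_weight, anchor_sigma = anchor_sigma,
                 total_reads = total_reads, seed = seed),
            class = "render_params")
}

#' Render a loop population into a binned contact matrix
#'
#' Builds the expected population contact map implied by the residency
#' model -- every cell's positioned loops pile up into focal
#' anchor-anchor spots with loop-domain squares between them, on top of
#' a distance-decay background -- then (optionally) samples
#' Poisson-distributed counts around the expectation scaled to
#' `params$total_reads`.  Unpositioned loop records contribute focal
#' mass at their recorded coordinates with per-cell weight.
#'
#' The expected matrix is
#' `E(i,j) = (s_ij + s0)^-alpha
#'   + sum_loops freq * [focal_weight * bell(i,j; anchors, sigma)
#'   + domain_weight * 1(i,j inside loop)]`
#' with the focal bell normalised to unit mass per pixel area, so
#' `focal_weight` is the total focal mass per loop per cell on the
#' background scale.
#'
#' @param pop A `population_loops` object.
#' @param map The parent `car_map`.
#' @param params A [render_params()] list.
#' @param bin_size Bin size in bp (typical 100-2000).
#' @param noise Sample counts (`TRUE`) or return the scaled expectation
#'   (`FALSE`).
#' @return A `contact_matrix`.
#' @export
render_map <- function(pop, map, params = render_params(),
                       bin_size = 200, noise = TRUE) {
  validate_car_map(map)
  chrom_length <- attr(map, "chrom_length")
  n <- ceiling(chrom_length / bin_size)
  b2 <- as.numeric(bin_size)^2

  # background: softened power-law in distance between bin centres
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * bin_size
  e <- (params$background_weight %||% 1) * (d + params$s0)^(-params$alpha) * b2
  rm(d)

  sigma_bins <- params$anchor_sigma / bin_size
  r_focal <- max(1L, ceiling(4 * sigma_bins))

  # focal and domain patches are added in place inside one loop; passing
  # the big matrix through helper functions would copy it on every call
  loops <- pop$loops
  un <- pop$unpositioned
  fi <- fj <- fw <- numeric(0)
  if (nrow(loops) > 0 && params$focal_weight > 0) {
    fi <- pmin(pmax(floor(loops$left_pos / bin_size) + 1L, 1L), n)
    fj <- pmin(pmax(floor(loops$right_pos / bin_size) + 1L, 1L), n)
    fw <- loops$frequency * params$focal_weight
  }
  if (nrow(un) > 0 && params$focal_weight > 0) {
    fi <- c(fi, pmin(pmax(floor(un$left_anchor / bin_size) + 1L, 1L), n))
    fj <- c(fj, pmin(pmax(floor(un$right_anchor / bin_size) + 1L, 1L), n))
    fw <- c(fw, rep(params$focal_weight / pop$n_cells, nrow(un)))
  }
  for (l in seq_along(fi)) {
    ai <- fi[l]; aj <- fj[l]
    if (ai == aj) next
    ii <- max(1L, ai - r_focal):min(n, ai + r_focal)
    jj <- max(1L, aj - r_focal):min(n, aj + r_focal)
    gi <- dnorm(ii, ai, sigma_bins)
    gj <- dnorm(jj, aj, sigma_bins)
    patch <- outer(gi, gj) * (fw[l] / (sum(gi) * sum(gj)))
    e[ii, jj] <- e[ii, jj] + patch
    e[jj, ii] <- e[jj, ii] + t(patch)
  }
  if (nrow(loops) > 0 && params$domain_weight > 0) {
    di <- pmin(pmax(floor(loops$left_pos / bin_size) + 1L, 1L), n)
    dj <- pmin(pmax(floor(loops$right_pos / bin_size) + 1L, 1L), n)
    for (l in seq_len(nrow(loops))) {
      if (dj[l] <= di[l]) next
      idx <- di[l]:dj[l]
      e[idx, idx] <- e[idx, idx] +
        loops$frequency[l] * params$domain_weight / length(idx)^2
    }
  }

  # scale the upper triangle (incl. diagonal) to total_reads
  ut <- upper.tri(e, diag = TRUE)
  scale <- params$total_reads / sum(e[ut])
  e <- e * scale
  if (noise) {
    counts <- matrix(0, n, n)
    counts[ut] <- with_seed(params$seed, rpois(sum(ut), e[ut]))
    counts <- counts + t(counts) - diag(diag(counts))
  } else {
    counts <- e
  }
  contact_matrix(counts, bin_size, chrom_length = chrom_length,
                 chrom_name = attr(map, "chrom_name"))
}
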