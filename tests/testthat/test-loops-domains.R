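# Irregular spacing by default: evenly spaced spots all share one
# diagonal, which distorts the distance-expected model they are tested
# against.
planted_map <- function(n_cars = 26, spacing = NULL, seed = 2,
                        bin_size = 300, noise = FALSE) {
  cm <- if (is.null(spacing)) {
    m <- build_car_map(n_cars, n_cars * 12000, spacing_median = 9000,
                       spacing_range = c(5500, 20000), seed = seed)
    m$occupancy <- rep(1, n_cars)
    m
  } else {
    even_car_map(n_cars, spacing = spacing, occupancy = 1)
  }
  pop <- simulate_population(cm, 100, seed = seed)
  m <- render_map(pop, cm, render_params(seed = seed + 1), bin_size = bin_size,
                  noise = noise)
  list(map = cm, pop = pop, m = ice_balance(m))
}

test_that("the donut caller recovers planted loops perfectly on noise-free maps", {
  px <- planted_map()
  calls <- call_loops(px$m, min_dist = 5000, merge_radius = 8L)
  truth <- px$pop$loops
  truth <- truth[truth$right_pos - truth$left_pos >= 5000, ]
  expect_equal(nrow(truth), 25)           # all adjacent loops are in band
  expect_equal(nrow(calls), nrow(truth))  # exactly n_cars - 1 adjacent loops
  # precision = recall = 1 with +-1 bin matching
  match <- vapply(seq_len(nrow(truth)), function(r) {
    any(abs(calls$bin_i - (floor(truth$left_pos[r] / 300) + 1)) <= 1 &
        abs(calls$bin_j - (floor(truth$right_pos[r] / 300) + 1)) <= 1)
  }, logical(1))
  expect_true(all(match))
})

test_that("the caller respects the distance filter and the null map", {
  px <- planted_map(n_cars = 10, spacing = 3500)
  # planted separation 3.5 kb < min_dist 5 kb -> nothing called
  calls <- call_loops(px$m, min_dist = 5000)
  expect_equal(nrow(calls), 0)

  # background-only noisy map -> (close to) zero calls at FDR 0.1
  cm <- even_car_map(10, spacing = 9000, occupancy = 0)
  pop <- simulate_population(cm, 100, seed = 1)
  m0 <- ice_balance(render_map(pop, cm, render_params(seed = 5), bin_size = 300))
  expect_lte(nrow(call_loops(m0)), 2)
})

test_that("loops per anchor clusters anchors and counts rightward partners", {
  calls <- carloops:::empty_loop_calls(200)
  expect_equal(nrow(loops_per_anchor(calls)), 0)

  calls <- tibble::tibble(
    bin_i = c(100L, 200L), bin_j = c(200L, 300L),
    a5 = (c(100, 200) - 0.5) * 200, a3 = (c(200, 300) - 0.5) * 200,
    observed = c(5, 5), local_expected = c(1, 1), fold = c(5, 5),
    p_value = c(0.001, 0.001), q_value = c(0.01, 0.01))
  attr(calls, "bin_size") <- 200
  class(calls) <- c("loop_calls", class(tibble::tibble()))
  h <- loops_per_anchor(calls)
  # anchors 100 and 200 each have exactly one rightward partner
  expect_equal(h$partners, 1L)
  expect_equal(h$n_anchors, 2L)
  expect_equal(attr(h, "mean_partners"), 1)
})

test_that("loop sizes track peak intervals in the forced cases", {
  cm <- even_car_map(11, spacing = 8000)
  empty <- carloops:::empty_loop_calls(200)
  svi <- loop_size_vs_interval(empty, cm)
  expect_equal(svi$median_interval, 8000)
  expect_true(is.na(svi$median_loop))

  px <- planted_map()
  calls <- call_loops(px$m, min_dist = 5000, merge_radius = 8L)
  svi <- loop_size_vs_interval(calls, px$map)
  # only adjacent loops exist, so the two medians coincide (within a bin)
  expect_lte(abs(svi$median_loop - svi$median_interval), 300)  # within one bin
})

test_that("anchor overlap fractions at the extremes", {
  px <- planted_map(n_cars = 12)
  calls <- call_loops(px$m, min_dist = 5000, merge_radius = 8L)
  expect_equal(anchor_overlap(calls, px$map, tol = 1000), 1, ignore_attr = TRUE)
  none <- carloops:::new_peak_set(numeric(0), numeric(0), numeric(0))
  expect_equal(anchor_overlap(calls, none), 0, ignore_attr = TRUE)
})

test_that("insulation: uniform maps are flat, block junctions are boundaries", {
  u <- cm_from(matrix(100, 60, 60), bin_size = 2000)
  ins <- insulation(u, res = 2000, window = 8000, min_prominence = 0.1)
  expect_lt(max(abs(ins$scores$score), na.rm = TRUE), 1e-9)
  expect_equal(nrow(ins$boundaries), 0)

  # two dense blocks -> a single boundary at the junction bin
  b <- matrix(1, 60, 60)
  b[1:30, 1:30] <- 50
  b[31:60, 31:60] <- 50
  ins2 <- insulation(cm_from(b, bin_size = 2000), res = 2000, window = 8000,
                     min_prominence = 0.1)
  expect_gte(nrow(ins2$boundaries), 1)
  top <- ins2$boundaries[which.max(ins2$boundaries$prominence), ]
  expect_true(abs(top$bin - 30.5) <= 1.5)
})

test_that("boundaries inside masked regions are suppressed", {
  b <- matrix(1, 60, 60)
  b[1:30, 1:30] <- 50
  b[31:60, 31:60] <- 50
  b[29:32, ] <- 0  # kill coverage at the junction so balancing masks it
  b[, 29:32] <- 0
  ins <- insulation(cm_from(b, bin_size = 2000), res = 2000, window = 8000,
                    min_prominence = 0.1)
  expect_false(any(ins$boundaries$bin %in% 29:32))
})

test_that("aggregate domain analysis: identity rescale, corner formula, oracle", {
  n <- 40
  x <- random_symmetric(n, seed = 12)
  m <- cm_from(x, bin_size = 1000)
  # single domain of exactly pseudo_size bins, no flank -> the sub-matrix
  dom <- tibble::tibble(start = 10000, end = 26000)  # 16 bins
  ada <- aggregate_domains(m, dom, pseudo_size = 16L, flank = 0,
                           norm = "raw")
  expect_equal(ada$mat, x[11:26, 11:26], tolerance = 1e-12)

  # a contact at (D_start, D_end) lands at rescaled (0, 1): with flank 0.5
  # and pseudo 32, that is pixel (9, 25) of the [-0.5, 1.5] grid
  ada2 <- aggregate_domains(m, dom, pseudo_size = 32L, flank = 0.5,
                            norm = "raw")
  ps <- function(coord, ds, de, flank, P) {
    min(max(floor(((coord - ds) / (de - ds) + flank) / (1 + 2 * flank) * P) + 1, 1), P)
  }
  expect_equal(ps(10000 + 500, 10000, 26000, 0.5, 32), 9)
  expect_equal(ps(26000 - 500, 10000, 26000, 0.5, 32), 24)

  # 10 random domains equal a naive per-contact re-mapping oracle
  set.seed(13)
  starts <- sort(sample(seq(2000, 20000, by = 1000), 10))
  doms <- tibble::tibble(start = starts, end = starts + sample(5:10, 10, TRUE) * 1000)
  got <- aggregate_domains(m, doms, pseudo_size = 12L, flank = 0.25,
                           norm = "raw")
  P <- 12L; flank <- 0.25
  acc <- matrix(0, P, P); cnt <- matrix(0, P, P)
  centers <- (seq_len(n) - 0.5) * 1000
  for (d in seq_len(nrow(doms))) {
    ds <- doms$start[d]; de <- doms$end[d]; L <- de - ds
    idx <- which(centers >= ds - flank * L & centers < de + flank * L)
    if (length(idx) < 2) next
    dacc <- matrix(0, P, P); dcnt <- matrix(0, P, P)
    for (a in idx) for (b in idx) {
      pi_ <- ps(centers[a], ds, de, flank, P)
      pj_ <- ps(centers[b], ds, de, flank, P)
      dacc[pi_, pj_] <- dacc[pi_, pj_] + x[a, b]
      dcnt[pi_, pj_] <- dcnt[pi_, pj_] + 1
    }
    has <- dcnt > 0
    acc[has] <- acc[has] + dacc[has] / dcnt[has]
    cnt[has] <- cnt[has] + 1
  }
  want <- acc / cnt; want[cnt == 0] <- NA_real_
  expect_equal(got$mat, want, tolerance = 1e-12)

  expect_error(aggregate_domains(m, doms[0, ], 16L), "zero domains")
})

test_that("boundary ChIP enrichment peaks at CAR boundaries and flags edge cases", {
  cm <- build_car_map(30, 3.2e5, seed = 14)
  tr <- synthesize_chip(cm, depth = 0, noise = FALSE, bin_size = 50)
  prof <- boundary_chip_enrichment(cm$pos[5:20], tr, flank = 5000)
  mid <- which(prof$profile$offset == 0)
  expect_equal(which.max(prof$profile$mean_signal), mid)
  expect_equal(nrow(prof$per_boundary), 16)

  flat <- tr; flat$score <- rep(2, nrow(flat))
  pf <- boundary_chip_enrichment(cm$pos[5:10], flat, flank = 5000)
  expect_true(all(abs(pf$profile$mean_signal - 2) < 1e-12))

  expect_error(boundary_chip_enrichment(numeric(0), tr), "empty")
  pe <- boundary_chip_enrichment(c(100, cm$pos[10]), tr, flank = 5000)
  expect_equal(pe$n_dropped, 1)
})
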