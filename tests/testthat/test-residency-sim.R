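test_that("occupancy sampling respects the degenerate limits and the binomial law", {
  cm <- even_car_map(10, occupancy = 1)
  expect_true(all(sample_occupancy(cm, 1, 1)))
  cm$occupancy <- rep(0, 10)
  expect_false(any(sample_occupancy(cm, 1, 1)))

  cm <- even_car_map(20, occupancy = 0.5)
  frac <- rowMeans(vapply(seq_len(10000),
                          function(cell) sample_occupancy(cm, cell, 99),
                          logical(20)))
  expect_true(all(abs(frac - 0.5) <= 0.02))
})

test_that("consecutive looping follows the forced patterns", {
  cm <- even_car_map(5)
  l1 <- form_loops_consecutive(fixed_state(c(T, T, T, T, F)), cm)
  expect_equal(cbind(l1$left_car, l1$right_car),
               cbind(1:3, 2:4))
  l2 <- form_loops_consecutive(fixed_state(c(T, F, F, T, T)), cm)
  expect_equal(cbind(l2$left_car, l2$right_car), cbind(c(1L, 4L), c(4L, 5L)))
  expect_equal(nrow(form_loops_consecutive(fixed_state(c(F, T, F, F, F)), cm)), 0)
  expect_true(all(l1$left_positioned & l1$right_positioned))
  expect_true(all(l1$left_anchor == cm$pos[l1$left_car]))
})

test_that("all 2^12 occupancy patterns match an independent looping oracle exactly", {
  n <- 12L
  cm <- even_car_map(n)
  p <- 0.5
  span_mass <- setNames(numeric(n - 1), seq_len(n - 1))
  for (code in 0:(2^n - 1)) {
    state <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
    got <- form_loops_consecutive(fixed_state(state), cm)
    want <- oracle_consecutive_loops(state)
    if (is.null(want) || nrow(want) == 0) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(cbind(got$left_car, got$right_car), unname(want))
    }
    w <- p^sum(state) * (1 - p)^sum(!state)
    if (nrow(got) > 0) {
      k <- got$right_car - got$left_car
      for (kk in k) span_mass[kk] <- span_mass[kk] + w
    }
  }
  # analytic expected loop count by span: (n - k) p^2 (1 - p)^(k - 1)
  k <- seq_len(n - 1)
  expect_equal(unname(span_mass), (n - k) * p^2 * (1 - p)^(k - 1),
               tolerance = 1e-12)
})

test_that("extruder growth obeys the halting rules", {
  cm <- even_car_map(10, spacing = 10000)
  # no occupied CARs: every loop unpositioned with total span = processivity
  st <- fixed_state(rep(FALSE, 10))
  loops <- extrude_cell(st, cm, n_extruders = 50, processivity = 20000, seed = 2)
  inner <- loops[loops$left_anchor > 0 & loops$right_anchor < attr(cm, "chrom_length") - 1, ]
  expect_true(all(!inner$left_positioned & !inner$right_positioned))
  expect_true(all(abs((inner$right_anchor - inner$left_anchor) - 20000) < 1e-6))

  # all occupied, processivity >> spacing: anchors at the flanking CARs
  st <- fixed_state(rep(TRUE, 10))
  loops <- extrude_cell(st, cm, n_extruders = 200, processivity = 1e6, seed = 3)
  mid <- loops[loops$left_positioned & loops$right_positioned, ]
  expect_gt(nrow(mid), 100)
  expect_true(all(mid$right_car - mid$left_car == 1L))
  expect_true(all(mid$left_anchor == cm$pos[mid$left_car]))

  # single occupied CAR: every positioned anchor is that CAR and the free
  # side never exceeds the remaining budget
  st <- fixed_state(c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
  loops <- extrude_cell(st, cm, n_extruders = 500, processivity = 30000, seed = 4)
  posd <- loops[loops$left_positioned | loops$right_positioned, ]
  expect_true(all(c(posd$left_car[posd$left_positioned],
                    posd$right_car[posd$right_positioned]) == 5L))
  expect_true(all(posd$right_anchor - posd$left_anchor <= 30000 + 1e-6))
})

test_that("population aggregation: degenerate limits, adjacent frequency, determinism", {
  cm <- even_car_map(15, occupancy = 1)
  pop <- simulate_population(cm, 50, seed = 1)
  expect_equal(nrow(pop$loops), 14)
  expect_true(all(pop$loops$frequency == 1))
  expect_true(all(pop$loops$right_car - pop$loops$left_car == 1))

  cm$occupancy <- rep(0, 15)
  expect_equal(nrow(simulate_population(cm, 50, seed = 1)$loops), 0)

  cm <- even_car_map(20, occupancy = 0.5)
  pop <- simulate_population(cm, 10000, seed = 5)
  adj <- pop$loops[pop$loops$right_car - pop$loops$left_car == 1, ]
  expect_true(all(abs(adj$frequency - 0.25) <= 0.02))

  pop2 <- simulate_population(cm, 10000, seed = 5)
  expect_identical(pop, pop2)

  # the fast aggregation path agrees with per-cell form_loops_consecutive
  small <- simulate_population(cm, 60, seed = 6)
  counts <- new.env()
  for (cell in 1:60) {
    l <- form_loops_consecutive(sample_occupancy(cm, cell, 6), cm)
    for (r in seq_len(nrow(l))) {
      key <- paste(l$left_car[r], l$right_car[r])
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  got <- setNames(small$loops$n, paste(small$loops$left_car, small$loops$right_car))
  want <- unlist(as.list(counts))
  expect_equal(got[sort(names(got))], want[sort(names(want))])
  pe1 <- simulate_population(cm, 200, mode = "extruder", seed = 9)
  pe2 <- simulate_population(cm, 200, mode = "extruder", seed = 9)
  expect_identical(pe1, pe2)
})

test_that("span histogram: degenerate limits and geometric decay direction", {
  cm <- even_car_map(10, occupancy = 1)
  sh <- span_histogram(simulate_population(cm, 20, seed = 1))
  expect_equal(sh$k, 1L)
  expect_equal(sh$prob, 1)

  empty <- simulate_population(even_car_map(10, occupancy = 0), 20, seed = 1)
  expect_equal(nrow(span_histogram(empty)), 0)
})

test_that("scenario transforms follow the depletion phenotypes", {
  cm <- even_car_map(11, occupancy = 0.8, centromere = 50000)
  cm$occupancy <- c(0.8, 0.4, rep(0.8, 9))

  expect_identical(apply_scenario(cm, "WT")$occupancy, cm$occupancy)
  expect_identical(apply_scenario(cm, "BRN1")$occupancy, cm$occupancy)
  expect_true(all(apply_scenario(cm, "MCD1")$occupancy == 0))
  expect_equal(apply_scenario(cm, "WPL1")$occupancy[1:2], c(0.4, 0.2))

  pd <- apply_scenario(cm, "PDS5")
  cen <- attr(cm, "centromere_index")
  d <- abs(cm$pos - cm$pos[cen])
  expect_equal(pd$occupancy[cen], cm$occupancy[cen])
  far <- d > 30000 & seq_along(d) != cen
  near <- d <= 30000 & seq_along(d) != cen
  expect_equal(pd$occupancy[far], cm$occupancy[far] * 0.05)
  expect_equal(pd$occupancy[near], cm$occupancy[near] * 0.7)
  expect_equal(attr(pd, "processivity_scale"), 10)

  expect_error(scenario("SMC4"), "unknown")
  expect_error(apply_scenario(even_car_map(5), "PDS5"), "centromere")
})

test_that("halving occupancy strictly increases the mean loop span (Wpl1 direction)", {
  for (sd in 1:5) {
    cm <- build_car_map(60, 6e5, seed = sd)
    wt <- span_histogram(simulate_population(cm, 1500, seed = 100 + sd))
    half <- apply_scenario(cm, "WPL1")
    wp <- span_histogram(simulate_population(half, 1500, seed = 100 + sd))
    expect_gt(attr(wp, "mean_span"), attr(wt, "mean_span"))
  }
})

test_that("PDS5 extruder anchors concentrate at the centromeric CAR", {
  cm <- build_car_map(60, 6e5, centromere = 3e5, seed = 8)
  pd <- apply_scenario(cm, "PDS5")
  pop <- simulate_population(pd, 800, mode = "extruder",
                             processivity = 30000 * attr(pd, "processivity_scale"),
                             seed = 9)
  cen <- attr(cm, "centromere_index")
  anchors <- c(rep(pop$loops$left_car, pop$loops$n),
               rep(pop$loops$right_car, pop$loops$n),
               pop$unpositioned$left_car[pop$unpositioned$left_positioned],
               pop$unpositioned$right_car[pop$unpositioned$right_positioned])
  tab <- table(anchors)
  # the centromere is the single most frequent positioned anchor
  expect_equal(as.integer(names(tab)[which.max(tab)]), cen)
})
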