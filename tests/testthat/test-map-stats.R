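test_that("contact decay bins, filters, and errors behave as documented", {
  cv <- contact_decay(rep(5000, 100))
  expect_equal(sum(cv$n > 0), 1)
  expect_true(cv$bin_lo[cv$n > 0] <= 5000 && cv$bin_hi[cv$n > 0] >= 5000)
  expect_equal(sum(cv$prob), 1)

  expect_error(contact_decay(rep(50, 10)), "minimum-distance")
})

test_that("a 1/s pair sample yields a log-log slope of -1", {
  # closed-form sampling oracle: inverse CDF of P(s) ~ 1/s on [1 kb, 100 kb]
  set.seed(42)
  u <- runif(2e5)
  s <- 1000 * (100)^u
  cv <- contact_decay(s, range = c(1000, 1e5))
  use <- cv$density > 0 & cv$mid > 1500 & cv$mid < 7e4
  fit <- coef(lm(log10(cv$density[use]) ~ log10(cv$mid[use])))[2]
  expect_lt(abs(fit - (-1)), 0.05)
})

test_that("decay slopes match exact and re-fitted values", {
  cv <- contact_decay(rep(5000, 10))  # dummy shell; overwrite with power law
  cv <- cv[cv$mid > 0, ]
  cv$density <- cv$mid^(-1.4)
  sl <- decay_slope(cv, window = 5)
  expect_true(all(abs(sl$slope - (-1.4)) < 1e-10))

  # window = number of usable bins -> the single global fit
  sl1 <- decay_slope(cv, window = nrow(cv))
  expect_equal(nrow(sl1), 1)
  expect_equal(sl1$slope, -1.4, tolerance = 1e-10)

  # random curve: every window equals an independent lm re-fit
  set.seed(7)
  cv$density <- cv$density * exp(rnorm(nrow(cv), 0, 0.3))
  sl <- decay_slope(cv, window = 4)
  for (i in seq_len(nrow(sl))) {
    xs <- log10(cv$mid[i:(i + 3)])
    ys <- log10(cv$density[i:(i + 3)])
    expect_equal(sl$slope[i], unname(coef(lm(ys ~ xs))[2]), tolerance = 1e-10)
  }
  expect_error(decay_slope(cv, window = 1000), "exceeds")
})

test_that("pile-ups match extraction, uniformity and the brute-force oracle", {
  n <- 60
  x <- matrix(0, n, n)
  x[20, 40] <- x[40, 20] <- 7
  m <- cm_from(x, bin_size = 1000)
  p <- pileup_at_pairs(m, data.frame(a5 = 19500, a3 = 39500),
                       half_width = 5000, norm = "balanced")
  expect_equal(p$n_stacked, 1)
  expect_equal(p$mat, x[15:25, 35:45])

  u <- cm_from(matrix(3, n, n), bin_size = 1000)
  pu <- pileup_at_pairs(u, data.frame(a5 = c(10500, 20500), a3 = c(30500, 40500)),
                        half_width = 3000, norm = "balanced")
  expect_true(all(pu$mat == 3))

  set.seed(8)
  r <- cm_from(random_symmetric(80, seed = 8), bin_size = 1000)
  prs_bins <- cbind(sample(15:35, 20, replace = TRUE),
                    sample(45:65, 20, replace = TRUE))
  prs <- data.frame(a5 = (prs_bins[, 1] - 0.5) * 1000,
                    a3 = (prs_bins[, 2] - 0.5) * 1000)
  got <- pileup_at_pairs(r, prs, half_width = 4000, norm = "balanced")
  want <- oracle_pileup(r$counts, prs_bins, 4)
  expect_equal(got$mat, want, tolerance = 1e-10)

  # pairs closer to the diagonal than half_width are excluded
  pd <- pileup_at_pairs(u, data.frame(a5 = c(10500, 20500), a3 = c(12500, 40500)),
                        half_width = 3000, norm = "balanced")
  expect_equal(pd$n_stacked, 1)
  expect_equal(pd$n_dropped, 1)
  expect_error(pileup_at_pairs(u, data.frame(a5 = 10500, a3 = 11500),
                               half_width = 3000), "no usable")
})

test_that("enrichment ratio: uniform, constructed, and indexed oracles", {
  p <- list(mat = matrix(2.5, 51, 51), res = 200)
  class(p) <- "pileup"
  expect_identical(enrichment_ratio(p), 1)

  p$mat <- matrix(1, 51, 51)
  p$mat[26, 26] <- 4
  expect_equal(enrichment_ratio(p), 4)

  set.seed(9)
  p$mat <- matrix(rexp(51 * 51), 51, 51)
  expect_equal(enrichment_ratio(p, corner_size = 10),
               oracle_enrichment(p$mat, 10), tolerance = 1e-10)
  expect_error(enrichment_ratio(p, corner_size = 30), "too large")
})

test_that("the interval series is strong at +1 and flat beyond when p = 1", {
  cm <- even_car_map(24, spacing = 9000, occupancy = 1)
  pop <- simulate_population(cm, 200, seed = 3)
  # unbalanced on purpose: with p = 1 the anchor rows carry so much focal
  # mass that ICE down-weights them, which would depress the k >= 3 centres
  m <- render_map(pop, cm, render_params(seed = 4), bin_size = 300,
                  noise = FALSE)
  s <- interval_pileup_series(m, cm, k_range = 1:6, corner_size = 5L)
  expect_gt(s$ratio[1], 3)
  expect_true(all(abs(s$ratio[3:6] - 1) < 0.2))
  expect_gt(s$ratio[1], 2 * max(s$ratio[3:6]))

  # k beyond the number of peaks -> empty entry
  s2 <- interval_pileup_series(m, cm, k_range = c(1, 30), corner_size = 5L)
  expect_equal(unname(s2$n_pairs[2]), 0L)
  expect_true(is.na(s2$ratio[2]))
})

test_that("barrier contrast reports NA for one-class flag vectors", {
  cm <- even_car_map(12, spacing = 9000, occupancy = 0.6)
  pop <- simulate_population(cm, 300, seed = 5)
  m <- ice_balance(render_map(pop, cm, render_params(seed = 6), bin_size = 300))

  cm$high_residency <- rep(FALSE, 12)
  b0 <- barrier_contrast(m, cm, corner_size = 5L)
  expect_true(is.na(b0$ratio[b0$class == "across_barrier"]))
  expect_false(is.na(b0$ratio[b0$class == "no_barrier"]))

  cm$high_residency <- rep(TRUE, 12)
  b1 <- barrier_contrast(m, cm, corner_size = 5L)
  expect_true(is.na(b1$ratio[b1$class == "no_barrier"]))
  expect_false(is.na(b1$ratio[b1$class == "across_barrier"]))
})
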