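test_that("the SMILES pool is large, deduplicated and role-pure", {
  pool <- fixture_pool()
  expect_gte(length(pool$azides), 100L)
  expect_gte(length(pool$alkynes), 60L)
  expect_gte(length(pool$acids), 100L)
  expect_equal(anyDuplicated(unlist(pool)), 0L)
  cg <- count_groups(pool$alkynes)
  expect_true(all(cg[, "terminal_alkyne"] == 1L))
  expect_true(all(cg[, "primary_sulfonamide"] == 1L))
  expect_true(all(cg[, "azide"] == 0L & cg[, "carboxylic_acid"] == 0L))
})

test_that("generated building blocks validate and respect requested sizes", {
  bb <- gen_building_blocks(5, 4, 6, seed = 77)
  expect_length(bb$azides, 5L)
  expect_length(bb$alkynes, 4L)
  expect_length(bb$acids, 6L)
  expect_true(all(vapply(bb$alkynes, `[[`, logical(1), "carries_sulfonamide")))
  expect_false(any(vapply(bb$azides, `[[`, logical(1), "carries_sulfonamide")))
  expect_error(gen_building_blocks(10000, 4, 6, seed = 1), "exceed")
})

test_that("generators are deterministic under a fixed seed", {
  b1 <- gen_building_blocks(4, 3, 4, seed = 9)
  b2 <- gen_building_blocks(4, 3, 4, seed = 9)
  expect_identical(vapply(b1$azides, `[[`, character(1), "smiles"),
                   vapply(b2$azides, `[[`, character(1), "smiles"))
  p1 <- gen_melt_plate(n_null = 10, n_controls = 2, seed = 13)
  p2 <- gen_melt_plate(n_null = 10, n_controls = 2, seed = 13)
  expect_identical(p1, p2)
  k1 <- gen_dose_kinetics(seed = 13)
  k2 <- gen_dose_kinetics(seed = 13)
  expect_identical(k1, k2)
  expect_false(identical(gen_melt_plate(n_null = 10, n_controls = 2, seed = 14), p1))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_melt_plate(n_null = 5, n_controls = 2, seed = 1))
  expect_identical(runif(1), before)
})

test_that("outcome generation matches the planted success rate on average", {
  ids <- sprintf("m%03d", 1:247)
  ssrs <- vapply(1:60, function(s) {
    compute_ssr(gen_outcomes(ids, ssr_true = 75, seed = s), rounded = FALSE)
  }, numeric(1))
  expect_equal(mean(ssrs), 75, tolerance = 2)
  expect_true(all(gen_outcomes(ids, ssr_true = 100, seed = 1)$isolated))
  expect_false(any(gen_outcomes(ids, ssr_true = 0, seed = 1)$isolated))
  oc <- gen_outcomes(ids, ssr_true = 80, yield_mean = 56, yield_sd = 15, seed = 3)
  y <- oc$yield_percent[!is.na(oc$yield_percent)]
  expect_true(all(y > 0 & y <= 100))
})

test_that("generated plates satisfy the melt-curve contract and ground truth", {
  plate <- gen_melt_plate(n_null = 6, shifters = data.frame(count = 1, delta = 3),
                          n_controls = 2, noise_frac = 0, seed = 2)
  one <- plate[plate$well == plate$well[1], ]
  expect_gte(nrow(one), 20L)
  expect_true(!is.unsorted(one$temperature_C, strictly = TRUE))
  expect_false(anyNA(plate$fluorescence))
  # zero noise, zero shifters: every extracted shift is numerically zero
  p0 <- gen_melt_plate(n_null = 5, shifters = data.frame(count = 0, delta = 0)[0, ],
                       n_controls = 2, null_sd = 0, noise_frac = 0, seed = 6)
  scr <- tsa_screen(p0)
  expect_true(all(abs(scr$shifts$delta_tm) < 1e-6))
})

test_that("kinetics generation refuses a dead assay window", {
  expect_error(gen_dose_kinetics(rate_control = 1e-4, rate_background = 1e-4),
               "exceed")
})
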