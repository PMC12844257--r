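test_that("Tm extraction recovers a noiseless transition with both methods", {
  mc <- melt_curve(seq(25, 95, by = 0.5), sigmoid_curve(tm = 55))
  for (m in c("derivative", "boltzmann")) {
    r <- extract_tm(mc, m)
    expect_true(r$usable)
    expect_equal(r$tm, 55, tolerance = 0.1)
  }
})

test_that("melt-curve input contracts are enforced", {
  expect_error(melt_curve(1:10, rnorm(10)), "20")
  expect_error(melt_curve(c(1:20, 20), rnorm(21)), "increasing")
  expect_error(melt_curve(seq(25, 95, 0.5), c(NA, sigmoid_curve()[-1])), "missing")
})

test_that("flat and boundary curves are flagged unusable", {
  grid <- seq(25, 95, by = 0.5)
  flat <- melt_curve(grid, rep(1, length(grid)))
  expect_false(extract_tm(flat, "derivative")$usable)
  expect_false(extract_tm(flat, "boltzmann")$usable)
  set.seed(3)
  noisy_flat <- melt_curve(grid, rep(1, length(grid)) + rnorm(length(grid), 0, 0.01))
  expect_false(extract_tm(noisy_flat, "derivative")$usable)
  # transition centred beyond the grid edge
  edge <- melt_curve(grid, sigmoid_curve(tm = 97))
  expect_false(extract_tm(edge, "derivative")$usable)
})

test_that("robust stats match the hand-checked example and a brute-force oracle", {
  st <- robust_stats(c(1, 2, 3, 4, 100))
  expect_equal(st$med, 3)
  expect_equal(st$rsd, 1.4826)
  expect_equal(robust_stats(c(1, 1, 1, 1))$rsd, 0)
  expect_equal(robust_stats(c(-2, 0, 2, 0))$med, 0)
  expect_error(robust_stats(c(1, 2, 3)), "at least 4")

  # sort-based median / MAD oracle, written independently of stats::mad
  oracle <- function(x) {
    med <- function(v) { s <- sort(v); n <- length(s)
      if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2 }
    m <- med(x); list(med = m, rsd = 1.4826 * med(abs(x - m)))
  }
  set.seed(99)
  for (rep in 1:200) {
    x <- rnorm(sample(4:30, 1), sd = runif(1, 0.1, 5))
    got <- robust_stats(x); want <- oracle(x)
    expect_equal(got$med, want$med)
    expect_equal(got$rsd, want$rsd)
  }
})

test_that("robust scale resists a single gross outlier (breakdown property)", {
  base <- c(-0.2, -0.1, 0, 0.1, 0.2, 0.05, -0.05)
  clean <- robust_stats(base)$rsd
  for (big in c(10, 1e3, 1e6)) {
    spiked <- robust_stats(c(base, big))$rsd
    expect_lt(spiked, 3 * clean + 0.5)   # bounded, unlike the classical SD
  }
  expect_gt(stats::sd(c(base, 1e6)), 1e5)
})

test_that("shifts are measured against the median control Tm", {
  tab <- data.frame(
    compound_id = c("a", "b", "bad", "control", "control", "control"),
    role = c("sample", "sample", "sample", "control", "control", "control"),
    tm = c(57, 53.5, NA, 55.2, 55.0, 54.8),
    usable = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  st <- compute_shifts(tab)
  expect_equal(attr(st, "reference_tm"), 55)
  expect_equal(st$delta_tm[st$compound_id == "a"], 2)
  expect_equal(st$delta_tm[st$compound_id == "b"], -1.5)
  expect_equal(attr(st, "excluded"), "bad")
  tab$usable[tab$role == "control"] <- FALSE
  expect_error(compute_shifts(tab), "control")
})

test_that("hit calling floors the adaptive threshold at the minimum shift", {
  # nine nulls and one +2 shifter: med = rsd = 0, so only the floor bites
  st <- data.frame(compound_id = sprintf("c%d", 1:10),
                   delta_tm = c(rep(0, 9), 2))
  out <- call_hits(st)
  expect_equal(sum(out$hit), 1L)
  expect_equal(out$compound_id[out$hit], "c10")
  expect_equal(out$direction[out$hit], "positive")
  # all below the floor: never a hit, whatever the rsd
  st2 <- data.frame(compound_id = sprintf("c%d", 1:10),
                    delta_tm = c(rep(0, 9), 0.4))
  expect_equal(sum(call_hits(st2)$hit), 0L)
})

test_that("hit thresholds scale with the shifts (scale equivariance)", {
  set.seed(7)
  d <- c(rnorm(40, 0, 0.2), 3, -2.5)
  base <- call_hits(data.frame(compound_id = sprintf("c%d", seq_along(d)),
                               delta_tm = d))
  for (cc in c(0.5, 2, 10)) {
    scaled <- call_hits(data.frame(compound_id = sprintf("c%d", seq_along(d)),
                                   delta_tm = cc * d), floor = 0.5 * cc)
    expect_equal(attr(scaled, "med"), cc * attr(base, "med"))
    expect_equal(attr(scaled, "rsd"), cc * attr(base, "rsd"))
    expect_equal(scaled$hit, base$hit)
  }
})

test_that("controls never influence the plate statistics", {
  plate <- gen_melt_plate(n_null = 20, shifters = data.frame(count = 1, delta = 3),
                          n_controls = 4, seed = 5)
  scr1 <- tsa_screen(plate)
  # replace control wells by wildly shifted curves: reference moves but the
  # sample MED/RSD stay identical because controls are excluded from them
  plate2 <- plate
  ctrl <- plate2$role == "control"
  grid <- seq(25, 95, by = 0.5)
  for (w in unique(plate2$well[ctrl])) {
    sel <- plate2$well == w
    plate2$fluorescence[sel] <- sigmoid_curve(tm = 70)
  }
  scr2 <- tsa_screen(plate2)
  expect_equal(scr2$plates$rsd, scr1$plates$rsd, tolerance = 1e-10)
  expect_equal(scr2$plates$med - scr1$plates$med,
               scr1$plates$reference_tm - scr2$plates$reference_tm,
               tolerance = 1e-6)
})

test_that("planted shifters are recovered from a full synthetic plate", {
  plate <- gen_melt_plate(n_null = 85,
                          shifters = data.frame(count = c(5, 10), delta = c(3, -2)),
                          n_controls = 8, null_sd = 0.15, seed = 42)
  scr <- tsa_screen(plate)
  hits <- scr$hits[scr$hits$hit_any, ]
  expect_equal(sum(hits$direction == "positive"), 5L)
  expect_equal(sum(hits$direction == "negative"), 10L)
  truth <- attr(plate, "truth")
  planted <- truth$compound_id[truth$true_delta != 0]
  expect_setequal(hits$compound_id, planted)
})
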