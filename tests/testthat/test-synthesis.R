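test_that("SSR reproduces the library-scale worked examples", {
  oc4 <- synthesis_outcomes(sprintf("4{%d}", 1:247), c(rep(TRUE, 186), rep(FALSE, 61)))
  expect_equal(compute_ssr(oc4), 75)
  oc7 <- synthesis_outcomes(sprintf("7{%d}", 1:89), c(rep(TRUE, 76), rep(FALSE, 13)))
  expect_equal(compute_ssr(oc7), 85)
  none <- synthesis_outcomes(sprintf("x%d", 1:10), rep(FALSE, 10))
  expect_equal(compute_ssr(none), 0)
  expect_error(compute_ssr(synthesis_outcomes(character(0), logical(0))), "no")
})

test_that("rounding is half away from zero, matching printed percentages", {
  # 186/247 = 75.30 -> 75; 76/89 = 85.39 -> 85; and a half-way case
  expect_equal(clickscreen:::round_half_up(74.5), 75)
  expect_equal(clickscreen:::round_half_up(85.39), 85)
  expect_equal(clickscreen:::round_half_up(-0.5), -1)
})

test_that("mean yield averages isolated yield-bearing members only", {
  oc <- synthesis_outcomes(sprintf("m%d", 1:5),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE),
                           c(50, 70, NA, NA, NA))
  expect_equal(mean_yield(oc), 60)       # (50+70)/2
  expect_equal(compute_ssr(oc), 60)      # 3/5, NA yield still counts as isolated
  expect_equal(mean_yield(synthesis_outcomes("a", TRUE, 56)), 56)
  expect_error(mean_yield(synthesis_outcomes("a", TRUE, NA)), "yield")
})

test_that("outcome invariants are enforced", {
  expect_error(synthesis_outcomes("a", FALSE, 50), "not isolated")
  expect_error(synthesis_outcomes("a", TRUE, 0), "\\(0, 100\\]")
  expect_error(synthesis_outcomes("a", TRUE, 101), "\\(0, 100\\]")
})

test_that("combined report pools counts and spaces; permutation invariant", {
  oc4 <- synthesis_outcomes(sprintf("4{%d}", 1:247), c(rep(TRUE, 186), rep(FALSE, 61)))
  oc7 <- synthesis_outcomes(sprintf("7{%d}", 1:89), c(rep(TRUE, 76), rep(FALSE, 13)))
  r4 <- library_report(oc4, 63080, "4")
  r7 <- library_report(oc7, 10251, "7")
  both <- combined_report(list(r4, r7))
  expect_equal(both$isolated_count, 262)
  expect_equal(both$theoretical_space, 73331)
  expect_equal(both$planned_count, 336)
  expect_equal(both$ssr_percent, 78)   # 100*262/336 = 77.98
  flipped <- combined_report(list(r7, r4))
  expect_equal(flipped$ssr_percent, both$ssr_percent)
  expect_equal(flipped$isolated_count, both$isolated_count)
  # identity on a single report
  solo <- combined_report(list(r4))
  expect_equal(solo$ssr_percent, r4$ssr_percent)
  expect_equal(solo$theoretical_space, r4$theoretical_space)
})

test_that("SSR is monotone in the isolated count", {
  ssrs <- vapply(0:20, function(k) {
    compute_ssr(synthesis_outcomes(sprintf("m%d", 1:20),
                                   c(rep(TRUE, k), rep(FALSE, 20 - k))),
                rounded = FALSE)
  }, numeric(1))
  expect_true(all(diff(ssrs) > 0))
})

test_that("reports serialize to JSON with exact and rounded SSR", {
  oc <- synthesis_outcomes(sprintf("m%d", 1:4), c(TRUE, TRUE, TRUE, FALSE),
                           c(40, 60, NA, NA))
  js <- report_json(library_report(oc, 1000, "t"))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$ssr_percent, 75)
  expect_equal(parsed$isolated_count, 3)
  expect_match(parsed$yield_basis, "isolated")
})
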