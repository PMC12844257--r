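test_that("theoretical space is the product of set sizes", {
  expect_equal(count_theoretical(c(83, 8, 95)), 63080)
  expect_equal(count_theoretical(c(3, 51, 67)), 10251)
  expect_equal(count_theoretical(c(1, 1, 1)), 1)
  expect_warning(out <- count_theoretical(c(0, 5, 5)), "empty")
  expect_equal(out, 0)
})

test_that("full-factorial enumeration emits one member per combination", {
  bb <- fixture_blocks()
  d <- library_design("4", bb$azides[1:2], bb$alkynes[1:2], bb$acids[1:2])
  mem <- enumerate_library(d, planned_only = FALSE)
  expect_equal(nrow(mem), 8L)
  expect_equal(count_theoretical(d), 8L)
  expect_length(unique(mem$member_id), 8L)
  expect_true(all(mem$status == "ok"))
  expect_true(all(grepl("^4\\{\\d+,\\d+,\\d+\\}$", mem$member_id)))
})

test_that("planned lists restrict enumeration and keep order", {
  bb <- fixture_blocks()
  pl <- data.frame(i = c(1, 2), j = c(1, 1), k = c(1, 3))
  d <- library_design("4", bb$azides[1:2], bb$alkynes[1:2], bb$acids[1:3],
                      planned = pl)
  mem <- enumerate_library(d)
  expect_equal(nrow(mem), 2L)
  expect_equal(mem$member_id, c("4{1,1,1}", "4{2,1,3}"))
})

test_that("planned triples with unknown labels are rejected", {
  bb <- fixture_blocks()
  expect_error(
    library_design("4", bb$azides[1:2], bb$alkynes[1:2], bb$acids[1:2],
                   planned = data.frame(i = 9, j = 1, k = 1)),
    "labels")
})

test_that("identical building blocks produce duplicate-flagged members", {
  bb <- fixture_blocks()
  az2 <- bb$azides[[1]]
  az2$index <- 2L   # same structure, different label
  d <- library_design("4", list(bb$azides[[1]], az2), bb$alkynes[1],
                      bb$acids[1])
  mem <- enumerate_library(d, planned_only = FALSE)
  expect_equal(nrow(mem), 2L)
  expect_equal(mem$product_smiles[1], mem$product_smiles[2])
  expect_equal(sum(mem$duplicate), 1L)
})

test_that("sulfonamide carrier placement is enforced", {
  bb <- fixture_blocks()
  # azides lack sulfonamides, so declaring them the carrier must fail
  expect_error(
    library_design("7", bb$azides[1:2], bb$alkynes[1:2], bb$acids[1:2],
                   sulfonamide_carrier = "azide"),
    "sulfonamide")
})

test_that("products round trip to SDF with member ids in the manifest", {
  bb <- fixture_blocks()
  d <- library_design("4", bb$azides[1], bb$alkynes[1], bb$acids[1:2])
  mem <- enumerate_library(d, planned_only = FALSE)
  sdf <- withr::local_tempfile(fileext = ".sdf")
  csv <- withr::local_tempfile(fileext = ".csv")
  n <- write_products(mem, sdf, csv)
  expect_equal(n, 2L)
  txt <- readLines(sdf)
  expect_equal(sum(txt == "$$$$"), 2L)
  expect_true(any(grepl("member_id", txt)))
  man <- read.csv(csv)
  expect_equal(man$member_id, mem$member_id)
})
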