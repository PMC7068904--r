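test_that("the L9 array matches the reference run order and is balanced", {
  oa <- build_orthogonal_array(3, 3)
  expect_s3_class(oa, "orthogonal_array")
  expect_equal(oa$runs, 9L)
  expect_identical(oa$cells[1, 1:3], c(1L, 1L, 1L))
  expect_identical(oa$cells[2, 1:3], c(1L, 2L, 2L))
  expect_identical(oa$cells[9, 1:3], c(3L, 3L, 2L))
  expect_identical(unname(oa$cells[, 1:3]), unname(reference_triples()))
  for (j in 1:4) {
    expect_identical(tabulate(oa$cells[, j], 3L), rep(3L, 3))
  }
})

test_that("every ordered level pair appears exactly once per L9 column pair", {
  cells <- build_orthogonal_array(3, 4)$cells
  for (j in 1:3) for (k in (j + 1):4) {
    counts <- brute_pair_counts(cells[, j], cells[, k], 3L)
    expect_identical(counts, matrix(1L, 3, 3),
                     info = sprintf("columns (%d,%d)", j, k))
  }
})

test_that("unsupported array sizes error descriptively", {
  expect_error(build_orthogonal_array(2, 3), "supported arrays")
  expect_error(build_orthogonal_array(3, 5), "L9")
})

test_that("orthogonality validation passes the canonical L9 and catches any single-cell perturbation", {
  oa <- build_orthogonal_array(3, 4)
  expect_true(validate_orthogonality(oa)$pass)
  for (r in 1:9) for (j in 1:4) {
    cells <- oa$cells
    cells[r, j] <- cells[r, j] %% 3L + 1L
    rep <- validate_orthogonality(cells)
    expect_false(rep$pass)
    expect_true(j %in% rep$failing_columns)
  }
})

test_that("orthogonality validation passes the 27-run full factorial with pair count 3", {
  des <- full_factorial(tka_factors())
  idx <- design_level_indices(des)
  rep <- validate_orthogonality(idx)
  expect_true(rep$pass)
  for (p in rep$pair_counts) expect_true(all(p$counts == 3L))
  # independent confirmation on one pair
  expect_identical(brute_pair_counts(idx[, 1], idx[, 3], 3L),
                   matrix(3L, 3, 3))
})

test_that("design instantiation decodes labels and angles per the reference runs", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  expect_equal(nrow(des), 9L)
  expect_equal(des$combination[2], "A1B2C2")
  expect_equal(unlist(des[2, c("varus_deg", "slope_deg", "rotation_deg")]),
               c(varus_deg = 0, slope_deg = 2, rotation_deg = 4))
  expect_equal(des$combination[8], "A3B2C1")
  expect_equal(unlist(des[8, c("varus_deg", "slope_deg", "rotation_deg")]),
               c(varus_deg = -3, slope_deg = 2, rotation_deg = 3))
  # full nine triples match the reference fixture's angles
  fx <- fe_reference_responses()
  expect_equal(des$varus_deg, fx$varus_deg)
  expect_equal(des$slope_deg, fx$slope_deg)
  expect_equal(des$rotation_deg, fx$rotation_deg)
  expect_equal(des$combination, fx$combination)
})

test_that("factor/array level mismatches are rejected", {
  bad <- list(factor_spec("varus angle", "A", c(0, 3), column = "varus_deg"))
  expect_error(instantiate_design(build_orthogonal_array(3, 3), bad),
               "levels")
})

test_that("full factorial enumerates the Cartesian product in lexicographic order", {
  expect_equal(nrow(full_factorial(tka_factors())), 27L)
  one <- full_factorial(tka_factors()["A"])
  expect_equal(nrow(one), 3L)
  expect_equal(one$varus_deg, c(0, 3, -3))
  two <- full_factorial(tka_factors()[c("A", "B")])
  idx <- design_level_indices(two)
  expect_equal(nrow(two), 9L)
  expect_identical(brute_pair_counts(idx[, 1], idx[, 2], 3L),
                   matrix(1L, 3, 3))
  # first factor varies slowest
  expect_identical(idx[, 1], rep(1:3, each = 3L))
})

test_that("design tables round-trip through CSV", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(des, path)
  header <- readLines(path, n = 1L)
  expect_equal(header,
               "run_id,combination,varus_deg,slope_deg,rotation_deg")
  back <- read_design(path, factors = tka_factors())
  expect_equal(as.data.frame(back), as.data.frame(des))
})

test_that("malformed combination labels are rejected", {
  f <- tka_factors()
  expect_error(decode_combination(f, "A1B2"), "match factor symbols|malformed")
  expect_error(decode_combination(f, "A1C2B2"), "match factor symbols")
  expect_error(decode_combination(f, "A1B2C9"), "out of range")
  expect_equal(decode_combination(f, "A3B1C2"), c(A = 3L, B = 1L, C = 2L))
})
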