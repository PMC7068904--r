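ref <- fe_reference_responses()

test_that("level means of the reference responses match the published screening table at 2 decimals", {
  K <- level_means(ref)
  expect_equal(unname(round(K$K, 2)), unname(reference_K_2dp()))
  # independent brute-force grouping oracle, full precision
  idx <- design_level_indices(ref)
  expect_equal(unname(K$K), brute_level_means(idx, ref$peak_pressure_mpa),
               tolerance = 1e-14)
})

test_that("level means agree with a brute-force grouping on random balanced designs", {
  set.seed(11)
  des9 <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  des27 <- full_factorial(tka_factors())
  for (des in list(des9, des27)) {
    for (rep in 1:5) {
      y <- stats::runif(nrow(des), 5, 40)
      rt <- response_table(des, y)
      K <- level_means(rt)
      idx <- design_level_indices(rt)
      expect_equal(unname(K$K), brute_level_means(idx, y),
                   tolerance = 1e-12)
      expect_equal(unname(compute_ranges(K)),
                   apply(brute_level_means(idx, y), 1,
                         function(r) max(r) - min(r)),
                   tolerance = 1e-12)
      # grand-mean conservation under balance
      expect_equal(unname(rowMeans(K$K)), rep(mean(y), 3),
                   tolerance = 1e-9)
    }
  }
})

test_that("constant responses give constant level means and zero ranges", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  K <- level_means(response_table(des, rep(10, 9)))
  expect_true(all(K$K == 10))
  expect_equal(unname(compute_ranges(K)), rep(0, 3))
  rr <- optimal_combination(K, "minimize")
  expect_equal(unname(rr$optimal_level), rep(1L, 3))  # lowest-index tie-break
})

test_that("ranges are shift-invariant and scale linearly", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  set.seed(7)
  y <- stats::runif(9, 10, 30)
  R0 <- compute_ranges(level_means(response_table(des, y)))
  expect_equal(compute_ranges(level_means(response_table(des, y + 5))), R0,
               tolerance = 1e-12)
  expect_equal(compute_ranges(level_means(response_table(des, 2.5 * y))),
               2.5 * R0, tolerance = 1e-12)
})

test_that("reference ranges, ranking and optimum reproduce the published analysis", {
  ra <- range_analysis(ref)
  expect_equal(unname(round(ra$ranking$R, 2)), unname(reference_R_2dp()))
  expect_equal(ra$ranking$ranking, c("A", "B", "C"))
  expect_equal(ra$ranking$optimal_combination, "A1B1C2")
  expect_equal(ra$ranking$optimal_angles,
               c(varus_deg = 0, slope_deg = 1, rotation_deg = 4))
})

test_that("factor ranking uses descending range with a stable tie-break", {
  expect_equal(rank_factors(c(A = 6.70, B = 2.36, C = 2.15)),
               c("A", "B", "C"))
  expect_equal(rank_factors(c(A = 1, B = 1, C = 1)), c("A", "B", "C"))
  expect_equal(rank_factors(c(A = 0.5, B = 2.0, C = 1.0)),
               c("B", "C", "A"))
})

test_that("maximizing picks the per-factor argmax levels", {
  # argmax of the reference K matrix: A level 3, B level 2, C level 1
  rr <- optimal_combination(level_means(ref), "maximize")
  expect_equal(rr$optimal_combination, "A3B2C1")
})

test_that("response spread reproduces the published differences", {
  sp <- response_spread(ref)
  expect_equal(sp$spread, 12.63, tolerance = 1e-9)
  sp2 <- response_spread(ref, extra = 16.37)
  expect_equal(sp2$spread, 13.36, tolerance = 1e-9)
  expect_equal(round(sp2$spread_pct, 1), 81.6)
  expect_equal(response_spread(c(5, 5, 5))$spread, 0)
  expect_equal(response_spread(c(5, 5, 5))$spread_pct, 0)
})

test_that("the trend table is one row per factor level and carries the means", {
  K <- level_means(ref)
  tt <- trend_table(K)
  expect_equal(nrow(tt), 9L)
  row <- tt[tt$symbol == "A" & tt$level_value_deg == 0, ]
  expect_equal(round(row$mean_peak_pressure_mpa, 2), 18.85)
  ttc <- trend_table(level_means(response_table(
    instantiate_design(build_orthogonal_array(3, 3), tka_factors()),
    rep(12, 9))))
  expect_true(all(ttc$mean_peak_pressure_mpa == 12))
})

test_that("invalid response tables are rejected", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  expect_error(response_table(des, rep(1, 8)), "one response per run")
  expect_error(response_table(des, c(rep(1, 8), -2)), "finite and > 0")
  expect_error(response_table(des, c(rep(1, 8), NA)), "finite")
  # unbalanced design: duplicate a run
  unb <- des[c(1, 1:9), ]
  attr(unb, "factors") <- attr(des, "factors")
  class(unb) <- class(des)
  expect_error(level_means(response_table(unb, rep(1, 10))), "unbalanced")
})
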