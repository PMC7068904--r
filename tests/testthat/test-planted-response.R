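test_that("the planted bowl returns its base value at the optimum and is symmetric in varus", {
  bowl <- planted_bowl()
  at <- function(v, s, r) {
    planted_response(implant_alignment(v, s, r), bowl)
  }
  expect_equal(at(0, 1, 4), 16.5)
  expect_equal(at(2, 1, 4), at(-2, 1, 4))
  expect_gt(at(0, 2, 4), at(0, 1, 4))
  expect_error(planted_bowl(weights = c(varus = -1, slope = 1,
                                        rotation = 1)),
               "negative curvature")
})

test_that("a noise-free screening recovers the planted optimum and curvature ordering", {
  cfg <- pipeline_config(list(evaluator = "planted"))
  res <- run_pipeline(cfg, out_dir = NULL)
  expect_equal(res$analysis$ranking$optimal_combination, "A1B1C2")
  # recovered influence ordering matches the configured curvature ordering
  w <- cfg$planted$bowl$weights
  expect_equal(res$analysis$ranking$ranking,
               c("A", "B", "C")[order(-w)])
  expect_true(res$verification$best_of_all)
  expect_equal(res$verification$peak_mpa, 16.5)
})

test_that("noise-free recovery holds for any bowl optimum on the level grid", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  f <- tka_factors()
  for (iv in 1:3) for (is in 1:3) for (ir in 1:3) {
    bowl <- planted_bowl(optimum = c(varus_deg = f$A$levels[iv],
                                     slope_deg = f$B$levels[is],
                                     rotation_deg = f$C$levels[ir]))
    rt <- evaluate_design(des, function(a) planted_response(a, bowl))
    rr <- optimal_combination(level_means(rt))
    expect_equal(unname(rr$optimal_level), c(iv, is, ir),
                 info = sprintf("optimum at levels (%d,%d,%d)", iv, is, ir))
  }
})

test_that("noise requires an explicit seed", {
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  expect_error(
    evaluate_design(des, function(a) planted_response(a),
                    noise_sd_mpa = 0.5),
    "seed")
})
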