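test_that("foundation modulus follows the bonded-layer formula", {
  k <- foundation_modulus(list(E_mpa = 685, nu = 0.4), 9)
  expect_equal(k, 685 * 0.6 / (1.4 * 0.2 * 9), tolerance = 1e-12)
  expect_equal(round(k, 3), 163.095)
  expect_equal(foundation_modulus(list(E_mpa = 100, nu = 0), 4), 25)
  expect_equal(foundation_modulus(list(E_mpa = 685, nu = 0.4), 18), k / 2)
  expect_error(foundation_modulus(list(E_mpa = 685, nu = 0.5), 9),
               "unsupported material")
  expect_error(foundation_modulus(list(E_mpa = 685, nu = 0.4), 0), "> 0")
})

test_that("ligament tension is zero at and below reference, increasing and convex above", {
  lig <- ligament_spec("lateral", 6.06, prestretch = 1)
  expect_equal(ligament_tension(lig, 1), 0)
  expect_equal(ligament_tension(lig, 0.9), 0)
  lam <- seq(1.001, 1.2, by = 0.001)
  f <- ligament_tension(lig, lam)
  expect_true(all(diff(f) > 0))
  # the Cauchy stress sigma = f * lambda / A0 is strictly convex above lambda = 1
  sigma <- f * lam / lig$ref_area_mm2
  expect_true(all(diff(diff(sigma)) > 0))
  expect_error(ligament_tension(lig, 0), "stretch")
})

test_that("ligament tangent modulus at reference stretch equals 6 C1", {
  for (c1 in c(6.06, 6.43)) {
    lig <- ligament_spec("medial", c1, prestretch = 1)
    # independent finite-difference oracle on the Cauchy stress
    # sigma = force * lambda / A0
    h <- 1e-7
    sigma <- function(l) ligament_tension(lig, l) * l / lig$ref_area_mm2
    tangent <- (sigma(1 + h) - sigma(1)) / h
    expect_equal(tangent, 6 * c1, tolerance = 1e-5)
  }
  expect_equal(6 * 6.06, 36.36)
})

test_that("single-condyle flat-foundation solve matches the closed form within 1%", {
  k <- foundation_modulus(default_materials()$polyethylene_liner, 9)
  R <- 30; F <- 1150
  sol <- solve_equilibrium(oracle_geometry(0.25),
                           implant_alignment(0, 0, 0, inherent_slope_deg = 0),
                           ligaments = NULL, load = load_case(F),
                           control = solver_control(tilt_dofs = FALSE))
  delta <- sol$state$settlement_mm
  # closed form: F = pi k R delta^2, peak = k delta
  expect_lt(abs(pi * k * R * delta^2 - F) / F, 0.01)
  delta_analytic <- sqrt(F / (pi * k * R))
  expect_lt(abs(peak_pressure(sol$map)$value - k * delta_analytic) /
              (k * delta_analytic), 0.01)
  # discretization error decreases with refinement
  sol2 <- solve_equilibrium(oracle_geometry(0.5),
                            implant_alignment(0, 0, 0,
                                              inherent_slope_deg = 0),
                            ligaments = NULL, load = load_case(F),
                            control = solver_control(tilt_dofs = FALSE))
  err <- function(s) abs(pi * k * R * s$state$settlement_mm^2 - F)
  expect_lt(err(sol), err(sol2) + 1e-9)
})

test_that("every converged solve conserves the applied load within 0.5%", {
  geom <- articular_geometry()
  des <- instantiate_design(build_orthogonal_array(3, 3), tka_factors())
  for (i in seq_len(nrow(des))) {
    al <- implant_alignment(des$varus_deg[i], des$slope_deg[i],
                            des$rotation_deg[i])
    sol <- solve_equilibrium(geom, al)
    total <- sum(sol$map$pressure) * sol$map$cell_area_mm2
    expect_lt(abs(total - 1150) / 1150, 0.005)
    expect_true(all(sol$map$pressure >= 0))
    expect_true(sol$state$converged)
    expect_lt(abs(sol$state$residual_force_n), 0.001 * 1150)
  }
})

test_that("zero misalignment gives equal compartment peaks and a 575/575 N load split", {
  r <- surrogate_response(articular_geometry(),
                          implant_alignment(0, 0, 0, inherent_slope_deg = 0))
  expect_lt(abs(diff(r$compartment_peaks_mpa)) / r$compartment_peaks_mpa[1],
            1e-6)
  expect_lt(abs(r$compartment_loads_n[["medial"]] - 575) / 575, 0.005)
  expect_lt(abs(r$compartment_loads_n[["lateral"]] - 575) / 575, 0.005)
})

test_that("plus/minus varus give mirror-image pressure maps on symmetric geometry", {
  geom <- articular_geometry()
  a <- surrogate_response(geom, implant_alignment(3, 1, 0))
  b <- surrogate_response(geom, implant_alignment(-3, 1, 0))
  # tolerance set by the solver's 0.1% residual stopping rule
  expect_lt(abs(a$peak_mpa - b$peak_mpa) / a$peak_mpa, 1e-3)
  mirrored <- b$map$pressure[rev(seq_len(nrow(b$map$pressure))), ]
  expect_lt(max(abs(a$map$pressure - mirrored)) / a$peak_mpa, 1e-3)
  # compartments swap
  expect_equal(unname(a$compartment_loads_n[["medial"]]),
               unname(b$compartment_loads_n[["lateral"]]),
               tolerance = 1e-3)
})

test_that("medial compartment load increases strictly with varus angle", {
  geom <- articular_geometry()
  med <- vapply(c(-3, 0, 3), function(v) {
    surrogate_response(geom,
                       implant_alignment(v, 1, 4))$compartment_loads_n[["medial"]]
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("the misaligned liner height field has the stated symmetries", {
  geom <- articular_geometry()
  s0 <- liner_surface(geom, implant_alignment(0, 0, 0,
                                              inherent_slope_deg = 0))
  # symmetric geometry: medial and lateral dish apexes at equal height
  apex <- function(s, comp) min(s$z[s$compartment == comp])
  expect_equal(apex(s0, 1L), apex(s0, 2L), tolerance = 1e-12)
  sv <- liner_surface(geom, implant_alignment(3, 0, 0,
                                              inherent_slope_deg = 0))
  sw <- liner_surface(geom, implant_alignment(-3, 0, 0,
                                              inherent_slope_deg = 0))
  expect_equal(sv$z, sw$z[rev(seq_len(nrow(sw$z))), ], tolerance = 1e-12)
  # varus drops the medial side
  expect_lt(apex(sv, 1L), apex(sv, 2L))
  expect_error(implant_alignment(rotation_deg = 90), "15 degrees")
  coarse <- articular_geometry(grid_spacing_mm = 4)
  expect_error(liner_surface(coarse, implant_alignment()), "too coarse")
})

test_that("peak pressure agrees with an exhaustive scan and breaks ties medially", {
  set.seed(42)
  for (rep in 1:10) {
    p <- matrix(stats::runif(20 * 15), 20, 15)
    map <- synthetic_pressure_map(p)
    pk <- peak_pressure(map)
    best <- which(p == max(p), arr.ind = TRUE)[1, ]
    expect_equal(pk$value, max(p))
    expect_equal(pk$x, map$x[best[1]])
    expect_equal(pk$y, map$y[best[2]])
  }
  p1 <- matrix(0, 4, 4); p1[2, 2] <- 3
  expect_equal(peak_pressure(synthetic_pressure_map(p1))$value, 3)
  # exact two-compartment tie resolves medial
  p2 <- matrix(0, 4, 4); p2[1, 2] <- 5; p2[4, 2] <- 5
  comp <- matrix(1L, 4, 4); comp[1:2, ] <- 2L
  pk2 <- peak_pressure(synthetic_pressure_map(p2, compartment = comp))
  expect_equal(pk2$compartment, "medial")
  expect_error(peak_pressure(synthetic_pressure_map(matrix(0, 3, 3))),
               "all-zero")
})

test_that("compartment loads sum to the integrated total and detect empty contact", {
  set.seed(5)
  p <- matrix(stats::runif(12 * 9), 12, 9)
  map <- synthetic_pressure_map(p)
  loads <- compartment_loads(map)
  expect_equal(sum(loads), sum(p) * map$cell_area_mm2, tolerance = 1e-12)
  p[map$compartment == 2L] <- 0
  map2 <- synthetic_pressure_map(p, compartment = map$compartment)
  expect_equal(compartment_loads(map2)[["lateral"]], 0)
})

test_that("pressure maps round-trip bit-exactly through delimited text", {
  r <- surrogate_response(articular_geometry(grid_halfwidth_x_mm = 30,
                                             grid_halfwidth_y_mm = 12),
                          implant_alignment(3, 1, 4))
  path <- withr::local_tempfile(fileext = ".csv")
  export_pressure_map(r$map, path)
  back <- read_pressure_map(path)
  expect_identical(back$pressure, r$map$pressure)
  expect_identical(back$compartment, r$map$compartment)
  expect_equal(back$x, r$map$x)
  expect_equal(back$y, r$map$y)
  expect_equal(back$spacing_mm, r$map$spacing_mm)
  # total load recomputed from the file matches the in-memory value
  expect_equal(sum(back$pressure) * back$cell_area_mm2,
               sum(r$map$pressure) * r$map$cell_area_mm2)
  expect_equal(back$load_n, r$map$load_n)
})
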