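# Brute-force / closed-form oracles kept independent of the implementation.

# Per-factor level means by explicit grouping loops.
brute_level_means <- function(idx, y) {
  m <- max(idx)
  K <- matrix(NA_real_, ncol(idx), m)
  for (j in seq_len(ncol(idx))) {
    for (i in seq_len(m)) {
      acc <- 0; n <- 0L
      for (r in seq_len(nrow(idx))) {
        if (idx[r, j] == i) { acc <- acc + y[r]; n <- n + 1L }
      }
      K[j, i] <- acc / n
    }
  }
  K
}

# Ordered-pair counts for two columns of level indices.
brute_pair_counts <- function(a, b, m) {
  counts <- matrix(0L, m, m)
  for (r in seq_along(a)) counts[a[r], b[r]] <- counts[a[r], b[r]] + 1L
  counts
}

# Level-index triples of the nine reference runs (varus, slope, rotation
# levels in declaration order 0/3/-3, 1/2/3, 3/4/5).
reference_triples <- function() {
  matrix(c(1L, 1L, 1L,  1L, 2L, 2L,  1L, 3L, 3L,
           2L, 1L, 2L,  2L, 2L, 3L,  2L, 3L, 1L,
           3L, 1L, 3L,  3L, 2L, 1L,  3L, 3L, 2L),
         ncol = 3, byrow = TRUE)
}

# Frozen 2-decimal level means / ranges of the packaged reference table
# (recomputed by hand from the nine responses: e.g. factor A level 1 is
# mean(18.99, 17.10, 20.46) = 18.85).
reference_K_2dp <- function() {
  matrix(c(18.85, 22.51, 25.55,
           21.28, 23.64, 21.99,
           23.33, 21.18, 22.41),
         nrow = 3, byrow = TRUE, dimnames = list(c("A", "B", "C"), NULL))
}
reference_R_2dp <- function() c(A = 6.70, B = 2.36, C = 2.15)

# A synthetic pressure map for unit tests of map utilities.
synthetic_pressure_map <- function(pressure, spacing = 0.5,
                                   compartment = NULL) {
  nx <- nrow(pressure); ny <- ncol(pressure)
  if (is.null(compartment)) {
    compartment <- matrix(1L, nx, ny)
    compartment[seq_len(floor(nx / 2)), ] <- 2L
  }
  structure(
    list(x = seq(0, by = spacing, length.out = nx),
         y = seq(0, by = spacing, length.out = ny),
         pressure = pressure, compartment = compartment,
         spacing_mm = spacing, cell_area_mm2 = spacing^2,
         foundation_modulus_mpa_mm = 163.0952,
         friction_coefficient = 0.04,
         load_n = sum(pressure) * spacing^2,
         load_offset_mm = c(x = 0, y = 0)),
    class = "pressure_map")
}

# Geometry variants used across solver tests.
oracle_geometry <- function(spacing = 0.25) {
  articular_geometry(condyle_radius_mm = 30, dish_radius_mm = Inf,
                     conformity_falloff_mm3 = 0,
                     grid_halfwidth_x_mm = 8, grid_halfwidth_y_mm = 8,
                     grid_spacing_mm = spacing, single_compartment = TRUE)
}
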