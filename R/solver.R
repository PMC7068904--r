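#' Solver control parameters
#'
#' @param max_iter Newton iteration cap (default 100).
#' @param tol_rel Relative residual tolerance (default 1e-3): force residual
#'   within `tol_rel * force`, moment residuals within
#'   `tol_rel * force * lever`, `lever` being the compartment offset.
#' @param damping Step-halving factor applied when a Newton step increases
#'   the scaled residual (default 0.5).
#' @param tilt_dofs Solve the varus-valgus and flexion-extension tilt DOFs
#'   (default `TRUE`); `FALSE` restricts equilibrium to vertical settlement
#'   (used for the single-condyle closed-form configuration).
#' @return List of control parameters.
#' @export
solver_control <- function(max_iter = 100, tol_rel = 1e-3, damping = 0.5,
                           tilt_dofs = TRUE) {
  list(max_iter = max_iter, tol_rel = tol_rel, damping = damping,
       tilt_dofs = tilt_dofs)
}

#' Solve the rigid-femur / elastic-foundation equilibrium
#'
#' The polyethylene liner is a bed of springs of foundation modulus
#' `k = E(1-nu) / ((1+nu)(1-2nu) t)` (see [foundation_modulus()]); the
#' femoral component is rigid. Local contact pressure is `p = k * delta`
#' with `delta` the vertical femoro-liner penetration (clamped at zero).
#' A damped Newton iteration finds the femoral settlement and the
#' varus-valgus and flexion-extension tilts such that the integrated
#' contact pressure balances the applied load and the net moments about the
#' load line are balanced by the collateral-ligament tensions. Contact is
#' frictionless (the recorded friction coefficient is metadata; with a
#' purely axial load at 0 degrees flexion, tangential tractions are second
#' order).
#'
#' @param geometry An [articular_geometry()].
#' @param alignment An [implant_alignment()].
#' @param materials Material list as from [default_materials()].
#' @param ligaments List with `medial` and `lateral` [ligament_spec()]s, or
#'   `NULL` for no ligaments.
#' @param load A [load_case()].
#' @param control A [solver_control()] list.
#' @return List with `state` (class `equilibrium_state`: settlement, tilts,
#'   residuals, iteration count, converged flag) and `map` (class
#'   `pressure_map`: the gridded pressure field with compartment labels).
#'   Non-convergence and total lift-off raise errors.
#' @export
solve_equilibrium <- function(geometry, alignment,
                              materials = default_materials(),
                              ligaments = default_ligaments(),
                              load = load_case(),
                              control = solver_control()) {
  stopifnot(inherits(geometry, "articular_geometry"),
            inherits(alignment, "implant_alignment"),
            inherits(load, "load_case"))
  k <- foundation_modulus(materials$polyethylene_liner,
                          geometry$liner_thickness_mm)
  surf <- liner_surface(geometry, alignment)
  zf <- .femoral_surface(geometry, surf$x, surf$y)
  area <- geometry$grid_spacing_mm^2

  X <- matrix(surf$x, length(surf$x), length(surf$y))
  Y <- matrix(surf$y, length(surf$x), length(surf$y), byrow = TRUE)
  gap <- zf - surf$z
  # conformity falloff: extra gap growing quartically from the dwell point
  c4 <- geometry$conformity_falloff_mm3
  if (c4 > 0) {
    d2 <- (X - surf$dwell[surf$compartment, "x"])^2 +
      (Y - surf$dwell[surf$compartment, "y"])^2
    gap <- gap + c4 * d2^2
  }
  ok <- is.finite(gap)
  if (!any(ok)) stop("load cannot be equilibrated: no femoro-liner overlap",
                     call. = FALSE)
  xc <- X[ok]; yc <- Y[ok]; g0 <- gap[ok]

  F <- load$force_n
  x_off <- load$ml_lever_mm * sin(.deg2rad(alignment$varus_deg))
  y_off <- -load$ap_lever_mm * sin(.deg2rad(alignment$effective_slope_deg))
  lever <- max(geometry$compartment_offset_mm, 10)
  tol <- c(control$tol_rel * F, control$tol_rel * F * lever,
           control$tol_rel * F * lever)

  lig_force <- function(u, alpha) {
    if (is.null(ligaments)) return(c(m = 0, l = 0, am = 0, al = 0))
    lm <- ligaments$medial; ll <- ligaments$lateral
    lam_m <- lm$prestretch - (u + alpha * lm$lever_arm_mm) / lm$ref_length_mm
    lam_l <- ll$prestretch - (u - alpha * ll$lever_arm_mm) / ll$ref_length_mm
    c(m = ligament_tension(lm, max(lam_m, 1e-6)),
      l = ligament_tension(ll, max(lam_l, 1e-6)),
      am = lm$lever_arm_mm, al = ll$lever_arm_mm)
  }

  residual <- function(q) {
    delta <- q[1] + q[2] * xc + q[3] * yc - g0
    p <- k * pmax(delta, 0)
    C <- sum(p) * area
    lig <- lig_force(q[1], q[2])
    c(C - F - lig["m"] - lig["l"],
      sum(p * xc) * area - lig["am"] * lig["m"] + lig["al"] * lig["l"] -
        F * x_off,
      sum(p * yc) * area - F * y_off)
  }
  scaled_norm <- function(r) max(abs(r) / tol)

  free <- if (control$tilt_dofs) 1:3 else 1L
  q <- c(min(g0) + 0.05, 0, 0)
  r <- residual(q)
  iter <- 0L
  steps <- c(1e-4, 1e-5, 1e-5)
  while (scaled_norm(r) > 1 && iter < control$max_iter) {
    iter <- iter + 1L
    J <- matrix(0, 3, 3)
    for (j in free) {
      qj <- q; qj[j] <- qj[j] + steps[j]
      J[, j] <- (residual(qj) - r) / steps[j]
    }
    dq <- numeric(3)
    sol <- tryCatch(solve(J[free, free, drop = FALSE], -r[free]),
                    error = function(e) NULL)
    if (is.null(sol)) {  # singular: no contact, push the femur down
      dq[1] <- 0.05
    } else dq[free] <- sol
    step <- 1
    repeat {
      r_new <- residual(q + step * dq)
      if (scaled_norm(r_new) < scaled_norm(r) || step < 1e-6) break
      step <- step * control$damping
    }
    q <- q + step * dq
    r <- r_new
  }
  converged <- scaled_norm(r) <= 1
  if (!converged) {
    stop(sprintf(
      "equilibrium solve did not converge in %d iterations (residuals: force %.3g N, moments %.3g / %.3g N mm)",
      control$max_iter, r[1], r[2], r[3]), call. = FALSE)
  }

  delta <- q[1] + q[2] * xc + q[3] * yc - g0
  p_cells <- k * pmax(delta, 0)
  if (sum(p_cells) == 0) {
    stop("load cannot be equilibrated: both compartments lifted off",
         call. = FALSE)
  }
  pressure <- matrix(0, length(surf$x), length(surf$y))
  pressure[ok] <- p_cells

  state <- structure(
    list(settlement_mm = q[1], vv_tilt_rad = q[2], fe_tilt_rad = q[3],
         residual_force_n = r[1], residual_moments_nmm = r[2:3],
         iterations = iter, converged = TRUE),
    class = "equilibrium_state")
  map <- structure(
    list(x = surf$x, y = surf$y, pressure = pressure,
         compartment = surf$compartment,
         spacing_mm = geometry$grid_spacing_mm, cell_area_mm2 = area,
         foundation_modulus_mpa_mm = k,
         friction_coefficient = materials$friction_coefficient,
         load_n = F, load_offset_mm = c(x = x_off, y = y_off)),
    class = "pressure_map")
  list(state = state, map = map)
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf(
    "<equilibrium_state> settlement %.4f mm, vv tilt %.5f rad, fe tilt %.5f rad; %d iterations, residual force %.3g N\n",
    x$settlement_mm, x$vv_tilt_rad, x$fe_tilt_rad, x$iterations,
    x$residual_force_n))
  invisible(x)
}

#' @export
print.pressure_map <- function(x, ...) {
  loads <- compartment_loads(x)
  pk <- peak_pressure(x)
  cat(sprintf(
    "<pressure_map> %d x %d grid @ %.2g mm; peak %.2f MPa (%s); loads medial %.1f N, lateral %.1f N\n",
    length(x$x), length(x$y), x$spacing_mm, pk$value, pk$compartment,
    loads["medial"], loads["lateral"]))
  invisible(x)
}

#' Peak contact pressure of a pressure map
#'
#' Maximum cell pressure with its compartment and grid location. When the
#' maximum is attained in both compartments (exact tie), the medial
#' compartment is reported.
#'
#' @param map A `pressure_map`.
#' @return List with `value` (MPa), `compartment` (`"medial"`/`"lateral"`),
#'   and `x`, `y` (mm).
#' @export
peak_pressure <- function(map) {
  stopifnot(inherits(map, "pressure_map"))
  vmax <- max(map$pressure)
  if (vmax <= 0) stop("all-zero pressure map", call. = FALSE)
  hits <- which(map$pressure == vmax, arr.ind = TRUE)
  comp <- map$compartment[hits]
  ord <- order(comp, hits[, 1], hits[, 2])  # medial first, then grid order
  best <- hits[ord[1], , drop = TRUE]
  list(value = vmax,
       compartment = c("medial", "lateral")[map$compartment[best[1], best[2]]],
       x = map$x[best[1]], y = map$y[best[2]])
}

#' Per-compartment contact loads
#'
#' @param map A `pressure_map`.
#' @return Named numeric `c(medial =, lateral =)` in N; the two sum to the
#'   integrated total load.
#' @export
compartment_loads <- function(map) {
  stopifnot(inherits(map, "pressure_map"))
  med <- sum(map$pressure[map$compartment == 1L]) * map$cell_area_mm2
  lat <- sum(map$pressure[map$compartment == 2L]) * map$cell_area_mm2
  c(medial = med, lateral = lat)
}

#' Export / read a pressure map as delimited text
#'
#' Long-format CSV (`x_mm,y_mm,pressure_mpa,compartment`) preceded by
#' `#`-prefixed metadata lines (grid origin, spacing, dimensions, units).
#' Values are written with 17 significant digits so a round trip is
#' bit-exact.
#'
#' @param map A `pressure_map`.
#' @param path Output file path.
#' @return `export_pressure_map` returns `path` invisibly;
#'   `read_pressure_map` returns a `pressure_map`.
#' @export
export_pressure_map <- function(map, path) {
  stopifnot(inherits(map, "pressure_map"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(
    sprintf("# origin_x_mm=%.17g", map$x[1]),
    sprintf("# origin_y_mm=%.17g", map$y[1]),
    sprintf("# spacing_mm=%.17g", map$spacing_mm),
    sprintf("# nx=%d", length(map$x)),
    sprintf("# ny=%d", length(map$y)),
    sprintf("# load_n=%.17g", map$load_n),
    sprintf("# foundation_modulus_mpa_mm=%.17g",
            map$foundation_modulus_mpa_mm),
    "# units=pressure:MPa,length:mm"
  )
  writeLines(meta, con)
  writeLines("x_mm,y_mm,pressure_mpa,compartment", con)
  idx <- which(array(TRUE, dim(map$pressure)), arr.ind = TRUE)
  writeLines(sprintf("%.17g,%.17g,%.17g,%d",
                     map$x[idx[, 1]], map$y[idx[, 2]],
                     map$pressure[idx], map$compartment[idx]), con)
  invisible(path)
}

#' @rdname export_pressure_map
#' @export
read_pressure_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^# *", "", meta_lines)
  kv <- kv[grepl("=", kv)]
  meta <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE)
  nx <- as.integer(meta["nx"]); ny <- as.integer(meta["ny"])
  h <- as.numeric(meta["spacing_mm"])
  x <- as.numeric(meta["origin_x_mm"]) + h * (seq_len(nx) - 1L)
  y <- as.numeric(meta["origin_y_mm"]) + h * (seq_len(ny) - 1L)
  pressure <- matrix(df$pressure_mpa, nx, ny)
  compartment <- matrix(as.integer(df$compartment), nx, ny)
  structure(
    list(x = x, y = y, pressure = pressure, compartment = compartment,
         spacing_mm = h, cell_area_mm2 = h^2,
         foundation_modulus_mpa_mm =
           as.numeric(meta["foundation_modulus_mpa_mm"]),
         friction_coefficient = NA_real_,
         load_n = as.numeric(meta["load_n"]),
         load_offset_mm = c(x = NA_real_, y = NA_real_)),
    class = "pressure_map")
}

#' Peak contact pressure for one alignment (surrogate evaluation)
#'
#' Convenience wrapper: solve the equilibrium and return the peak pressure
#' and derived summaries for a single alignment.
#'
#' @inheritParams solve_equilibrium
#' @return List with `peak_mpa`, `peak_compartment`, `compartment_loads_n`,
#'   `compartment_peaks_mpa`, `state`, and `map`.
#' @export
surrogate_response <- function(geometry, alignment,
                               materials = default_materials(),
                               ligaments = default_ligaments(),
                               load = load_case(),
                               control = solver_control()) {
  sol <- solve_equilibrium(geometry, alignment, materials, ligaments, load,
                           control)
  pk <- peak_pressure(sol$map)
  peaks <- c(
    medial = if (any(sol$map$compartment == 1L))
      max(sol$map$pressure[sol$map$compartment == 1L]) else 0,
    lateral = if (any(sol$map$compartment == 2L))
      max(sol$map$pressure[sol$map$compartment == 2L]) else 0)
  list(peak_mpa = pk$value, peak_compartment = pk$compartment,
       compartment_loads_n = compartment_loads(sol$map),
       compartment_peaks_mpa = peaks,
       state = sol$state, map = sol$map)
}
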