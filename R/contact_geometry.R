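.deg2rad <- function(d) d * pi / 180

#' Tibial-component alignment
#'
#' The three implantation angles plus the component's built-in posterior
#' slope. The slope the femur actually articulates against is
#' `effective_slope_deg = cut_slope_deg + inherent_slope_deg`; the screening
#' factors address the *cut* slope.
#'
#' @param varus_deg Coronal tilt, varus positive (medial side drops), valgus
#'   negative.
#' @param cut_slope_deg Posterior slope of the tibial cut, degrees.
#' @param rotation_deg External rotation of the tray, degrees (positive =
#'   external; the medial side moves anteriorly on a right knee).
#' @param inherent_slope_deg Component's built-in posterior slope, degrees
#'   (default 3).
#' @return An object of class `implant_alignment` with the four input angles
#'   and the derived `effective_slope_deg`.
#' @export
implant_alignment <- function(varus_deg = 0, cut_slope_deg = 0,
                              rotation_deg = 0, inherent_slope_deg = 3) {
  angs <- c(varus_deg = varus_deg, cut_slope_deg = cut_slope_deg,
            rotation_deg = rotation_deg,
            inherent_slope_deg = inherent_slope_deg)
  if (any(!is.finite(angs))) stop("alignment angles must be finite",
                                  call. = FALSE)
  eff <- cut_slope_deg + inherent_slope_deg
  if (any(abs(c(angs, eff)) >= 15)) {
    stop("alignment angles must satisfy |angle| < 15 degrees ",
         "(got ", paste(sprintf("%s=%g", names(angs), angs), collapse = ", "),
         ")", call. = FALSE)
  }
  structure(as.list(c(angs, effective_slope_deg = eff)),
            class = "implant_alignment")
}

#' @export
print.implant_alignment <- function(x, ...) {
  cat(sprintf(
    "<implant_alignment> varus %g, cut slope %g (+%g inherent = %g effective), external rotation %g deg\n",
    x$varus_deg, x$cut_slope_deg, x$inherent_slope_deg,
    x$effective_slope_deg, x$rotation_deg))
  invisible(x)
}

# Right-handed rotation matrices; frame: X medial(+)/lateral, Y anterior(+),
# Z proximal(+). Varus = rotation about Y that drops +X; posterior slope =
# rotation about X that drops -Y; external rotation = rotation about Z that
# moves +X anteriorly.
.rot_x <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE)
}
.rot_y <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE)
}
.rot_z <- function(a) {
  c_ <- cos(a); s <- sin(a)
  matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Alignment rotation matrix
#'
#' Extrinsic rotations about the tray centre applied in order: external
#' rotation about Z, effective posterior slope about X, varus-valgus about
#' Y (`M = Ry(varus) Rx(slope) Rz(rotation)`).
#'
#' @param alignment An [implant_alignment()].
#' @return 3x3 rotation matrix mapping component-frame points to the fixed
#'   femoral frame.
#' @export
alignment_matrix <- function(alignment) {
  stopifnot(inherits(alignment, "implant_alignment"))
  .rot_y(.deg2rad(alignment$varus_deg)) %*%
    .rot_x(.deg2rad(alignment$effective_slope_deg)) %*%
    .rot_z(.deg2rad(alignment$rotation_deg))
}

#' Articular geometry of the condyle-on-liner contact
#'
#' An idealized symmetric articulation: two spherical femoral condyles
#' (radius `condyle_radius_mm`) seated in two spherical liner dishes (radius
#' `dish_radius_mm` > condyle radius) centred at `+/- compartment_offset_mm`
#' on the medial-lateral axis, with a flat plateau between/around the dishes
#' at `plateau_height_mm` above the dish bottoms. `dish_radius_mm = Inf`
#' gives a flat liner (used with `single_compartment = TRUE` for closed-form
#' checks). `conformity_falloff_mm3` adds an extra femoro-liner gap
#' `c4 * d^4` with `d` the distance from the dish dwell point, emulating the
#' loss of conformity of real inserts away from the dwell point; set it to 0
#' for an ideally spherical dish.
#'
#' These dimensions are illustrative defaults, not vendor geometry; all are
#' overridable.
#'
#' @param condyle_radius_mm Femoral condyle radius (default 30).
#' @param dish_radius_mm Liner dish radius (default 45); may be `Inf`.
#' @param compartment_offset_mm Medial-lateral distance from the tray centre
#'   to each dish centre (default 24).
#' @param liner_thickness_mm Polyethylene liner thickness (default 9).
#' @param plateau_height_mm Height of the inter-dish plateau above the dish
#'   bottoms (default 2.5).
#' @param conformity_falloff_mm3 Quartic gap coefficient, 1/mm^3 (default
#'   2e-5).
#' @param grid_halfwidth_x_mm,grid_halfwidth_y_mm Half-extents of the
#'   pressure grid (defaults 40 and 20).
#' @param grid_spacing_mm Grid spacing (default 0.5).
#' @param single_compartment If `TRUE`, a single condyle/dish pair at the
#'   tray centre (closed-form test configuration).
#' @return An object of class `articular_geometry`.
#' @export
articular_geometry <- function(condyle_radius_mm = 30, dish_radius_mm = 45,
                               compartment_offset_mm = 24,
                               liner_thickness_mm = 9,
                               plateau_height_mm = 2.5,
                               conformity_falloff_mm3 = 2e-5,
                               grid_halfwidth_x_mm = 40,
                               grid_halfwidth_y_mm = 20,
                               grid_spacing_mm = 0.5,
                               single_compartment = FALSE) {
  if (!(condyle_radius_mm > 0) || !(dish_radius_mm > condyle_radius_mm)) {
    stop("need dish_radius_mm > condyle_radius_mm > 0", call. = FALSE)
  }
  if (!(liner_thickness_mm > 0)) stop("liner thickness must be > 0",
                                      call. = FALSE)
  if (!(grid_spacing_mm > 0) || !(plateau_height_mm > 0)) {
    stop("grid spacing and plateau height must be > 0", call. = FALSE)
  }
  if (conformity_falloff_mm3 < 0) {
    stop("conformity_falloff_mm3 must be >= 0", call. = FALSE)
  }
  centers <- if (single_compartment) {
    matrix(c(0, 0), 1, 2, dimnames = list("medial", c("x", "y")))
  } else {
    matrix(c(compartment_offset_mm, 0, -compartment_offset_mm, 0),
           2, 2, byrow = TRUE,
           dimnames = list(c("medial", "lateral"), c("x", "y")))
  }
  structure(
    list(condyle_radius_mm = condyle_radius_mm,
         dish_radius_mm = dish_radius_mm,
         compartment_offset_mm = compartment_offset_mm,
         liner_thickness_mm = liner_thickness_mm,
         plateau_height_mm = plateau_height_mm,
         conformity_falloff_mm3 = conformity_falloff_mm3,
         grid_halfwidth_x_mm = grid_halfwidth_x_mm,
         grid_halfwidth_y_mm = grid_halfwidth_y_mm,
         grid_spacing_mm = grid_spacing_mm,
         centers = centers,
         single_compartment = single_compartment),
    class = "articular_geometry"
  )
}

#' Component material properties
#'
#' Elastic modulus (MPa) and Poisson ratio per component, plus the articular
#' friction coefficient (0.04), which the frictionless surrogate records as
#' metadata only.
#'
#' @return Named list of `list(E_mpa, nu)` entries (`cortical_bone`,
#'   `cancellous_bone`, `femoral_component`, `tibial_component`,
#'   `polyethylene_liner`, `bone_cement`) plus `friction_coefficient`.
#' @export
default_materials <- function() {
  list(
    cortical_bone      = list(E_mpa = 16600,  nu = 0.3),
    cancellous_bone    = list(E_mpa = 2400,   nu = 0.3),
    femoral_component  = list(E_mpa = 210000, nu = 0.3),
    tibial_component   = list(E_mpa = 117000, nu = 0.3),
    polyethylene_liner = list(E_mpa = 685,    nu = 0.4),
    bone_cement        = list(E_mpa = 3000,   nu = 0.3),
    friction_coefficient = 0.04
  )
}

#' Elastic-foundation modulus of a bonded layer
#'
#' Stiffness (pressure per unit penetration) of a thin elastic layer bonded
#' to a rigid backing: `k = E (1 - nu) / ((1 + nu) (1 - 2 nu) t)`. This is
#' the confined (oedometric) modulus divided by the layer thickness.
#'
#' @param material A `list(E_mpa, nu)` entry, e.g. from
#'   [default_materials()].
#' @param thickness_mm Layer thickness in mm.
#' @return Foundation modulus in MPa/mm.
#' @export
#' @examples
#' foundation_modulus(default_materials()$polyethylene_liner, 9)
foundation_modulus <- function(material, thickness_mm) {
  E <- material$E_mpa; nu <- material$nu
  stopifnot(is.numeric(E), is.numeric(nu), E > 0)
  if (!(thickness_mm > 0)) stop("thickness must be > 0", call. = FALSE)
  if (nu < 0 || nu >= 0.5) {
    stop("unsupported material: need 0 <= nu < 0.5 (nu = 0.5 means an ",
         "incompressible layer with infinite confined stiffness)",
         call. = FALSE)
  }
  E * (1 - nu) / ((1 + nu) * (1 - 2 * nu) * thickness_mm)
}

#' Collateral ligament specification
#'
#' A point-to-point uniaxial incompressible Neo-Hookean spring standing in
#' for a collateral ligament: initial shear modulus `C1`, reference length
#' and cross-section, and the medial-lateral lever arm of its attachment
#' from the tray centre. Reference dimensions are placeholders (the
#' anatomical values are not part of the model's inputs) and are
#' configuration-overridable.
#'
#' @param side `"medial"` or `"lateral"`.
#' @param c1_mpa Initial shear modulus C1 (MPa).
#' @param ref_length_mm Reference (slack) length L0 (default 60).
#' @param ref_area_mm2 Reference cross-section A0 (default 30).
#' @param lever_arm_mm Attachment lever arm from the tray centre (default
#'   35); the medial ligament attaches at `+lever`, the lateral at `-lever`.
#' @param prestretch Stretch at the neutral assembled position (default
#'   0.95, i.e. 5 percent slack, mirroring the passive varus-valgus laxity
#'   of an extended knee: the collaterals engage only under appreciable
#'   tilt and do not add compression across the articulation in routine
#'   equilibria).
#' @return An object of class `ligament_spec`.
#' @export
ligament_spec <- function(side = c("medial", "lateral"), c1_mpa,
                          ref_length_mm = 60, ref_area_mm2 = 30,
                          lever_arm_mm = 35, prestretch = 0.95) {
  side <- match.arg(side)
  if (!(c1_mpa > 0) || !(ref_length_mm > 0) || !(ref_area_mm2 > 0)) {
    stop("C1, reference length and reference area must be > 0",
         call. = FALSE)
  }
  structure(list(side = side, c1_mpa = c1_mpa,
                 ref_length_mm = ref_length_mm,
                 ref_area_mm2 = ref_area_mm2,
                 lever_arm_mm = lever_arm_mm, prestretch = prestretch),
            class = "ligament_spec")
}

#' Default collateral ligament pair
#'
#' Medial C1 = 6.43 MPa, lateral C1 = 6.06 MPa.
#'
#' @return List with elements `medial` and `lateral`.
#' @export
default_ligaments <- function() {
  list(medial = ligament_spec("medial", 6.43),
       lateral = ligament_spec("lateral", 6.06))
}

#' Axial tension of a Neo-Hookean ligament spring
#'
#' Uniaxial incompressible Neo-Hookean Cauchy stress
#' `sigma = 2 C1 (lambda^2 - 1/lambda)`; the tensile force on the current
#' cross-section `A0 / lambda` is `sigma A0 / lambda` for `lambda >= 1` and
#' zero below (ligaments carry no compression). The tangent stiffness
#' `d sigma / d lambda` at `lambda = 1` is `6 C1`.
#'
#' @param spec A [ligament_spec()].
#' @param stretch Stretch ratio `lambda > 0` (may be a vector).
#' @return Axial force in N (0 when slack).
#' @export
ligament_tension <- function(spec, stretch) {
  stopifnot(inherits(spec, "ligament_spec"))
  if (any(stretch <= 0)) stop("stretch must be > 0", call. = FALSE)
  sigma <- 2 * spec$c1_mpa * (stretch^2 - 1 / stretch)
  force <- sigma * spec$ref_area_mm2 / stretch
  ifelse(stretch >= 1, force, 0)
}

#' Axial load case
#'
#' A vertical compressive load (default 1150 N, about twice body weight)
#' at 0 degrees flexion, applied along the limb mechanical axis. Component
#' malalignment deviates that axis from the tray centre: varus shifts the
#' load line medially by `ml_lever_mm * sin(varus)`, posterior slope shifts
#' it posteriorly by `ap_lever_mm * sin(effective slope)`. The levers are
#' reduced-order stand-ins for the limb geometry above and below the joint
#' and are configuration-overridable.
#'
#' @param force_n Axial compressive force in N (default 1150).
#' @param flexion_deg Flexion angle; only 0 is supported.
#' @param ml_lever_mm Medial-lateral mechanical-axis lever (default 100).
#' @param ap_lever_mm Anterior-posterior mechanical-axis lever (default 50).
#' @return An object of class `load_case`.
#' @export
load_case <- function(force_n = 1150, flexion_deg = 0,
                      ml_lever_mm = 100, ap_lever_mm = 50) {
  if (!(force_n > 0)) stop("force must be > 0", call. = FALSE)
  if (flexion_deg != 0) {
    stop("only the 0-degree flexion load case is supported", call. = FALSE)
  }
  structure(list(force_n = force_n, flexion_deg = 0,
                 ml_lever_mm = ml_lever_mm, ap_lever_mm = ap_lever_mm),
            class = "load_case")
}

#' Height field of the misaligned liner's upper surface
#'
#' Evaluates the liner's articular surface on a regular grid in the fixed
#' femoral frame after rotating the component (about the tray centre) by,
#' in order: external rotation about Z, effective posterior slope about X,
#' varus-valgus about Y. Spherical dishes transform exactly (a rotated
#' sphere is a sphere); the plateau plane transforms as a plane; the surface
#' is the pointwise minimum of plateau and dishes.
#'
#' @param geometry An [articular_geometry()].
#' @param alignment An [implant_alignment()].
#' @return A list of class `liner_surface` with grid vectors `x`, `y`,
#'   height matrix `z` (mm, `length(x)` x `length(y)`), integer compartment
#'   matrix (1 = medial, 2 = lateral), the transformed dwell points
#'   (`dwell`, one row per compartment), and the rotation matrix `M`.
#' @export
liner_surface <- function(geometry, alignment) {
  stopifnot(inherits(geometry, "articular_geometry"),
            inherits(alignment, "implant_alignment"))
  h <- geometry$grid_spacing_mm
  Rd <- geometry$dish_radius_mm
  p0 <- geometry$plateau_height_mm
  if (is.finite(Rd)) {
    aperture <- 2 * sqrt(Rd^2 - (Rd - p0)^2)
    if (aperture / h < 8) {
      stop("grid too coarse to resolve the dishes: ",
           sprintf("%.1f cells across a %.1f mm aperture (need >= 8)",
                   aperture / h, aperture), call. = FALSE)
    }
  }
  M <- alignment_matrix(alignment)
  x <- seq(-geometry$grid_halfwidth_x_mm, geometry$grid_halfwidth_x_mm,
           by = h)
  y <- seq(-geometry$grid_halfwidth_y_mm, geometry$grid_halfwidth_y_mm,
           by = h)
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)

  # plateau plane through (0, 0, p0) with normal M %*% ez
  n <- M[, 3]
  P0 <- M %*% c(0, 0, p0)
  z_plane <- P0[3] + (n[1] * (P0[1] - X) + n[2] * (P0[2] - Y)) / n[3]

  ncomp <- nrow(geometry$centers)
  dwell <- matrix(NA_real_, ncomp, 3,
                  dimnames = list(rownames(geometry$centers),
                                  c("x", "y", "z")))
  if (is.finite(Rd)) {
    zs <- vector("list", ncomp)
    for (i in seq_len(ncomp)) {
      S <- M %*% c(geometry$centers[i, 1], geometry$centers[i, 2], Rd)
      d2 <- (X - S[1])^2 + (Y - S[2])^2
      zi <- S[3] - sqrt(pmax(Rd^2 - d2, 0))
      zi[d2 >= Rd^2] <- Inf
      zs[[i]] <- zi
      dwell[i, ] <- c(S[1], S[2], S[3] - Rd)  # vertical low point
    }
    if (ncomp == 2L) {
      comp <- ifelse(zs[[2]] < zs[[1]], 2L, 1L)
      z <- pmin(z_plane, zs[[1]], zs[[2]])
    } else {
      comp <- matrix(1L, length(x), length(y))
      z <- pmin(z_plane, zs[[1]])
    }
  } else {
    # flat liner: the (rotated) plane through the origin
    P0f <- M %*% c(0, 0, 0)
    z <- P0f[3] + (n[1] * (P0f[1] - X) + n[2] * (P0f[2] - Y)) / n[3]
    comp <- matrix(1L, length(x), length(y))
    for (i in seq_len(ncomp)) {
      S <- M %*% c(geometry$centers[i, 1], geometry$centers[i, 2], 0)
      dwell[i, ] <- S
    }
    if (ncomp == 2L) comp[X < (dwell[1, 1] + dwell[2, 1]) / 2] <- 2L
  }
  structure(list(x = x, y = y, z = z, compartment = comp, dwell = dwell,
                 M = M, spacing = h),
            class = "liner_surface")
}

# Fixed femoral lower surface on the same grid: spherical condyles above the
# compartment centres, bottoms at z = 0 (touching the neutral dish bottoms).
.femoral_surface <- function(geometry, x, y) {
  Rf <- geometry$condyle_radius_mm
  X <- matrix(x, length(x), length(y))
  Y <- matrix(y, length(x), length(y), byrow = TRUE)
  z <- matrix(Inf, length(x), length(y))
  cap2 <- (0.8 * Rf)^2  # restrict to the usable cap, away from the equator
  for (i in seq_len(nrow(geometry$centers))) {
    d2 <- (X - geometry$centers[i, 1])^2 + (Y - geometry$centers[i, 2])^2
    zi <- Rf - sqrt(pmax(Rf^2 - d2, 0))
    zi[d2 > cap2] <- Inf
    z <- pmin(z, zi)
  }
  z
}
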