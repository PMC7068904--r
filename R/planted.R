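#' Planted analytic response bowl
#'
#' A smooth convex response surface with a known optimum, used to exercise
#' the design/analysis pipeline independently of the mechanical solver:
#' `p = base + w_v (varus - v0)^2 + w_s (slope - s0)^2 + w_r (rot - r0)^2`
#' (slope = cut slope). Defaults put the optimum at (0, 1, 4) degrees with
#' curvature weights ordered varus > slope > rotation, so a noise-free
#' screening over the standard levels recovers that combination and
#' influence ordering. Weight magnitudes are sized so the smallest
#' level-mean contrast (rotation, 0.6 MPa) stays clearly above the
#' level-mean noise at few-percent response noise.
#'
#' @param base_mpa Response at the optimum (default 16.5).
#' @param optimum Named numeric `c(varus_deg=, slope_deg=, rotation_deg=)`
#'   (default `c(0, 1, 4)`).
#' @param weights Named non-negative curvatures in MPa/deg^2
#'   (default `c(varus = 1.0, slope = 0.8, rotation = 0.6)`).
#' @return An object of class `planted_bowl`.
#' @export
planted_bowl <- function(base_mpa = 16.5,
                         optimum = c(varus_deg = 0, slope_deg = 1,
                                     rotation_deg = 4),
                         weights = c(varus = 1.0, slope = 0.8,
                                     rotation = 0.6)) {
  optimum <- optimum[c("varus_deg", "slope_deg", "rotation_deg")]
  weights <- weights[c("varus", "slope", "rotation")]
  if (anyNA(optimum) || anyNA(weights)) {
    stop("optimum needs varus_deg/slope_deg/rotation_deg and weights ",
         "varus/slope/rotation entries", call. = FALSE)
  }
  if (!(base_mpa > 0)) stop("base_mpa must be > 0", call. = FALSE)
  if (any(weights < 0)) stop("negative curvature weights", call. = FALSE)
  structure(list(base_mpa = base_mpa, optimum = optimum, weights = weights),
            class = "planted_bowl")
}

#' Evaluate the planted response
#'
#' @param alignment An [implant_alignment()] (the bowl is a function of
#'   varus, *cut* slope and external rotation).
#' @param coeffs A [planted_bowl()].
#' @return Peak contact pressure in MPa (deterministic; see
#'   [evaluate_design()] for seeded noise).
#' @export
planted_response <- function(alignment, coeffs = planted_bowl()) {
  stopifnot(inherits(alignment, "implant_alignment"),
            inherits(coeffs, "planted_bowl"))
  d <- c(alignment$varus_deg, alignment$cut_slope_deg,
         alignment$rotation_deg) - coeffs$optimum
  coeffs$base_mpa + sum(coeffs$weights * d^2)
}
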