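# Paraxial ray-transfer engine.
#
# Rays are (y, alpha) with alpha = n * u (reduced angle). A refraction of
# power P (dioptres) maps alpha' = alpha - P y; a translation over physical
# distance d (mm) in medium n maps y' = y + (d / 1000 / n) alpha. Matrices
# therefore mix units (heights in m internally via the 1/1000 factors) and
# every element has unit determinant. The system matrix composes elements
# front to back; cardinal points follow from the standard identities
# P = -C, pp1 = n_obj (1 - D) / P, pp2 = n_img (A - 1) / P.

paraxial_refraction <- function(power) {
  matrix(c(1, -power, 0, 1), 2, 2)
}

paraxial_translation <- function(d_mm, n_medium) {
  matrix(c(1, 0, d_mm / 1000 / n_medium, 1), 2, 2)
}

#' Build a paraxial system from an ordered element list
#'
#' Elements are applied front to back. Each element is a list with `type`
#' `"refraction"` (fields: `power` in D, or `radius` in mm with `n_before`,
#' `n_after`) or `"gap"` (fields: `d` in mm, `n` refractive index). The
#' object records the physical axial position of the output plane relative
#' to the input plane (gaps accumulate; an optional `z_out` overrides it,
#' used when the last element is a thin equivalent placed between principal
#' planes).
#'
#' @param elements List of element lists, front to back.
#' @param n_object,n_image Refractive indices of object and image space.
#' @param z_out Optional physical position (mm) of the output plane,
#'   measured from the input plane; defaults to the summed gaps.
#' @return An object of class `paraxial_system` with fields `M` (2 x 2
#'   system matrix), `n_object`, `n_image`, `z_out`.
#' @seealso [cardinal_points()]
#' @examples
#' # single thin lens of 10 D in air
#' sys <- paraxial_system(list(list(type = "refraction", power = 10)))
#' cardinal_points(sys)$power
#' @export
paraxial_system <- function(elements, n_object = 1, n_image = 4 / 3,
                            z_out = NULL) {
  M <- diag(2)
  z <- 0
  for (el in elements) {
    if (identical(el$type, "refraction")) {
      p <- el$power
      if (is.null(p)) {
        if (is.infinite(el$radius)) {
          p <- 0
        } else {
          if (el$radius == 0) abort("Zero radius of curvature in paraxial system.")
          p <- 1000 * (el$n_after - el$n_before) / el$radius
        }
      }
      M <- paraxial_refraction(p) %*% M
    } else if (identical(el$type, "gap")) {
      M <- paraxial_translation(el$d, el$n) %*% M
      z <- z + el$d
    } else {
      abort("Unknown paraxial element type.")
    }
  }
  structure(list(M = M, n_object = n_object, n_image = n_image,
                 z_out = z_out %||% z),
            class = "paraxial_system")
}

#' Cardinal points of a paraxial system
#'
#' Equivalent power and the positions of the principal points and back focal
#' point, expressed relative to the front vertex (input plane) of the
#' system, posterior-positive.
#'
#' @param sys A [paraxial_system()].
#' @return A list: `power` (D), `pp1`, `pp2` (mm from the front vertex),
#'   `bfd` (back focal distance from the output plane, mm), `f2` (back focal
#'   length from pp2, mm), `focal_point` (mm from the front vertex).
#' @export
cardinal_points <- function(sys) {
  M <- sys$M
  P <- -M[2, 1]
  if (abs(P) < 1e-12) abort("Afocal system: cardinal points undefined.")
  A <- M[1, 1]
  D <- M[2, 2]
  pp1 <- 1000 * sys$n_object * (1 - D) / P
  pp2 <- sys$z_out + 1000 * sys$n_image * (A - 1) / P
  f2 <- 1000 * sys$n_image / P
  list(power = P, pp1 = pp1, pp2 = pp2,
       bfd = 1000 * sys$n_image * A / P,
       f2 = f2, focal_point = pp2 + f2)
}

# Corneal system: two refracting surfaces separated by the corneal thickness.
corneal_system <- function(r_ca, r_cp, CCT, idx = refractive_indices()) {
  paraxial_system(
    list(
      list(type = "refraction", radius = r_ca,
           n_before = idx$n_air, n_after = idx$n_c),
      list(type = "gap", d = CCT, n = idx$n_c),
      list(type = "refraction", radius = r_cp,
           n_before = idx$n_c, n_after = idx$n)
    ),
    n_object = idx$n_air, n_image = idx$n, z_out = CCT
  )
}

# Whole-eye system: cornea followed by a thin lens of power P_lb placed at
# the lenticular principal points (0.571 LT behind the anterior lens pole
# for the first, 0.378 LT in front of the posterior pole for the second).
# Between lens principal planes the mapping is the bare refraction, so the
# output plane sits physically at ACD_tot + 0.622 LT.
eye_system <- function(r_ca, r_cp, CCT, AD, LT, P_lb,
                       idx = refractive_indices()) {
  ACD_tot <- CCT + AD
  paraxial_system(
    list(
      list(type = "refraction", radius = r_ca,
           n_before = idx$n_air, n_after = idx$n_c),
      list(type = "gap", d = CCT, n = idx$n_c),
      list(type = "refraction", radius = r_cp,
           n_before = idx$n_c, n_after = idx$n),
      list(type = "gap", d = AD + 0.571 * LT, n = idx$n),
      list(type = "refraction", power = P_lb)
    ),
    n_object = idx$n_air, n_image = idx$n,
    z_out = ACD_tot + 0.622 * LT
  )
}

#' Literal tabulated principal-point formulas
#'
#' Evaluates the tabulated closed-form strings for the second corneal and
#' second ocular principal points, which involve index symbols (`n_a`,
#' `n_v`) that the source table leaves undefined, and reports the
#' discrepancy against the normative ray-transfer engine. With
#' `n_a = n` the corneal formula reproduces the engine value referenced to
#' the posterior (not anterior) corneal vertex. Provided for documentation
#' and comparison only; nothing downstream consumes these values.
#'
#' @param r_ca,r_cp,CCT,AD,LT Corneal radii and intraocular distances, mm.
#' @param P_lb Lens power, D.
#' @param n_a,n_v Index values substituted into the literal strings.
#' @param idx [refractive_indices()].
#' @return A tibble comparing literal and engine values (mm, from the
#'   anterior corneal vertex) with their difference.
#' @export
literal_principal_points <- function(r_ca, r_cp, CCT, AD, LT, P_lb,
                                     n_a = NULL, n_v = NULL,
                                     idx = refractive_indices()) {
  n_a <- n_a %||% idx$n_air
  n_v <- n_v %||% idx$n
  cs <- cardinal_points(corneal_system(r_ca, r_cp, CCT, idx))
  es <- cardinal_points(eye_system(r_ca, r_cp, CCT, AD, LT, P_lb, idx))
  P_ca <- 1000 * (idx$n_c - idx$n_air) / r_ca
  ACD_tot <- CCT + AD
  ASL <- ACD_tot + LT
  lit_ppc2 <- -CCT * n_a / idx$n_c * P_ca / cs$power
  lit_ppeye2 <- ASL - (lit_ppc2 + ACD_tot + 0.571 * LT) *
    n_v / n_a * cs$power / es$power
  tibble::tibble(
    quantity = c("pp_c2", "pp_eye2"),
    literal = c(lit_ppc2, lit_ppeye2),
    engine = c(cs$pp2, es$pp2),
    difference = .data$literal - .data$engine
  )
}
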