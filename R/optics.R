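# Vectorised closed-form optics. Each function takes a per-eye tibble and
# appends derived columns. The closed forms are algebraically identical to
# the ray-transfer engine in paraxial.R (asserted to < 1e-9 D in the test
# suite); the engine remains the normative definition of the principal
# points, the closed forms are the cohort-scale implementation.

required_cols <- function(data, cols, fn) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s(): missing column(s): %s",
                  fn, paste(missing, collapse = ", ")))
  }
}

eye_ids <- function(data) {
  if ("eye_id" %in% names(data)) as.character(data$eye_id)
  else as.character(seq_len(nrow(data)))
}

#' Validate raw biometry rows
#'
#' Checks the physical invariants of a raw biometry table: all radii and
#' distances positive, positive vitreous depth (AL > CCT + AD + LT) and
#' |SE| <= `se_limit` (screening rule). Returns a logical vector plus a
#' per-row reason attribute; it never throws.
#'
#' @param data Tibble with columns `SE`, `r_ca`, `r_cp`, `CCT`, `AD`, `LT`,
#'   `AL`.
#' @param se_limit Screening limit on |SE|, dioptres.
#' @return Logical vector (`TRUE` = valid) with attribute `"reason"`
#'   (character, `NA` for valid rows).
#' @export
validate_biometry <- function(data, se_limit = 15) {
  required_cols(data, c("SE", "r_ca", "r_cp", "CCT", "AD", "LT", "AL"),
                "validate_biometry")
  reason <- rep(NA_character_, nrow(data))
  num <- c("SE", "r_ca", "r_cp", "CCT", "AD", "LT", "AL")
  bad_na <- !complete.cases(data[num])
  reason[bad_na] <- "missing value"
  pos <- c("r_ca", "r_cp", "CCT", "AD", "LT", "AL")
  bad_pos <- !bad_na &
    Reduce(`|`, lapply(data[pos], function(x) !is.na(x) & x <= 0))
  reason[bad_pos] <- "non-positive distance or radius"
  bad_vcd <- is.na(reason) &
    (data$AL - (data$CCT + data$AD + data$LT)) <= 0
  reason[bad_vcd] <- "non-positive vitreous depth (AL <= CCT + AD + LT)"
  bad_se <- is.na(reason) & abs(data$SE) > se_limit
  reason[bad_se] <- sprintf("|SE| > %g D screening limit", se_limit)
  ok <- is.na(reason)
  attr(ok, "reason") <- reason
  ok
}

#' Axial distance bookkeeping
#'
#' Appends the composite intraocular distances: total anterior chamber depth
#' `ACD_tot = CCT + AD`, anterior segment length `ASL = ACD_tot + LT` and
#' vitreous chamber depth `VCD = AL - ASL`.
#'
#' @param data Tibble with columns `CCT`, `AD`, `LT`, `AL` (mm).
#' @return The input tibble with `ACD_tot`, `ASL`, `VCD` appended.
#' @examples
#' derive_distances(tibble::tibble(CCT = 0.53, AD = 2.64, LT = 4.25, AL = 23.14))
#' @export
derive_distances <- function(data) {
  required_cols(data, c("CCT", "AD", "LT", "AL"), "derive_distances")
  out <- dplyr::mutate(data,
                       ACD_tot = .data$CCT + .data$AD,
                       ASL = .data$ACD_tot + .data$LT,
                       VCD = .data$AL - .data$ASL)
  bad <- which(!is.na(out$VCD) & out$VCD <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-positive vitreous chamber depth for eye(s): %s",
      paste(head(eye_ids(data)[bad], 10), collapse = ", ")))
  }
  out
}

#' Corneal powers and principal points
#'
#' Appends the anterior and posterior surface powers, the thick-lens total
#' corneal power and the corneal principal points (mm from the anterior
#' corneal vertex, posterior-positive, so `pp_c1`/`pp_c2` are typically
#' slightly negative). A flat posterior surface (`r_cp = Inf`) contributes
#' zero power.
#'
#' @param data Tibble with columns `r_ca`, `r_cp`, `CCT`.
#' @param idx [refractive_indices()].
#' @return Input tibble with `P_ca`, `P_cp`, `P_c`, `pp_c1`, `pp_c2`
#'   appended.
#' @export
corneal_power <- function(data, idx = refractive_indices()) {
  required_cols(data, c("r_ca", "r_cp", "CCT"), "corneal_power")
  if (any(data$r_ca == 0 | data$r_cp == 0, na.rm = TRUE)) {
    abort("Zero corneal radius of curvature; cannot compute surface power.")
  }
  dplyr::mutate(data,
    P_ca = 1000 * (idx$n_c - idx$n_air) / .data$r_ca,
    P_cp = ifelse(is.infinite(.data$r_cp), 0,
                  1000 * (idx$n - idx$n_c) / .data$r_cp),
    P_c = .data$P_ca + .data$P_cp -
      0.001 * .data$P_ca * .data$P_cp * .data$CCT / idx$n_c,
    # matrix-engine closed forms, anterior-vertex origin
    pp_c1 = idx$n_air * .data$CCT * .data$P_cp / (idx$n_c * .data$P_c),
    pp_c2 = .data$CCT - idx$n * .data$CCT * .data$P_ca / (idx$n_c * .data$P_c)
  )
}

# Shared closed-form chain from (P_c, pp_c2, ACD_tot, LT, AL, P_lb) to the
# whole-eye cardinal quantities. Vectorised over eyes and over P_lb.
whole_eye_chain <- function(P_c, pp_c2, ACD_tot, LT, AL, P_lb, idx) {
  d <- ACD_tot + 0.571 * LT - pp_c2      # corneal pp2 -> lens pp1, mm
  P_eye <- P_c + P_lb - 0.001 * P_c * P_lb * d / idx$n
  z_l2 <- ACD_tot + 0.622 * LT
  pp_eye2 <- z_l2 - d * P_c / P_eye
  list(d = d, P_eye = P_eye, pp_eye2 = pp_eye2,
       f_eye2 = 1000 * idx$n / P_eye,
       P_ax = 1000 * idx$n / (AL - pp_eye2))
}

#' Whole-eye power and cardinal points
#'
#' Combines the thick-lens cornea with a thin crystalline lens of power
#' `P_lb` placed between the lenticular principal points (0.571 LT /
#' -0.378 LT), yielding the whole-eye equivalent power, its principal
#' points (mm from the anterior corneal vertex), the back focal length and
#' the back focal point.
#'
#' @param data Tibble with `P_c`, `pp_c1`, `pp_c2`, `ACD_tot`, `LT`, `AL`
#'   and `P_lb` (run [corneal_power()] and [derive_distances()] first, and
#'   supply `P_lb` e.g. from [bennett_lens_power()]).
#' @param idx [refractive_indices()].
#' @return Input tibble with `pp_l1`, `pp_l2`, `P_eye`, `pp_eye1`,
#'   `pp_eye2`, `f_eye2`, `F` appended.
#' @export
eye_cardinal_points <- function(data, idx = refractive_indices()) {
  required_cols(data, c("P_c", "pp_c1", "pp_c2", "ACD_tot", "LT", "AL", "P_lb"),
                "eye_cardinal_points")
  ch <- whole_eye_chain(data$P_c, data$pp_c2, data$ACD_tot, data$LT,
                        data$AL, data$P_lb, idx)
  if (any(ch$P_eye <= 0, na.rm = TRUE)) {
    bad <- which(ch$P_eye <= 0)
    abort(sprintf("Non-converging eye (P_eye <= 0) for eye(s): %s",
                  paste(head(eye_ids(data)[bad], 10), collapse = ", ")))
  }
  # first ocular principal point: pp1 of the two-element combination, i.e.
  # pp_c1 shifted by the front-side effectivity of the lens power
  pp_eye1 <- data$pp_c1 +
    (idx$n_air / idx$n) * ch$d * data$P_lb / ch$P_eye
  dplyr::mutate(data,
                pp_l1 = 0.571 * .data$LT,
                pp_l2 = -0.378 * .data$LT,
                P_eye = ch$P_eye,
                pp_eye1 = pp_eye1,
                pp_eye2 = ch$pp_eye2,
                f_eye2 = ch$f_eye2,
                F = ch$pp_eye2 + ch$f_eye2)
}

#' Axial power and model refraction
#'
#' The axial power is the whole-eye power that would focus a distant object
#' exactly on the retina for the measured axial length,
#' `P_ax = 1000 n / (AL - pp_eye2)`; the model spherical equivalent is the
#' power surplus `SE_model = P_ax - P_eye`.
#'
#' @param data Tibble with `AL`, `pp_eye2`, `P_eye`.
#' @param idx [refractive_indices()].
#' @return Input tibble with `P_ax`, `SE_model` appended.
#' @export
axial_power <- function(data, idx = refractive_indices()) {
  required_cols(data, c("AL", "pp_eye2", "P_eye"), "axial_power")
  if (any(data$AL <= data$pp_eye2, na.rm = TRUE)) {
    bad <- which(data$AL <= data$pp_eye2)
    abort(sprintf("AL <= pp_eye2 for eye(s): %s",
                  paste(head(eye_ids(data)[bad], 10), collapse = ", ")))
  }
  dplyr::mutate(data,
                P_ax = 1000 * idx$n / (.data$AL - .data$pp_eye2),
                SE_model = .data$P_ax - .data$P_eye)
}

#' Bennett crystalline-lens power
#'
#' Estimates the crystalline-lens power from refraction, corneal power and
#' the intraocular distances, with the lens principal points fixed at
#' 0.571 LT / -0.378 LT of the lens thickness. Two methods:
#'
#' * `"eq1-solve"` (default): the unique lens power for which the forward
#'   paraxial model returns `SE_model = SE`, found by monotone bisection on
#'   \[5, 45\] D to |dSE| < 1e-9 D. This guarantees an exact round trip
#'   against the forward model.
#' * `"vergence"`: the classical vergence propagation. The incoming
#'   vergence `SE + P_c` at the second corneal principal point is
#'   propagated over the reduced distance to the first lenticular
#'   principal point; the required outgoing vergence is
#'   `1000 n / (AL - z_l2)` with `z_l2 = ACD_tot + 0.622 LT`; the lens
#'   power is their difference.
#'
#' The two methods reference the refraction at slightly different planes
#' (the forward model at the eye's first principal plane, the vergence
#' chain at the cornea), a second-order difference that grows roughly
#' quadratically with |SE|: they agree within 0.25 D for refractions up
#' to about +-8 D and drift to ~0.7 D at the +-15 D screening limit.
#'
#' The input SE is taken as already referenced to the corneal plane (no
#' vertex correction); set `vertex_mm` to a positive spectacle vertex
#' distance to convert first (off by default and not used by the standard
#' pipeline).
#'
#' @param data Tibble with `SE`, `P_c`, `pp_c2`, `ACD_tot`, `LT`, `AL`.
#' @param idx [refractive_indices()].
#' @param method `"eq1-solve"` or `"vergence"`.
#' @param vertex_mm Optional spectacle vertex distance (mm); 0 disables.
#' @param bracket Search bracket for `"eq1-solve"`, dioptres.
#' @return Input tibble with `P_lb` appended.
#' @export
bennett_lens_power <- function(data, idx = refractive_indices(),
                               method = c("eq1-solve", "vergence"),
                               vertex_mm = 0, bracket = c(5, 45)) {
  method <- match.arg(method)
  required_cols(data, c("SE", "P_c", "pp_c2", "ACD_tot", "LT", "AL"),
                "bennett_lens_power")
  se <- data$SE
  if (vertex_mm > 0) se <- se / (1 - 0.001 * vertex_mm * se)
  if (method == "vergence") {
    d <- data$ACD_tot + 0.571 * data$LT - data$pp_c2
    z_l2 <- data$ACD_tot + 0.622 * data$LT
    denom_ax <- data$AL - z_l2
    if (any(denom_ax <= 0, na.rm = TRUE)) {
      abort("Vergence denominator AL - z_l2 <= 0.")
    }
    V1 <- se + data$P_c
    eff <- 1 - 0.001 * d * V1 / idx$n
    if (any(eff <= 0, na.rm = TRUE)) {
      abort("Vergence effectivity denominator <= 0.")
    }
    P_lb <- 1000 * idx$n / denom_ax - V1 / eff
    return(dplyr::mutate(data, P_lb = P_lb))
  }
  # eq1-solve: SE_model is strictly decreasing in P_lb over the bracket,
  # so 80 bisection halvings pin the root to machine precision.
  f <- function(P_lb) {
    ch <- whole_eye_chain(data$P_c, data$pp_c2, data$ACD_tot, data$LT,
                          data$AL, P_lb, idx)
    ch$P_ax - ch$P_eye - se
  }
  lo <- rep(bracket[1], nrow(data))
  hi <- rep(bracket[2], nrow(data))
  flo <- f(lo)
  fhi <- f(hi)
  no_root <- is.na(flo) | is.na(fhi) | flo * fhi > 0
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    take_lo <- !is.na(fm) & (sign(fm) == sign(flo))
    lo[take_lo] <- mid[take_lo]
    flo[take_lo] <- fm[take_lo]
    hi[!take_lo] <- mid[!take_lo]
  }
  P_lb <- (lo + hi) / 2
  resid <- abs(f(P_lb))
  fail <- no_root | is.na(resid) | resid > 1e-9
  if (any(fail)) {
    abort(sprintf(
      "No Bennett lens power in [%g, %g] D for eye(s): %s",
      bracket[1], bracket[2],
      paste(head(eye_ids(data)[fail], 10), collapse = ", ")))
  }
  dplyr::mutate(data, P_lb = P_lb)
}

#' Scale an eye to its axial length
#'
#' Rescales a derived biometry table to the unitless axial-length frame:
#' every axial distance is divided by AL and every power multiplied by
#' AL/1000, so that e.g. a 42 D cornea in a 23 mm eye becomes 0.966. Under
#' this transform the thick-lens combination of scaled surface powers
#' equals the scaled total power exactly (isotropic-scaling identity).
#'
#' @param data Derived biometry tibble (output of [derive_biometry()]).
#' @return Tibble with the same column names, distances and powers
#'   rescaled; carries attribute `al_scaled = TRUE`. Unitless columns
#'   (`P_cr`, `AL_CR`, `subgroup`, ids) are untouched.
#' @export
scale_to_AL <- function(data) {
  required_cols(data, "AL", "scale_to_AL")
  if (any(data$AL <= 0, na.rm = TRUE)) abort("AL must be positive.")
  dist_cols <- intersect(
    c("CCT", "AD", "LT", "ACD_tot", "ASL", "VCD", "r_ca", "r_cp",
      "pp_c1", "pp_c2", "pp_l1", "pp_l2", "pp_eye1", "pp_eye2",
      "f_eye2", "F"), names(data))
  power_cols <- intersect(
    c("SE", "P_ca", "P_cp", "P_c", "P_lb", "P_eye", "P_ax", "SE_model"),
    names(data))
  out <- data
  for (cl in dist_cols) out[[cl]] <- data[[cl]] / data$AL
  for (cl in power_cols) out[[cl]] <- data[[cl]] * data$AL / 1000
  out$AL <- rep(1, nrow(data))
  attr(out, "al_scaled") <- TRUE
  out
}

#' Derive the full biometry table for a cohort
#'
#' Runs the complete per-eye derivation chain: distance bookkeeping,
#' corneal thick-lens power and principal points, Bennett lens power from
#' the measured refraction, whole-eye cardinal points, axial power and
#' model refraction, plus the corneal power fraction `P_cr = P_c / P_eye`
#' and the axial-length-to-corneal-radius ratio `AL_CR = AL / r_ca`.
#' Rows failing validation (or without a Bennett solution) are excluded
#' with a reason, not fatal; exclusions are attached as an attribute and
#' announced.
#'
#' @param data Raw cohort tibble with columns `SE`, `r_ca`, `r_cp`, `CCT`,
#'   `AD`, `LT`, `AL` (plus any id/covariate columns, which pass through).
#' @param idx [refractive_indices()].
#' @param method Bennett method, see [bennett_lens_power()].
#' @param se_limit Screening limit on |SE|, dioptres.
#' @return Derived tibble (one row per retained eye) with attribute
#'   `"exclusions"`: a tibble of `eye_id`, `row`, `reason`.
#' @examples
#' eye <- tibble::tibble(SE = 0, r_ca = 7.8, r_cp = 6.5, CCT = 0.54,
#'                       AD = 2.7, LT = 4.2, AL = 23.3)
#' derive_biometry(eye)$P_eye
#' @export
derive_biometry <- function(data, idx = refractive_indices(),
                            method = c("eq1-solve", "vergence"),
                            se_limit = 15) {
  method <- match.arg(method)
  if (nrow(data) == 0) {
    warn("derive_biometry(): empty input; returning empty output.")
    out <- data
    attr(out, "exclusions") <-
      tibble::tibble(eye_id = character(), row = integer(),
                     reason = character())
    return(out)
  }
  ids <- eye_ids(data)
  ok <- validate_biometry(data, se_limit = se_limit)
  reason <- attr(ok, "reason")
  keep <- data[ok, , drop = FALSE]
  excl <- tibble::tibble(eye_id = ids[!ok], row = which(!ok),
                         reason = reason[!ok])
  out <- NULL
  if (nrow(keep) > 0) {
    step <- derive_distances(keep)
    step <- corneal_power(step, idx)
    # Bennett may fail row-wise (no root in bracket): retry excluding those
    res <- tryCatch(bennett_lens_power(step, idx, method = method),
                    error = function(e) e)
    if (inherits(res, "error")) {
      solvable <- vapply(seq_len(nrow(step)), function(i) {
        !inherits(tryCatch(
          bennett_lens_power(step[i, , drop = FALSE], idx, method = method),
          error = function(e) e), "error")
      }, logical(1))
      bad_ids <- eye_ids(step)[!solvable]
      excl <- dplyr::bind_rows(excl, tibble::tibble(
        eye_id = bad_ids,
        row = match(bad_ids, ids),
        reason = "no Bennett lens power in bracket"))
      step <- step[solvable, , drop = FALSE]
      res <- bennett_lens_power(step, idx, method = method)
    }
    if (nrow(res) > 0) {
      out <- res |>
        eye_cardinal_points(idx) |>
        axial_power(idx) |>
        dplyr::mutate(P_cr = .data$P_c / .data$P_eye,
                      AL_CR = .data$AL / .data$r_ca)
    }
  }
  if (is.null(out)) out <- data[integer(0), , drop = FALSE]
  if (nrow(excl) > 0) {
    inform(sprintf("derive_biometry(): excluded %d of %d eye(s): %s",
                   nrow(excl), nrow(data),
                   paste(unique(excl$reason), collapse = "; ")))
  }
  attr(out, "exclusions") <- excl
  out
}
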