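#' Refractive indices of the schematic eye
#'
#' The three refractive indices used throughout the paraxial model: air,
#' cornea, and the ocular humours (aqueous and vitreous are taken as one
#' medium, as in the Gullstrand--Emsley reduced eye).
#'
#' @param n_air Refractive index of air.
#' @param n_c Refractive index of the cornea.
#' @param n Refractive index of the ocular humours.
#'
#' @return An object of class `refractive_indices`: a named list with
#'   elements `n_air`, `n_c`, `n`.
#' @examples
#' refractive_indices()
#' @export
refractive_indices <- function(n_air = 1, n_c = 1.376, n = 4 / 3) {
  stopifnot(is.numeric(n_air), is.numeric(n_c), is.numeric(n))
  if (any(c(n_air, n_c, n) <= 0)) {
    abort("Refractive indices must be positive.")
  }
  structure(list(n_air = n_air, n_c = n_c, n = n),
            class = "refractive_indices")
}

#' Bigaussian parameter set
#'
#' Parameters of the two-term Gaussian ("bigaussian") description of a
#' distribution,
#' \deqn{f(x) = a_1 e^{-((x-\mu_1)/\sigma_1)^2} + a_2 e^{-((x-\mu_2)/\sigma_2)^2}.}
#' Note the exponent carries no factor 1/2, so `sigma` is a width, not a
#' standard deviation: the SD of each component is `sigma / sqrt(2)` and its
#' integral is `a * sigma * sqrt(pi)`. Component 1 is always the narrow
#' ("Regulated") term; the constructor relabels if needed (ties on sigma go
#' to the larger amplitude).
#'
#' @param a1,a2 Non-negative amplitudes (per-bin proportions when fitted to a
#'   1 D histogram of proportions).
#' @param mu1,mu2 Component centres, dioptres.
#' @param sigma1,sigma2 Positive component widths, dioptres.
#'
#' @return An object of class `bigauss_params`.
#' @seealso [eval_bigaussian()], [component_weights()], [mixture_moments()]
#' @examples
#' bigauss_params(0.423, 0.372, 0.935, 0.0668, 0.226, 2.369)
#' @export
bigauss_params <- function(a1, mu1, sigma1, a2, mu2, sigma2) {
  v <- c(a1 = a1, mu1 = mu1, sigma1 = sigma1,
         a2 = a2, mu2 = mu2, sigma2 = sigma2)
  if (any(!is.finite(v))) abort("Bigaussian parameters must be finite.")
  if (a1 < 0 || a2 < 0) abort("Amplitudes a1, a2 must be non-negative.")
  if (sigma1 <= 0 || sigma2 <= 0) abort("Widths sigma1, sigma2 must be positive.")
  swap <- sigma1 > sigma2 || (sigma1 == sigma2 && a1 < a2)
  if (swap) {
    tmp <- c(a1, mu1, sigma1)
    a1 <- a2; mu1 <- mu2; sigma1 <- sigma2
    a2 <- tmp[1]; mu2 <- tmp[2]; sigma2 <- tmp[3]
  }
  structure(list(a1 = a1, mu1 = mu1, sigma1 = sigma1,
                 a2 = a2, mu2 = mu2, sigma2 = sigma2),
            class = "bigauss_params")
}

#' @export
print.bigauss_params <- function(x, ...) {
  cat("Bigaussian parameters (exponent without 1/2; component SD = sigma/sqrt(2))\n")
  cat(sprintf("  narrow : a = %.4g, mu = %.4g D, sigma = %.4g D\n",
              x$a1, x$mu1, x$sigma1))
  cat(sprintf("  broad  : a = %.4g, mu = %.4g D, sigma = %.4g D\n",
              x$a2, x$mu2, x$sigma2))
  w <- component_weights(x)
  cat(sprintf("  weights: %.1f%% / %.1f%%\n", 100 * w[1], 100 * w[2]))
  invisible(x)
}

#' Reference bigaussian fit of the adult refractive distribution
#'
#' The published two-component description of the cycloplegic spherical
#' equivalent distribution of a large adult cohort, fitted on 1 D histogram
#' proportions between -10 and +10 D. Used as the default refraction model of
#' the synthetic-cohort generator.
#'
#' @return A [bigauss_params()] object.
#' @examples
#' component_weights(se_mixture_reference())  # ~ 71.4% / 28.6%
#' @export
se_mixture_reference <- function() {
  bigauss_params(a1 = 0.423, mu1 = 0.372, sigma1 = 0.935,
                 a2 = 0.0668, mu2 = 0.226, sigma2 = 2.369)
}

#' Reference biometry moments of an adult cohort
#'
#' Whole-cohort means and standard deviations of the main ocular biometry
#' parameters of a large adult population (n = 2000), used as generator
#' targets. Units: dioptres for powers and SE, millimetres for distances.
#'
#' @return A tibble with columns `parameter`, `mean`, `sd`.
#' @export
biometry_reference_moments <- function() {
  tibble::tribble(
    ~parameter, ~mean, ~sd,
    "SE",      0.02, 1.52,
    "CCT",     0.53, 0.03,
    "AD",      2.64, 0.32,
    "LT",      4.25, 0.29,
    "VCD",    15.72, 0.85,
    "AL",     23.14, 0.90,
    "P_c",    42.02, 1.47,
    "P_lb",   26.00, 1.88,
    "P_eye",  63.43, 2.25,
    "P_ax",   63.50, 2.63
  )
}

#' Reference correlation matrix of ocular biometry
#'
#' Whole-cohort Pearson correlations between refraction and the main
#' biometric parameters of a large adult population, used as generator
#' targets. Order: SE, AD, LT, VCD, AL, P_c, P_lb.
#'
#' @return A symmetric 7 x 7 correlation matrix with unit diagonal.
#' @export
biometry_reference_correlations <- function() {
  nm <- c("SE", "AD", "LT", "VCD", "AL", "P_c", "P_lb")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  R["SE", "AD"]   <- -0.313
  R["SE", "LT"]   <-  0.191
  R["SE", "VCD"]  <- -0.552
  R["SE", "AL"]   <- -0.570
  R["SE", "P_c"]  <- -0.111
  R["SE", "P_lb"] <- -0.085
  R["AD", "LT"]   <- -0.576
  R["AD", "VCD"]  <-  0.345
  R["AD", "AL"]   <-  0.491
  R["AD", "P_c"]  <- -0.008
  R["AD", "P_lb"] <- -0.367
  R["LT", "VCD"]  <- -0.362
  R["LT", "AL"]   <- -0.225
  R["LT", "P_c"]  <- -0.023
  R["LT", "P_lb"] <-  0.273
  R["VCD", "AL"]  <-  0.951
  R["VCD", "P_c"] <- -0.588
  R["VCD", "P_lb"] <- -0.525
  R["AL", "P_c"]  <- -0.569
  R["AL", "P_lb"] <- -0.537
  R["P_c", "P_lb"] <- 0.174
  R[lower.tri(R)] <- t(R)[lower.tri(R)]
  R
}

#' Emmetropia criterion
#'
#' An eye is emmetropic when its spherical equivalent lies within the given
#' bounds, both inclusive by default (-0.5 D <= SE <= +0.5 D).
#'
#' @param lower,upper Bounds in dioptres, `lower < upper`.
#' @param inclusive Length-2 logical: include the lower / upper bound.
#' @return An object of class `emmetropia_criterion`.
#' @export
emmetropia_criterion <- function(lower = -0.5, upper = 0.5,
                                 inclusive = c(TRUE, TRUE)) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    abort("Emmetropia bounds must satisfy lower < upper.")
  }
  structure(list(lower = lower, upper = upper,
                 inclusive = as.logical(inclusive)),
            class = "emmetropia_criterion")
}

#' Test eyes against an emmetropia criterion
#'
#' @param se Numeric vector of spherical equivalents, dioptres.
#' @param criterion An [emmetropia_criterion()].
#' @return Logical vector, `TRUE` for emmetropic eyes.
#' @export
is_emmetropic <- function(se, criterion = emmetropia_criterion()) {
  lo <- if (criterion$inclusive[1]) se >= criterion$lower else se > criterion$lower
  hi <- if (criterion$inclusive[2]) se <= criterion$upper else se < criterion$upper
  lo & hi
}

#' Uniqueness tolerance specification
#'
#' Device repeatabilities used to decide whether two eyes are biometrically
#' indistinguishable. Two eyes form an indistinguishable pair when the
#' absolute difference in every listed parameter is at most
#' `limit_factor * repeatability` (the limits of agreement).
#'
#' @param parameters Character vector of compared parameters.
#' @param repeatability Device repeatabilities, same order (D for SE and
#'   powers, mm for distances).
#' @param limit_factor Multiplier turning repeatability into a limit of
#'   agreement (default 1.96).
#' @return An object of class `uniqueness_spec`.
#' @export
uniqueness_spec <- function(parameters = c("SE", "P_c", "P_lb",
                                           "ACD_tot", "LT", "AL"),
                            repeatability = c(0.25, 0.12, 0.25,
                                              0.009, 0.015, 0.019),
                            limit_factor = 1.96) {
  if (length(parameters) != length(repeatability)) {
    abort("`parameters` and `repeatability` must have the same length.")
  }
  if (any(repeatability <= 0)) abort("Repeatabilities must be positive.")
  structure(list(parameters = parameters,
                 repeatability = setNames(repeatability, parameters),
                 limit_factor = limit_factor),
            class = "uniqueness_spec")
}

# Internal: fixed column order of the 5-D biometry mixture.
mv_dimensions <- function() c("SE", "P_c", "P_lb", "ACD_tot", "AL")
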