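# Covariance-ellipse classification of eyes into Regulated and
# Dysregulated subgroups. An eye is Regulated when, for every unordered
# pair of the five mixture dimensions, its 2-D Mahalanobis distance to the
# Regulated component centre (in the pair's covariance submatrix metric)
# is at most epsilon -- i.e. it lies inside all ten pairwise covariance
# ellipses whose semi-axes are the eigenvectors scaled by
# epsilon * sqrt(eigenvalue).

#' One-dimensional coverage of an epsilon-scaled interval
#'
#' For a univariate normal, the interval mean +/- epsilon * SD covers
#' `2 Phi(epsilon) - 1` of the distribution; epsilon = 2.26 gives 97.62%.
#' Note this one-dimensional reading differs from the coverage of a 2-D
#' ellipse at the same epsilon, which is `1 - exp(-epsilon^2 / 2)`.
#'
#' @param epsilon Positive scale factor.
#' @return Coverage probability in (0, 1).
#' @examples
#' coverage_1d(2.26)
#' @export
coverage_1d <- function(epsilon) {
  stopifnot(is.numeric(epsilon), all(epsilon > 0))
  2 * pnorm(epsilon) - 1
}

#' Pairwise covariance ellipses of a fitted mixture component
#'
#' For each of the ten unordered pairs of the five mixture dimensions,
#' eigen-decomposes the 2 x 2 covariance submatrix of the chosen component
#' and returns the ellipse centred on the component mean with semi-axes
#' `epsilon * sqrt(lambda_i)` along the eigenvectors.
#'
#' @param fit An [fit_multivariate_bigaussian()] result.
#' @param epsilon Positive ellipse scale.
#' @param component `"Regulated"` (default) or `"Dysregulated"`.
#' @return A tibble with one row per pair: `var_x`, `var_y`, `center_x`,
#'   `center_y`, semi-axis lengths `len1 >= len2`, axis direction
#'   components `vec1_x`, `vec1_y`, `vec2_x`, `vec2_y`, and `angle_deg` of
#'   the major axis.
#' @export
pair_ellipses <- function(fit, epsilon,
                          component = c("Regulated", "Dysregulated")) {
  stopifnot(inherits(fit, "mv_bigauss_fit"), epsilon > 0)
  component <- match.arg(component)
  dims <- fit$dimensions
  S <- fit$covariances[[component]]
  mu <- fit$means[component, ]
  pairs <- combn(dims, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    sub <- S[pr, pr]
    ev <- eigen(sub, symmetric = TRUE)
    if (any(ev$values <= 0)) {
      abort(sprintf("Covariance submatrix for (%s, %s) is not positive definite.",
                    pr[1], pr[2]))
    }
    tibble::tibble(
      var_x = pr[1], var_y = pr[2],
      center_x = mu[[pr[1]]], center_y = mu[[pr[2]]],
      len1 = epsilon * sqrt(ev$values[1]),
      len2 = epsilon * sqrt(ev$values[2]),
      vec1_x = ev$vectors[1, 1], vec1_y = ev$vectors[2, 1],
      vec2_x = ev$vectors[1, 2], vec2_y = ev$vectors[2, 2],
      angle_deg = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    )
  })
}

# Pairwise Mahalanobis distances of every eye to the Regulated centre:
# n x 10 matrix of distances (not squared), columns named "var_x:var_y".
pairwise_mahalanobis <- function(X, fit) {
  dims <- fit$dimensions
  mu <- fit$means["Regulated", ]
  S <- fit$covariances[["Regulated"]]
  pairs <- combn(dims, 2, simplify = FALSE)
  out <- matrix(NA_real_, nrow(X), length(pairs),
                dimnames = list(NULL, vapply(pairs, paste, character(1),
                                             collapse = ":")))
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    out[, k] <- sqrt(mahalanobis(X[, pr, drop = FALSE], mu[pr], S[pr, pr]))
  }
  out
}

#' Classify eyes as Regulated or Dysregulated
#'
#' An eye is Regulated iff it lies inside the Regulated component's
#' epsilon-scaled covariance ellipse for all ten parameter pairs
#' (equivalently: its 2-D Mahalanobis distance is <= epsilon for every
#' pair); an eye outside at least one ellipse is Dysregulated.
#'
#' @param data Tibble containing the five mixture dimensions
#'   ([mv_dimensions()]); other columns pass through.
#' @param fit An [fit_multivariate_bigaussian()] result.
#' @param epsilon Positive ellipse scale.
#' @return The input tibble with columns `subgroup` (factor, levels
#'   Regulated/Dysregulated), `n_failing_pairs` and `failing_pairs`
#'   (";"-separated pair labels, `""` for Regulated eyes) appended;
#'   attribute `"epsilon"` records the scale used.
#' @export
classify_cohort <- function(data, fit, epsilon) {
  stopifnot(inherits(fit, "mv_bigauss_fit"), epsilon > 0)
  required_cols(data, fit$dimensions, "classify_cohort")
  X <- as.matrix(data[fit$dimensions])
  if (any(!is.finite(X))) abort("Non-finite values in classification input.")
  D <- pairwise_mahalanobis(X, fit)
  failing <- D > epsilon
  n_fail <- rowSums(failing)
  labels <- apply(failing, 1, function(f) {
    paste(colnames(D)[f], collapse = ";")
  })
  out <- dplyr::mutate(
    data,
    subgroup = factor(ifelse(n_fail == 0, "Regulated", "Dysregulated"),
                      levels = c("Regulated", "Dysregulated")),
    n_failing_pairs = as.integer(n_fail),
    failing_pairs = labels)
  attr(out, "epsilon") <- epsilon
  out
}

#' Calibrate the ellipse scale against a target Regulated fraction
#'
#' Bisects epsilon over `bracket` for the smallest scale whose Regulated
#' fraction reaches the target (normally the narrow-component weight of
#' the 1-D refractive fit). The fraction is a step function of epsilon, so
#' the achieved fraction generally overshoots the target slightly rather
#' than matching it exactly.
#'
#' @param data Tibble with the five mixture dimensions.
#' @param fit An [fit_multivariate_bigaussian()] result.
#' @param target Target Regulated fraction in (0, 1).
#' @param bracket Epsilon search interval.
#' @param tol Bisection tolerance on epsilon.
#' @return A list: `epsilon`, `fraction` (achieved Regulated fraction at
#'   that epsilon), `target`, `n`. Errors (reporting the boundary
#'   fractions) if the target is unattainable at the upper bracket.
#' @export
calibrate_epsilon <- function(data, fit, target, bracket = c(0.5, 5),
                              tol = 1e-3) {
  stopifnot(target > 0, target < 1)
  required_cols(data, fit$dimensions, "calibrate_epsilon")
  X <- as.matrix(data[fit$dimensions])
  D <- pairwise_mahalanobis(X, fit)
  dmax <- apply(D, 1, max)  # eye is Regulated iff dmax <= epsilon
  frac <- function(eps) mean(dmax <= eps)
  f_lo <- frac(bracket[1])
  f_hi <- frac(bracket[2])
  if (f_hi < target) {
    abort(sprintf(
      "Target fraction %.3f unattainable: fraction is %.3f at eps = %g and %.3f at eps = %g.",
      target, f_lo, bracket[1], f_hi, bracket[2]))
  }
  if (f_lo >= target) {
    return(list(epsilon = bracket[1], fraction = f_lo,
                target = target, n = nrow(X)))
  }
  lo <- bracket[1]
  hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (frac(mid) >= target) hi <- mid else lo <- mid
  }
  list(epsilon = hi, fraction = frac(hi), target = target, n = nrow(X))
}
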