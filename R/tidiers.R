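# broom-style tidiers for the fitted objects.

#' Tidy a 1-D bigaussian fit
#'
#' @param x A `bigauss_fit` from [fit_bigaussian_1d()].
#' @param ... Unused.
#' @return One row per component: `component` (Regulated = narrow,
#'   Dysregulated = broad), `amplitude`, `mean`, `sigma` (width), `sd`
#'   (sigma/sqrt(2)), `weight`.
#' @method tidy bigauss_fit
#' @export
tidy.bigauss_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    component = c("Regulated", "Dysregulated"),
    amplitude = c(p$a1, p$a2),
    mean = c(p$mu1, p$mu2),
    sigma = c(p$sigma1, p$sigma2),
    sd = c(p$sigma1, p$sigma2) / sqrt(2),
    weight = unname(x$weights))
}

#' Glance at a 1-D bigaussian fit
#'
#' @param x A `bigauss_fit`.
#' @param ... Unused.
#' @return One-row tibble: `r2`, `sse`, `n`, `n_bins`, `n_converged`.
#' @method glance bigauss_fit
#' @export
glance.bigauss_fit <- function(x, ...) {
  tibble::tibble(r2 = x$r2, sse = x$sse, n = x$n,
                 n_bins = nrow(x$histogram), n_converged = x$n_converged)
}

#' Tidy a multivariate bigaussian fit
#'
#' @param x An `mv_bigauss_fit` from [fit_multivariate_bigaussian()].
#' @param ... Unused.
#' @return Long tibble: `component`, `weight`, `parameter`, `mean`, `sd`
#'   (marginal SD from the component covariance).
#' @method tidy mv_bigauss_fit
#' @export
tidy.mv_bigauss_fit <- function(x, ...) {
  purrr::map_dfr(c("Regulated", "Dysregulated"), function(comp) {
    tibble::tibble(
      component = comp,
      weight = unname(x$weights[comp]),
      parameter = x$dimensions,
      mean = unname(x$means[comp, ]),
      sd = sqrt(diag(x$covariances[[comp]])))
  })
}

#' Glance at a multivariate bigaussian fit
#'
#' @param x An `mv_bigauss_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `AIC`, `n`, `restarts`,
#'   `n_converged`, `weight_regulated`.
#' @method glance mv_bigauss_fit
#' @export
glance.mv_bigauss_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, n = x$n,
                 restarts = x$restarts, n_converged = x$n_converged,
                 weight_regulated = unname(x$weights["Regulated"]))
}
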