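# Two-component multivariate Gaussian mixture over the five biometry
# dimensions (SE, P_c, P_lb, ACD_tot, AL): expectation-maximisation with
# k-means initial conditions, repeated from many seeds, keeping the
# converged fit with the lowest AIC.

# log density of a multivariate normal via Cholesky; X is n x d
log_dmvn <- function(X, mean, sigma) {
  d <- ncol(X)
  ch <- chol(sigma)
  centred <- sweep(X, 2, mean)
  z <- backsolve(ch, t(centred), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

regularise_cov <- function(sigma) {
  # symmetrise and, on degeneracy, inflate the diagonal by 1e-6 * trace / d
  sigma <- (sigma + t(sigma)) / 2
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    sigma <- sigma + diag(1e-6 * sum(diag(sigma)) / ncol(sigma), ncol(sigma))
  }
  sigma
}

em_one_restart <- function(X, init, max_iter, tol) {
  n <- nrow(X)
  w <- init$w
  mu <- init$mu          # list of 2 mean vectors
  S <- lapply(init$S, regularise_cov)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- cbind(log(w[1]) + log_dmvn(X, mu[[1]], S[[1]]),
                log(w[2]) + log_dmvn(X, mu[[2]], S[[2]]))
    mx <- pmax(lg[, 1], lg[, 2])
    lse <- mx + log(exp(lg[, 1] - mx) + exp(lg[, 2] - mx))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lg - lse)
    nk <- colSums(resp)
    if (any(nk < ncol(X) + 1)) return(NULL)  # degenerate component
    w <- nk / n
    for (k in 1:2) {
      mu[[k]] <- colSums(resp[, k] * X) / nk[k]
      centred <- sweep(X, 2, mu[[k]])
      S[[k]] <- regularise_cov(crossprod(centred * sqrt(resp[, k])) / nk[k])
    }
    if (is.finite(ll_old) && ll - ll_old < tol * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(w = w, mu = mu, S = S, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, converged = converged)
}

#' Fit a two-component multivariate Gaussian mixture to ocular biometry
#'
#' Fits the five-dimensional two-component Gaussian mixture over
#' (SE, P_c, P_lb, ACD_tot, AL) by maximum likelihood: each restart seeds
#' the expectation-maximisation iteration from a k-means split, full
#' covariance matrices are estimated with a small diagonal regularisation
#' on degeneracy, and the converged restart with the lowest Akaike
#' Information Criterion is kept (k = 41 free parameters: one weight, two
#' mean vectors, two symmetric 5 x 5 covariances). Components are
#' relabelled so that component 1 is the compact ("Regulated") one --
#' smaller covariance determinant, ties broken by larger weight.
#'
#' @param data Tibble or matrix containing the five columns of
#'   [mv_dimensions()] in any position (tibble) or exactly that order
#'   (matrix).
#' @param restarts Number of k-means/EM restarts (published protocol: 1000;
#'   default 50 is adequate at cohort scale).
#' @param seed Integer seed; restart r uses stream `seed + r`.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return An object of class `mv_bigauss_fit`: `weights` (length 2),
#'   `means` (2 x 5 matrix), `covariances` (list of two 5 x 5 matrices),
#'   `loglik`, `aic`, `n`, `dimensions`, `restarts`, `n_converged`,
#'   `ll_traces` (list of per-restart log-likelihood traces; the winning
#'   restart index in `best_restart`). Component 1 is Regulated.
#' @seealso [classify_cohort()], [pair_ellipses()], [tidy.mv_bigauss_fit()]
#' @export
fit_multivariate_bigaussian <- function(data, restarts = 50, seed = 1,
                                        max_iter = 500, tol = 1e-8) {
  dims <- mv_dimensions()
  if (is.matrix(data)) {
    if (ncol(data) != length(dims)) {
      abort(sprintf("Matrix input must have %d columns (%s).",
                    length(dims), paste(dims, collapse = ", ")))
    }
    X <- data
    colnames(X) <- dims
  } else {
    required_cols(data, dims, "fit_multivariate_bigaussian")
    X <- as.matrix(data[dims])
  }
  if (any(!is.finite(X))) abort("Non-finite values in mixture input.")
  n <- nrow(X)
  if (n < 50) abort("Need at least 50 eyes for the multivariate fit.")
  d <- ncol(X)
  k_free <- 1 + 2 * (d + d * (d + 1) / 2)   # 41 for d = 5
  best <- NULL
  best_aic <- Inf
  best_r <- NA_integer_
  ll_traces <- vector("list", restarts)
  n_conv <- 0L
  for (r in seq_len(restarts)) {
    init <- withr::with_seed(seed + r, {
      km <- tryCatch(kmeans(X, centers = 2, nstart = 1, iter.max = 50),
                     error = function(e) NULL)
      if (is.null(km) || min(km$size) < d + 1) {
        # random fallback split
        grp <- sample(rep(1:2, length.out = n))
      } else {
        grp <- km$cluster
      }
      list(
        w = as.numeric(table(factor(grp, levels = 1:2))) / n,
        mu = lapply(1:2, function(k) colMeans(X[grp == k, , drop = FALSE])),
        S = lapply(1:2, function(k) {
          S <- stats::cov(X[grp == k, , drop = FALSE])
          if (any(!is.finite(S))) S <- stats::cov(X)
          S
        })
      )
    })
    fit <- tryCatch(em_one_restart(X, init, max_iter, tol),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ll_traces[[r]] <- fit$ll_trace
    if (!fit$converged) next
    n_conv <- n_conv + 1L
    aic <- 2 * k_free - 2 * fit$loglik
    if (aic < best_aic) {
      best_aic <- aic
      best <- fit
      best_r <- r
    }
  }
  if (is.null(best)) {
    abort(sprintf("All %d restarts degenerate or unconverged.", restarts))
  }
  # Regulated = component with the smaller covariance determinant,
  # tie-break on the larger weight
  dets <- vapply(best$S, det, numeric(1))
  reg <- if (dets[1] < dets[2]) 1L
         else if (dets[2] < dets[1]) 2L
         else which.max(best$w)
  ord <- c(reg, setdiff(1:2, reg))
  means <- do.call(rbind, best$mu[ord])
  dimnames(means) <- list(c("Regulated", "Dysregulated"), dims)
  covs <- best$S[ord]
  names(covs) <- c("Regulated", "Dysregulated")
  covs <- lapply(covs, function(S) { dimnames(S) <- list(dims, dims); S })
  structure(list(weights = setNames(best$w[ord],
                                    c("Regulated", "Dysregulated")),
                 means = means,
                 covariances = covs,
                 loglik = best$loglik,
                 aic = best_aic,
                 n = n,
                 dimensions = dims,
                 restarts = restarts,
                 n_converged = n_conv,
                 best_restart = best_r,
                 ll_traces = ll_traces),
            class = "mv_bigauss_fit")
}

#' @export
print.mv_bigauss_fit <- function(x, ...) {
  cat(sprintf(
    "Two-component Gaussian mixture over (%s)\n",
    paste(x$dimensions, collapse = ", ")))
  cat(sprintf("  n = %d, restarts = %d (%d converged), logLik = %.2f, AIC = %.2f\n",
              x$n, x$restarts, x$n_converged, x$loglik, x$aic))
  cat(sprintf("  weights: Regulated %.3f / Dysregulated %.3f\n",
              x$weights[1], x$weights[2]))
  cat("  Regulated means:\n")
  print(round(x$means[1, ], 3))
  invisible(x)
}
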