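# Fixtures built in code: random physiological eyes whose refraction is
# produced by the forward paraxial model from a known lens power, so every
# eye is guaranteed to admit a Bennett solution and the true P_lb is known.

random_eyes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    raw <- tibble::tibble(
      r_ca = runif(n, 7.0, 8.6),
      r_cp = runif(n, 6.0, 7.2),
      CCT = runif(n, 0.45, 0.62),
      AD = runif(n, 2.0, 3.4),
      LT = runif(n, 3.6, 5.0),
      AL = runif(n, 21, 27),
      P_lb_true = runif(n, 18, 32))
    idx <- refractive_indices()
    fwd <- raw |>
      derive_distances() |>
      corneal_power(idx) |>
      dplyr::mutate(P_lb = .data$P_lb_true) |>
      eye_cardinal_points(idx) |>
      axial_power(idx)
    out <- dplyr::mutate(raw, SE = fwd$SE_model)
    # keep eyes whose implied refraction passes screening
    out[abs(out$SE) <= 15, , drop = FALSE]
  })
}

# One plausible fixed eye (cohort-scale averages)
mean_eye <- function() {
  tibble::tibble(SE = 0.02, r_ca = 7.75, r_cp = 6.46, CCT = 0.53,
                 AD = 2.64, LT = 4.25, AL = 23.14)
}

# Hand-built two-component 5-D mixture fit object for classification tests
toy_mv_fit <- function(means, covs, weights = c(0.7, 0.3)) {
  dims <- c("SE", "P_c", "P_lb", "ACD_tot", "AL")
  m <- rbind(means[[1]], means[[2]])
  dimnames(m) <- list(c("Regulated", "Dysregulated"), dims)
  covs <- lapply(covs, function(S) {
    dimnames(S) <- list(dims, dims)
    S
  })
  names(covs) <- c("Regulated", "Dysregulated")
  structure(list(weights = stats::setNames(weights,
                                           c("Regulated", "Dysregulated")),
                 means = m, covariances = covs,
                 loglik = NA_real_, aic = NA_real_, n = NA_integer_,
                 dimensions = dims, restarts = 0L, n_converged = 0L,
                 best_restart = NA_integer_, ll_traces = list()),
            class = "mv_bigauss_fit")
}

# Sample from a planted two-component 5-D Gaussian mixture
sample_planted_mixture <- function(n, mu1, mu2, S1, S2, w1, seed) {
  withr::with_seed(seed, {
    comp <- 1L + (runif(n) > w1)
    X <- matrix(NA_real_, n, 5)
    for (k in 1:2) {
      idx <- which(comp == k)
      mu <- if (k == 1) mu1 else mu2
      S <- if (k == 1) S1 else S2
      X[idx, ] <- matrix(rnorm(length(idx) * 5), length(idx), 5) %*%
        chol(S) + matrix(mu, length(idx), 5, byrow = TRUE)
    }
    colnames(X) <- c("SE", "P_c", "P_lb", "ACD_tot", "AL")
    list(X = X, component = comp)
  })
}
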