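# Synthetic cohort generation. Emulates an adult population cohort whose
# refractive distribution follows the reference bigaussian and whose
# biometry reproduces the reference means, SDs and correlation structure,
# so that every downstream stage can be exercised without access to the
# (non-public) source data.

#' Specify a synthetic cohort
#'
#' Bundles the generator parameters: sample size, refractive mixture,
#' per-parameter means and SDs, correlation targets, generation mode and
#' seed. The correlation matrix is checked for positive definiteness and,
#' if needed, repaired to the nearest correlation matrix (the repair is
#' recorded in the `repaired` field and announced).
#'
#' @param n Number of eyes.
#' @param se_params Refraction model, a [bigauss_params()]
#'   (default [se_mixture_reference()]).
#' @param moments Tibble of `parameter`, `mean`, `sd`
#'   (default [biometry_reference_moments()]); must cover CCT, AD, LT, AL,
#'   P_c.
#' @param correlations Correlation matrix over (SE, AD, LT, VCD, AL, P_c,
#'   P_lb) (default [biometry_reference_correlations()]). The generator
#'   imposes the (SE, AD, LT, AL, P_c) block; VCD and P_lb arise from the
#'   accounting identity and the lens-power inversion and are checked, not
#'   imposed.
#' @param mode `"refraction-first"` (default): draw SE from the mixture
#'   and biometry conditionally on it; `"biometry-first"`: draw biometry
#'   and lens power jointly and compute SE forward (stress-testing only).
#' @param seed Integer seed.
#' @param se_limit Truncation of |SE|, dioptres (rejection sampling).
#' @param al_bounds Physiologic axial-length bounds, mm (rejection).
#' @param cct_mean,cct_sd Independent CCT model, mm.
#' @param radius_ratio Fixed posterior/anterior corneal radius ratio used
#'   to invert corneal power into two radii.
#' @param rejection_cap Maximum total draws as a multiple of `n`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 2000,
                        se_params = se_mixture_reference(),
                        moments = biometry_reference_moments(),
                        correlations = biometry_reference_correlations(),
                        mode = c("refraction-first", "biometry-first"),
                        seed = 1,
                        se_limit = 15,
                        al_bounds = c(19, 32),
                        cct_mean = 0.53, cct_sd = 0.03,
                        radius_ratio = 6.5 / 7.8,
                        rejection_cap = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(se_params, "bigauss_params"),
            n >= 0, se_limit > 0, rejection_cap > 1,
            all(c("parameter", "mean", "sd") %in% names(moments)))
  need <- c("CCT", "AD", "LT", "AL", "P_c")
  if (!all(need %in% moments$parameter)) {
    abort(sprintf("`moments` must cover: %s.", paste(need, collapse = ", ")))
  }
  if (any(moments$sd < 0)) abort("Moment SDs must be non-negative.")
  if (!isSymmetric(unname(correlations)) ||
      any(abs(diag(correlations) - 1) > 1e-12)) {
    abort("`correlations` must be symmetric with unit diagonal.")
  }
  repaired <- FALSE
  ev <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    correlations <- as.matrix(
      Matrix::nearPD(correlations, corr = TRUE)$mat)
    repaired <- TRUE
    inform("cohort_spec(): correlation matrix repaired to nearest PD.")
  }
  structure(list(n = as.integer(n), se_params = se_params,
                 moments = moments, correlations = correlations,
                 mode = mode, seed = as.integer(seed),
                 se_limit = se_limit, al_bounds = al_bounds,
                 cct_mean = cct_mean, cct_sd = cct_sd,
                 radius_ratio = radius_ratio,
                 rejection_cap = rejection_cap,
                 repaired = repaired),
            class = "cohort_spec")
}

#' Sample refractions from a bigaussian mixture
#'
#' Draws the component with probability proportional to `a_i sigma_i`
#' (see [component_weights()]) and the value from
#' `Normal(mu_i, sigma_i / sqrt(2))` -- the sqrt(2) follows from the
#' exponent convention of the bigaussian. Values beyond `+-limit` are
#' redrawn (rejection).
#'
#' @param n Number of draws.
#' @param params A [bigauss_params()].
#' @param seed Optional integer seed (local).
#' @param limit Truncation, dioptres.
#' @return A tibble with columns `SE` (dioptres) and `component`
#'   (integer 1 = narrow, 2 = broad).
#' @export
sample_se_mixture <- function(n, params = se_mixture_reference(),
                              seed = NULL, limit = 15) {
  stopifnot(n >= 0)
  if (n == 0) return(tibble::tibble(SE = numeric(), component = integer()))
  draw <- function() {
    w <- component_weights(params)
    comp <- 1L + (runif(n) > w[1])
    mu <- c(params$mu1, params$mu2)[comp]
    sdv <- (c(params$sigma1, params$sigma2) / sqrt(2))[comp]
    se <- rnorm(n, mu, sdv)
    out_of_range <- abs(se) > limit
    guard <- 0
    while (any(out_of_range) && guard < 100) {
      m <- sum(out_of_range)
      comp[out_of_range] <- 1L + (runif(m) > w[1])
      se[out_of_range] <- rnorm(m, c(params$mu1, params$mu2)[comp[out_of_range]],
                                (c(params$sigma1, params$sigma2) /
                                   sqrt(2))[comp[out_of_range]])
      out_of_range <- abs(se) > limit
      guard <- guard + 1
    }
    tibble::tibble(SE = se, component = comp)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Target covariance over (SE, AD, LT, AL, P_c) used for conditioning.
# The SE variance is the refraction mixture's own variance, not the
# tabulated whole-cohort SD: the latter includes tails beyond the fit
# range and would shrink every realised SE correlation (see vignette).
conditioning_covariance <- function(spec) {
  vars <- c("SE", "AD", "LT", "AL", "P_c")
  R <- spec$correlations[vars, vars]
  sds <- setNames(spec$moments$sd, spec$moments$parameter)[vars]
  sds["SE"] <- mixture_moments(spec$se_params)$sd
  Sigma <- diag(sds) %*% R %*% diag(sds)
  dimnames(Sigma) <- list(vars, vars)
  Sigma
}

# Invert total corneal power into (r_ca, r_cp) with a fixed radius ratio:
# with u = 1000 / r_ca the thick-lens formula is a quadratic in u.
invert_corneal_radii <- function(P_c, CCT, ratio, idx = refractive_indices()) {
  A <- (idx$n_c - idx$n_air) + (idx$n - idx$n_c) / ratio
  B <- -0.001 * (idx$n_c - idx$n_air) * (idx$n - idx$n_c) / (ratio * idx$n_c)
  u <- (-A + sqrt(A^2 + 4 * B * CCT * P_c)) / (2 * B * CCT)
  r_ca <- 1000 / u
  tibble::tibble(r_ca = r_ca, r_cp = ratio * r_ca)
}

# symmetric PSD square root (tolerates zero / singular covariances)
psd_sqrt <- function(S) {
  E <- eigen((S + t(S)) / 2, symmetric = TRUE)
  E$vectors %*% diag(sqrt(pmax(E$values, 0)), nrow(S)) %*% t(E$vectors)
}

generate_batch <- function(m, spec, idx) {
  se <- sample_se_mixture(m, spec$se_params, limit = spec$se_limit)
  Sigma <- conditioning_covariance(spec)
  mu <- setNames(spec$moments$mean, spec$moments$parameter)
  mu_se <- mixture_moments(spec$se_params)$mean
  b_vars <- c("AD", "LT", "AL", "P_c")
  beta <- Sigma[b_vars, "SE"] / Sigma["SE", "SE"]
  cond_cov <- Sigma[b_vars, b_vars] -
    tcrossprod(Sigma[b_vars, "SE"]) / Sigma["SE", "SE"]
  Z <- matrix(rnorm(m * 4), m, 4) %*% psd_sqrt(cond_cov)
  cond_mean <- outer(se$SE - mu_se, beta) +
    matrix(mu[b_vars], m, 4, byrow = TRUE)
  B <- cond_mean + Z
  colnames(B) <- b_vars
  CCT <- rnorm(m, spec$cct_mean, spec$cct_sd)
  radii <- invert_corneal_radii(B[, "P_c"], CCT, spec$radius_ratio, idx)
  tibble::tibble(SE = se$SE, component = se$component,
                 r_ca = radii$r_ca, r_cp = radii$r_cp, CCT = CCT,
                 AD = B[, "AD"], LT = B[, "LT"], AL = B[, "AL"],
                 P_c_target = B[, "P_c"])
}

generate_batch_biometry_first <- function(m, spec, idx) {
  vars <- c("AD", "LT", "AL", "P_c", "P_lb")
  R <- spec$correlations[vars, vars]
  sds <- setNames(spec$moments$sd, spec$moments$parameter)[vars]
  mu <- setNames(spec$moments$mean, spec$moments$parameter)[vars]
  Sigma <- diag(sds) %*% R %*% diag(sds)
  B <- matrix(rnorm(m * 5), m, 5) %*% psd_sqrt(Sigma) +
    matrix(mu, m, 5, byrow = TRUE)
  colnames(B) <- vars
  CCT <- rnorm(m, spec$cct_mean, spec$cct_sd)
  radii <- invert_corneal_radii(B[, "P_c"], CCT, spec$radius_ratio, idx)
  base <- tibble::tibble(r_ca = radii$r_ca, r_cp = radii$r_cp, CCT = CCT,
                         AD = B[, "AD"], LT = B[, "LT"], AL = B[, "AL"],
                         P_lb = B[, "P_lb"])
  # forward model: SE implied by the drawn biometry and lens power
  fwd <- base |>
    derive_distances() |>
    corneal_power(idx)
  ch <- whole_eye_chain(fwd$P_c, fwd$pp_c2, fwd$ACD_tot, fwd$LT, fwd$AL,
                        base$P_lb, idx)
  dplyr::mutate(base, SE = ch$P_ax - ch$P_eye,
                component = NA_integer_,
                P_c_target = fwd$P_c)
}

#' Generate a synthetic cohort
#'
#' In the default refraction-first mode, each eye's spherical equivalent
#' is drawn from the bigaussian mixture and its (AD, LT, AL, P_c) from the
#' Gaussian conditional distribution given SE implied by the target
#' moments and correlations; CCT is drawn independently; corneal power is
#' inverted into two radii at a fixed radius ratio. The construction
#' guarantees that the paraxial derivation chain (with Bennett lens power)
#' reproduces each eye's drawn SE exactly, and that vitreous depth arises
#' from the accounting identity VCD = AL - ASL rather than being sampled.
#' Eyes violating physical invariants, the axial-length bounds, or without
#' a Bennett solution are rejected and redrawn (capped at
#' `rejection_cap * n` total draws).
#'
#' @param spec A [cohort_spec()].
#' @param idx [refractive_indices()].
#' @return A tibble of `n` eyes: `eye_id`, `age_y`, `sex`, `SE`, `r_ca`,
#'   `r_cp`, `CCT`, `AD`, `LT`, `AL`, `component` (latent mixture label,
#'   `NA` in biometry-first mode). Attributes: `"spec"`, `"n_rejected"`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200, seed = 7))
#' nrow(cohort)
#' @export
generate_cohort <- function(spec, idx = refractive_indices()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  empty <- tibble::tibble(
    eye_id = character(), age_y = numeric(), sex = character(),
    SE = numeric(), r_ca = numeric(), r_cp = numeric(), CCT = numeric(),
    AD = numeric(), LT = numeric(), AL = numeric(), component = integer())
  if (n == 0) {
    attr(empty, "spec") <- spec
    attr(empty, "n_rejected") <- 0L
    return(empty)
  }
  withr::with_seed(spec$seed, {
    acc <- NULL
    drawn <- 0
    rejected <- 0
    zero_sd <- all(spec$moments$sd == 0) && spec$cct_sd == 0
    while (is.null(acc) || nrow(acc) < n) {
      have <- if (is.null(acc)) 0L else nrow(acc)
      m <- max(32, ceiling(1.2 * (n - have)))
      if (!zero_sd) {
        m <- min(m, ceiling(spec$rejection_cap * n) - drawn)
        if (m <= 0) {
          abort(sprintf(
            "Rejection cap exceeded: %d draws for %d accepted eyes.",
            drawn, have))
        }
      }
      batch <- if (spec$mode == "refraction-first") {
        generate_batch(m, spec, idx)
      } else {
        generate_batch_biometry_first(m, spec, idx)
      }
      drawn <- drawn + m
      ok <- validate_biometry(batch, se_limit = spec$se_limit) &
        batch$AL >= spec$al_bounds[1] & batch$AL <= spec$al_bounds[2] &
        batch$r_ca > 4 & batch$r_ca < 15
      batch <- batch[which(ok), , drop = FALSE]
      if (nrow(batch) > 0 && spec$mode == "refraction-first") {
        # keep only eyes with a Bennett lens-power solution
        step <- batch |> derive_distances() |> corneal_power(idx)
        solvable <- tryCatch({
          bennett_lens_power(step, idx)
          rep(TRUE, nrow(step))
        }, error = function(e) {
          vapply(seq_len(nrow(step)), function(i) {
            !inherits(tryCatch(
              bennett_lens_power(step[i, , drop = FALSE], idx),
              error = function(e) e), "error")
          }, logical(1))
        })
        batch <- batch[solvable, , drop = FALSE]
      }
      rejected <- drawn - (if (is.null(acc)) 0 else nrow(acc)) - nrow(batch)
      acc <- if (is.null(acc)) batch else dplyr::bind_rows(acc, batch)
    }
    acc <- acc[seq_len(n), , drop = FALSE]
    age <- pmin(pmax(round(rnorm(n, 49.2, 5.7)), 39), 64)
    sex <- ifelse(runif(n) < 0.387, "M", "F")
    out <- tibble::tibble(
      eye_id = sprintf("eye%05d", seq_len(n)),
      age_y = age, sex = sex,
      SE = acc$SE, r_ca = acc$r_ca, r_cp = acc$r_cp, CCT = acc$CCT,
      AD = acc$AD, LT = acc$LT, AL = acc$AL,
      component = acc$component)
    attr(out, "spec") <- spec
    attr(out, "n_rejected") <- as.integer(drawn - n)
    out
  })
}

#' Validate a generated cohort against its specification
#'
#' Self-consistency report: parameter means within 4 standard errors of
#' the generator targets (the SE target being the mixture's own mean),
#' realised Pearson correlations within tolerance of the correlation
#' targets (including the implicitly generated VCD), positive excess
#' kurtosis of the refractive distribution (leptokurtosis), and the raw
#' biometry invariants. Failures are reported, not thrown.
#'
#' @param cohort A cohort tibble from [generate_cohort()] (or the same
#'   schema).
#' @param spec The [cohort_spec()] it should conform to.
#' @param cor_tol Tolerance on correlation entries.
#' @return A tibble with columns `check`, `target`, `value`, `tol`,
#'   `pass`.
#' @export
validate_cohort <- function(cohort, spec, cor_tol = 0.05) {
  stopifnot(inherits(spec, "cohort_spec"), nrow(cohort) > 0)
  idx <- refractive_indices()
  der <- cohort |> derive_distances() |> corneal_power(idx)
  der <- bennett_lens_power(der, idx)
  mu <- setNames(spec$moments$mean, spec$moments$parameter)
  mm <- mixture_moments(spec$se_params)
  n <- nrow(cohort)
  mean_check <- function(name, x, target, sd_pop) {
    tibble::tibble(check = paste0("mean(", name, ")"),
                   target = target, value = mean(x),
                   tol = 4 * sd_pop / sqrt(n),
                   pass = abs(mean(x) - target) <= 4 * sd_pop / sqrt(n))
  }
  sds <- setNames(spec$moments$sd, spec$moments$parameter)
  checks <- dplyr::bind_rows(
    mean_check("SE", cohort$SE, mm$mean, mm$sd),
    mean_check("CCT", cohort$CCT, spec$cct_mean, spec$cct_sd),
    mean_check("AD", cohort$AD, mu["AD"], sds["AD"]),
    mean_check("LT", cohort$LT, mu["LT"], sds["LT"]),
    mean_check("AL", cohort$AL, mu["AL"], sds["AL"]),
    mean_check("P_c", der$P_c, mu["P_c"], sds["P_c"])
  )
  cor_pairs <- list(c("SE", "AD"), c("SE", "LT"), c("SE", "AL"),
                    c("SE", "P_c"), c("AD", "LT"), c("AD", "AL"),
                    c("AD", "P_c"), c("LT", "AL"), c("LT", "P_c"),
                    c("AL", "P_c"), c("AL", "VCD"))
  cor_checks <- purrr::map_dfr(cor_pairs, function(pr) {
    target <- spec$correlations[pr[1], pr[2]]
    value <- cor(der[[pr[1]]], der[[pr[2]]])
    tol <- if (identical(pr, c("AL", "VCD"))) 0.03 else cor_tol
    tibble::tibble(check = sprintf("cor(%s, %s)", pr[1], pr[2]),
                   target = target, value = value, tol = tol,
                   pass = abs(value - target) <= tol)
  })
  se_c <- cohort$SE - mean(cohort$SE)
  kurt <- n * sum(se_c^4) / sum(se_c^2)^2 - 3
  kurt_check <- tibble::tibble(check = "ex_kurtosis(SE) > 0",
                               target = 0, value = kurt, tol = NA_real_,
                               pass = kurt > 0)
  inv_ok <- all(validate_biometry(cohort, se_limit = spec$se_limit))
  inv_check <- tibble::tibble(check = "raw biometry invariants",
                              target = 1, value = as.numeric(inv_ok),
                              tol = NA_real_, pass = inv_ok)
  dplyr::bind_rows(checks, cor_checks, kurt_check, inv_check)
}
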