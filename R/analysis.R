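# Descriptive cohort analyses: summary table with emmetropic/whole-cohort
# comparison, Bonferroni-masked correlation matrix, refraction-binned
# overlap summaries, alignment regressions, biometric uniqueness counting
# and the relative (AL-scaled) profile.

table_params <- function(data) {
  c(if ("age_y" %in% names(data)) "age_y",
    intersect(c("SE", "CCT", "AD", "LT", "VCD", "AL",
                "P_c", "P_lb", "P_eye", "P_ax"), names(data)))
}

param_units <- function(p) {
  dplyr::case_match(p,
    "age_y" ~ "years",
    c("SE", "P_c", "P_lb", "P_eye", "P_ax") ~ "D",
    c("CCT", "AD", "LT", "VCD", "AL") ~ "mm",
    .default = "")
}

#' Descriptive summary: emmetropic eyes versus the entire cohort
#'
#' Mean, SD and range per parameter for the emmetropic subset and the
#' entire cohort (the emmetropic eyes are a subset of, not complementary
#' to, the comparison group -- the published convention), with an unpaired
#' two-sample t-test per parameter at the Bonferroni-corrected threshold
#' 0.05/11.
#'
#' @param data Derived biometry tibble (needs at least `SE`; statistics
#'   are reported for whichever of the standard parameters are present).
#' @param criterion [emmetropia_criterion()].
#' @param alpha Significance threshold after Bonferroni correction.
#' @return A tibble with one row per parameter: `parameter`, `unit`,
#'   `n_emm`, `mean_emm`, `sd_emm`, `min_emm`, `max_emm`, `n_all`,
#'   `mean_all`, `sd_all`, `min_all`, `max_all`, `p_value`, `significant`.
#' @export
descriptive_table <- function(data, criterion = emmetropia_criterion(),
                              alpha = 0.05 / 11) {
  required_cols(data, "SE", "descriptive_table")
  if (nrow(data) == 0) abort("Empty cohort.")
  emm <- data[is_emmetropic(data$SE, criterion), , drop = FALSE]
  if (nrow(emm) == 0) {
    warn("No emmetropic eyes under the criterion; emmetropic columns are NA.")
  }
  params <- table_params(data)
  purrr::map_dfr(params, function(p) {
    xa <- data[[p]]
    xe <- emm[[p]]
    pv <- if (length(xe) > 1 && sd(xa) > 0 && sd(xe) > 0) {
      t.test(xe, xa)$p.value
    } else NA_real_
    tibble::tibble(
      parameter = p, unit = param_units(p),
      n_emm = length(xe),
      mean_emm = if (length(xe)) mean(xe) else NA_real_,
      sd_emm = if (length(xe) > 1) sd(xe) else NA_real_,
      min_emm = if (length(xe)) min(xe) else NA_real_,
      max_emm = if (length(xe)) max(xe) else NA_real_,
      n_all = length(xa),
      mean_all = mean(xa), sd_all = sd(xa),
      min_all = min(xa), max_all = max(xa),
      p_value = pv,
      significant = !is.na(pv) & pv < alpha)
  })
}

#' Pearson correlation matrix with Bonferroni mask
#'
#' Pairwise Pearson correlations and p-values over the standard parameter
#' set (SE, AD, LT, VCD, AL, P_c, P_lb, P_eye, P_ax), with a significance
#' mask at the Bonferroni-corrected threshold. Zero-variance columns are
#' flagged and their entries set to `NA` rather than propagating `NaN`.
#'
#' @param data Derived biometry tibble.
#' @param params Parameters to correlate (defaults to those of the
#'   standard set present in `data`).
#' @param alpha Significance threshold (default 0.05/11).
#' @return An object of class `cohort_correlations`: list with matrices
#'   `r`, `p`, `significant`, the `n` used, `alpha`, and `degenerate`
#'   (names of zero-variance columns).
#' @export
correlation_matrix <- function(data, params = NULL, alpha = 0.05 / 11) {
  params <- params %||%
    intersect(c("SE", "AD", "LT", "VCD", "AL", "P_c", "P_lb",
                "P_eye", "P_ax"), names(data))
  required_cols(data, params, "correlation_matrix")
  if (nrow(data) < 3) abort("Need at least 3 rows for correlations.")
  k <- length(params)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(params, params))
  degenerate <- params[vapply(data[params], function(x) sd(x) == 0,
                              logical(1))]
  for (i in seq_len(k)) {
    r[i, i] <- if (params[i] %in% degenerate) NA_real_ else 1
    p[i, i] <- 0
    for (j in seq_len(i - 1)) {
      if (params[i] %in% degenerate || params[j] %in% degenerate) next
      ct <- cor.test(data[[params[i]]], data[[params[j]]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  sig <- !is.na(p) & p < alpha
  diag(sig) <- FALSE
  structure(list(r = r, p = p, significant = sig, n = nrow(data),
                 alpha = alpha, degenerate = degenerate),
            class = "cohort_correlations")
}

#' @export
print.cohort_correlations <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (n = %d, Bonferroni alpha = %.4g)\n",
              x$n, x$alpha))
  print(round(x$r, digits))
  if (length(x$degenerate)) {
    cat("Zero-variance column(s):", paste(x$degenerate, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Refraction-binned biometry summary
#'
#' Splits the cohort into 1 D bins of spherical equivalent (integer-centred
#' bins, half-integer edges, left-closed: SE = 0.49 falls in bin 0, SE =
#' 0.50 in bin +1) and summarises each biometric parameter per bin with
#' its mean and the 95% confidence interval of the mean. Bins with fewer
#' than 3 eyes are reported but their CI is suppressed.
#'
#' @param data Derived biometry tibble.
#' @param params Parameters to summarise.
#' @param width Bin width, dioptres.
#' @return A tibble: `bin` (centre, D), `parameter`, `n`, `mean`, `ci_lo`,
#'   `ci_hi`.
#' @export
binned_group_summary <- function(data,
                                 params = c("P_c", "P_lb", "ACD_tot", "AL"),
                                 width = 1) {
  required_cols(data, c("SE", params), "binned_group_summary")
  if (nrow(data) == 0) abort("Empty cohort.")
  data |>
    dplyr::mutate(bin = floor(.data$SE / width + 0.5) * width) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value") |>
    dplyr::group_by(.data$bin, .data$parameter) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data$value),
                     se = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(
      half = ifelse(.data$n >= 3,
                    qt(0.975, pmax(.data$n - 1, 1)) * .data$se, NA_real_),
      ci_lo = .data$mean - .data$half,
      ci_hi = .data$mean + .data$half) |>
    dplyr::select("bin", "parameter", "n", "mean", "ci_lo", "ci_hi") |>
    dplyr::arrange(.data$parameter, .data$bin)
}

#' Alignment regressions of lens-surface positions on axial length
#'
#' Ordinary least-squares regressions of the anterior chamber depth
#' (ACD_tot, anterior lens surface) and anterior segment length (ASL,
#' posterior lens surface) on axial length within an AL window (default
#' 20--27 mm; longer eyes no longer follow the linear alignment), plus
#' per-refractive-group regression slopes of P_c, P_lb and ACD_tot on AL,
#' where groups are 1 D refraction bins with at least `min_group_n` eyes.
#'
#' @param data Derived biometry tibble with `AL`, `ACD_tot`, `ASL`, `SE`,
#'   `P_c`, `P_lb`.
#' @param window AL window (mm), inclusive.
#' @param min_group_n Minimum eyes per refractive bin for the group slopes.
#' @return A list of class `alignment_regressions`: `fits` -- tibble with
#'   one row per response (`response`, `slope`, `intercept`, `r2`,
#'   `resid_sd`, `n`, `window_lo`, `window_hi`); `group_slopes` -- tibble
#'   (`bin`, `response`, `slope`, `intercept`, `n`).
#' @export
fit_alignment_regressions <- function(data, window = c(20, 27),
                                      min_group_n = 20) {
  required_cols(data, c("AL", "ACD_tot", "ASL", "SE", "P_c", "P_lb"),
                "fit_alignment_regressions")
  win <- data[data$AL >= window[1] & data$AL <= window[2], , drop = FALSE]
  if (nrow(win) < 10) abort("Fewer than 10 eyes in the AL window.")
  if (sd(win$AL) == 0) abort("Degenerate AL variance in window.")
  one_fit <- function(response) {
    m <- lm(win[[response]] ~ win$AL)
    tibble::tibble(response = response,
                   slope = unname(coef(m)[2]),
                   intercept = unname(coef(m)[1]),
                   r2 = summary(m)$r.squared,
                   resid_sd = sd(stats::residuals(m)),
                   n = nrow(win),
                   window_lo = window[1], window_hi = window[2])
  }
  fits <- dplyr::bind_rows(one_fit("ACD_tot"), one_fit("ASL"))
  groups <- data |>
    dplyr::mutate(bin = floor(.data$SE + 0.5)) |>
    dplyr::group_by(.data$bin) |>
    dplyr::filter(dplyr::n() >= min_group_n, sd(.data$AL) > 0) |>
    dplyr::ungroup()
  group_slopes <- purrr::map_dfr(c("P_c", "P_lb", "ACD_tot"), function(resp) {
    groups |>
      dplyr::group_by(.data$bin) |>
      dplyr::group_modify(function(g, key) {
        m <- lm(g[[resp]] ~ g$AL)
        tibble::tibble(response = resp,
                       slope = unname(coef(m)[2]),
                       intercept = unname(coef(m)[1]),
                       n = nrow(g))
      }) |>
      dplyr::ungroup()
  })
  structure(list(fits = fits, group_slopes = group_slopes),
            class = "alignment_regressions")
}

#' @export
print.alignment_regressions <- function(x, ...) {
  cat("Alignment regressions on AL\n")
  print(x$fits)
  invisible(x)
}

#' Count biometrically indistinguishable pairs of eyes
#'
#' Two eyes form an indistinguishable pair when the absolute difference in
#' every parameter of the uniqueness specification is at most the limit of
#' agreement (limit factor times the device repeatability). All unordered
#' pairs are counted; matched eyes are not removed, so three mutually
#' identical eyes yield three pairs. The search sorts on the
#' tightest-tolerance parameter so only candidate neighbours are compared;
#' the result is identical to the exhaustive O(n^2) comparison.
#'
#' @param data Derived biometry tibble containing the spec's parameters.
#' @param spec A [uniqueness_spec()].
#' @return A list: `n_pairs`, `pairs` (tibble `id1`, `id2`), `tolerances`
#'   (named limits of agreement actually applied).
#' @export
uniqueness_pairs <- function(data, spec = uniqueness_spec()) {
  required_cols(data, spec$parameters, "uniqueness_pairs")
  n <- nrow(data)
  tol <- spec$limit_factor * spec$repeatability
  ids <- eye_ids(data)
  if (n < 2) {
    return(list(n_pairs = 0L,
                pairs = tibble::tibble(id1 = character(), id2 = character()),
                tolerances = tol))
  }
  X <- as.matrix(data[spec$parameters])
  # scan along the relatively tightest parameter
  rel <- tol / vapply(seq_along(tol), function(j) max(sd(X[, j]), 1e-12),
                      numeric(1))
  key <- which.min(rel)
  ord <- order(X[, key])
  Xs <- X[ord, , drop = FALSE]
  i1 <- integer(0)
  i2 <- integer(0)
  for (i in seq_len(n - 1)) {
    j <- i + 1
    while (j <= n && Xs[j, key] - Xs[i, key] <= tol[key]) {
      if (all(abs(Xs[j, ] - Xs[i, ]) <= tol)) {
        i1 <- c(i1, ord[i])
        i2 <- c(i2, ord[j])
      }
      j <- j + 1
    }
  }
  pairs <- tibble::tibble(id1 = ids[pmin(i1, i2)], id2 = ids[pmax(i1, i2)])
  pairs <- dplyr::arrange(pairs, .data$id1, .data$id2)
  list(n_pairs = nrow(pairs), pairs = pairs, tolerances = tol)
}

#' Relative (axial-length-scaled) profile of the eye
#'
#' Per-eye positions of the refracting surfaces as a percentage of axial
#' length (posterior cornea, anterior lens, posterior lens) and the
#' relative power contributions of cornea and lens, `P_c / P_eye` and
#' `P_lb / P_eye`. With `effectivity = TRUE` an alternative contribution
#' is added in which each element's power is first translated to the
#' eye's second principal plane by vergence effectivity; this variant is
#' non-normative and reported only for comparison.
#'
#' @param data Derived biometry tibble.
#' @param effectivity Add the non-normative principal-plane-effectivity
#'   contributions.
#' @param idx [refractive_indices()].
#' @return A tibble: `eye_id` (if present), `AL`, `pos_cornea_post_pct`,
#'   `pos_lens_ant_pct`, `pos_lens_post_pct`, `P_cr`, `lens_fraction`
#'   (and, optionally, `P_cr_eff`, `lens_fraction_eff`).
#' @export
relative_scaling_profile <- function(data, effectivity = FALSE,
                                     idx = refractive_indices()) {
  required_cols(data, c("CCT", "ACD_tot", "ASL", "AL", "P_c", "P_lb",
                        "P_eye"), "relative_scaling_profile")
  out <- tibble::tibble(
    AL = data$AL,
    pos_cornea_post_pct = 100 * data$CCT / data$AL,
    pos_lens_ant_pct = 100 * data$ACD_tot / data$AL,
    pos_lens_post_pct = 100 * data$ASL / data$AL,
    P_cr = data$P_c / data$P_eye,
    lens_fraction = data$P_lb / data$P_eye)
  if ("eye_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(eye_id = data$eye_id), out)
  }
  if (effectivity) {
    required_cols(data, c("pp_eye2", "pp_c2", "LT"),
                  "relative_scaling_profile")
    # translate element powers to the eye's second principal plane
    # (vergence effectivity over the reduced distance); non-normative.
    t_c <- (data$pp_eye2 - data$pp_c2) / (1000 * idx$n)
    t_l <- (data$pp_eye2 - (data$ACD_tot + 0.571 * data$LT)) / (1000 * idx$n)
    pc_eff <- data$P_c / (1 - t_c * data$P_c)
    pl_eff <- data$P_lb / (1 - t_l * data$P_lb)
    out$P_cr_eff <- pc_eff / (pc_eff + pl_eff)
    out$lens_fraction_eff <- pl_eff / (pc_eff + pl_eff)
  }
  out
}
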