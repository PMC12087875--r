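# ggplot2 graphics for the main result types.

#' Plot a 1-D bigaussian fit over its histogram
#'
#' Histogram proportions with the fitted bigaussian and its two
#' components.
#'
#' @param object A `bigauss_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bigauss_fit
#' @export
autoplot.bigauss_fit <- function(object, ...) {
  h <- object$histogram
  p <- object$params
  grid <- tibble::tibble(x = seq(min(h$center), max(h$center), length.out = 400))
  grid$total <- eval_bigaussian(p, grid$x)
  grid$narrow <- p$a1 * exp(-((grid$x - p$mu1) / p$sigma1)^2)
  grid$broad <- p$a2 * exp(-((grid$x - p$mu2) / p$sigma2)^2)
  long <- tidyr::pivot_longer(grid, c("total", "narrow", "broad"),
                              names_to = "curve", values_to = "y")
  ggplot2::ggplot() +
    ggplot2::geom_col(data = h,
                      ggplot2::aes(x = .data$center, y = .data$proportion),
                      fill = "grey80", colour = "grey50", width = 1) +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$curve,
                                    linetype = .data$curve)) +
    ggplot2::scale_colour_manual(
      values = c(total = "black", narrow = "firebrick", broad = "steelblue")) +
    ggplot2::labs(x = "Spherical equivalent (D)",
                  y = "Proportion per 1 D bin",
                  colour = NULL, linetype = NULL,
                  title = sprintf("Bigaussian fit (r2 = %.3f)", object$r2)) +
    ggplot2::theme_minimal()
}

ellipse_path <- function(e, n_points = 181) {
  th <- seq(0, 2 * pi, length.out = n_points)
  tibble::tibble(
    x = e$center_x + e$len1 * cos(th) * e$vec1_x + e$len2 * sin(th) * e$vec2_x,
    y = e$center_y + e$len1 * cos(th) * e$vec1_y + e$len2 * sin(th) * e$vec2_y)
}

#' Plot one parameter pair of a multivariate bigaussian fit
#'
#' Scatter of the cohort over the chosen pair with the epsilon-scaled
#' covariance ellipses of both components.
#'
#' @param object An `mv_bigauss_fit`.
#' @param data Cohort tibble containing the pair columns (optional; the
#'   ellipses alone are drawn without it).
#' @param pair Character vector of two dimension names.
#' @param epsilon Ellipse scale.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot mv_bigauss_fit
#' @export
autoplot.mv_bigauss_fit <- function(object, data = NULL,
                                    pair = c("SE", "AL"), epsilon = 2.26,
                                    ...) {
  stopifnot(length(pair) == 2, all(pair %in% object$dimensions))
  paths <- purrr::map_dfr(c("Regulated", "Dysregulated"), function(comp) {
    ell <- pair_ellipses(object, epsilon, component = comp)
    e <- ell[(ell$var_x == pair[1] & ell$var_y == pair[2]) |
             (ell$var_x == pair[2] & ell$var_y == pair[1]), ]
    flip <- e$var_x != pair[1]
    pth <- ellipse_path(e)
    if (flip) pth <- tibble::tibble(x = pth$y, y = pth$x)
    pth$component <- comp
    pth
  })
  g <- ggplot2::ggplot()
  if (!is.null(data)) {
    g <- g + ggplot2::geom_point(
      data = data,
      ggplot2::aes(x = .data[[pair[1]]], y = .data[[pair[2]]]),
      alpha = 0.25, size = 0.6, colour = "grey40")
  }
  g +
    ggplot2::geom_path(
      data = paths,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$component),
      linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(Regulated = "firebrick", Dysregulated = "black")) +
    ggplot2::labs(x = pair[1], y = pair[2], colour = NULL,
                  title = sprintf("Covariance ellipses at ε = %.2f",
                                  epsilon)) +
    ggplot2::theme_minimal()
}

#' Plot the refraction-binned overlap of biometric parameters
#'
#' Per-bin means with 95% confidence intervals, one facet per parameter
#' (the analogue of the overlap-of-distributions figure).
#'
#' @param binned Output of [binned_group_summary()].
#' @return A ggplot.
#' @export
plot_binned_overlap <- function(binned) {
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      width = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Spherical equivalent bin (D)", y = "Mean ± 95% CI") +
    ggplot2::theme_minimal()
}

#' Plot the AL/CR ratio against refraction
#'
#' @param data Derived biometry tibble with `SE`, `AL_CR`.
#' @param criterion [emmetropia_criterion()] used to highlight emmetropic
#'   eyes.
#' @return A ggplot.
#' @export
plot_al_cr <- function(data, criterion = emmetropia_criterion()) {
  required_cols(data, c("SE", "AL_CR"), "plot_al_cr")
  d <- dplyr::mutate(data, emmetropic = is_emmetropic(.data$SE, criterion))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$SE, y = .data$AL_CR,
                                  colour = .data$emmetropic)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_hline(yintercept = 3, linetype = 2, colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey20",
                                            `FALSE` = "steelblue"),
                                 labels = c(`TRUE` = "emmetropic",
                                            `FALSE` = "ametropic")) +
    ggplot2::labs(x = "Spherical equivalent (D)", y = "AL/CR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the relative scaling profile
#'
#' Surface positions as a percentage of axial length against AL, with the
#' corneal power fraction on a second panel.
#'
#' @param profile Output of [relative_scaling_profile()].
#' @return A ggplot.
#' @export
plot_relative_scaling <- function(profile) {
  pos <- tidyr::pivot_longer(
    profile,
    c("pos_cornea_post_pct", "pos_lens_ant_pct", "pos_lens_post_pct"),
    names_to = "surface", values_to = "pct")
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$AL, y = .data$pct,
                                    colour = .data$surface)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::labs(x = "Axial length (mm)", y = "Position (% of AL)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
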