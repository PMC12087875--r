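# End-to-end reproduction pipeline: generate (or read) a cohort, derive
# the optics, run every descriptive and bigaussian analysis, classify,
# and write a report directory.

#' Pipeline configuration
#'
#' Defaults mirror the published analysis conditions: n = 2000 eyes,
#' bigaussian refraction model, 1 D emmetropia band \[-0.5, +0.5\] D, the
#' standard uniqueness tolerances, and (by default at interactive scale)
#' 1000 multivariate restarts; lower `restarts` for quick runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param n Cohort size (ignored when `input_csv` is given).
#' @param input_csv Optional path to an existing cohort CSV; skips
#'   generation.
#' @param restarts Multivariate fit restarts.
#' @param mode Generator mode, see [cohort_spec()].
#' @param epsilon_bracket Ellipse-scale search interval.
#' @param criterion [emmetropia_criterion()].
#' @param u_spec [uniqueness_spec()].
#' @param se_params [bigauss_params()] refraction model for generation.
#' @param write_figures Write PNG figures (TRUE by default).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, n = 2000,
                            input_csv = NULL, restarts = 1000,
                            mode = "refraction-first",
                            epsilon_bracket = c(0.5, 5),
                            criterion = emmetropia_criterion(),
                            u_spec = uniqueness_spec(),
                            se_params = se_mixture_reference(),
                            write_figures = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n = as.integer(n), input_csv = input_csv,
                 restarts = restarts, mode = mode,
                 epsilon_bracket = epsilon_bracket,
                 criterion = criterion, u_spec = u_spec,
                 se_params = se_params,
                 write_figures = isTRUE(write_figures)),
            class = "pipeline_config")
}

config_fingerprint <- function(config) {
  rlang::hash(config[setdiff(names(config), "out_dir")])
}

#' Run the full reproduction pipeline
#'
#' Stages, in order: generate (or read) the cohort; derive the full
#' per-eye optics; descriptive table; correlation matrix; refraction-
#' binned summary; 1-D bigaussian fit of the refractions; multivariate
#' bigaussian fit; ellipse-scale calibration against the 1-D narrow
#' weight; Regulated/Dysregulated classification; alignment regressions;
#' uniqueness pairs; relative scaling profile; report. Every artifact is
#' written under `config$out_dir` together with a manifest carrying the
#' package version, seed and configuration hash. A failing stage stops
#' the run but retains the artifacts written so far plus a failure
#' manifest.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; the stage results are
#'   returned as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  log <- list()
  results <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      jsonlite::write_json(
        list(failed_stage = name, error = conditionMessage(e),
             completed = names(results)),
        out("failure_manifest.json"), auto_unbox = TRUE)
      abort(sprintf("Pipeline stage '%s' failed: %s",
                    name, conditionMessage(e)))
    })
    log[[name]] <<- list(seconds = as.numeric(Sys.time() - t0, units = "secs"))
    results[[name]] <<- val
    inform(sprintf("[pipeline] %-16s done (%.1fs)", name,
                   log[[name]]$seconds))
    val
  }

  cohort <- stage("cohort", {
    if (!is.null(config$input_csv)) {
      read_cohort(config$input_csv)
    } else {
      generate_cohort(cohort_spec(n = config$n, seed = config$seed,
                                  mode = config$mode,
                                  se_params = config$se_params))
    }
  })
  write_cohort(cohort, out("cohort.csv"))

  derived <- stage("derive", derive_biometry(cohort))
  excl <- attr(derived, "exclusions")

  desc <- stage("descriptive", descriptive_table(derived, config$criterion))
  readr::write_csv(desc, out("descriptive_table.csv"))

  corr <- stage("correlations", correlation_matrix(derived))
  readr::write_csv(tibble::as_tibble(corr$r, rownames = "parameter"),
                   out("correlations_r.csv"))
  readr::write_csv(tibble::as_tibble(corr$p, rownames = "parameter"),
                   out("correlations_p.csv"))

  binned <- stage("binned", binned_group_summary(derived))
  readr::write_csv(binned, out("binned_summary.csv"))

  se_fit <- stage("fit_se", fit_bigaussian_1d(derived$SE, seed = config$seed))
  jsonlite::write_json(
    list(params = unclass(se_fit$params), r2 = se_fit$r2,
         weights = as.list(se_fit$weights), n = se_fit$n),
    out("se_fit.json"), auto_unbox = TRUE, digits = NA)

  mv_fit <- stage("fit_biometry",
                  fit_multivariate_bigaussian(derived,
                                              restarts = config$restarts,
                                              seed = config$seed))
  jsonlite::write_json(
    list(weights = as.list(mv_fit$weights),
         means = apply(mv_fit$means, 1, as.list),
         loglik = mv_fit$loglik, aic = mv_fit$aic,
         n = mv_fit$n, restarts = mv_fit$restarts),
    out("mv_fit.json"), auto_unbox = TRUE, digits = NA)

  calib <- stage("calibrate",
                 calibrate_epsilon(derived, mv_fit,
                                   target = unname(se_fit$weights["w1"]),
                                   bracket = config$epsilon_bracket))

  classified <- stage("classify",
                      classify_cohort(derived, mv_fit, calib$epsilon))
  write_cohort(classified, out("derived.csv"))
  jsonlite::write_json(
    list(epsilon = calib$epsilon,
         coverage_1d = coverage_1d(calib$epsilon),
         target = calib$target,
         fraction_regulated = mean(classified$subgroup == "Regulated"),
         fraction_dysregulated = mean(classified$subgroup == "Dysregulated"),
         per_pair_failures = as.list(colSums(
           pairwise_mahalanobis(as.matrix(derived[mv_fit$dimensions]),
                                mv_fit) > calib$epsilon))),
    out("classification.json"), auto_unbox = TRUE, digits = NA)

  regs <- stage("regressions", fit_alignment_regressions(derived))
  readr::write_csv(regs$fits, out("regressions.csv"))
  readr::write_csv(regs$group_slopes, out("group_slopes.csv"))

  uniq <- stage("uniqueness", uniqueness_pairs(derived, config$u_spec))
  jsonlite::write_json(
    list(n_pairs = uniq$n_pairs, pairs = uniq$pairs,
         tolerances = as.list(uniq$tolerances)),
    out("uniqueness.json"), auto_unbox = TRUE, digits = NA)

  prof <- stage("scaling", relative_scaling_profile(derived))
  readr::write_csv(prof, out("scaling_profile.csv"))

  if (config$write_figures) {
    stage("figures", {
      ggplot2::ggsave(out("fig_se_fit.png"), autoplot(se_fit),
                      width = 6, height = 4, dpi = 120)
      ggplot2::ggsave(out("fig_ellipses.png"),
                      autoplot(mv_fit, derived, pair = c("SE", "AL"),
                               epsilon = calib$epsilon),
                      width = 6, height = 4, dpi = 120)
      ggplot2::ggsave(out("fig_overlap.png"), plot_binned_overlap(binned),
                      width = 7, height = 5, dpi = 120)
      ggplot2::ggsave(out("fig_al_cr.png"),
                      plot_al_cr(derived, config$criterion),
                      width = 6, height = 4, dpi = 120)
      TRUE
    })
  }

  stage("report", {
    emm_n <- sum(is_emmetropic(derived$SE, config$criterion))
    lines <- c(
      "# Cohort reproduction report",
      "",
      sprintf("- package: emmetrics %s", as.character(packageVersion("emmetrics"))),
      sprintf("- seed: %d; config hash: %s", config$seed,
              config_fingerprint(config)),
      sprintf("- cohort: %d eyes (%d excluded during derivation)",
              nrow(derived), nrow(excl)),
      sprintf("- emmetropic eyes: %d (%.1f%%)", emm_n,
              100 * emm_n / nrow(derived)),
      "",
      "## Refractive distribution",
      sprintf("- bigaussian weights: %.1f%% / %.1f%% (r2 = %.3f)",
              100 * se_fit$weights[1], 100 * se_fit$weights[2], se_fit$r2),
      "",
      "## Subgroups",
      sprintf("- epsilon = %.3f (1-D coverage %.2f%%)", calib$epsilon,
              100 * coverage_1d(calib$epsilon)),
      sprintf("- Regulated %.1f%% / Dysregulated %.1f%%",
              100 * mean(classified$subgroup == "Regulated"),
              100 * mean(classified$subgroup == "Dysregulated")),
      "",
      "## Alignment regressions (AL window 20-27 mm)",
      sprintf("- %s: slope %.4f, intercept %.4f, r2 %.3f, resid SD %.2f mm",
              regs$fits$response, regs$fits$slope, regs$fits$intercept,
              regs$fits$r2, regs$fits$resid_sd),
      "",
      "## Uniqueness",
      sprintf("- indistinguishable pairs: %d", uniq$n_pairs))
    writeLines(lines, out("report.md"))
    TRUE
  })

  jsonlite::write_json(
    list(package_version = as.character(packageVersion("emmetrics")),
         seed = config$seed,
         config_hash = config_fingerprint(config),
         files = list.files(config$out_dir),
         stage_seconds = lapply(log, `[[`, "seconds")),
    out("manifest.json"), auto_unbox = TRUE)

  res_dir <- config$out_dir
  attr(res_dir, "results") <- results
  invisible(res_dir)
}
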