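# Cohort CSV schema. Files use unit-suffixed headers; in R the columns
# carry plain parameter names. UTF-8, decimal point, one row per eye.

cohort_schema <- function() {
  c(eye_id = "eye_id", age_y = "age_y", sex = "sex",
    SE = "SE_D", r_ca = "r_ca_mm", r_cp = "r_cp_mm", CCT = "CCT_mm",
    AD = "AD_mm", LT = "LT_mm", AL = "AL_mm",
    ACD_tot = "ACD_tot_mm", ASL = "ASL_mm", VCD = "VCD_mm",
    P_ca = "P_ca_D", P_cp = "P_cp_D", P_c = "P_c_D", P_lb = "P_lb_D",
    P_eye = "P_eye_D", pp_eye2 = "pp_eye2_mm", P_ax = "P_ax_D",
    SE_model = "SE_model_D", P_cr = "P_cr", AL_CR = "AL_CR",
    subgroup = "subgroup")
}

#' Read a cohort CSV
#'
#' Reads a per-eye cohort file with the package's column schema
#' (`eye_id, age_y, sex, SE_D, r_ca_mm, r_cp_mm, CCT_mm, AD_mm, LT_mm,
#' AL_mm`, plus optional derived columns) and returns a tibble with plain
#' parameter names (`SE`, `r_ca`, ...). A missing required column is
#' fatal; rows with unparsable numeric cells are dropped with their line
#' numbers reported.
#'
#' @param path Path to a CSV file.
#' @return A cohort tibble; attribute `"rejected_rows"` lists dropped data
#'   rows (file line numbers and reason).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  schema <- cohort_schema()
  required <- schema[c("eye_id", "age_y", "sex", "SE", "r_ca", "r_cp",
                       "CCT", "AD", "LT", "AL")]
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(unname(required), hdr)
  if (length(missing) > 0) {
    abort(sprintf("Missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  numeric_file_cols <- setdiff(intersect(unname(schema), hdr),
                               c("eye_id", "sex", "subgroup"))
  types <- do.call(readr::cols, c(
    setNames(rep(list(readr::col_double()), length(numeric_file_cols)),
             numeric_file_cols),
    list(.default = readr::col_guess())))
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = types, show_col_types = FALSE))
  probs <- readr::problems(raw)
  rejected <- tibble::tibble(line = integer(), reason = character())
  if (nrow(probs) > 0) {
    bad_lines <- sort(unique(probs$row))  # file lines, header included
    rejected <- tibble::tibble(
      line = bad_lines,
      reason = vapply(bad_lines, function(r) {
        pr <- probs[probs$row == r, ]
        sprintf("unparsable cell in column(s) %s",
                paste(unique(hdr[pr$col]), collapse = ", "))
      }, character(1)))
    inform(sprintf("read_cohort(): dropped %d malformed row(s) at line(s) %s",
                   length(bad_lines),
                   paste(head(bad_lines, 10), collapse = ", ")))
    raw <- raw[-(bad_lines - 1L), , drop = FALSE]
  }
  present <- schema[unname(schema) %in% names(raw)]
  out <- raw[unname(present)]
  names(out) <- names(present)
  attr(out, "rejected_rows") <- rejected
  out
}

#' Write a cohort CSV
#'
#' Writes a cohort tibble (plain parameter names) using the file schema of
#' [read_cohort()]. Numeric values keep full double precision, so a
#' write/read round trip is value-identical to within 1e-12.
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  schema <- cohort_schema()
  known <- schema[names(schema) %in% names(data)]
  extra <- setdiff(names(data), c(names(known), "component"))
  out <- data[names(known)]
  names(out) <- unname(known)
  if ("component" %in% names(data)) out$component <- data$component
  for (cl in extra) out[[cl]] <- data[[cl]]
  readr::write_csv(out, path)
  invisible(path)
}
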