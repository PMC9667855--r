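#' Read and write the survey's tabular inputs and outputs
#'
#' Thin readers over [readr::read_csv()] with column checks: subject tables
#' (`subject_id`, optional `sex`, `entry_age`, `exit_age`/`event` for a
#' single-outcome cohort, covariate columns), long diagnosis tables
#' (`subject_id`, `code`, `chapter`, `diagnosis_age`) and code-to-chapter
#' maps (`code`, `chapter`).
#'
#' @param path File path.
#' @return A tibble.
#' @name survey_io
NULL

read_checked <- function(path, required) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(paste0(path, " lacks column(s): ", paste(missing, collapse = ", ")))
  }
  out
}

#' @rdname survey_io
#' @export
read_subjects <- function(path) read_checked(path, c("subject_id", "entry_age"))

#' @rdname survey_io
#' @export
read_cohort <- function(path) {
  read_checked(path, c("subject_id", "entry_age", "exit_age", "event"))
}

#' @rdname survey_io
#' @export
read_events <- function(path) {
  read_checked(path, c("subject_id", "code", "diagnosis_age"))
}

#' @rdname survey_io
#' @export
read_chapter_map <- function(path) read_checked(path, c("code", "chapter"))

#' Serialise a proportional-hazards fit to CSV
#'
#' Writes one row per design column: term, covariate, level, role, estimate,
#' standard error and p-value.
#'
#' @param fit A [fit_ph()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ph_fit <- function(fit, path) {
  stopifnot(inherits(fit, "ph_fit"))
  readr::write_csv(fit$coefficients, path)
  invisible(path)
}

#' Write or read a Weibull baseline hazard as config-style text
#'
#' Two `key = value` lines (`shape = `, `scale = `).
#'
#' @param bh A [weibull_hazard()].
#' @param path File path.
#' @return `path` (write) or a [weibull_hazard()] (read).
#' @export
write_baseline <- function(bh, path) {
  stopifnot(inherits(bh, "weibull_hazard"))
  writeLines(c(paste("shape =", format(bh$shape, digits = 17)),
               paste("scale =", format(bh$scale, digits = 17))), path)
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  kv <- read_ini_flat(path)
  weibull_hazard(as.numeric(kv[["shape"]]), as.numeric(kv[["scale"]]))
}

read_ini_flat <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    out[[trimws(sub("=.*$", "", ln))]] <- trimws(sub("^[^=]*=", "", ln))
  }
  out
}
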