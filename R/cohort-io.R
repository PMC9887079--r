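# Delimited-text cohort input/output. One row per scan; columns lesion_id,
# patient_id, time_months, volume_cm3 and optional label, subgroup,
# upfront_wbrt. Numbers are written with 17 significant digits so that
# write -> read -> write round-trips bit-identically.

.num17 <- function(x) sprintf("%.17g", x)

#' Write a cohort as delimited text
#'
#' Writes one CSV row per scan. Times are written as months since the
#' lesion's first scan (the model is time-translation invariant and
#' absolute dates are avoided). Volumes are written in cm^3 with full
#' double precision.
#'
#' @param lesions List of [lesion_series()] or `"synthetic_lesion"`
#'   objects (their observed series is written; use [write_truth()] for
#'   the generator's truth table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(lesions, path) {
  lesions <- lapply(lesions, function(x)
    if (inherits(x, "synthetic_lesion")) x$series else x)
  rows <- lapply(lesions, function(s) {
    data.frame(lesion_id = s$lesion_id, patient_id = s$patient_id,
               time_months = .num17(s$times - s$times[1]),
               volume_cm3 = .num17(s$volumes),
               label = s$label, subgroup = s$subgroup,
               upfront_wbrt = s$upfront_wbrt, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the generator's truth table
#'
#' True parameters and noiseless growth rates of a synthetic cohort, one
#' row per lesion, kept in a separate file so the observable cohort table
#' never contains truth columns.
#'
#' @param cohort List of `"synthetic_lesion"` objects from
#'   [generate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(cohort, path) {
  stopifnot(all(vapply(cohort, inherits, logical(1), "synthetic_lesion")))
  rows <- lapply(cohort, function(x) {
    data.frame(lesion_id = x$series$lesion_id,
               true_beta = .num17(x$true_params$beta),
               true_alpha = .num17(x$true_params$alpha),
               true_v0 = .num17(x$true_params$v0),
               true_lambda1 = .num17(x$true_lambda$lambda1),
               true_lambda2 = .num17(x$true_lambda$lambda2),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Reads a CSV with columns `lesion_id`, `patient_id`, `time_months`,
#' `volume_cm3` and optional `label`, `subgroup`, `upfront_wbrt`, one row
#' per scan, groups rows by lesion and sorts by time. Lesions that fail
#' the inclusion criterion (three increasing volumes) are loaded and
#' flagged ineligible rather than rejected; downstream code screens on
#' [is_fittable()].
#'
#' @param path CSV file path.
#' @param units `"cm3"` (default) or `"mm3"` (volumes divided by 1000 on
#'   read; a single internal unit avoids silent thousand-fold errors).
#' @param fail_fast If `TRUE` (default) any malformed row aborts the read
#'   with per-row diagnostics; if `FALSE` offending lesions are dropped
#'   with a warning.
#' @return List of [lesion_series()].
#' @export
read_cohort <- function(path, units = c("cm3", "mm3"), fail_fast = TRUE) {
  units <- match.arg(units)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("lesion_id", "time_months", "volume_cm3")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L)
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (units == "mm3") d$volume_cm3 <- d$volume_cm3 / 1000
  problems <- character(0)
  key <- paste(d$lesion_id, d$time_months)
  if (anyDuplicated(key))
    problems <- c(problems, paste("duplicate (lesion, time) rows:",
                                  paste(unique(key[duplicated(key)]),
                                        collapse = "; ")))
  bad_vol <- which(!is.finite(d$volume_cm3) | d$volume_cm3 <= 0)
  if (length(bad_vol) > 0L)
    problems <- c(problems, paste("non-positive volume in row(s):",
                                  paste(bad_vol, collapse = ", ")))
  if (length(problems) > 0L && fail_fast)
    stop(paste(problems, collapse = "\n"), call. = FALSE)
  if (length(problems) > 0L)
    warning(paste(problems, collapse = "\n"))

  opt <- function(rows, col, default)
    if (col %in% names(d) && !is.na(d[[col]][rows[1]]) &&
        nzchar(as.character(d[[col]][rows[1]]))) d[[col]][rows[1]] else default
  out <- list()
  for (id in unique(d$lesion_id)) {
    rows <- which(d$lesion_id == id)
    rows <- rows[order(d$time_months[rows])]
    if (any(!is.finite(d$volume_cm3[rows]) | d$volume_cm3[rows] <= 0) ||
        anyDuplicated(d$time_months[rows])) next  # reported above
    out[[length(out) + 1L]] <- lesion_series(
      id,
      times = d$time_months[rows],
      volumes = d$volume_cm3[rows],
      patient_id = opt(rows, "patient_id", NA_character_),
      label = opt(rows, "label", "unknown"),
      subgroup = opt(rows, "subgroup", NA_character_),
      upfront_wbrt = as.logical(opt(rows, "upfront_wbrt", NA)))
  }
  out
}
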