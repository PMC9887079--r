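# Longitudinal volume series for a single lesion.

#' Longitudinal lesion volume series
#'
#' One lesion's dated contrast-enhancing volume measurements, with an
#' optional outcome label (`"PD"` progressive disease, `"RN"` radiation
#' necrosis, or `"unknown"`) and optional treatment annotations.
#'
#' A series is *fittable* (eligible for exponent identification) when it has
#' at least three measurements and the first three volumes are strictly
#' increasing — the inclusion criterion of the analysis, since the growth
#' model only describes increasing volumes and three points are needed to
#' identify its three parameters.
#'
#' @param lesion_id Identifier for the lesion (coerced to character).
#' @param times Acquisition times in months, strictly increasing, length
#'   >= 2.
#' @param volumes Contrast-enhancing volumes in cm^3, all positive, same
#'   length as `times`.
#' @param patient_id Optional patient identifier.
#' @param label Outcome label: `"PD"`, `"RN"` or `"unknown"` (default).
#' @param subgroup Optional focal-treatment subgroup, `"SRS"`
#'   (single-session radiosurgery) or `"FSRT"` (fractionated radiotherapy).
#' @param upfront_wbrt Optional logical: whole-brain radiotherapy given
#'   before the focal treatment.
#'
#' @return An object of class `"lesion_series"`.
#' @seealso [is_fittable()], [fit_vb_exponent()], [growth_rates()]
#' @examples
#' s <- lesion_series("L1", times = c(0, 3, 5.5), volumes = c(0.4, 0.9, 2.1),
#'                    label = "RN")
#' is_fittable(s)
#' @export
lesion_series <- function(lesion_id, times, volumes, patient_id = NA_character_,
                          label = c("unknown", "PD", "RN"),
                          subgroup = NA_character_, upfront_wbrt = NA) {
  label <- match.arg(label)
  times <- as.numeric(times)
  volumes <- as.numeric(volumes)
  if (length(times) != length(volumes))
    stop("'times' and 'volumes' must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("a lesion series needs at least 2 measurements", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(volumes)))
    stop("'times' and 'volumes' must be finite", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(volumes <= 0))
    stop("'volumes' must be positive", call. = FALSE)
  if (!is.na(subgroup) && !subgroup %in% c("SRS", "FSRT"))
    stop("'subgroup' must be \"SRS\", \"FSRT\" or NA", call. = FALSE)
  structure(list(lesion_id = as.character(lesion_id),
                 patient_id = as.character(patient_id),
                 times = times, volumes = volumes, label = label,
                 subgroup = as.character(subgroup),
                 upfront_wbrt = as.logical(upfront_wbrt)),
            class = "lesion_series")
}

#' @export
print.lesion_series <- function(x, ...) {
  cat(sprintf("Lesion %s (patient %s) — label %s", x$lesion_id,
              x$patient_id, x$label))
  if (!is.na(x$subgroup)) cat(", ", x$subgroup, sep = "")
  if (isTRUE(x$upfront_wbrt)) cat(" + upfront WBRT")
  cat("\n")
  print(data.frame(time_months = x$times, volume_cm3 = x$volumes),
        row.names = FALSE)
  cat(if (is_fittable(x)) "eligible for exponent fitting\n"
      else "NOT eligible: needs 3 increasing volumes\n")
  invisible(x)
}

#' Inclusion criterion: three increasing volumes
#'
#' Checks whether the first three measurements of a series show a volume
#' increase at each time point, the eligibility criterion for fitting the
#' growth exponent.
#'
#' @param series A [lesion_series()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_fittable <- function(series) {
  stopifnot(inherits(series, "lesion_series"))
  length(series$volumes) >= 3L && all(diff(series$volumes[1:3]) > 0)
}
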