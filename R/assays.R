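#' Kinetic slope of a single absorbance trace
#'
#' Ordinary least-squares slope of absorbance versus time, using every
#' timepoint. For the colorimetric amylase assay one activity unit is
#' defined as the amount of enzyme raising absorbance by one unit per
#' minute, so the fitted slope *is* the activity in assay units. The slope
#' is exact on noiseless linear traces and invariant to a constant offset.
#'
#' @param time_min Numeric vector of times in minutes, strictly increasing.
#' @param absorbance Matching vector of absorbance readings.
#' @return The slope (absorbance units per minute).
#' @export
#' @examples
#' kinetic_slope(0:6, 0.05 + 1.0 * 0:6) # 1 activity unit
kinetic_slope <- function(time_min, absorbance) {
  if (length(time_min) < 3L) {
    abort("a kinetic trace needs at least 3 timepoints")
  }
  if (length(absorbance) != length(time_min)) {
    abort("`time_min` and `absorbance` must have equal length")
  }
  if (any(diff(time_min) <= 0)) {
    abort("`time_min` must be strictly increasing")
  }
  unname(coef(lm(absorbance ~ time_min))[2])
}

#' Amylase activity from kinetic traces
#'
#' Fits a kinetic slope per trace. Traces are grouped by `sample` plus any
#' of `replicate` / `tech` columns present; when a `tech` column marks
#' technical duplicates their slopes are averaged within each biological
#' replicate before any unit conversion, mirroring the usual plate layout
#' (technical duplicates inside biological triplicates). If a calibration
#' curve is supplied, slopes are also converted to concentration units by
#' inverse prediction.
#'
#' @param traces Long tibble with columns `sample`, `time_min`,
#'   `absorbance`, optionally `replicate` and `tech`.
#' @param calibration Optional [fit_calibration()] curve.
#' @return Tibble with one row per sample (x replicate): `activity_units`
#'   (the slope) and, with a calibration, `concentration` and
#'   `extrapolated`.
#' @export
amylase_activity <- function(traces, calibration = NULL) {
  check_columns(traces, c("sample", "time_min", "absorbance"), "traces")
  keys <- intersect(c("sample", "replicate", "tech"), names(traces))
  out <- traces |>
    group_by(across(all_of(keys))) |>
    summarise(
      activity_units = kinetic_slope(.data$time_min, .data$absorbance),
      .groups = "drop"
    )
  if ("tech" %in% keys) {
    out <- out |>
      group_by(across(all_of(setdiff(keys, "tech")))) |>
      summarise(activity_units = mean(.data$activity_units),
                .groups = "drop")
  }
  if (!is.null(calibration)) {
    conc <- concentration_from_slope(calibration, out$activity_units)
    out$concentration <- conc$concentration
    out$extrapolated <- conc$extrapolated
  }
  out
}

#' Fit an amylase calibration curve
#'
#' Ordinary least-squares line of standard response (kinetic slope) versus
#' standard concentration. A valid curve has positive gain; the fitted gain,
#' intercept, R-squared and the standard range are kept for inverse
#' prediction and reporting.
#'
#' @param standards Tibble with columns `concentration`, `response`.
#' @return Object of class `calibration_curve`.
#' @export
#' @examples
#' std <- sim_calibration_series(response_per_unit = 0.002)
#' fit_calibration(std)
fit_calibration <- function(standards) {
  check_columns(standards, c("concentration", "response"), "standards")
  if (length(unique(standards$concentration)) < 2L) {
    abort("calibration needs at least 2 distinct concentrations")
  }
  if (any(standards$concentration < 0)) {
    abort("standard concentrations must be non-negative")
  }
  fit <- lm(response ~ concentration, data = standards)
  structure(
    list(
      gain = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = suppressWarnings(summary(fit)$r.squared),
      conc_range = range(standards$concentration),
      n = nrow(standards),
      model = fit
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "Calibration curve: gain %.4g, intercept %.4g, R^2 %.4f (%d standards, %g-%g units)\n",
    x$gain, x$intercept, x$r_squared, x$n, x$conc_range[1], x$conc_range[2]
  ))
  invisible(x)
}

#' Concentration by inverse prediction from a calibration curve
#'
#' `(slope - intercept) / gain`, with a flag for slopes whose predicted
#' concentration falls outside the standard range (extrapolation).
#'
#' @param curve A `calibration_curve`.
#' @param slope Numeric vector of measured kinetic slopes.
#' @return Tibble with `slope`, `concentration`, `extrapolated`.
#' @export
concentration_from_slope <- function(curve, slope) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.finite(curve$gain) || curve$gain <= 0) {
    abort("invalid calibration curve: gain must be positive")
  }
  conc <- (slope - curve$intercept) / curve$gain
  tibble(
    slope = slope,
    concentration = conc,
    extrapolated = conc < curve$conc_range[1] | conc > curve$conc_range[2]
  )
}

# Vectorized Miller-unit core: 1000 (A420 - f A550) / (t * v * OD600).
miller_unit_value <- function(a420, a550, od600, time_min, volume_ml,
                              scatter_factor = 1.75) {
  if (any(od600 <= 0)) abort("`od600` must be positive")
  if (any(time_min <= 0)) abort("`time_min` must be positive")
  if (any(volume_ml <= 0)) abort("`volume_ml` must be positive")
  1000 * (a420 - scatter_factor * a550) / (time_min * volume_ml * od600)
}

#' Beta-galactosidase activity in Miller units
#'
#' Classical Miller formula
#' `1000 * (A420 - 1.75 * A550) / (t * v * OD600)`
#' with reaction time `t` in minutes, assayed culture volume `v` in mL and
#' culture density OD600 — activity in nmol ONP per OD per minute. The 1.75
#' factor corrects A420 for light scattering by cell debris (estimated from
#' A550) and is configurable.
#'
#' @param readings Tibble with columns `od600`, `a420`, `a550`, `time_min`,
#'   `volume_ml` (see [sim_bgal_readings()]).
#' @param scatter_factor Scatter-correction coefficient (default 1.75).
#' @return The tibble with a `miller_units` column appended.
#' @export
#' @examples
#' miller_units(tibble::tibble(
#'   od600 = 0.7, a420 = 0.420, a550 = 0, time_min = 15, volume_ml = 0.1
#' ))
miller_units <- function(readings, scatter_factor = 1.75) {
  check_columns(readings, c("od600", "a420", "a550", "time_min",
                            "volume_ml"), "readings")
  mutate(as_tibble(readings), miller_units = miller_unit_value(
    .data$a420, .data$a550, .data$od600, .data$time_min, .data$volume_ml,
    scatter_factor = scatter_factor
  ))
}
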