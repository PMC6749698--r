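#' Tidy a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
#' @exportS3Method
tidy.calibration_curve <- function(x, ...) {
  cf <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = rownames(cf),
    estimate = cf[, "Estimate"],
    std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"],
    p.value = cf[, "Pr(>|t|)"]
  )
}

#' Glance at a calibration curve
#'
#' @param x A `calibration_curve`.
#' @param ... Unused.
#' @return One-row tibble: `gain`, `intercept`, `r.squared`, `sigma`,
#'   `nobs`, `conc_min`, `conc_max`.
#' @export
#' @exportS3Method
glance.calibration_curve <- function(x, ...) {
  tibble(
    gain = x$gain,
    intercept = x$intercept,
    r.squared = x$r_squared,
    sigma = suppressWarnings(summary(x$model)$sigma),
    nobs = x$n,
    conc_min = x$conc_range[1],
    conc_max = x$conc_range[2]
  )
}

#' Tidy an identity matrix into long form
#'
#' @param x An [identity_matrix()].
#' @param ... Unused.
#' @return Tibble of unordered pairs: `seq_a`, `seq_b`, `identity`.
#' @export
#' @exportS3Method
tidy.identity_matrix <- function(x, ...) {
  m <- unclass(x)
  nm <- rownames(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    seq_a = nm[pairs[, 1]],
    seq_b = nm[pairs[, 2]],
    identity = m[pairs]
  )
}

#' Glance at a local alignment
#'
#' @param x An `sw_alignment` from [sw_align()].
#' @param ... Unused.
#' @return One-row tibble: `score`, `n_identical`, `alignment_length`,
#'   `percent_identity` (alignment-length denominator).
#' @export
#' @exportS3Method
glance.sw_alignment <- function(x, ...) {
  tibble(
    score = x$score,
    n_identical = x$n_identical,
    alignment_length = x$alignment_length,
    percent_identity = percent_identity(x)
  )
}
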