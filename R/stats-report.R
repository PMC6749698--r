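#' Normalize yields to the no-chaperone reference
#'
#' For each amylase, every replicate activity is divided by the mean
#' activity of that amylase's reference cell — the strain expressing the
#' amylase with no added chaperone gene — so the reference cell maps to mean
#' 1.0 and all other cells become relative yields. Normalization is
#' scale-invariant within an amylase: multiplying all raw activities of one
#' amylase by a constant changes no relative value.
#'
#' @param observations Tibble with columns `amylase`, `prsA`, `replicate`,
#'   `activity` (one row per biological determination; activities >= 0).
#' @param reference Value of `prsA` marking the reference cell
#'   (default `"none"`).
#' @return The tibble with a `relative` column appended.
#' @export
normalize_to_reference <- function(observations, reference = "none") {
  check_columns(observations, c("amylase", "prsA", "replicate", "activity"),
                "observations")
  observations <- as_tibble(observations)
  bad <- observations |>
    group_by(.data$amylase) |>
    summarise(
      n_ref = sum(.data$prsA == reference),
      ref_mean = if (any(.data$prsA == reference)) {
        mean(.data$activity[.data$prsA == reference])
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_ref < 2L | is.na(.data$ref_mean) |
                    .data$ref_mean <= 0)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "missing or degenerate reference cell (prsA = \"%s\") for amylase(s): %s",
      reference, paste(bad$amylase, collapse = ", ")
    ))
  }
  observations |>
    group_by(.data$amylase) |>
    mutate(relative = .data$activity /
             mean(.data$activity[.data$prsA == reference])) |>
    ungroup()
}

#' Two-sample t-test guarded against zero-variance cells
#'
#' Welch's unequal-variance t-test by default (`var_equal = TRUE` switches
#' to the pooled-variance test). Noiseless synthetic data produce cells with
#' zero within-group variance, where the t statistic is undefined; those
#' cases are resolved deterministically: both groups constant with equal
#' means gives p = 1, with unequal means p is reported as the smallest
#' positive double and the result is flagged degenerate.
#'
#' @param x,y Numeric replicate vectors (length >= 2 each).
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return List with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
pairwise_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("both groups need at least 2 replicates")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, p_value = 1, df = NA_real_,
                  degenerate = TRUE))
    }
    return(list(statistic = Inf * sign(mean(x) - mean(y)),
                p_value = .Machine$double.xmin, df = NA_real_,
                degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = var_equal)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Bonferroni adjustment for a family of m comparisons
#'
#' `p_adj = min(1, m * p)`. The family size defaults to the number of
#' p-values supplied but can be set explicitly, e.g. when each amylase row
#' contributes its own family of reference comparisons. Monotone in `p` and
#' the identity when `m = 1`.
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size.
#' @return Adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (any(m < 1L)) abort("`m` must be at least 1")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  pmin(1, m * p)
}

#' Classify adjusted p-values into significance classes
#'
#' `significant` for p < 0.05, `marginal` for 0.05 <= p < 0.10 (the
#' asterisk band of a yield table), otherwise `ns`. Boundaries are closed
#' on the left of each band: p = 0.05 is marginal, p = 0.10 is ns.
#'
#' @param p Adjusted p-values.
#' @param alpha Significance threshold (default 0.05).
#' @param marginal Upper bound of the marginal band (default 0.10).
#' @return Character vector over `significant`, `marginal`, `ns`.
#' @export
classify_significance <- function(p, alpha = 0.05, marginal = 0.10) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < alpha ~ "significant",
    p < marginal ~ "marginal",
    TRUE ~ "ns"
  )
}

#' Reference-normalized relative-yield table with Bonferroni-corrected tests
#'
#' The full statistics stage of a co-expression screen: replicate activities
#' are normalized per amylase to the no-chaperone reference cell
#' ([normalize_to_reference()]); each non-reference cell is compared to the
#' reference by a two-sample t-test on the normalized replicate values
#' ([pairwise_test()]); raw p-values are Bonferroni-corrected with family
#' size equal to the number of non-reference cells in that amylase's row;
#' adjusted p-values are classified ([classify_significance()]).
#'
#' @param observations Tibble of replicate yields, see
#'   [normalize_to_reference()].
#' @param reference Reference level of `prsA` (default `"none"`).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param alpha,marginal Significance thresholds for classification.
#' @return Tibble of class `yield_table` with one row per (amylase, prsA)
#'   cell: `amylase`, `prsA`, `n`, `mean_ratio`, `sd`, `p_raw`, `p_adj`,
#'   `class`, `degenerate`. The reference cell has mean_ratio 1 and `NA`
#'   p-values.
#' @export
#' @examples
#' obs <- tidyr::crossing(
#'   amylase = "AmyL", prsA = c("none", "prsA_Bs", "prsA_Bl"),
#'   replicate = 1:6
#' )
#' obs$activity <- c(10, 10, 11, 9, 10, 10, 20, 21, 19, 20, 22, 18,
#'                   10, 11, 10, 9, 10, 10)
#' relative_yield_table(obs)
relative_yield_table <- function(observations, reference = "none",
                                 var_equal = FALSE, alpha = 0.05,
                                 marginal = 0.10) {
  normed <- normalize_to_reference(observations, reference = reference)
  cells <- normed |>
    group_by(.data$amylase, .data$prsA) |>
    summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$relative),
      sd = sd(.data$relative),
      values = list(.data$relative),
      .groups = "drop"
    )
  out <- cells |>
    group_by(.data$amylase) |>
    mutate(
      .m = sum(.data$prsA != reference),
      .test = map(seq_len(dplyr::n()), function(i) {
        if (.data$prsA[i] == reference) {
          return(list(p_value = NA_real_, degenerate = FALSE))
        }
        ref_values <- .data$values[.data$prsA == reference][[1]]
        pairwise_test(.data$values[[i]], ref_values,
                      var_equal = var_equal)
      })
    ) |>
    ungroup() |>
    mutate(
      p_raw = map_dbl(.data$.test, "p_value"),
      degenerate = vapply(.data$.test, function(t) isTRUE(t$degenerate),
                          logical(1)),
      p_adj = if_else(is.na(.data$p_raw), NA_real_,
                      bonferroni_adjust(.data$p_raw, m = .data$.m)),
      class = classify_significance(.data$p_adj, alpha = alpha,
                                    marginal = marginal)
    ) |>
    select(all_of(c("amylase", "prsA", "n", "mean_ratio", "sd", "p_raw",
                    "p_adj", "class", "degenerate")))
  structure(out,
            class = c("yield_table", class(out)),
            reference = reference,
            var_equal = var_equal, alpha = alpha, marginal = marginal)
}

#' Render a relative-yield table for reading
#'
#' One row per amylase, one column per chaperone: `mean (sd)` with
#' typographic significance marks — significant cells wrapped in underscores
#' (emphasis), marginal cells suffixed with an asterisk.
#'
#' @param tbl A `yield_table` from [relative_yield_table()].
#' @param digits Digits for means and SDs.
#' @return A data frame of formatted strings, amylases as rows.
#' @export
render_yield_table <- function(tbl, digits = 2) {
  stopifnot(inherits(tbl, "yield_table"))
  fmt <- sprintf("%%.%df (%%.%df)", digits, digits)
  formatted <- tbl |>
    mutate(cell = sprintf(fmt, .data$mean_ratio, .data$sd),
           cell = dplyr::case_when(
             !is.na(.data$class) & .data$class == "significant" ~
               paste0("_", .data$cell, "_"),
             !is.na(.data$class) & .data$class == "marginal" ~
               paste0(.data$cell, "*"),
             TRUE ~ .data$cell
           )) |>
    select(all_of(c("amylase", "prsA", "cell"))) |>
    tidyr::pivot_wider(names_from = "prsA", values_from = "cell")
  as.data.frame(formatted)
}

#' Write the machine-readable twin of a yield table
#'
#' @param tbl A `yield_table`.
#' @param path Output TSV path.
#' @return `tbl`, invisibly.
#' @export
write_yield_table <- function(tbl, path) {
  readr::write_tsv(as_tibble(tbl), path)
  invisible(tbl)
}
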