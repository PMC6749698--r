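#' Remove modified peptides
#'
#' Drops every peptide row flagged as carrying a variable modification.
#' Label-free quantification uses unmodified peptides only, because a
#' modification splits one peptide's signal across several precursor species.
#'
#' @param peptides Peptide tibble with at least an `is_modified` column (see
#'   [sim_peptide_table()] or [read_peptide_table()] for the full dialect).
#' @return The tibble restricted to unmodified rows.
#' @export
filter_modified <- function(peptides) {
  check_columns(peptides, "is_modified", "peptides")
  dplyr::filter(peptides, !.data$is_modified)
}

# A reported intensity is one that is present and strictly positive:
# search-engine tables use 0 (or blank) for non-detection.
drop_unreported <- function(peptides) {
  check_columns(peptides, "intensity", "peptides")
  dplyr::filter(peptides, !is.na(.data$intensity), .data$intensity > 0)
}

#' Median-normalize peptide intensities per replicate
#'
#' Each biological replicate (each `strain_id` x `replicate_id` cell, i.e.
#' one MS run) is normalized separately by dividing every reported intensity
#' by the median of the reported intensities in that run. Unreported
#' intensities (missing or zero) are removed first. The median is taken over
#' all reported, unmodified intensities of the run, before any protein-level
#' filtering; for an even count it is the mean of the two middle values.
#'
#' @param peptides Peptide tibble in the package dialect. Rows flagged
#'   `is_modified` should already have been removed with [filter_modified()];
#'   if any remain a warning is raised and they are dropped here.
#' @return The tibble with unreported rows removed and a `norm_intensity`
#'   column appended. After normalization the median reported intensity of
#'   every run equals 1 (exactly so for odd counts).
#' @export
median_normalize <- function(peptides) {
  check_columns(peptides, c("strain_id", "replicate_id", "intensity"),
                "peptides")
  if ("is_modified" %in% names(peptides) && any(peptides$is_modified)) {
    warn("modified peptides present; removing them before normalization")
    peptides <- filter_modified(peptides)
  }
  peptides <- drop_unreported(peptides)
  if (nrow(peptides) == 0L) {
    warn("no reported intensities; nothing to normalize")
    return(mutate(peptides, norm_intensity = numeric(0)))
  }
  peptides |>
    group_by(.data$strain_id, .data$replicate_id) |>
    mutate(norm_intensity = .data$intensity / median(.data$intensity)) |>
    ungroup()
}

#' Hi3 protein intensities per replicate
#'
#' For every protein in every run, sums the `n_top` (default 3) largest
#' median-normalized peptide intensities — the Hi3 top-3 estimator of
#' protein abundance. A protein's Hi3 value is only defined in a run where at
#' least `n_top` peptide intensities are reported; otherwise it is `NA`. Ties
#' at the third-largest intensity are harmless: the sum of the three largest
#' values does not depend on which of the tied rows are taken.
#'
#' @param peptides Normalized peptide tibble from [median_normalize()].
#' @param n_top Number of top peptides summed, and the minimum number of
#'   reported peptides required for a value.
#' @return Tibble with one row per protein per run observed anywhere in the
#'   table: `protein_id`, `strain_id`, `replicate_id`, `n_peptides`, `hi3`.
#' @export
hi3_quantify <- function(peptides, n_top = 3L) {
  check_columns(peptides,
                c("protein_id", "strain_id", "replicate_id",
                  "norm_intensity"), "peptides")
  if (n_top < 1L) abort("`n_top` must be at least 1")
  runs <- distinct(peptides, .data$strain_id, .data$replicate_id)
  proteins <- distinct(peptides, .data$protein_id)
  grid <- cross_join(proteins, runs)
  observed <- peptides |>
    group_by(.data$protein_id, .data$strain_id, .data$replicate_id) |>
    summarise(
      n_peptides = dplyr::n(),
      hi3 = if (dplyr::n() >= n_top) {
        sum(sort(.data$norm_intensity, decreasing = TRUE)[seq_len(n_top)])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  grid |>
    left_join(observed,
              by = c("protein_id", "strain_id", "replicate_id")) |>
    mutate(n_peptides = dplyr::coalesce(.data$n_peptides, 0L)) |>
    arrange(.data$protein_id, .data$strain_id, .data$replicate_id)
}

#' Flag proteins valid for quantification
#'
#' A protein is quantifiable in a strain when its Hi3 value is present in at
#' least `min_present` of that strain's replicates. The default generalizes
#' the two-out-of-three rule to `ceiling(2 * n_replicates / 3)`, which
#' reduces to 2 of 3 for triplicates.
#'
#' @param quants Hi3 tibble from [hi3_quantify()].
#' @param min_present Minimum replicates with a value; `NULL` for the
#'   default rule.
#' @return `quants` with logical `quantifiable` appended (constant within
#'   each protein x strain).
#' @export
replicate_filter <- function(quants, min_present = NULL) {
  check_columns(quants, c("protein_id", "strain_id", "replicate_id", "hi3"),
                "quants")
  quants |>
    group_by(.data$strain_id) |>
    mutate(.n_rep = n_distinct(.data$replicate_id)) |>
    group_by(.data$protein_id, .data$strain_id) |>
    mutate(
      quantifiable = sum(!is.na(.data$hi3)) >=
        (min_present %||% ceiling(2 * .data$.n_rep[1] / 3))
    ) |>
    ungroup() |>
    select(-all_of(".n_rep"))
}

#' Per-protein quantification summary
#'
#' Collapses the per-replicate Hi3 table to one row per protein per strain:
#' number of replicates with a value, quantifiable flag, and mean Hi3 over
#' the replicates where it is present.
#'
#' @param quants Output of [replicate_filter()].
#' @return Tibble with `protein_id`, `strain_id`, `n_present`,
#'   `quantifiable`, `mean_hi3` (`NA` when no replicate has a value).
#' @export
protein_quant_summary <- function(quants) {
  check_columns(quants, c("protein_id", "strain_id", "hi3", "quantifiable"),
                "quants")
  quants |>
    group_by(.data$protein_id, .data$strain_id) |>
    summarise(
      n_present = sum(!is.na(.data$hi3)),
      quantifiable = .data$quantifiable[1],
      mean_hi3 = if (any(!is.na(.data$hi3))) {
        mean(.data$hi3[!is.na(.data$hi3)])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
}

#' Relative protein abundance per replicate
#'
#' In each run, a quantifiable protein's relative abundance is its Hi3 value
#' divided by the summed Hi3 values of all quantifiable proteins present in
#' that run — the denominator includes the protein itself, so the fractions
#' of the quantifiable proteins present in a run sum to 1.
#'
#' @param quants Output of [replicate_filter()].
#' @return Tibble of quantifiable, present observations: `protein_id`,
#'   `strain_id`, `replicate_id`, `hi3`, `fraction`.
#' @export
relative_abundance <- function(quants) {
  check_columns(quants, c("protein_id", "strain_id", "replicate_id", "hi3",
                          "quantifiable"), "quants")
  quants |>
    dplyr::filter(.data$quantifiable, !is.na(.data$hi3)) |>
    group_by(.data$strain_id, .data$replicate_id) |>
    mutate(fraction = .data$hi3 / sum(.data$hi3)) |>
    ungroup() |>
    select(all_of(c("protein_id", "strain_id", "replicate_id", "hi3",
                    "fraction")))
}

#' Summarize relative abundance across replicates
#'
#' Two conventions are offered because published screens rarely state which
#' they use. `mean_of_ratios` (default) averages the per-replicate fractions.
#' `ratio_of_means` first averages each protein's Hi3 value across the
#' replicates where it is present and then takes the fraction of the summed
#' replicate-averaged values. The reported `sd_fraction` is always the SD of
#' the per-replicate fractions, as a dispersion measure.
#'
#' @param abundance Per-replicate fractions from [relative_abundance()].
#' @param mode Averaging convention, see above.
#' @return Tibble with `protein_id`, `strain_id`, `n_replicates`,
#'   `mean_fraction`, `sd_fraction`.
#' @export
abundance_summary <- function(abundance,
                              mode = c("mean_of_ratios",
                                       "ratio_of_means")) {
  mode <- match.arg(mode)
  check_columns(abundance, c("protein_id", "strain_id", "hi3", "fraction"),
                "abundance")
  out <- abundance |>
    group_by(.data$protein_id, .data$strain_id) |>
    summarise(
      n_replicates = dplyr::n(),
      mean_fraction = mean(.data$fraction),
      sd_fraction = sd(.data$fraction),
      mean_hi3 = mean(.data$hi3),
      .groups = "drop"
    )
  if (mode == "ratio_of_means") {
    out <- out |>
      group_by(.data$strain_id) |>
      mutate(mean_fraction = .data$mean_hi3 / sum(.data$mean_hi3)) |>
      ungroup()
  }
  select(out, -all_of("mean_hi3"))
}

#' Fold change of a protein's relative abundance between strains
#'
#' Ratio of a protein's relative abundance in one strain over another, under
#' either averaging convention of [abundance_summary()]. The SD of the ratio
#' is propagated to first order from the per-strain replicate SDs.
#'
#' @param abundance Per-replicate fractions from [relative_abundance()].
#' @param protein Protein accession.
#' @param strain_num,strain_den Strain labels for numerator and denominator.
#' @param mode Averaging convention, passed to [abundance_summary()].
#' @return One-row tibble with `protein_id`, `strain_num`, `strain_den`,
#'   `fold_change`, `sd`. If the protein is not quantifiable in either
#'   strain, `fold_change` is `NA` and `status` says which side is missing;
#'   otherwise `status` is `"ok"`.
#' @export
strain_fold_change <- function(abundance, protein, strain_num, strain_den,
                               mode = c("mean_of_ratios",
                                        "ratio_of_means")) {
  mode <- match.arg(mode)
  check_columns(abundance, c("protein_id", "strain_id", "fraction"),
                "abundance")
  smry <- abundance_summary(abundance, mode = mode)
  pick_mean <- function(strain) {
    dplyr::filter(smry, .data$protein_id == protein,
                  .data$strain_id == strain)$mean_fraction
  }
  pick_reps <- function(strain) {
    dplyr::filter(abundance, .data$protein_id == protein,
                  .data$strain_id == strain)$fraction
  }
  m_num <- pick_mean(strain_num)
  m_den <- pick_mean(strain_den)
  if (length(m_num) == 0L || length(m_den) == 0L) {
    missing_in <- c(strain_num, strain_den)[c(length(m_num) == 0L,
                                              length(m_den) == 0L)]
    return(tibble(
      protein_id = protein, strain_num = strain_num,
      strain_den = strain_den, fold_change = NA_real_, sd = NA_real_,
      status = paste("not quantifiable in",
                     paste(missing_in, collapse = ", "))
    ))
  }
  fc <- m_num / m_den
  rel_var <- function(x) {
    if (length(x) > 1L && mean(x) > 0) (sd(x) / mean(x))^2 else 0
  }
  tibble(
    protein_id = protein, strain_num = strain_num, strain_den = strain_den,
    fold_change = fc,
    sd = fc * sqrt(rel_var(pick_reps(strain_num)) +
                     rel_var(pick_reps(strain_den))),
    status = "ok"
  )
}

#' Run the full Hi3 quantification pipeline
#'
#' Convenience wrapper chaining [filter_modified()], [median_normalize()],
#' [hi3_quantify()], [replicate_filter()] and [relative_abundance()].
#'
#' @param peptides Raw peptide tibble in the package dialect.
#' @param n_top Top-peptide count for Hi3 (default 3).
#' @param min_present Replicate-filter threshold; `NULL` for the
#'   two-out-of-three rule.
#' @return List with `quants` (per-replicate Hi3 with quantifiable flags),
#'   `abundance` (per-replicate fractions) and `summary`
#'   (per-protein-per-strain mean and SD of the fraction).
#' @export
#' @examples
#' truth <- sim_proteome_truth(n_proteins = 8, seed = 1)
#' sim <- sim_peptide_table(truth, seed = 2)
#' res <- hi3_pipeline(sim$peptides)
#' head(res$summary)
hi3_pipeline <- function(peptides, n_top = 3L, min_present = NULL) {
  quants <- peptides |>
    filter_modified() |>
    median_normalize() |>
    hi3_quantify(n_top = n_top) |>
    replicate_filter(min_present = min_present)
  abundance <- relative_abundance(quants)
  list(
    quants = quants,
    abundance = abundance,
    summary = abundance_summary(abundance)
  )
}
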