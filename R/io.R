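#' Read and write the peptide-table dialect
#'
#' The package's peptide tables are plain TSV with header columns
#' `protein_id`, `peptide_seq`, `is_modified`, `strain_id`, `replicate_id`,
#' `intensity` — one row per peptide observation per run. Missing
#' intensities may be blank or 0; both mean "not reported".
#'
#' @param path File path.
#' @return A peptide tibble.
#' @export
read_peptide_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    peptide_seq = readr::col_character(),
    is_modified = readr::col_logical(),
    strain_id = readr::col_character(),
    replicate_id = readr::col_character(),
    intensity = readr::col_double()
  ))
  check_columns(tbl, c("protein_id", "peptide_seq", "is_modified",
                       "strain_id", "replicate_id", "intensity"), "table")
  tbl
}

#' @rdname read_peptide_table
#' @param peptides Peptide tibble to write.
#' @export
write_peptide_table <- function(peptides, path) {
  readr::write_tsv(peptides, path)
  invisible(peptides)
}

#' Import a search-engine peptide table
#'
#' Maps the wide peptide export of a standard proteomics search engine
#' (columns `Sequence`, `Proteins`, `Modifications`, and one
#' `Intensity <sample>` column per run) onto the package's long dialect.
#' The leading accession is taken when `Proteins` lists several separated by
#' `;` (no razor-peptide logic); a peptide is modified when `Modifications`
#' is anything other than `Unmodified`.
#'
#' @param path Path to the tab-separated peptide export.
#' @param sample_map Tibble mapping run names to the design: columns
#'   `sample` (the text after `"Intensity "` in the header), `strain_id`,
#'   `replicate_id`.
#' @return A peptide tibble in the package dialect.
#' @export
read_search_engine_peptides <- function(path, sample_map) {
  check_columns(sample_map, c("sample", "strain_id", "replicate_id"),
                "sample_map")
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  check_columns(raw, c("Sequence", "Proteins"), "peptide export")
  int_cols <- grep("^Intensity .", names(raw), value = TRUE)
  if (length(int_cols) == 0L) {
    abort("no 'Intensity <sample>' columns found")
  }
  long <- raw |>
    mutate(
      protein_id = vapply(strsplit(.data$Proteins, ";", fixed = TRUE),
                          `[`, character(1), 1L),
      peptide_seq = .data$Sequence,
      is_modified = if ("Modifications" %in% names(raw)) {
        !is.na(.data$Modifications) & .data$Modifications != "Unmodified"
      } else {
        FALSE
      }
    ) |>
    select(all_of(c("protein_id", "peptide_seq", "is_modified", int_cols))) |>
    pivot_longer(all_of(int_cols), names_to = "sample",
                 values_to = "intensity") |>
    mutate(
      sample = sub("^Intensity ", "", .data$sample),
      intensity = suppressWarnings(as.numeric(.data$intensity))
    ) |>
    left_join(as_tibble(sample_map), by = "sample")
  unmapped <- unique(long$sample[is.na(long$strain_id)])
  if (length(unmapped) > 0L) {
    abort(sprintf("runs missing from `sample_map`: %s",
                  paste(unmapped, collapse = ", ")))
  }
  select(long, all_of(c("protein_id", "peptide_seq", "is_modified",
                        "strain_id", "replicate_id", "intensity")))
}

#' Read and write protein or nucleotide FASTA as a tibble
#'
#' Thin wrappers over \pkg{Biostrings} returning/taking the package's
#' `name`/`seq` tibble form.
#'
#' @param path FASTA file path.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide.
#' @return Tibble with columns `name`, `seq`.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- switch(type,
    AA = Biostrings::readAAStringSet(path),
    DNA = Biostrings::readDNAStringSet(path)
  )
  tibble(
    name = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    seq = as.character(set)
  )
}

#' @rdname read_fasta
#' @param seqs Tibble with columns `name`, `seq`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  check_columns(seqs, c("name", "seq"), "seqs")
  set <- switch(type,
    AA = Biostrings::AAStringSet(setNames(seqs$seq, seqs$name)),
    DNA = Biostrings::DNAStringSet(setNames(seqs$seq, seqs$name))
  )
  Biostrings::writeXStringSet(set, path)
  invisible(seqs)
}

#' Read a signal-peptide boundary configuration
#'
#' TSV with columns `name` and `mature_start` (0-based index of the first
#' mature residue), as consumed by [trim_signal_peptide()].
#'
#' @param path File path.
#' @return Named integer vector, name -> mature start.
#' @export
read_mature_config <- function(path) {
  cfg <- readr::read_tsv(path, col_types = readr::cols(
    name = readr::col_character(),
    mature_start = readr::col_integer()
  ))
  setNames(cfg$mature_start, cfg$name)
}

#' Write a percent-identity matrix as TSV
#'
#' The scoring parameters travel with the matrix as `#`-prefixed header
#' comments, so the convention behind the numbers is never lost.
#'
#' @param m An [identity_matrix()].
#' @param path Output path.
#' @return `m`, invisibly.
#' @export
write_identity_matrix <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# percent identity; substitution matrix %s; gap open %s; gap extend %s; denominator %s",
    attr(m, "submat") %||% "unknown",
    attr(m, "gap_open") %||% "unknown",
    attr(m, "gap_extend") %||% "unknown",
    attr(m, "denominator") %||% "unknown"
  ), con)
  df <- cbind(name = rownames(m), as.data.frame(unclass(m)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}
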