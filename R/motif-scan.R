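#' Count matching bases between a window and a canonical motif
#'
#' Position-by-position comparison of two equal-length nucleotide strings,
#' case-insensitive. `N` never counts as a match, on either side: an
#' ambiguous base carries no evidence of motif conservation.
#'
#' @param window Observed bases.
#' @param canonical Canonical motif of the same length.
#' @return Integer count of identical positions.
#' @export
#' @examples
#' count_matches("TTTTTACA", "TTTTCACA") # 7 of 8
count_matches <- function(window, canonical) {
  if (nchar(window) != nchar(canonical)) {
    abort("`window` and `canonical` must have equal length")
  }
  w <- strsplit(toupper(window), "")[[1]]
  k <- strsplit(toupper(canonical), "")[[1]]
  sum(w == k & w != "N" & k != "N")
}

# Vectorized per-offset match counts of `canonical` against every window of
# the forward strand of `region`. Returns an integer vector of length
# nchar(region) - nchar(canonical) + 1 (empty if the motif is longer).
window_match_counts <- function(region, canonical) {
  rc <- strsplit(toupper(region), "")[[1]]
  kc <- strsplit(toupper(canonical), "")[[1]]
  L <- length(rc)
  k <- length(kc)
  if (k > L) return(integer(0))
  n_win <- L - k + 1L
  counts <- integer(n_win)
  valid <- rc != "N"
  for (j in seq_len(k)) {
    if (kc[j] == "N") next
    idx <- seq.int(j, j + n_win - 1L)
    counts <- counts + as.integer(rc[idx] == kc[j] & valid[idx])
  }
  counts
}

#' Scan a region for degenerate motif matches
#'
#' Slides the canonical motif along the region and reports every window
#' sharing at least `min_matches` bases with it. With `both_strands = TRUE`
#' the reverse strand is scanned too (by matching the motif's reverse
#' complement on the forward strand), so an operator written on the minus
#' strand — like the second CssR box found between a start codon and its
#' Shine-Dalgarno sequence — is still found. Overlapping hits are all
#' reported; no masking is applied, since regulatory features genuinely
#' overlap (e.g. an operator superimposed on a -35 box).
#'
#' Coordinates are 0-based, half-open, always on the forward strand; a minus
#' strand hit reports the forward-strand interval it occupies, and
#' `matched_seq` gives the bases as read on the hit's own strand.
#'
#' @param region Nucleotide string over A/C/G/T/N.
#' @param canonical Canonical motif sequence.
#' @param min_matches Minimum identical bases for a hit; defaults to a
#'   single mismatch allowance, `nchar(canonical) - 1`.
#' @param both_strands Scan the reverse strand as well (default `TRUE`).
#' @param anchor Optional 0-based forward-strand position of a reference
#'   point (e.g. a start codon); hits then report
#'   `offset_to_anchor = start - anchor`.
#' @param motif_name Label used in the output.
#' @return Tibble sorted by `start` then strand (`+` before `-`) with
#'   columns `motif`, `start`, `end`, `strand`, `n_matches`, `matched_seq`
#'   and, when `anchor` is given, `offset_to_anchor`.
#' @export
#' @examples
#' scan_motif("GGGTTTTCACAGGG", "TTTTCACA", min_matches = 8)
scan_motif <- function(region, canonical, min_matches = nchar(canonical) - 1L,
                       both_strands = TRUE, anchor = NULL,
                       motif_name = "motif") {
  if (min_matches < 1L || min_matches > nchar(canonical)) {
    abort("`min_matches` must lie in [1, motif length]")
  }
  k <- nchar(canonical)
  if (k > nchar(region)) {
    warn("canonical motif is longer than the region; no hits possible")
    hits <- tibble(motif = character(), start = integer(), end = integer(),
                   strand = character(), n_matches = integer(),
                   matched_seq = character())
    if (!is.null(anchor)) hits$offset_to_anchor <- integer()
    return(hits)
  }
  strands <- if (both_strands) c("+", "-") else "+"
  hits <- map(strands, function(s) {
    target <- if (s == "+") canonical else dna_revcomp(canonical)
    counts <- window_match_counts(region, target)
    keep <- which(counts >= min_matches)
    if (length(keep) == 0L) return(NULL)
    start <- keep - 1L
    found <- substr(rep(region, length(keep)), keep, keep + k - 1L)
    if (s == "-") found <- vapply(found, dna_revcomp, character(1))
    tibble(
      motif = motif_name, start = start, end = start + k,
      strand = s, n_matches = counts[keep],
      matched_seq = toupper(unname(found))
    )
  }) |> bind_rows()
  if (nrow(hits) == 0L) {
    hits <- tibble(motif = character(), start = integer(), end = integer(),
                   strand = character(), n_matches = integer(),
                   matched_seq = character())
  }
  if (!is.null(anchor)) hits$offset_to_anchor <- hits$start - as.integer(anchor)
  arrange(hits, .data$start, .data$strand)
}

#' Scan for sigma-A promoter pairs (-35/-10 boxes)
#'
#' Finds all (-35, -10) hexamer pairs in which each box matches at least
#' `min_matches_per_box` of its canonical bases (TTGACA and TATAAT) and the
#' spacer between the boxes lies in `spacer_range` (housekeeping sigma-A
#' promoters have a 17 +/- 1 bp spacer). Both orientations are searched: on
#' the minus strand the -10 box lies left of the -35 box in forward
#' coordinates.
#'
#' The promoter center reported for each pair is, by default, the midpoint
#' of the full -35-through--10 span (`center = "promoter_midpoint"`);
#' `"minus10_midpoint"` uses the midpoint of the -10 box instead. The
#' convention used is echoed in the output, because statements like
#' "centered 60 bp upstream" depend on it.
#'
#' @param region Nucleotide string.
#' @param minus35,minus10 Canonical hexamers.
#' @param min_matches_per_box Minimum matches per box (default 5 of 6).
#' @param spacer_range Inclusive spacer length range (default 16-18).
#' @param both_strands Search the reverse orientation too.
#' @param anchor Optional 0-based anchor (e.g. start codon position);
#'   `offset_to_anchor = center - anchor` is then reported (negative =
#'   centered upstream of a forward-strand anchor).
#' @param center Centering convention, see above.
#' @return Tibble with one row per promoter pair: `strand`, `start`, `end`
#'   (full span, 0-based half-open, forward strand), `start_35`, `start_10`
#'   (box starts), `n_matches_35`, `n_matches_10`, `spacer`, `center`,
#'   `center_convention` and optionally `offset_to_anchor`.
#' @export
scan_sigma_a <- function(region, minus35 = "TTGACA", minus10 = "TATAAT",
                         min_matches_per_box = 5L,
                         spacer_range = c(16L, 18L),
                         both_strands = TRUE, anchor = NULL,
                         center = c("promoter_midpoint",
                                    "minus10_midpoint")) {
  center <- match.arg(center)
  conv <- center
  k35 <- nchar(minus35)
  k10 <- nchar(minus10)
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- list()
  for (s in strands) {
    t35 <- if (s == "+") minus35 else dna_revcomp(minus35)
    t10 <- if (s == "+") minus10 else dna_revcomp(minus10)
    c35 <- window_match_counts(region, t35)
    c10 <- window_match_counts(region, t10)
    h35 <- which(c35 >= min_matches_per_box) - 1L
    h10 <- which(c10 >= min_matches_per_box) - 1L
    if (length(h35) == 0L || length(h10) == 0L) next
    for (p35 in h35) {
      for (p10 in h10) {
        spacer <- if (s == "+") p10 - (p35 + k35) else p35 - (p10 + k10)
        if (spacer < spacer_range[1] || spacer > spacer_range[2]) next
        span_start <- min(p35, p10)
        span_end <- max(p35 + k35, p10 + k10)
        ctr <- switch(center,
          promoter_midpoint = (span_start + span_end) / 2,
          minus10_midpoint = p10 + k10 / 2
        )
        rows[[length(rows) + 1L]] <- tibble(
          strand = s, start = span_start, end = span_end,
          start_35 = p35, start_10 = p10,
          n_matches_35 = c35[p35 + 1L], n_matches_10 = c10[p10 + 1L],
          spacer = spacer, center = ctr, center_convention = conv
        )
      }
    }
  }
  hits <- if (length(rows)) bind_rows(rows) else tibble(
    strand = character(), start = integer(), end = integer(),
    start_35 = integer(), start_10 = integer(),
    n_matches_35 = integer(), n_matches_10 = integer(),
    spacer = integer(), center = numeric(), center_convention = character()
  )
  if (!is.null(anchor)) hits$offset_to_anchor <- hits$center - anchor
  arrange(hits, .data$start, .data$strand)
}

#' Write motif hits as BED-like TSV
#'
#' @param hits Hit tibble from [scan_motif()] or [scan_sigma_a()].
#' @param path Output path.
#' @param region_name Name recorded in the first column.
#' @return `hits`, invisibly.
#' @export
write_motif_hits <- function(hits, path, region_name = "region") {
  is_sigma <- "start_35" %in% names(hits)
  bed <- tibble(
    chrom = region_name,
    start = hits$start,
    end = hits$end,
    name = if (is_sigma) {
      sprintf("sigmaA_%d/%d+%d/%d", hits$n_matches_35, nchar("TTGACA"),
              hits$n_matches_10, nchar("TATAAT"))
    } else {
      hits$motif
    },
    score = if (is_sigma) hits$n_matches_35 + hits$n_matches_10
            else hits$n_matches,
    strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(hits)
}
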