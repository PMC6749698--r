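#' Trim signal peptides to obtain mature sequences
#'
#' Secreted and membrane-anchored bacterial proteins carry an N-terminal
#' signal peptide that is cleaved on export; sequence comparisons between
#' homologs are made on the mature part only, because signal peptides evolve
#' under different constraints. Boundaries are user-supplied (0-based index
#' of the first mature residue; 0 means no trimming), not predicted.
#'
#' @param seqs Tibble with columns `name` and `seq`, optionally
#'   `mature_start`.
#' @param mature_start Named integer vector (name -> 0-based mature start)
#'   overriding / supplying the column. Sequences without an entry are left
#'   untrimmed.
#' @return The tibble with `seq` trimmed and `mature_start` recorded.
#' @export
trim_signal_peptide <- function(seqs, mature_start = NULL) {
  check_columns(seqs, c("name", "seq"), "seqs")
  seqs <- as_tibble(seqs)
  if (!is.null(mature_start)) {
    seqs$mature_start <- unname(mature_start[seqs$name])
    seqs$mature_start[is.na(seqs$mature_start)] <- 0L
  } else if (!("mature_start" %in% names(seqs))) {
    seqs$mature_start <- 0L
  }
  seqs$mature_start <- as.integer(seqs$mature_start)
  if (any(seqs$mature_start < 0L) ||
        any(seqs$mature_start >= nchar(seqs$seq))) {
    abort("`mature_start` must lie in [0, sequence length - 1]")
  }
  mutate(seqs, seq = substr(.data$seq, .data$mature_start + 1L,
                            nchar(.data$seq)))
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under affine-gap scoring: a gap of length L costs
#' `gap_open + L * gap_extend`. Defaults are the classic local-alignment
#' settings (BLOSUM62, open 10, extend 0.5). When no positive-scoring
#' alignment exists the result is the empty alignment with score 0.
#'
#' @param a,b Amino-acid strings (non-empty).
#' @param submat Substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"PAM250"`) or a numeric matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @return Object of class `sw_alignment`: list with `score`, `aligned_a`,
#'   `aligned_b` (gapped segment strings), `n_identical`,
#'   `alignment_length`, `len_a`, `len_b`, and the scoring `params`.
#' @export
#' @examples
#' aln <- sw_align("MKLVINLA", "MKLVGNLA")
#' percent_identity(aln)
sw_align <- function(a, b, submat = "BLOSUM62", gap_open = 10,
                     gap_extend = 0.5) {
  if (!is.character(a) || !is.character(b) || nchar(a) == 0L ||
        nchar(b) == 0L) {
    abort("both sequences must be non-empty strings")
  }
  mat <- if (is.matrix(submat)) {
    submat
  } else {
    get(data(list = submat, package = "Biostrings",
             envir = environment()))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    # No positive-scoring segment pair: the empty local alignment wins.
    aligned_a <- ""
    aligned_b <- ""
    sc <- 0
  } else {
    aligned_a <- as.character(Biostrings::alignedPattern(aln))
    aligned_b <- as.character(Biostrings::alignedSubject(aln))
  }
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  structure(
    list(
      score = sc,
      aligned_a = aligned_a,
      aligned_b = aligned_b,
      n_identical = sum(ca == cb & ca != "-"),
      alignment_length = length(ca),
      len_a = nchar(a),
      len_b = nchar(b),
      params = list(
        submat = if (is.matrix(submat)) "custom" else submat,
        gap_open = gap_open, gap_extend = gap_extend
      )
    ),
    class = "sw_alignment"
  )
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf(
    "Local alignment: score %.1f, %d/%d identical (%s, open %g, extend %g)\n",
    x$score, x$n_identical, x$alignment_length, x$params$submat,
    x$params$gap_open, x$params$gap_extend
  ))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a local alignment
#'
#' @param aln An `sw_alignment` from [sw_align()].
#' @param denominator Either `"alignment_length"` (default; identical
#'   positions over all alignment columns, gap columns included) or
#'   `"shorter_sequence"` (over the length of the shorter input sequence).
#'   The convention matters for divergent pairs and is therefore explicit.
#' @return Percent identity in \[0, 100\]; 0 for an empty alignment.
#' @export
percent_identity <- function(aln,
                             denominator = c("alignment_length",
                                             "shorter_sequence")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(aln, "sw_alignment"))
  den <- switch(denominator,
    alignment_length = aln$alignment_length,
    shorter_sequence = min(aln$len_a, aln$len_b)
  )
  if (den == 0L) return(0)
  100 * aln$n_identical / den
}

#' All-pairs percent-identity matrix
#'
#' Aligns every unordered pair of mature sequences locally and fills a
#' symmetric percent-identity matrix (diagonal 100). Each pair is aligned
#' once, so symmetry holds by construction.
#'
#' @param seqs Tibble with columns `name`, `seq` (already trimmed with
#'   [trim_signal_peptide()] if signal peptides are present).
#' @param denominator Identity denominator, see [percent_identity()].
#' @inheritParams sw_align
#' @return A numeric matrix of class `identity_matrix` with the scoring
#'   parameters attached as attributes.
#' @export
identity_matrix <- function(seqs,
                            denominator = c("alignment_length",
                                            "shorter_sequence"),
                            submat = "BLOSUM62", gap_open = 10,
                            gap_extend = 0.5) {
  denominator <- match.arg(denominator)
  check_columns(seqs, c("name", "seq"), "seqs")
  if (anyDuplicated(seqs$name)) abort("sequence names must be unique")
  n <- nrow(seqs)
  m <- matrix(100, n, n, dimnames = list(seqs$name, seqs$name))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        aln <- sw_align(seqs$seq[i], seqs$seq[j], submat = submat,
                        gap_open = gap_open, gap_extend = gap_extend)
        pid <- percent_identity(aln, denominator = denominator)
        m[i, j] <- pid
        m[j, i] <- pid
      }
    }
  }
  structure(m,
            class = c("identity_matrix", "matrix", "array"),
            denominator = denominator, submat = if (is.matrix(submat))
              "custom" else submat,
            gap_open = gap_open, gap_extend = gap_extend)
}

#' Convert percent identity to a distance matrix
#'
#' `d = 1 - identity / 100`, zero diagonal — the simple divergence scale on
#' which tree branch lengths are expressed.
#'
#' @param m An [identity_matrix()] (or plain numeric matrix in percent).
#' @return A symmetric numeric distance matrix.
#' @export
identity_to_distance <- function(m) {
  d <- 1 - unclass(m) / 100
  diag(d) <- 0
  attributes(d)[setdiff(names(attributes(d)), c("dim", "dimnames"))] <- NULL
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (via \pkg{ape}); on an additive distance matrix
#' the generating tree topology and branch lengths are recovered exactly.
#' Negative branch-length estimates, which NJ can produce on noisy
#' non-additive input, are clamped to zero with a message.
#'
#' @param d Symmetric distance matrix (or `dist`) with taxon names.
#' @return An unrooted `phylo` tree with non-negative branch lengths.
#' @export
build_nj_tree <- function(d) {
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    inform(sprintf(
      "%d negative branch length(s) clamped to 0",
      sum(tree$edge.length < 0)
    ))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Write a tree in Newick format
#'
#' @param tree A `phylo` object.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}
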