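# Internal helpers shared across modules.

# Abort unless `df` has every column in `cols`.
check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

check_positive_scalar <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (x > 0 || (allow_zero && x == 0))
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single %s number",
      name, if (allow_zero) "non-negative" else "positive"
    ))
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  invisible(as.integer(seed))
}

# Uppercase DNA reverse complement for a single character string.
dna_revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# Random tryptic-looking peptide: 6-19 residues ending in K or R.
random_peptide <- function(min_len = 7L, max_len = 20L) {
  len <- sample(seq.int(min_len, max_len), 1L)
  aa <- c(
    "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
  )
  paste0(
    paste(sample(aa, len - 1L, replace = TRUE), collapse = ""),
    sample(c("K", "R"), 1L)
  )
}
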