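# Independent reference implementations used as oracles. These are written
# in plain base R with explicit loops, deliberately sharing no code with the
# package's vectorized/dplyr implementations.

# ---- Hi3 relative-abundance oracle --------------------------------------
# Straight-line reimplementation of the full quantification pipeline:
# modified filter -> per-run median normalization -> top-3 sum (>= 3
# peptides) -> 2-of-3 replicate filter -> per-run fractions.
oracle_relative_abundance <- function(df, n_top = 3, min_present = NULL) {
  df <- as.data.frame(df)
  df <- df[!df$is_modified, , drop = FALSE]
  df <- df[!is.na(df$intensity) & df$intensity > 0, , drop = FALSE]
  df$run <- paste(df$strain_id, df$replicate_id, sep = "\r")
  runs <- unique(df$run)
  df$norm <- NA_real_
  for (r in runs) {
    idx <- df$run == r
    df$norm[idx] <- df$intensity[idx] / median(df$intensity[idx])
  }
  proteins <- unique(df$protein_id)
  hi3 <- list()
  for (p in proteins) {
    for (r in runs) {
      v <- df$norm[df$protein_id == p & df$run == r]
      hi3[[paste(p, r, sep = "\r")]] <- if (length(v) >= n_top) {
        sum(rev(sort(v))[1:n_top])
      } else {
        NA_real_
      }
    }
  }
  strain_of <- function(r) strsplit(r, "\r")[[1]][1]
  rep_of <- function(r) strsplit(r, "\r")[[1]][2]
  strains <- unique(vapply(runs, strain_of, character(1)))
  quantifiable <- list()
  for (p in proteins) {
    for (s in strains) {
      rs <- runs[vapply(runs, strain_of, character(1)) == s]
      present <- sum(vapply(rs, function(r) {
        !is.na(hi3[[paste(p, r, sep = "\r")]])
      }, logical(1)))
      need <- if (is.null(min_present)) ceiling(2 * length(rs) / 3)
              else min_present
      quantifiable[[paste(p, s, sep = "\r")]] <- present >= need
    }
  }
  out <- NULL
  for (r in runs) {
    s <- strain_of(r)
    tot <- 0
    for (p in proteins) {
      v <- hi3[[paste(p, r, sep = "\r")]]
      if (quantifiable[[paste(p, s, sep = "\r")]] && !is.na(v)) {
        tot <- tot + v
      }
    }
    for (p in proteins) {
      v <- hi3[[paste(p, r, sep = "\r")]]
      if (quantifiable[[paste(p, s, sep = "\r")]] && !is.na(v)) {
        out <- rbind(out, data.frame(
          protein_id = p, strain_id = s, replicate_id = rep_of(r),
          fraction = v / tot, stringsAsFactors = FALSE
        ))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), strain_id = character(),
                      replicate_id = character(), fraction = numeric())
  }
  out
}

# Random small peptide table for oracle-equivalence testing.
random_peptide_table <- function(n_proteins, n_peptides_max = 6,
                                 strains = c("A", "B"), n_replicates = 3,
                                 missing_rate = 0.15,
                                 modified_fraction = 0.1) {
  rows <- list()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (p in seq_len(n_proteins)) {
    n_pep <- sample.int(n_peptides_max, 1)
    for (q in seq_len(n_pep)) {
      pep <- paste(sample(aa, 8, replace = TRUE), collapse = "")
      modified <- runif(1) < modified_fraction
      for (s in strains) {
        for (r in seq_len(n_replicates)) {
          if (runif(1) < missing_rate) next
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = sprintf("P%02d", p),
            peptide_seq = sprintf("%s_%d", pep, q),
            is_modified = modified,
            strain_id = s,
            replicate_id = sprintf("R%d", r),
            intensity = exp(runif(1, log(1e3), log(1e7))),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

# ---- Smith-Waterman enumeration oracle ----------------------------------
# A local alignment is a chain of aligned residue pairs (i1<i2<..., j1<j2<...)
# scored as sum of substitution scores minus (open + extend * len) for every
# non-empty gap run between consecutive pairs. The optimum over all chains
# (or the empty alignment, score 0) is the Smith-Waterman score. Exhaustive
# recursion over chains; feasible for sequences up to ~8 residues.
oracle_sw_score <- function(a, b, mat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av)
  lb <- length(bv)
  best <- 0
  rec <- function(ai, bi, acc, last_a, last_b) {
    if (ai > la || bi > lb) return(invisible())
    for (p in ai:la) {
      for (q in bi:lb) {
        s <- acc + mat[av[p], bv[q]]
        if (!is.na(last_a)) {
          ga <- p - last_a - 1
          gb <- q - last_b - 1
          if (ga > 0) s <- s - (gap_open + gap_extend * ga)
          if (gb > 0) s <- s - (gap_open + gap_extend * gb)
        }
        if (s > best) best <<- s
        rec(p + 1, q + 1, s, p, q)
      }
    }
  }
  rec(1, 1, 0, NA, NA)
  best
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# ---- Motif-scan oracle ---------------------------------------------------
# Naive double-loop scan over every window on both strands, with its own
# complement table.
oracle_scan_motif <- function(region, canonical, min_matches,
                              both_strands = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(x) paste(rev(unname(comp[strsplit(x, "")[[1]]])),
                          collapse = "")
  n_match <- function(w, k) {
    wv <- strsplit(w, "")[[1]]
    kv <- strsplit(k, "")[[1]]
    cnt <- 0
    for (i in seq_along(wv)) {
      if (wv[i] != "N" && kv[i] != "N" && wv[i] == kv[i]) cnt <- cnt + 1
    }
    cnt
  }
  k <- nchar(canonical)
  L <- nchar(region)
  out <- NULL
  strands <- if (both_strands) c("+", "-") else "+"
  if (k <= L) {
    for (start0 in 0:(L - k)) {
      w <- substr(region, start0 + 1, start0 + k)
      for (s in strands) {
        read <- if (s == "+") w else rc(w)
        nm <- n_match(read, canonical)
        if (nm >= min_matches) {
          out <- rbind(out, data.frame(
            start = start0, end = start0 + k, strand = s, n_matches = nm,
            stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), n_matches = integer())
  }
  # deterministic tie-break: "+" before "-" regardless of locale collation
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
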