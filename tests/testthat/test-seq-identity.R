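test_that("signal-peptide trimming removes exactly the stated prefix", {
  seqs <- tibble::tibble(name = c("a", "b", "c"),
                         seq = c("MKKLVSA", "MSSPQRS", "MAV"))
  out <- trim_signal_peptide(seqs, c(a = 0L, b = 3L, c = 2L))
  expect_equal(out$seq, c("MKKLVSA", "PQRS", "V"))
  expect_equal(nchar(seqs$seq) - nchar(out$seq), c(0L, 3L, 2L))
  expect_error(trim_signal_peptide(seqs, c(a = 7L, b = 0L, c = 0L)),
               "mature_start")
})

test_that("self-alignment is full length and fully identical", {
  aln <- sw_align("MKLV", "MKLV")
  expect_equal(aln$n_identical, 4L)
  expect_equal(aln$alignment_length, 4L)
  expect_equal(aln$score, 5 + 5 + 4 + 4) # BLOSUM62 diagonal M,K,L,V
  expect_equal(percent_identity(aln), 100)
})

test_that("all-negative cross scores give the empty alignment with score 0", {
  # A vs W scores -3 in BLOSUM62; no positive segment pair exists
  aln <- sw_align("AAAA", "WWWW")
  expect_equal(aln$score, 0)
  expect_equal(aln$alignment_length, 0L)
  expect_equal(percent_identity(aln), 0)
})

test_that("empty sequences are rejected", {
  expect_error(sw_align("", "MKLV"), "non-empty")
  expect_error(sw_align("MKLV", ""), "non-empty")
})

test_that("alignment score is symmetric and identity bounded", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_aa_seq(sample(4:12, 1))
    b <- random_aa_seq(sample(4:12, 1))
    ab <- sw_align(a, b)
    ba <- sw_align(b, a)
    expect_equal(ab$score, ba$score)
    pid <- percent_identity(ab)
    expect_gte(pid, 0)
    expect_lte(pid, 100)
  }
})

test_that("scores match the exhaustive chain-enumeration oracle", {
  b62 <- get(data("BLOSUM62", package = "Biostrings",
                  envir = environment()))
  set.seed(17)
  for (i in 1:30) {
    a <- random_aa_seq(sample(2:8, 1))
    b <- random_aa_seq(sample(2:8, 1))
    expect_equal(sw_align(a, b)$score,
                 oracle_sw_score(a, b, b62),
                 tolerance = 1e-9)
  }
})

test_that("percent identity honors the denominator convention", {
  # identical halves: MKLVMKLV vs MKLV aligns the 4-mer exactly
  aln <- sw_align("MKLVWWWW", "MKLV")
  expect_equal(aln$n_identical, 4L)
  expect_equal(percent_identity(aln, "alignment_length"), 100)
  expect_equal(percent_identity(aln, "shorter_sequence"), 100)
  # a 17/34 case by construction: arithmetic only
  fake <- structure(list(score = 1, aligned_a = "", aligned_b = "",
                         n_identical = 17L, alignment_length = 34L,
                         len_a = 40L, len_b = 36L,
                         params = list()), class = "sw_alignment")
  expect_equal(percent_identity(fake), 50)
})

test_that("identity matrix is symmetric with unit diagonal and tracks truth", {
  fam <- sim_sequence_family(120, c(0.1, 0.3, 0.5), seed = 13)
  m <- identity_matrix(fam$sequences)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(unname(diag(m)), rep(100, 4))
  # point substitutions only: local alignment recovers the realized identity
  # for ancestor-descendant pairs (gapless, full length)
  expect_equal(unname(m[1, 2]), unname(fam$identity[1, 2]), tolerance = 2)
  expect_equal(unname(m[1, 3]), unname(fam$identity[1, 3]), tolerance = 3)
  td <- tidy(m)
  expect_equal(nrow(td), 6L)
})

test_that("identity converts to distance with zero diagonal", {
  fam <- sim_sequence_family(80, c(0.2, 0.4), seed = 21)
  d <- identity_to_distance(identity_matrix(fam$sequences))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(91)
  for (i in 1:10) {
    n_taxa <- sample(5:8, 1)
    true_tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.05, 1))
    d <- ape::cophenetic.phylo(true_tree)
    est <- build_nj_tree(d)
    expect_true(all(est$edge.length >= 0))
    d_est <- ape::cophenetic.phylo(est)
    expect_equal(d_est[rownames(d), colnames(d)], d, tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), est), 0,
                 ignore_attr = TRUE)
  }
})

test_that("three taxa give the unique unrooted topology", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tree <- build_nj_tree(d)
  expect_equal(ape::Ntip(tree), 3L)
  expect_equal(tree$Nnode, 1L)
  nwk <- write_newick(tree)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("a duplicate taxon forms a zero-length cherry", {
  base <- ape::rtree(5, br = function(n) runif(n, 0.2, 1))
  d <- ape::cophenetic.phylo(base)
  dd <- rbind(cbind(d, dup = d[, 1]), dup = c(d[1, ], 0))
  rownames(dd)[6] <- "dup"
  tree <- build_nj_tree(dd)
  d_est <- ape::cophenetic.phylo(tree)
  expect_equal(d_est["dup", rownames(d)[1]], 0, tolerance = 1e-12)
})

test_that("permuting taxa permutes labels but not the tree", {
  true_tree <- ape::rtree(6, br = function(n) runif(n, 0.1, 1))
  d <- ape::cophenetic.phylo(true_tree)
  perm <- sample(rownames(d))
  t1 <- build_nj_tree(d)
  t2 <- build_nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(t1)[rownames(d), rownames(d)],
               tolerance = 1e-9)
})

test_that("FASTA and identity-matrix round trips preserve content", {
  fam <- sim_sequence_family(50, c(0.2, 0.3), seed = 33)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam$sequences, fa, type = "AA")
  back <- read_fasta(fa, type = "AA")
  expect_equal(as.data.frame(back), as.data.frame(fam$sequences))
  m <- identity_matrix(fam$sequences)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_identity_matrix(m, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "^# percent identity")
  reread <- read.delim(tsv, comment.char = "#", row.names = 1)
  expect_equal(as.matrix(reread), unclass(m), ignore_attr = TRUE,
               tolerance = 1e-6)
})
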