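make_peptides <- function(intensities, protein = "P1", strain = "A",
                          replicate = "R1", modified = FALSE) {
  tibble::tibble(
    protein_id = protein,
    peptide_seq = sprintf("PEP%02d", seq_along(intensities)),
    is_modified = modified,
    strain_id = strain,
    replicate_id = replicate,
    intensity = intensities
  )
}

test_that("modified peptides are removed and only those", {
  tbl <- dplyr::bind_rows(
    make_peptides(c(1, 2), modified = FALSE),
    make_peptides(c(3, 4), protein = "P2", modified = TRUE)
  )
  out <- filter_modified(tbl)
  expect_equal(nrow(out), 2L)
  expect_true(all(!out$is_modified))
  expect_identical(filter_modified(make_peptides(1:3)),
                   make_peptides(1:3))
  all_mod <- filter_modified(make_peptides(1:4, modified = TRUE))
  expect_equal(nrow(all_mod), 0L)
})

test_that("median normalization matches hand computation and conventions", {
  tbl <- make_peptides(c(10, 20, 30, 40))
  out <- median_normalize(tbl)
  # even count: median is the mean of the two middle values (25)
  expect_equal(out$norm_intensity, c(0.4, 0.8, 1.2, 1.6))
  # a single intensity normalizes to exactly 1
  expect_equal(median_normalize(make_peptides(37))$norm_intensity, 1)
  # odd counts leave the median of the normalized values at exactly 1
  odd <- median_normalize(make_peptides(c(5, 50, 500)))
  expect_identical(median(odd$norm_intensity), 1)
})

test_that("normalization is scale-invariant per replicate", {
  tbl <- dplyr::bind_rows(
    make_peptides(c(10, 20, 30), replicate = "R1"),
    make_peptides(c(40, 50, 60), replicate = "R2")
  )
  scaled <- dplyr::mutate(tbl, intensity = intensity *
                            ifelse(replicate_id == "R1", 1000, 1))
  expect_equal(median_normalize(scaled)$norm_intensity,
               median_normalize(tbl)$norm_intensity)
})

test_that("zero and missing intensities are both unreported", {
  tbl <- make_peptides(c(10, 0, NA, 30))
  out <- median_normalize(tbl)
  expect_equal(nrow(out), 2L)
  expect_equal(sort(out$intensity), c(10, 30))
})

test_that("hi3 sums the top three normalized intensities", {
  tbl <- make_peptides(c(10, 20, 30, 40))
  q <- hi3_quantify(median_normalize(tbl))
  expect_equal(q$hi3, 0.8 + 1.2 + 1.6)
  # exactly three equal peptides: each normalizes to 1, sum is 3
  q3 <- hi3_quantify(median_normalize(make_peptides(c(7, 7, 7))))
  expect_equal(q3$hi3, 3)
  # two peptides only: no value
  q2 <- hi3_quantify(median_normalize(make_peptides(c(1, 2))))
  expect_true(is.na(q2$hi3))
})

test_that("ties at the third-largest intensity do not disturb the sum", {
  tbl <- make_peptides(c(5, 5, 5, 5, 1))
  shuffled <- tbl[c(3, 5, 1, 4, 2), ]
  expect_equal(hi3_quantify(median_normalize(tbl))$hi3,
               hi3_quantify(median_normalize(shuffled))$hi3)
})

test_that("two-out-of-three replicate rule generalizes as ceiling(2n/3)", {
  base <- function(reps_with_value, n_rep = 3) {
    dplyr::bind_rows(lapply(seq_len(n_rep), function(r) {
      i <- if (r %in% reps_with_value) c(1, 2, 3) else c(1, 2)
      make_peptides(i, replicate = sprintf("R%d", r))
    }))
  }
  run <- function(tbl) {
    q <- replicate_filter(hi3_quantify(median_normalize(tbl)))
    unique(q$quantifiable)
  }
  expect_true(run(base(1:3)))
  expect_true(run(base(1:2)))
  expect_false(run(base(1)))
  # 6 replicates: ceiling(12/6... 2*6/3) = 4 required
  expect_false(run(base(1:3, n_rep = 6)))
  expect_true(run(base(1:4, n_rep = 6)))
  # override wins over the default rule
  q <- replicate_filter(hi3_quantify(median_normalize(base(1))),
                        min_present = 1)
  expect_true(unique(q$quantifiable))
})

test_that("fractions sum to one per replicate and respect trivial cases", {
  one <- make_peptides(c(2, 3, 4))
  res <- hi3_pipeline(dplyr::bind_rows(
    one,
    lapply(2:3, function(r) make_peptides(c(2, 3, 4),
                                          replicate = sprintf("R%d", r)))
  ))
  expect_equal(res$abundance$fraction, rep(1, 3))
  # two proteins with identical peptides split 0.5 / 0.5
  two <- dplyr::bind_rows(lapply(1:3, function(r) dplyr::bind_rows(
    make_peptides(c(2, 3, 4), protein = "P1",
                  replicate = sprintf("R%d", r)),
    make_peptides(c(2, 3, 4), protein = "P2",
                  replicate = sprintf("R%d", r))
  )))
  res2 <- hi3_pipeline(two)
  expect_equal(res2$abundance$fraction, rep(0.5, 6))
  sums <- tapply(res2$abundance$fraction,
                 paste(res2$abundance$strain_id,
                       res2$abundance$replicate_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a target missing from a strain yields an explicit status, not zero", {
  truth <- sim_proteome_truth(n_proteins = 5, seed = 2)
  sim <- sim_peptide_table(truth, seed = 3)
  res <- hi3_pipeline(sim$peptides)
  fc <- strain_fold_change(res$abundance, "NOT_A_PROTEIN", "B", "A")
  expect_true(is.na(fc$fold_change))
  expect_match(fc$status, "not quantifiable")
})

test_that("pipeline matches the brute-force oracle on random tables", {
  set.seed(101)
  for (i in 1:25) {
    tbl <- random_peptide_table(sample.int(10, 1))
    res <- hi3_pipeline(tibble::as_tibble(tbl))$abundance
    orc <- oracle_relative_abundance(tbl)
    m <- merge(as.data.frame(res), orc,
               by = c("protein_id", "strain_id", "replicate_id"),
               all = TRUE)
    expect_equal(nrow(m), nrow(res))
    expect_equal(nrow(m), nrow(orc))
    expect_true(all(abs(m$fraction.x - m$fraction.y) < 1e-9))
  }
})

test_that("scaling one replicate leaves hi3 values and fractions unchanged", {
  set.seed(55)
  tbl <- tibble::as_tibble(random_peptide_table(6, missing_rate = 0,
                                                modified_fraction = 0))
  scaled <- dplyr::mutate(tbl, intensity = intensity *
                            ifelse(strain_id == "A" & replicate_id == "R2",
                                   137, 1))
  r1 <- hi3_pipeline(tbl)
  r2 <- hi3_pipeline(scaled)
  expect_equal(r1$quants$hi3, r2$quants$hi3)
  expect_equal(r1$abundance$fraction, r2$abundance$fraction)
})

test_that("raising the target's intensities never lowers its fraction", {
  set.seed(77)
  tbl <- tibble::as_tibble(random_peptide_table(6, missing_rate = 0,
                                                modified_fraction = 0))
  quantified <- hi3_pipeline(tbl)$abundance
  target <- sort(unique(quantified$protein_id))[1]
  frac_of <- function(t) {
    ab <- hi3_pipeline(t)$abundance
    mean(ab$fraction[ab$protein_id == target])
  }
  f0 <- frac_of(tbl)
  for (mult in c(1.5, 3, 10)) {
    boosted <- dplyr::mutate(tbl, intensity = intensity *
                               ifelse(protein_id == target, mult, 1))
    f1 <- frac_of(boosted)
    expect_gte(f1, f0 - 1e-12)
    f0 <- f1
  }
})

test_that("both averaging conventions agree on noiseless data", {
  truth <- sim_proteome_truth(n_proteins = 10, seed = 4)
  sim <- sim_peptide_table(truth, intensity_cv = 0, seed = 5)
  ab <- hi3_pipeline(sim$peptides)$abundance
  s1 <- abundance_summary(ab, mode = "mean_of_ratios")
  s2 <- abundance_summary(ab, mode = "ratio_of_means")
  expect_equal(s1$mean_fraction, s2$mean_fraction, tolerance = 1e-9)
})

test_that("search-engine import maps wide intensity columns to the dialect", {
  path <- withr::local_tempfile(fileext = ".txt")
  wide <- data.frame(
    Sequence = c("AAAK", "CCCR"),
    Proteins = c("P1;P9", "P2"),
    Modifications = c("Unmodified", "Oxidation (M)"),
    check.names = FALSE
  )
  wide[["Intensity A_1"]] <- c(100, 200)
  wide[["Intensity A_2"]] <- c(0, 300)
  write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  smap <- tibble::tibble(sample = c("A_1", "A_2"), strain_id = "A",
                         replicate_id = c("R1", "R2"))
  out <- read_search_engine_peptides(path, smap)
  expect_equal(nrow(out), 4L)
  expect_equal(sort(unique(out$protein_id)), c("P1", "P2"))
  expect_equal(out$is_modified, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(read_search_engine_peptides(
    path, tibble::tibble(sample = "A_1", strain_id = "A",
                         replicate_id = "R1")
  ), "missing from")
})

test_that("peptide tables round-trip through TSV", {
  truth <- sim_proteome_truth(n_proteins = 3, seed = 6)
  sim <- sim_peptide_table(truth, seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(sim$peptides, path)
  back <- read_peptide_table(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$peptides),
               tolerance = 1e-12)
})
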