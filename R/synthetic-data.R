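#' Simulated proteome ground truth
#'
#' Builds the ground-truth description of a membrane proteome for
#' [sim_peptide_table()]: a set of background proteins at constant abundance
#' across strains plus one spiked target protein whose abundance changes by a
#' known fold between strains. This emulates a co-expression screen in which a
#' single membrane protein (e.g. a PrsA-family foldase) responds to the
#' genetic background while the bulk proteome stays put.
#'
#' @param n_proteins Total number of proteins, including the target.
#' @param strains Character vector of strain labels.
#' @param target_protein Accession given to the spiked protein.
#' @param target_fold_change Named numeric vector, one fold change per strain,
#'   applied to the target's base abundance. Background proteins have fold 1
#'   in every strain.
#' @param n_peptides_range Integer range from which each protein's observable
#'   peptide count is drawn uniformly.
#' @param base_abundance_range Range of base abundances (arbitrary intensity
#'   units); values are drawn log-uniformly, emulating the large dynamic range
#'   of a membrane proteome.
#' @param seed Integer seed; the same seed reproduces the table exactly.
#'
#' @return A tibble with columns `protein_id`, `n_peptides`,
#'   `base_abundance`, and a list-column `fold_change` holding a named
#'   per-strain fold-change vector for each protein.
#' @seealso [sim_peptide_table()]
#' @export
#' @examples
#' sim_proteome_truth(n_proteins = 5, seed = 1)
sim_proteome_truth <- function(n_proteins = 50L,
                               strains = c("A", "B"),
                               target_protein = "P_TARGET",
                               target_fold_change = c(A = 1, B = 2),
                               n_peptides_range = c(3L, 12L),
                               base_abundance_range = c(1e5, 1e8),
                               seed = 1L) {
  seed <- check_seed(seed)
  if (n_proteins < 1L) abort("`n_proteins` must be at least 1")
  if (!setequal(names(target_fold_change), strains)) {
    abort("`target_fold_change` must be named by `strains`")
  }
  if (any(target_fold_change <= 0)) abort("fold changes must be positive")
  withr::with_seed(seed, {
    ids <- c(
      target_protein,
      sprintf("P_BG%03d", seq_len(max(0L, n_proteins - 1L)))
    )
    flat_fold <- setNames(rep(1, length(strains)), strains)
    tibble(
      protein_id = ids,
      n_peptides = sample(
        seq.int(n_peptides_range[1], n_peptides_range[2]),
        n_proteins,
        replace = TRUE
      ),
      base_abundance = exp(runif(
        n_proteins,
        log(base_abundance_range[1]),
        log(base_abundance_range[2])
      )),
      fold_change = c(
        list(target_fold_change[strains]),
        rep(list(flat_fold), n_proteins - 1L)
      )
    )
  })
}

#' Simulate a peptide-level intensity table
#'
#' Generates the peptide table a search engine would export for a label-free
#' LC-MS/MS experiment: one row per (protein, peptide, strain, replicate)
#' observation, with per-peptide response factors, multiplicative lognormal
#' noise, missing observations, and modified-peptide flags. The returned
#' manifest carries the complete ground truth, so every downstream
#' quantification step can be checked against known values.
#'
#' The intensity model is
#' `base_abundance * fold_change[strain] * response_factor[peptide] * noise`,
#' where the response factor is drawn once per peptide (lognormal with
#' `sdlog = peptide_sigma`, emulating unequal ionization efficiencies — this
#' is what makes Hi3's top-3 selection non-trivial) and the noise is lognormal
#' with coefficient of variation `intensity_cv` (mean 1). With
#' `intensity_cv = 0`, `missing_rate = 0` and `modified_fraction = 0` the
#' table is a deterministic function of `truth` and `seed`.
#'
#' @param truth Ground-truth tibble as returned by [sim_proteome_truth()].
#' @param n_replicates Number of biological replicates per strain.
#' @param intensity_cv Coefficient of variation of the multiplicative
#'   lognormal intensity noise; 0 means noiseless.
#' @param missing_rate Probability that any single (peptide, replicate)
#'   intensity is unreported (missing completely at random).
#' @param modified_fraction Probability that a peptide carries a modification
#'   flag (drawn once per peptide; modified peptides are filtered out by the
#'   quantification pipeline).
#' @param peptide_sigma Lognormal `sdlog` of the per-peptide response factor.
#' @param seed Integer seed.
#'
#' @return An object of class `sim_peptide_data`: a list with
#'   * `peptides` — tibble with columns `protein_id`, `peptide_seq`,
#'     `is_modified`, `strain_id`, `replicate_id`, `intensity`;
#'   * `manifest` — per-peptide ground truth (`protein_id`, `peptide_seq`,
#'     `response_factor`, `is_modified`);
#'   * `truth` — the input truth tibble.
#' @export
#' @examples
#' truth <- sim_proteome_truth(n_proteins = 5, seed = 1)
#' sim <- sim_peptide_table(truth, intensity_cv = 0, seed = 2)
#' head(sim$peptides)
sim_peptide_table <- function(truth,
                              n_replicates = 3L,
                              intensity_cv = 0.1,
                              missing_rate = 0,
                              modified_fraction = 0,
                              peptide_sigma = 0.5,
                              seed = 1L) {
  check_columns(truth, c("protein_id", "n_peptides", "base_abundance",
                         "fold_change"), "truth")
  if (nrow(truth) < 1L) abort("`truth` must describe at least one protein")
  if (any(truth$base_abundance <= 0)) {
    abort("all `base_abundance` values must be positive")
  }
  if (any(truth$n_peptides < 1L)) abort("`n_peptides` must be >= 1")
  if (n_replicates < 2L) abort("`n_replicates` must be at least 2")
  check_probability(missing_rate, "missing_rate")
  check_probability(modified_fraction, "modified_fraction")
  check_positive_scalar(intensity_cv, "intensity_cv", allow_zero = TRUE)
  seed <- check_seed(seed)

  strains <- names(truth$fold_change[[1]])
  if (any(vapply(truth$fold_change,
                 function(f) !setequal(names(f), strains) || any(f <= 0),
                 logical(1)))) {
    abort("every `fold_change` entry must be positive and named by the same strains")
  }

  withr::with_seed(seed, {
    # Per-peptide ground truth, drawn once.
    manifest <- truth |>
      mutate(.pep = map(.data$n_peptides, function(k) {
        vapply(seq_len(k), function(i) random_peptide(), character(1))
      })) |>
      select(all_of(c("protein_id", ".pep"))) |>
      unnest(all_of(".pep")) |>
      rename(peptide_seq = ".pep")
    manifest <- manifest |>
      mutate(
        response_factor = rlnorm(nrow(manifest), meanlog = 0,
                                 sdlog = peptide_sigma),
        is_modified = runif(nrow(manifest)) < modified_fraction
      )

    sdlog <- sqrt(log(1 + intensity_cv^2))
    replicate_ids <- sprintf("R%d", seq_len(n_replicates))

    fold_tbl <- truth |>
      mutate(.f = map(.data$fold_change, function(f) {
        tibble(strain_id = strains, fold = unname(f[strains]))
      })) |>
      select(all_of(c("protein_id", "base_abundance", ".f"))) |>
      unnest(all_of(".f"))

    peptides <- manifest |>
      left_join(fold_tbl, by = "protein_id",
                relationship = "many-to-many") |>
      cross_join(tibble(replicate_id = replicate_ids))
    peptides <- peptides |>
      mutate(
        noise = rlnorm(nrow(peptides), meanlog = -sdlog^2 / 2, sdlog = sdlog),
        intensity = .data$base_abundance * .data$fold *
          .data$response_factor * .data$noise,
        missing = runif(nrow(peptides)) < missing_rate
      ) |>
      filter(!.data$missing) |>
      select(all_of(c("protein_id", "peptide_seq", "is_modified",
                      "strain_id", "replicate_id", "intensity"))) |>
      arrange(.data$protein_id, .data$peptide_seq, .data$strain_id,
              .data$replicate_id)

    structure(
      list(peptides = peptides, manifest = manifest, truth = truth),
      class = "sim_peptide_data"
    )
  })
}

#' @export
print.sim_peptide_data <- function(x, ...) {
  cat(sprintf(
    "Simulated peptide data: %d proteins, %d peptides, %d intensity rows\n",
    nrow(x$truth), nrow(x$manifest), nrow(x$peptides)
  ))
  print(x$peptides, n = 5)
  invisible(x)
}

#' Simulate a protein sequence family of known divergence
#'
#' Draws a random ancestor sequence and derives each family member by
#' substituting a prescribed fraction of its positions, always to a different
#' residue. Identity between the ancestor (first member) and member *i* is
#' therefore exactly `100 * (1 - fraction_i)` by construction; the identity
#' between two derived members depends on where their substitutions landed,
#' so the *realized* all-pairs identity matrix, counted position by position,
#' is returned as the ground truth against which alignment-based identity can
#' be checked.
#'
#' @param ancestor_length Sequence length.
#' @param substitution_fractions Either a numeric vector giving, for each
#'   non-ancestor member, the fraction of positions substituted relative to
#'   the ancestor, or a square matrix whose first row holds those fractions
#'   (the layout of a pairwise divergence target). Fractions must lie in
#'   \[0, 1\].
#' @param names Optional member names; defaults to `seq1, seq2, ...`.
#' @param alphabet Residue alphabet; defaults to the 20 amino acids.
#' @param seed Integer seed.
#'
#' @return An object of class `sim_sequence_family`: a list with
#'   `sequences` (tibble of `name`, `seq`) and `identity` (realized percent
#'   identity matrix from direct position counting, diagonal 100).
#' @export
#' @examples
#' fam <- sim_sequence_family(100, c(0.1, 0.34), seed = 1)
#' fam$identity
sim_sequence_family <- function(ancestor_length,
                                substitution_fractions,
                                names = NULL,
                                alphabet = c(
                                  "A", "C", "D", "E", "F", "G", "H", "I",
                                  "K", "L", "M", "N", "P", "Q", "R", "S",
                                  "T", "V", "W", "Y"
                                ),
                                seed = 1L) {
  seed <- check_seed(seed)
  if (ancestor_length < 1L) abort("`ancestor_length` must be positive")
  if (is.matrix(substitution_fractions)) {
    if (nrow(substitution_fractions) != ncol(substitution_fractions)) {
      abort("`substitution_fractions` matrix must be square")
    }
    fractions <- substitution_fractions[1, -1]
  } else {
    fractions <- substitution_fractions
  }
  if (any(fractions < 0 | fractions > 1)) {
    abort("substitution fractions must lie in [0, 1]")
  }
  n <- length(fractions) + 1L
  nm <- names %||% sprintf("seq%d", seq_len(n))
  if (length(nm) != n) abort("`names` must have one entry per member")

  withr::with_seed(seed, {
    ancestor <- sample(alphabet, ancestor_length, replace = TRUE)
    seqs <- vector("list", n)
    seqs[[1]] <- ancestor
    for (i in seq_along(fractions)) {
      s <- ancestor
      k <- round(fractions[i] * ancestor_length)
      if (k > 0) {
        pos <- sample.int(ancestor_length, k)
        s[pos] <- vapply(s[pos], function(res) {
          sample(setdiff(alphabet, res), 1L)
        }, character(1))
      }
      seqs[[i + 1L]] <- s
    }
    identity <- matrix(100, n, n, dimnames = list(nm, nm))
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        pid <- 100 * sum(seqs[[i]] == seqs[[j]]) / ancestor_length
        identity[i, j] <- pid
        identity[j, i] <- pid
      }
    }
    structure(
      list(
        sequences = tibble(
          name = nm,
          seq = vapply(seqs, paste, character(1), collapse = "")
        ),
        identity = identity
      ),
      class = "sim_sequence_family"
    )
  })
}

#' Simulate a promoter region with implanted degenerate motifs
#'
#' Builds a random nucleotide background and copies each requested motif into
#' it at a stated position and strand, with exactly `n_mismatches` positions
#' randomized to a different base. The implant manifest records, for each
#' motif, the forward-strand interval it occupies and the number of bases it
#' still shares with the canonical sequence, so a motif scanner's hits can be
#' checked against construction.
#'
#' @param length Region length in bases.
#' @param implants Tibble (or data frame) with columns `motif` (canonical
#'   sequence as written on its own strand), `position` (0-based forward
#'   strand start), `strand` (`"+"` or `"-"`), `n_mismatches` (exact count of
#'   substituted positions). Implants must fit in the region and must not
#'   overlap one another.
#' @param seed Integer seed.
#'
#' @return An object of class `sim_promoter_region`: a list with `sequence`
#'   (single uppercase DNA string) and `manifest` (tibble with columns
#'   `motif`, `start`, `end`, `strand`, `n_mismatches`, `expected_matches`,
#'   `implanted_seq` — the implanted bases as read on the motif's strand).
#' @export
#' @examples
#' reg <- sim_promoter_region(
#'   200,
#'   tibble::tibble(motif = "TTTTCACA", position = 40,
#'                  strand = "+", n_mismatches = 1),
#'   seed = 1
#' )
#' reg$manifest
sim_promoter_region <- function(length, implants = NULL, seed = 1L) {
  seed <- check_seed(seed)
  if (length < 1L) abort("`length` must be positive")
  withr::with_seed(seed, {
    region <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    manifest <- tibble(
      motif = character(), start = integer(), end = integer(),
      strand = character(), n_mismatches = integer(),
      expected_matches = integer(), implanted_seq = character()
    )
    if (!is.null(implants) && nrow(implants) > 0) {
      check_columns(implants, c("motif", "position", "strand",
                                "n_mismatches"), "implants")
      implants <- as_tibble(implants)
      k <- nchar(implants$motif)
      start <- as.integer(implants$position)
      end <- start + k
      if (any(start < 0L) || any(end > length)) {
        abort("implants must fit within the region")
      }
      ord <- order(start)
      if (any(start[ord][-1] < end[ord][-length(end)])) {
        abort("implanted motifs must not overlap")
      }
      if (any(implants$n_mismatches < 0L |
                implants$n_mismatches > k)) {
        abort("`n_mismatches` must lie in [0, motif length]")
      }
      rows <- vector("list", nrow(implants))
      for (i in seq_len(nrow(implants))) {
        oriented <- toupper(implants$motif[i])
        if (implants$strand[i] == "-") oriented <- dna_revcomp(oriented)
        bases <- strsplit(oriented, "")[[1]]
        m <- as.integer(implants$n_mismatches[i])
        if (m > 0) {
          pos <- sample.int(k[i], m)
          bases[pos] <- vapply(bases[pos], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1L)
          }, character(1))
        }
        region[seq.int(start[i] + 1L, end[i])] <- bases
        as_read <- paste(bases, collapse = "")
        if (implants$strand[i] == "-") as_read <- dna_revcomp(as_read)
        rows[[i]] <- tibble(
          motif = toupper(implants$motif[i]),
          start = start[i], end = end[i],
          strand = implants$strand[i],
          n_mismatches = m,
          expected_matches = k[i] - m,
          implanted_seq = as_read
        )
      }
      manifest <- bind_rows(rows)
    }
    structure(
      list(sequence = paste(region, collapse = ""), manifest = manifest),
      class = "sim_promoter_region"
    )
  })
}

#' Simulate linear kinetic absorbance traces
#'
#' One trace per entry of `true_slopes`: absorbance rising linearly with time
#' from a common intercept, plus optional Gaussian read noise. Default timing
#' matches a 6-minute microplate kinetic read with one measurement per minute
#' (7 points, 0-6 min).
#'
#' @param true_slopes Numeric vector of true slopes (absorbance units per
#'   minute), optionally named by sample.
#' @param n_timepoints Number of reads per trace.
#' @param dt Minutes between reads.
#' @param intercept Common starting absorbance.
#' @param noise_sd Gaussian noise SD per read; 0 gives exact lines.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `sample`, `time_min`, `absorbance`.
#' @export
sim_kinetic_traces <- function(true_slopes,
                               n_timepoints = 7L,
                               dt = 1,
                               intercept = 0.05,
                               noise_sd = 0,
                               seed = 1L) {
  seed <- check_seed(seed)
  if (n_timepoints < 3L) abort("`n_timepoints` must be at least 3")
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  nm <- base::names(true_slopes) %||% sprintf("S%d", seq_along(true_slopes))
  times <- seq(0, by = dt, length.out = n_timepoints)
  withr::with_seed(seed, {
    out <- map2(nm, unname(true_slopes), function(s, b) {
      tibble(
        sample = s,
        time_min = times,
        absorbance = intercept + b * times +
          if (noise_sd > 0) rnorm(n_timepoints, 0, noise_sd) else 0
      )
    })
    bind_rows(out)
  })
}

#' Simulate an amylase calibration series
#'
#' Standards at known concentrations with a linear slope response
#' (`response = intercept + response_per_unit * concentration`) plus optional
#' Gaussian noise. Default concentrations follow a 0-500 concentration-unit
#' dilution series.
#'
#' @param concentrations Standard concentrations (must be non-negative).
#' @param response_per_unit True gain: response (slope units) per
#'   concentration unit.
#' @param intercept Response at zero concentration.
#' @param noise_sd Gaussian noise SD on the responses.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `concentration`, `response`.
#' @export
sim_calibration_series <- function(concentrations = seq(0, 500, by = 100),
                                   response_per_unit = 0.002,
                                   intercept = 0,
                                   noise_sd = 0,
                                   seed = 1L) {
  seed <- check_seed(seed)
  if (any(concentrations < 0)) abort("concentrations must be non-negative")
  check_positive_scalar(response_per_unit, "response_per_unit")
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  withr::with_seed(seed, {
    tibble(
      concentration = as.numeric(concentrations),
      response = intercept + response_per_unit * concentrations +
        if (noise_sd > 0) rnorm(length(concentrations), 0, noise_sd) else 0
    )
  })
}

#' Simulate beta-galactosidase plate readings
#'
#' Inverts the Miller-unit formula to produce raw A420 readings consistent
#' with stated true activities, culture densities, reaction time and assayed
#' volume, with a fixed scatter reading at A550 and optional Gaussian noise
#' on A420. Defaults mirror a 15-minute ONPG reaction on 0.1 mL of culture.
#'
#' @param true_miller_units Numeric vector of true activities (Miller units),
#'   optionally named by sample.
#' @param od600 Culture densities, one per sample (recycled if scalar).
#' @param time_min Reaction time in minutes.
#' @param volume_ml Culture volume assayed, in mL.
#' @param a550 Scatter absorbance (scalar or per sample).
#' @param noise_sd Gaussian noise SD added to A420.
#' @param seed Integer seed.
#'
#' @return Tibble with columns `sample`, `od600`, `a420`, `a550`,
#'   `time_min`, `volume_ml`.
#' @export
sim_bgal_readings <- function(true_miller_units,
                              od600,
                              time_min = 15,
                              volume_ml = 0.1,
                              a550 = 0.05,
                              noise_sd = 0,
                              seed = 1L) {
  seed <- check_seed(seed)
  n <- length(true_miller_units)
  od600 <- rep_len(od600, n)
  a550 <- rep_len(a550, n)
  if (any(od600 <= 0)) abort("`od600` must be positive")
  check_positive_scalar(time_min, "time_min")
  check_positive_scalar(volume_ml, "volume_ml")
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  nm <- base::names(true_miller_units) %||% sprintf("S%d", seq_len(n))
  withr::with_seed(seed, {
    a420 <- unname(true_miller_units) * time_min * volume_ml * od600 / 1000 +
      1.75 * a550 +
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    tibble(
      sample = nm, od600 = od600, a420 = a420, a550 = a550,
      time_min = time_min, volume_ml = volume_ml
    )
  })
}
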