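---
title: "Methods behind secscreen: quantification, comparison and statistics for chaperone-assisted secretion screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind secscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secscreen)
library(dplyr)
```

## The scientific setting

Industrial *Bacillus* strains secrete alpha-amylases at high level, and the
yield of a secreted amylase often depends on the extracytoplasmic foldase
PrsA — a membrane-anchored lipoprotein chaperone that assists folding of
exported proteins at the membrane–wall interface. A typical screen
co-expresses an amylase with a panel of PrsA homologs and asks four
computational questions:

1. **How much chaperone is in the membrane?** Label-free LC-MS/MS of the
   membrane fraction, quantified by the Hi3 top-3-peptide method, gives each
   strain's PrsA level as a fraction of the whole detected proteome.
2. **How related are the players?** Percent-identity matrices of the mature
   protein sequences (signal peptides removed), from pairwise local
   alignment, plus a neighbor-joining tree as a visual summary.
3. **Is the chaperone gene itself regulated?** The upstream region is
   scanned for degenerate matches to the housekeeping sigma-A promoter
   boxes and to the CssR secretion-stress operator octamer.
4. **Did co-expression help?** Amylase activities, normalized per amylase to
   the strain with no added chaperone gene, compared by Bonferroni-corrected
   pairwise t-tests.

`secscreen` implements these four stages as composable tibble-in /
tibble-out functions, together with a synthetic-data module that generates
every input with known ground truth. Raw wet-lab data for such screens are
generally not deposited, so the package's guarantees are established
against construction: every stage is tested against the manifests of the
generators and against independent brute-force reimplementations.

## Hi3 quantification

The pipeline consumes a peptide-level intensity table (one row per peptide
per run) and follows the standard post-search recipe:

* modified peptides are removed (`filter_modified()`);
* each biological replicate is normalized separately by dividing through
  the median of its reported intensities (`median_normalize()`);
* a protein's abundance in a run is the sum of its three most intense
  normalized peptides, defined only when at least three peptide
  intensities are reported there (`hi3_quantify()`);
* a protein is valid for quantification when it has values in at least two
  of three replicates (`replicate_filter()`);
* a protein's relative abundance in a run is its Hi3 value divided by the
  summed Hi3 values of all quantifiable proteins in that run
  (`relative_abundance()`).

Conventions that the recipe leaves open are fixed explicitly:

* **Zero intensities are unreported.** Search-engine tables use 0 for
  non-detection; a zero row is treated exactly like a missing one.
* **The normalization median** is taken over all reported, unmodified
  intensities of the run — normalization precedes protein-level filtering.
  For an even count the median is the mean of the two middle values.
* **Ties at the third-largest peptide** cannot change the top-3 sum, so the
  result is deterministic by value, not by row order.
* **The denominator includes the target itself**: "all quantified proteins"
  makes no exclusion, and this keeps the per-run fractions summing to 1.
* **Generalizing two-of-three**: for n replicates the default threshold is
  `ceiling(2n/3)`, which preserves the proportion and reduces to 2 of 3 for
  triplicates; it is overridable.
* **Averaging order**: per-replicate fractions are computed first and then
  averaged (`mean_of_ratios`); the alternative (`ratio_of_means`) is one
  switch away in `abundance_summary()` because published figures rarely say
  which was used. On noiseless data the two agree.

The invariants the tests enforce are the ones a practitioner would reach
for on a whiteboard: per-run scale invariance (normalization divides it
out), conservation (fractions sum to 1), monotonicity (raising the
target's intensities never lowers its fraction), and exact agreement with
a plain-loop reimplementation on hundreds of small random tables.

## The synthetic proteome

`sim_proteome_truth()` + `sim_peptide_table()` emulate a two-strain
membrane-proteome comparison: 50 proteins by default, base abundances drawn
log-uniformly over three orders of magnitude (1e5–1e8 intensity units),
3–12 observable peptides per protein, three biological replicates, and one
spiked target protein whose fold change between strains is the recovery
target. Peptide intensities are
`base_abundance x fold_change x response_factor x noise`:

* the **response factor** is drawn once per peptide (lognormal, sdlog 0.5),
  emulating unequal ionization efficiencies — without it, Hi3's top-3
  selection would be trivial;
* the **noise** is lognormal with mean 1 and a coefficient of variation of
  0.1 by default. Published screens of this kind report no dispersion
  estimates for peptide intensities, so 10% is adopted as a conventional
  figure for technical variability in label-free data, chosen once;
* **missingness** is intensity-independent (MCAR) — the simplest model that
  exercises the two-of-three filter and the three-peptide rule;
* all randomness flows from one seed (via `withr::with_seed()`), so every
  generated dataset is byte-reproducible.

What the generator does *not* emulate: intensity-dependent missingness,
retention-time or m/z structure, chromatographic artifacts, shared/razor
peptides, or between-replicate batch effects. Passing the recovery tests
therefore shows that the *arithmetic* of the pipeline is right and robust
to realistic noise and missingness — not that Hi3 is unbiased on real
spectra. One structural effect the synthetic data do expose is the
**denominator composition effect**: a spiked target changes the summed
proteome between strains, so even noiseless recovery of a fold-2 spike is
slightly below 2. The tests compare noiseless recovery against the oracle
(exact agreement) rather than against the nominal fold, and the noisy
recovery criterion (median over 20 seeds within 15% of truth for folds
0.5, 1 and 2 at cv 0.1) absorbs both the noise and this composition effect.

## Sequence identity and trees

Mature sequences (signal peptides trimmed at user-supplied, not predicted,
boundaries) are compared by Smith–Waterman local alignment with affine
gaps. The alignment engine is Biostrings' `pairwiseAlignment()`; the
package fixes and records the conventions:

* default scoring BLOSUM62, gap open 10, gap extend 0.5 (a gap of length L
  costs `10 + 0.5 L`) — the classic local-alignment defaults, configurable
  and echoed in the output headers of `write_identity_matrix()`;
* percent identity defaults to identical columns over the full alignment
  length including gap columns; the shorter-sequence denominator is a
  switch, because published identity tables rarely state their convention;
* an all-negative score landscape yields the empty alignment with score 0
  and identity 0.

The test suite checks the engine against an exhaustive enumeration oracle:
a local alignment is a chain of aligned residue pairs with affine gap costs
between consecutive pairs, and for sequences of length at most 8 all chains
can be enumerated. Scores agree exactly over hundreds of random pairs.

The identity matrix converts to the simple divergence distance
`d = 1 - identity/100` and is summarized by a neighbor-joining tree
(`ape::nj`). NJ is exact on additive matrices; the tests verify exact
recovery of topology and branch lengths for random 5–8-taxon trees, and
negative branch estimates (possible on non-additive input) are clamped to
zero with a message. No bootstrap support and no multiple alignment are
provided — the tree is a visual companion to the identity matrix, not a
phylogenetic inference.

The divergence generator `sim_sequence_family()` mutates each member away
from a random ancestor at a prescribed fraction of positions, always to a
different residue, so ancestor–descendant identity is exact by
construction; for all other pairs the realized identity (direct position
count) is returned as ground truth. A full pairwise divergence target is
not generally realizable from a single ancestor, which is why the
generator's contract is anchored to the ancestor row and the realized
matrix.

## Motif scanning

`scan_motif()` finds every window of a region sharing at least
`min_matches` bases with a canonical motif, on both strands; minus-strand
hits are found by matching the motif's reverse complement on the forward
strand and are reported on the forward-strand interval they occupy.
Coordinates are 0-based half-open throughout; `N` never counts as a match;
overlapping hits are all reported, because real regulatory features overlap
(a CssR operator superimposed on a −35 box is exactly the motivating
case). The scanner is vectorized per motif position; the test oracle is a
naive per-window double loop, and the two agree on hit sets across
hundreds of random kilobase regions.

`scan_sigma_a()` pairs −35 (TTGACA) and −10 (TATAAT) hexamer hits, each
with at least 5 of 6 canonical bases by default, separated by a 16–18 bp
spacer. The reported promoter center is by default the midpoint of the
full −35-through-−10 span; "centered N bp upstream" statements depend on
the centering convention, which is unstated in most papers, so the
convention is configurable (`minus10_midpoint` as the alternative) and is
echoed in every output row.

## Assay units

* **Amylase**: one activity unit is the enzyme amount increasing absorbance
  (A405) by one unit per minute; `kinetic_slope()` is the least-squares
  slope over all timepoints (default seven readings, 0–6 min) rather than a
  first-to-last difference, using every reading and damping single-read
  noise. `fit_calibration()` relates slopes to standard concentrations
  (0–500 concentration units) by ordinary least squares;
  `concentration_from_slope()` inverts it and flags extrapolation beyond
  the standard range. Technical duplicates are averaged before unit
  conversion, biological replicates after.
* **Beta-galactosidase**: the unit has the dimensions nmol·OD⁻¹·min⁻¹, and
  the classical Miller formula with the 1.75 scatter correction is adopted:
  `1000 (A420 − 1.75 A550) / (t · v · OD600)` with t = 15 min and
  v = 0.1 mL as defaults matching the usual assay layout. The 1.75 factor
  is configurable because laboratories differ; absolute Miller magnitudes
  are therefore comparable only within a fixed convention.

## Yield statistics

`relative_yield_table()` reproduces the structure of a relative-yield
matrix: per amylase, replicate activities are divided by the mean of the
reference cell (the strain with no added chaperone gene), each
non-reference cell is compared to the reference by a two-sample t-test on
the normalized values, and p-values are Bonferroni-corrected with family
size equal to the number of non-reference cells in that amylase's row —
the correction family is the row's reference comparisons, not the whole
matrix, matching how such tables describe their correction.

Choices made where the convention is commonly unstated:

* **Welch's t-test** is the default ("pairwise t-test" alone does not pin
  the variance assumption); the pooled test is a switch, recorded in the
  result's attributes.
* **Degenerate cells**: noiseless synthetic data produce zero within-group
  variance. Both groups constant and equal gives p = 1; constant and
  unequal gives p reported as the smallest positive double with a
  `degenerate` flag — deterministic answers instead of division-by-zero.
* **Significance classes**: significant for p < 0.05, marginal for
  0.05 ≤ p < 0.10 (the asterisk band), else ns; the boundaries are
  half-open exactly as written and covered by boundary tests at 0.05 and
  0.10.
* **Replicate structure**: six determinations per cell are treated as six
  independent values for the test's degrees of freedom; whether they arise
  as 2 experiments x 3 biological replicates is a design fact the table
  format does not carry.

## Problem sizes and reproducibility

The test-suite and acceptance-script problem sizes are chosen so the whole
battery reruns in a couple of minutes on one core while still being
decisive: 200 random tables for pipeline-vs-oracle equality (tolerance
1e-9), 20 seeds per fold for spike recovery, 100 random pairs for the
alignment oracle, 50 trees for NJ exactness, 100 kilobase regions for the
scan oracle. Every stochastic step takes an explicit seed, and generators
isolate their RNG state, so results are stable across sessions and
platforms.

## Known limitations

* No protein inference: the leading accession of a peptide's protein list
  is taken as given; shared peptides are not reassigned.
* The identity matrix depends on scoring parameters and the identity
  denominator; comparisons across publications require matching both.
* Motif scanning is count-based by design — no position-weight-matrix
  scoring and no enrichment statistics; a hit is a statement about base
  matches, not about binding.
* Absolute Miller units and assay units are convention-bound; only
  within-study ratios are meaningful, which is why the statistics stage
  works exclusively on reference-normalized values.
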