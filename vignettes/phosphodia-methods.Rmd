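---
title: "Methods: phosphosite localization, collapse and stoichiometry for DIA phosphoproteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphosite localization, collapse and stoichiometry for DIA phosphoproteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphodia)
library(dplyr)
```

## The problem

Data-independent acquisition (DIA) fragments everything inside wide
(here 14 Da) isolation windows. For phosphopeptides this creates a specific
ambiguity: positional isomers — peptides with identical sequence and phospho
count but the phospho group on a different serine, threonine or tyrosine —
have identical precursor mass, co-isolate in the same window, and often
co-elute. Assigning the modified residue therefore has to come from the
fragment level: only *site-determining* ions, whose mass differs between
isomer placements, carry localization information. This package implements a
peptide-centric localization score for DIA, the collapse of precursor-level
reports into site-level quantification tables, a label-free regression model
for fractional phosphosite stoichiometry, and the statistics used to
benchmark all of it — together with seed-deterministic synthetic-data
generators so that every stage can be validated against known ground truth
without instrument data.

## Site localization model

For a peptide with `p` variable phospho groups and `n` candidate S/T/Y
residues, all `choose(n, p)` placements are enumerated as *site candidates*
(`enumerate_site_candidates()`). The theoretical b/y fragment masses of all
candidates are pooled and deduplicated at 1e-4 Da
(`site_determining_fragments()`); each unique mass is annotated per candidate
as:

* **confirming** — in this candidate's theoretical set but not in every
  candidate's,
* **refuting** — in another candidate's set but not in this one's,
* **neutral** — shared by all candidates (no localization information).

Every unique mass is then scored against the data
(`score_fragment_evidence()`): its XIC is extracted across the boundaries of
the precursor's detected peak group, and a per-fragment weight is formed from
bounded components:

* *intensity* — position of the fragment apex inside the group's dynamic
  range, 1 for the strongest fragment and decaying by decade
  (`intensity_decades = 3`). The component is a function of the intensity
  *ratio* to the strongest fragment, not of absolute counts, which makes the
  final score invariant to a global intensity rescale of the run — an
  invariant we consider a hard requirement for a fractional confidence (a
  component based on absolute log-intensity would violate it);
* *mass accuracy* — `exp(-(ppm / sigma_ppm)^2 / 2)` of the apex centroid,
  `sigma_ppm = 10`;
* *XIC correlation* — Pearson correlation against the peak-group consensus
  profile. Fragments with `r < r_min = 0.25` are treated as co-isolated
  interference and their weight is forced to 0, the DIA-specific advantage
  over single-spectrum localization;
* optionally *isotope similarity* of the observed M+1/M+0 ratio to the
  averagine expectation (off by default: it requires resolved fragment
  isotope peaks, and in centroided data with interference it removes more
  signal than error).

The weight is the product of the clamped components, so any failing
component vetoes a fragment (a `"mean"` combination is available as a
strategy option). A candidate's raw score is the sum of the weights of its
observed confirming fragments minus the sum over its observed refuting
fragments, floored at zero; *fractional confidences* are the floored scores
normalized to sum to one. When no fragment evidence survives, confidence is
uniform over candidates — reporting ignorance honestly rather than
abstaining, and downstream Class I cutoffs then exclude the peptide anyway.
Per-residue site confidence is the sum of the fractional confidences of the
candidates containing that residue (so residue confidences sum to `p`), and
residues at or above the threshold are **Class I** sites: 0.75 for
library-based analysis, 0.99 recommended for library-free pseudo-DDA
analysis.

Two design points deserve a note. First, the subtraction of refuting
evidence is applied at the *candidate* level (the form shown in the score's
defining figure), and the site level only aggregates candidate fractions;
applying a second subtraction at site level would double-penalize. Second,
b1 ions are generated although several search engines omit them: the b1 ion
of an N-terminal phospho-residue is the single most site-determining ion of
such peptides. Neutral-loss (-H3PO4) ions are excluded from the evidence by
default since they localize identically to their parent ion and would double
count; a flag enables them.

## Peak-group detection

Peak groups are detected on the summed fragment XIC trace: Savitzky-Golay
smoothing (window 5, order 2), candidate apexes at local maxima above a
noise floor of 5% of the trace maximum, boundaries at the nearest local
minima. Groups are ranked by
`0.5 * spectral contrast angle(fragment areas, library intensities) +
0.5 * mean pairwise fragment-trace correlation`; ties resolve to earlier
retention time. This score is a deliberately simple, documented stand-in for
proprietary peak-group scores in commercial DIA software — adequate for the
synthetic benchmarks here, and not claimed to match any vendor
implementation.

## Pseudo-DDA (library-free) spectrum generation

`detect_3d_features()` builds MS1 features in three dimensions (m/z,
intensity, retention time) by connecting per-scan centroid peaks across
adjacent scans within 10 ppm, with a gap limit of 1 scan and a minimum span
of 3 scans. `build_pseudo_spectra()` extracts fragment XICs in each
feature's isolation window over its elution span and keeps fragment masses
whose profile correlation with the feature's MS1 trace is at least 0.8;
contested masses go to the best-correlating feature. The output is a
DDA-like peak list per precursor feature that a conventional search engine
could consume; the search engine itself is out of scope.

## Collapse to peptide- and site-level tables

`collapse_to_modified_peptides()` sums charge states of the same modified
sequence per run in **linear** intensity space and log2-transforms the sums
afterwards; missing (sequence, run) combinations remain missing and are
never zero-filled. `collapse_to_sites()` explodes each localized phospho
position at or above the cutoff (default 0.75) into a MaxQuant-style site
key — protein, 1-based protein position (`peptide_start + position - 1`),
and multiplicity (`___1/___2/___3`), kept as part of the key so that singly
and doubly phosphorylated forms of one residue are separate rows. When one
precursor carries two localized sites of equal probability straddling the
cutoff, both are retained. Protein groups are keyed by their first
accession, with the full list preserved as annotation.
`denormalize_and_requantile()` undoes software normalization (division by
per-run factors) and provides cross-run quantile normalization; for complete
matrices the quantile step uses the classic mean-of-sorted-columns
reference, for matrices with missing values a rank-interpolation variant
that leaves missing entries missing.

## Label-free stoichiometry (3DMM)

The occupancy `a` of a site is the fraction of the protein's copies carrying
the phospho group. With phosphopeptide intensity `P`, non-phosphorylated
counterpart intensity `N` and protein intensity `Q` (linear scale,
de-normalized, quantile-normalized), the model is a plane through the
origin:

\[ Q_i \approx \alpha P_i + \beta N_i \]

fitted by nonnegative least squares over *all* conditions and replicates of
a site at once — response factors are physical and cannot be negative, and
unconstrained least squares on noisy data can produce occupancies outside
[0, 1] structurally rather than by noise. Occupancies are evaluated on
replicate-mean intensities,

\[ a_i = \frac{\alpha P_i}{\alpha P_i + \beta N_i}, \]

which is invariant to a common rescaling of `(alpha, beta)` and hence to the
protein intensity scale. Two noiseless conditions reduce exactly to the
closed-form two-ratio solution `occupancy_two_condition()` (`a_B = (z-y)/(x-y)`,
`a_A = x (z-y) / (z (x-y))` for phospho/counterpart/protein ratios
`x`, `y`, `z`), which the test suite verifies to 1e-6. Degenerate fits
(all-zero counterpart, or a response factor at the boundary) are flagged
rather than silently reported; out-of-range occupancies are clipped to
[0, 1] with a flag.

Missing triplet entries are filled by `extrapolate_missing()`: peptide forms
mapping to the same group (charge states, missed cleavages) are assumed to
behave linearly with each other; the donor with the highest Pearson
correlation over at least two shared observations provides a least-squares
line in log space (intensities are multiplicative, so log space is the
natural domain for a linear relation between forms). Entries without an
eligible donor stay missing, and filled entries carry an `imputed` flag.
Replicates enter the regression as independent points rather than as means:
with only 2-3 replicates per condition, averaging first would discard the
information the plane fit needs to separate noise from regulation.

## Benchmark statistics

`filter_min_valid()` keeps features with at least `min_valid` (default 3)
valid values in at least one treatment group. `normalize_and_impute()`
median-centers each sample and imputes missing values from
`Normal(mean - 1.8 sd, 0.3 sd)` of the sample's observed distribution — the
field-standard treatment of missing-not-at-random low-abundance values; with
a fixed seed the imputation is bit-reproducible. `sam_test()` implements the
s0-moderated d-score, `d = (mean1 - mean2) / (s + s0)` with pooled standard
error `s`, and for multi-class designs an s0-moderated F-type statistic,
`sqrt(between-group mean square) / (pooled within-group sd + s0)`; the exact
multi-class moderation is not uniquely pinned down in the literature, so the
choice is documented here and kept monotone in group separation. q-values
come from group-label permutations (default 250): expected false positives
over observed positives at each |d| threshold, made monotone. The test suite
verifies on an all-null 2,000-feature simulation that the number of q <= 0.05
calls stays within twice the nominal budget. `roc_from_scores()` thresholds
|d| and reports TPR/FPR with trapezoidal AUC; `mse_decomposition()` reports
`bias = |mean - truth|`, the population variance, the classical
`mse = bias^2 + variance`, and additionally the additive `bias + variance`
summary used in quantification-benchmark figures ("positive bias" is read as
the absolute bias).

## Synthetic-data generators

Three generators emulate the benchmark designs the package is tested
against; all are seed-deterministic and write ground truth alongside.

* `simulate_dia_run()` forward-models a centroided DIA acquisition with the
  48 x 14 Da / 1 Da overlap window scheme starting at 350 Da: each roster
  peptide contributes an averagine MS1 isotope envelope and the singly
  charged b/y fragments of its true site placement, shaped by a Gaussian
  elution profile (sigma 5 s) on a 2-3 s cycle grid, with multiplicative
  log-normal peak noise and optional uniform-m/z interference peaks per
  window. Positional isomers are simulated as two roster rows of one
  sequence; identical apexes are the hardest, default co-elution case.
* `simulate_species_mix()` emulates a two-species ratio benchmark: a
  constant background population and a regulated subpopulation scaled by
  the design ratios {0.25, 0.5, 1.5, 2} over a 1:1 reference, log-normal
  base intensities, multiplicative replicate noise at 10% CV.
* `simulate_stoichiometry_benchmark()` draws per-site protein abundances
  log-normal and emits `P = alpha a T`, `N = beta (1-a) T`, `Q = T` with
  independent 10% CV noise on the occupancy grid {1, 10, 50, 90, 99}%.

What the generators deliberately do **not** model: retention-time drift and
prediction, profile-mode peaks, charge-state envelopes beyond the roster
charge, AGC/injection-time saturation, chimeric MS1 features, and
proteome-scale rosters. Passing the synthetic benchmarks therefore
demonstrates the correctness of the algorithms under their stated model, not
instrument-level performance; headline numbers from real instrument data
(site counts per run, error rates on synthetic-peptide spike-ins) are not
reproducible from simulation and are not claimed.

## Problem sizes and numerical choices

The shipped benchmark suites use 500 sites x 5 conditions x 3 replicates for
stoichiometry, 1,000 + 200 features for the ratio design, 100 precursors per
simulated DIA run for the localization suite, and 2,000 features x 250
permutations for the null-FDR check — sizes chosen so each suite represents
its design faithfully while the whole validation remains a desk-scale
computation. Mass deduplication uses 1e-4 Da (below instrument resolution,
above float noise); XIC tolerances default to 20 ppm for fragments and
10 ppm for MS1 features; retention time is seconds everywhere (mzML minutes
converted on read); isolation windows are closed intervals so 1-Da overlaps
double-assign, matching the overlap's purpose of recovering edge precursors.
Confidence ties at the Class I threshold use `>=` and report all tied
residues, leaving disambiguation to the collapse keys.

## A worked example

```{r example, eval = FALSE}
roster <- random_phosphopeptide_roster(20, seed = 1)
sim <- simulate_dia_run(dia_sim_config(roster, seed = 1))
pep <- modified_peptide(roster$sequence[1], 1)
loc <- localize_precursor(sim$run, pep, roster$charge[1],
                          build_window_scheme(),
                          rt_range = roster$rt[1] + c(-45, 45))
tidy(loc)          # per-residue confidences and Class I flags
autoplot(loc)      # confidence bar chart

bench <- simulate_stoichiometry_benchmark(n_sites = 100, seed = 1)
fit_3dmm_by_site(bench$triplets) |>
  dplyr::group_by(condition) |>
  dplyr::summarise(median_occupancy = median(occupancy))
```

## Known limitations

* The peak-group quality score and the component weighting are principled
  stand-ins, not reverse-engineered vendor formulas; absolute score values
  are not comparable to any commercial tool, only the resulting fractional
  confidences are meaningful.
* Localization reports no decoy-based global FDR; the Class I cutoff is a
  per-precursor confidence threshold.
* The pseudo-DDA path stops at spectrum generation; database search and
  target-decoy control belong to external engines.
* Stoichiometry assumes the counterpart peptide and protein are observable
  and that response factors are shared across conditions for a given site;
  sites violating this (e.g. co-modified counterparts) yield flagged,
  not silently wrong, fits.
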