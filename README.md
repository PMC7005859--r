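# phosphodia

Phosphosite localization, site-level quantification and fractional
stoichiometry for data-independent acquisition (DIA) phosphoproteomics, with
seed-deterministic synthetic benchmarks for every stage.

## What problem this solves

DIA co-fragments every precursor inside wide isolation windows (48 windows of
14 Da with 1 Da overlap in the default scheme). Phosphopeptide *positional
isomers* — same sequence, same phospho count, different modified S/T/Y
residue — share a precursor mass, co-isolate and often co-elute, so the
modified residue must be inferred from site-determining fragment ions. This
package is for computational proteomics researchers who need:

* **Localization**: a peptide-centric DIA site-localization score. All
  `choose(n, p)` site candidates are enumerated; unique fragment masses are
  annotated per candidate as confirming/refuting/neutral; each observed mass
  gets a weight from bounded components (relative intensity, mass accuracy
  `exp(-(ppm/σ)²/2)`, XIC correlation against the peak-group consensus with
  interference removal below `r = 0.25`, optional isotope similarity). A
  candidate's score is Σ confirming − Σ refuting weights (floored at 0), the
  fractional confidence is the score over the candidate total, and per-residue
  confidences (summing to `p`) are thresholded at 0.75 for **Class I** calls
  (0.99 recommended for library-free mode).
* **Collapse**: transformation of precursor-level reports into
  modification-specific peptide tables and MaxQuant-like site tables
  (`protein_S123___1` keys, linear-space summation then log2, missing stays
  missing), plus de-normalization and quantile normalization.
* **Stoichiometry**: the label-free 3D multiple-regression model (3DMM). For
  each site, phospho (`P`), counterpart non-phospho (`N`) and protein (`Q`)
  intensities over all conditions and replicates are fitted as
  `Q ≈ αP + βN` (nonnegative least squares, plane through the origin);
  occupancy per condition is `a = αP / (αP + βN)`. Two noiseless conditions
  reduce exactly to the closed form `a_B = (z−y)/(x−y)`,
  `a_A = x(z−y)/(z(x−y))`. Missing entries are filled by linear-behavior
  extrapolation between peptide forms in log space.
* **Benchmark statistics**: min-valid filtering, median centering,
  downshifted-normal imputation (width 0.3, downshift 1.8), s0-moderated
  SAM/ANOVA tests with permutation FDR, d-score ROC curves, and
  bias/variance MSE decomposition.
* **Synthetic data**: forward simulation of DIA runs with known true sites
  (mzML-compatible), the mixed-species ratio benchmark (0.25/0.5/1.5/2-fold
  over constant background), and the stoichiometry benchmark
  (1/10/50/90/99% occupancy grid).

## Worked example

```r
library(phosphodia)
library(dplyr)

# localize a simulated phosphopeptide precursor
roster <- random_phosphopeptide_roster(10, seed = 2)
sim <- simulate_dia_run(dia_sim_config(roster, interference_density = 1, seed = 3))
pep <- modified_peptide(roster$sequence[1], 1)
loc <- localize_precursor(sim$run, pep, roster$charge[1], build_window_scheme(),
                          rt_range = roster$rt[1] + c(-45, 45))
tidy(loc)

# stoichiometry benchmark: recover the designed occupancy grid
bench <- simulate_stoichiometry_benchmark(n_sites = 500, cv = 0.10,
                                          replicates = 3, seed = 1)
fit_3dmm_by_site(bench$triplets) |>
  group_by(condition) |>
  summarise(median_occupancy = median(occupancy)) |>
  inner_join(bench$truth, by = "condition")
```

which prints

```
  condition median_occupancy occupancy
1        c1      0.009985274      0.01
2        c2      0.099619396      0.10
3        c3      0.500031028      0.50
4        c4      0.900247409      0.90
5        c5      0.989901142      0.99
```

— the median fitted occupancy per condition (left) against the designed
ground-truth occupancy (right): the 3DMM recovers the full 1–99% grid to a
fraction of a percentage point under 10% CV noise. For the first example,
`tidy(loc)` lists each candidate S/T/Y residue with its fractional
confidence and Class I flag; on high signal-to-noise simulated runs the true
site carries essentially all the confidence.

A thin command-line wrapper is installed as `exec/phosphodia`
(subcommands `simulate-mix`, `simulate-stoich`, `localize`, `collapse`,
`stoich`, `stats`, `benchmark`), e.g.

```sh
Rscript exec/phosphodia benchmark --name stoich --seed 1
```

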