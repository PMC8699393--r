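# lineagepump

Lineage-aware analysis of intercellular fluorescence transfer in time-lapse
co-culture recordings.

## The problem

Fibroblasts inject cytoplasmic contents into adjacent cancer cells through
transient cell-projection contacts ("cell-projection pumping").  When donor
fibroblasts (HDF) carry a red lipophilic label (DiD) and acceptor
osteosarcoma cells (SAOS-2) are tracked individually through days of
time-lapse microscopy, each cancer cell's accumulated label is a per-cell
dose of received fibroblast contents.  This package implements the
statistics that turn tracked lineage forests into answers to two questions:

1. Does the received dose correlate with cell phenotype — profile area,
   circularity, migration velocity, and the propensity to divide?
2. Do those effects **persist through mitosis** into daughter cells?

The second question is answered by comparing two dose measures per cell:

* **Fa** — absolute fluorescence: the normalized value at the cell's final
  fluorescence frame (normalization fixes the starting-generation median
  of co-cultured acceptors at 100 units);
* **Fmc** — mother-compensated fluorescence: `Fa + mother's Fa / 2`,
  restoring the half of the mother's label handed to the sister at
  division.

If an effect survives mitosis, compensation restores order and Kendall's
tau against Fmc beats tau against Fa; if it dies with the mother,
compensation adds noise and Fa wins.  Scoring each experiment ±1/0 this
way (flipping signs when tau(Fa) is negative so strength is compared) and
averaging gives the **persistence index** `(1 + mean score)/2 ∈ [0, 1]` —
the proportion-weight of experiments showing persistence.  For the mitosis
association, per-experiment ratios `pFa`/`pFmc` (median uptake rate of
dividing over non-dividing cells) are scored analogously.

The package provides the lineage-forest data model with validation,
track-table I/O, mask-based morphometrics (area, marching-squares
perimeter, circularity `4πA/P²`, masked fluorescence), migration velocity
on a 2-h centroid grid with the short-final-interval rule, tie-corrected
Kendall tau-b with generation groupings, sister-pair difference analysis,
dividing/non-dividing comparisons, the persistence index, and an
agent-based co-culture simulator with per-phenotype persistence switches
and known ground truth.

## Worked example

Simulate the default seven-experiment co-culture layout (durations 4, 2,
3.6, 4, 4, 5, 4 days; area/velocity drivers reset at division, circularity
inherited) and run the full pipeline:

```r
library(lineagepump)
batch   <- simulate_experiment_batch(seed = 1)
forests <- lapply(batch, `[[`, "forest")
print(forests$a)
#> <lineage_forest> experiment a: 382 cells, 10328 observations, 4.00 days
#>   fates: divided=98, incomplete-division=2, apoptosis=11, incomplete=271
#>   generations: 0, 1, 2

report <- run_analysis(forests)
print(report)
#> <analysis_report> 7 experiment(s)
#>   area        (all): median tau Fa 0.55, Fmc 0.52; persistence index 0.00
#>   circularity (cumulative-1): median tau Fa -0.36, Fmc -0.39; persistence index 0.86
#>   velocity    (all): median tau Fa 0.12, Fmc 0.11; persistence index 0.43
#>   mitosis: persistence index 0.00
```

Reading the output: area correlates strongly with received fluorescence
(median tau 0.55 across experiments) but Fa beats Fmc everywhere, so the
index is 0.00 — the area effect does not survive division (the simulator's
area driver indeed resets).  Circularity's inverse correlation is stronger
under Fmc in 6 of 7 experiments (index 0.86): the inherited driver is
detected.  `report$correlations`, `report$sister` and `report$mitosis`
hold the per-experiment tables behind these summaries, and
`write_report(report, "out/")` writes them as deterministic CSV/JSON.

The numbered scripts under `analysis/` run the same stages as a workflow —
`01_reproduce_published_tables.R` (summary statistics recomputed from the
printed per-experiment tables), `02_simulate_cocultures.R` and
`03_run_pipeline.R` (simulate, write track tables, analyse them from
disk), `04_persistence_recovery.R` (reset vs inherit recovery study) —
writing their tables under `results/`.

## Layout

* `R/` — the package: data model (`lineage_forest`), I/O, morphometrics,
  fluorescence accounting, migration, association statistics, persistence
  index, simulator, pipeline.
* `analysis/` — numbered workflow drivers writing to `results/`.
* `tests/testthat/` — unit, property (oracle-backed) and acceptance tests.
* `vignettes/lineagepump-methods.Rmd` — the methods account: model
  assumptions, parameter defaults and why, numerical choices, limitations.
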