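# nisslcyto

Classifying cells in Nissl-stained cortex — and measuring how reliably
humans do it.

Stereological counts of neurons, glia and endothelial cells in cerebral
cortex depend on a visual judgment: given a stained cell body under the
light microscope, which of the five cell classes is it? `nisslcyto`
turns the cytological criteria behind that judgment into an executable,
deterministic rule engine, provides the statistics used to quantify how
well independent raters agree when applying such criteria, and simulates
whole rating experiments with configurable biological variability and
rater noise.

The package is aimed at quantitative neuroanatomists and at anyone
building or auditing annotation pipelines with categorical labels and
multiple (possibly missing) raters.

## What it computes

**Classification.** A cell is a symbolic *cytological profile*: nuclear
staining intensity, nuclear shape, cytoplasmic rim, envelope folding,
three heterochromatin compartments (peripheral / net / perinucleolar),
nucleolus, euchromatin texture, inclusions and context flags. Four
questions are asked in order — Is the nucleus darkly stained? Is it
surrounded by a continuous rim of cytoplasm? How is heterochromatin
distributed? How is euchromatin stained? — yielding one of six fine
labels (large/small neuron, astrocyte, oligodendrocyte, microglia,
endothelial), with documented disambiguation rules for the three hard
pairs (small neuron vs astrocyte, microglia vs oligodendrocyte,
astrocyte vs endothelial).

**Reliability.** For a units × raters ratings table with categories
c = 1..K, the coincidence matrix o_ck counts all ordered pairs of labels
given to the same unit by distinct raters (a unit with m_u raters
contributes m_u(m_u−1) pairs). Krippendorff's alpha for nominal data is

    alpha = 1 − D_o / D_e,
    D_o = (1/n) Σ_{c≠k} o*_ck,
    D_e = Σ_{c≠k} n_c n_k / (n(n−1)),

where o\*_ck are the per-unit (m_u−1)-normalized coincidences, n the
number of pairable values and n_c the category totals. Alpha is 1 at
perfect agreement, 0 at chance; missing raters are handled through the
pairable-value rule. Pairwise percent agreement (mean ± SEM across
rater pairs) and disagreement rankings complete the report.

**Simulation.** Labeled profiles are drawn from per-type feature
distributions (modal value with probability 0.8, remainder on documented
variants); each virtual rater mis-sees each feature with probability θ
within a confusable-value map; ratings follow the two-test design (236
cells × 8 raters, then 114 cells × 7 raters). See the methods vignette
(`vignettes/nisslcyto-methods.Rmd`) for the model and its calibration.

## Worked example

Classify one profile — a dark, round nucleus with one stand-out
heterochromatin granule and a perinuclear halo:

```r
library(nisslcyto)
p <- validate_profile(list(
  nucleus_stain = "dark", nuclear_shape = "round",
  cytoplasm_rim = "not_visible", envelope_folding = FALSE,
  het_peripheral = "few_granules", het_net = "rounded_granules_one_larger",
  het_perinucleolar = "single_thick_granule",
  nucleolus = "not_visible", nucleolus_count = 0,
  euchromatin_texture = "dark_obscured", inclusions = "none",
  accessory_flags = "perinuclear_halo"))
classify(p)
#> Classification: oligodendrocyte (rating: oligodendrocyte)
#>   path: Q1 -> Q3
#>   ambiguity: unambiguous
#>   supporting: perinuclear_halo
```

The cell was resolved on questions 1 and 3 alone (dark nucleus, then the
oligodendrocyte heterochromatin pattern), with the halo as supporting
evidence.

Simulate a full two-test rating experiment and score it:

```r
sim <- simulate_ratings(seed = 7)
reliability_report(sim$ratings)
#> Inter-rater reliability
#>   Krippendorff's alpha: 0.78  (D_o = 0.1759, D_e = 0.7968)
#>   pairable pairs: 18004
#>   percent agreement: 82.29 +/- 0.61%
#>   alpha by experience: experienced 0.86, inexperienced 0.74
#>   alpha by test: test1 0.79, test2 0.76
#>   top disagreements: neuron-astrocyte (764), astrocyte-endothelial (646), neuron-endothelial (536), oligodendrocyte-microglia (342)
```

Eight simulated raters (three experienced at θ = 0.04, five
inexperienced at θ = 0.10) rated 350 cells; agreement is well above
chance, experienced raters agree more, and the commonest confusions are
the anticipated hard pairs.

`run_pipeline(pipeline_config(seed = 17, out_dir = "runs/exp1"))` writes
the profiles, the ratings CSV and a versioned JSON report in one call. A
thin command-line wrapper with `classify`, `simulate`, `reliability` and
`pipeline` subcommands ships in `inst/scripts/nisslcyto`.

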