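---
title: "Cell-type classification and rater reliability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type classification and rater reliability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nisslcyto)
```

## The problem

Stereological estimates of neuron and glia numbers in cortex rest on a
step that is rarely quantified: a human looking down a microscope at a
Nissl-stained cell and deciding whether it is a neuron, an astrocyte, an
oligodendrocyte, a microglial cell or an endothelial cell. `nisslcyto`
models that decision as an explicit, reproducible procedure. It provides

1. a **rule engine** that classifies a symbolic cytological profile — a
   record of categorical visual features, not pixels — into one of six fine
   types (large/small neuron, astrocyte, oligodendrocyte, microglia,
   endothelial);
2. an **inter-rater reliability** layer (coincidence matrices,
   Krippendorff's alpha for nominal data with missing ratings, pairwise
   percent agreement, disagreement rankings); and
3. a **simulator** of rating experiments, in which panels of noisy virtual
   raters apply the rule engine to independently perturbed observations of
   the same cells.

## The feature model

A profile records one value per feature from a closed vocabulary
(`cyto_vocabulary()`): overall nuclear staining intensity (dark/light),
nuclear shape, the cytoplasmic rim, nuclear-envelope folding, the three
heterochromatin compartments (peripheral, i.e. under the envelope; the
net extending into the nuclear interior; perinucleolar), the nucleolus
and its count, euchromatin texture, cytoplasmic inclusions, and accessory
context flags (satellite positions, perinuclear halo, molding to a
vessel). Three cross-field invariants keep the space coherent: a dark
nucleus obscures euchromatin texture; a nucleolus that is not visible has
count zero; a nucleus molded to a vessel carries the corresponding
context flag. `validate_profile()` canonicalizes free-text tokens through
a shipped alias table and enforces the invariants; profiles located
inside the endothelial basal membrane (pericytes) are rejected at
validation, because thick Nissl sections cannot distinguish them.

## The decision algorithm

`classify()` asks four questions in a fixed order:

* **Q1 — is the nucleus darkly stained?** Dark nuclei belong to the small
  glia. An elongated, comma-shaped or polylobular dark nucleus is
  microglial outright. Round or ovoid dark nuclei continue to Q3.
* **Q2 — is the nucleus surrounded by a continuous rim of cytoplasm?**
  Among light nuclei, a continuous (thick or thin) rim marks a neuron;
  otherwise the cell is an astrocyte, an endothelial cell — or a small
  neuron whose thin rim escaped notice, which is where the pitfall rules
  enter.
* **Q3 — how is heterochromatin distributed?** In the dark branch, many
  small granules forming a grid indicate microglia; a net of two to four
  rounded granules with one stand-out granule indicates an
  oligodendrocyte. In the neuron branch, an empty-looking nucleus with a
  prominent nucleolus and at most thin perinucleolar granules is a large
  neuron; thick perinucleolar clumps with a few variable net granules mark
  a small neuron. In the rimless light branch, a peripheral rim of
  heterochromatin with attached granules sends the cell to Q4, while
  central heterochromatin (thick perinucleolar clumps) or envelope folding
  re-opens the small-neuron hypothesis.
* **Q4 — how is euchromatin stained?** Homogeneous staining marks an
  astrocyte, watery staining an endothelial cell.

Every published branch is treated as a hard rule, so the classifier is a
total, deterministic function: reproducibility requires that the same
profile always yields the same label. Profiles that no primary rule
matches are routed through `disambiguate()` with the candidate pair of
the nearest branch (small neuron/astrocyte, microglia/oligodendrocyte,
astrocyte/endothelial — the three documented hard pairs), and residual
ties fall to a deterministic tie-break: prefer the candidate with more
accessory support (yellow inclusions for astrocytes, greenish inclusions
and neuropil threads for microglia, perinuclear halo or pinkish crescent
for oligodendrocytes, vessel molding for endothelial cells, envelope
folding for small neurons), then a fixed fallback order (astrocyte over
small neuron, oligodendrocyte over microglia, astrocyte over
endothelial). With `tiebreak = FALSE` the same fallback label is
returned but marked `flagged` with its candidate set, for interactive
review. Within the neuron branch, residual profiles split on euchromatin
texture alone (an empty-looking nucleus is the large-neuron hallmark);
this two-way call is this package's reading of the table of features, as
the published questions do not address degenerate neuron profiles.

Two further readings were genuinely open and are resolved as follows: an
ovoid dark nucleus goes to the round/ovoid branch (some microglia are
round or ovoid, so shape alone cannot exclude them); and a light rimless
profile whose rim may simply be indiscernible is decided through the
pitfall rules rather than forced to astrocyte/endothelial.

The six prototype profiles (`prototype_profiles()`) transcribe the modal
column of the thick-section feature table per type; the endothelial
prototype is assembled from the prose description, since the table has no
endothelial column. Classification recovers all six exactly and
unambiguously:

```{r}
sapply(prototype_profiles(), function(p) classify(p)$label$fine)
```

### Verifying totality

The decision-relevant profile space is finite. `enumerate_profiles()`
enumerates it under a documented convention: stain and texture jointly
within their valid strata, the canonical nucleolus count (0 when not
visible, 1 otherwise — the count never changes a decision), and accessory
flags as the empty set plus singletons (the full 64-subset power set
multiplies the space 64-fold without exercising new rules, since flags
only enter tie-breaks additively). The test suite classifies the entire
215,040-row core space with both the package engine and an independently
coded flat rule table and requires 100% agreement, plus a seeded random
sample of the flag-bearing extension.

## Reliability statistics

A `ratings_table` is a units × raters categorical matrix over the
five-way rating vocabulary (fine neuron labels collapse to "neuron"),
with missing entries allowed and optional rater-experience and test tags.

The **coincidence matrix** counts pairwise rater categorizations per
unit: every ordered pair of labels from two distinct raters of the same
cell contributes one count, so agreement on a neuron adds 2 to the
neuron–neuron diagonal and a neuron/astrocyte split adds 1 to each
symmetric off-diagonal cell. Units rated by fewer than two raters carry
no pairable value and are excluded (their number is logged). With
complete data the counts total N·m·(m−1).

**Krippendorff's alpha** is 1 − D_o/D_e with the nominal difference
function (cell types are unordered). The package keeps two scales side by
side: the raw permutation counts above, which are what a printed
coincidence matrix shows and what `disagreement_ranking()` sorts, and the
canonical coincidences in which each unit's pairs are weighted by
1/(m_u−1) so that every pairable *value* carries equal weight. Alpha is
computed from the canonical scale with n = number of pairable values:
this is the standard estimator, remains correct when raters are missing
on some units (as in a two-test design where one rater skips the second
test), and coincides with the raw-count ratio up to O(1/n) when every
unit has the same number of raters. D_e = Σ_{c≠k} n_c n_k / (n(n−1)) is
the disagreement expected if labels were assigned at chance with the
observed category totals; alpha is exactly 1 iff no off-diagonal mass
exists, near 0 for unit-independent random rating, and undefined (NA,
with a reason) when all ratings fall in one category.

**Percent agreement** is averaged over unordered rater pairs (share of
co-rated units with equal labels), with its SEM taken across rater pairs
— the only population a pairwise mean supports. **Disagreement rankings**
report o_ck + o_kc per unordered pair by default; `half_counts = TRUE`
gives the once-per-disagreement convention some reports quote.

## The synthetic rating experiment

`profile_generator_config()` defines per-type, per-feature categorical
distributions. Defaults place 0.8 of the mass on the modal table value
and spread the rest over documented variants; the three variant rates
with the largest downstream effect are exposed directly: the probability
a microglial nucleus is round or ovoid (0.35), that an oligodendrocyte
nucleus is lightly stained (0.03 monkey, 0.10 human — "light"
oligodendrocytes are a described human feature), and that a small
neuron's thin rim is not discernible (0.15). These are settings a
microscopist would recognize as realistic for thick Nissl material; they
are configuration, not constants. Features are drawn independently and
then repaired to satisfy the cross-field invariants (texture follows the
stain stratum). `prototype_mode = TRUE` collapses every distribution to
its mode, so generation reproduces the six prototypes exactly — the
generator's regression anchor.

A `rater_model` mis-sees each feature independently with probability θ,
substituting a uniform draw from that value's *confusable set*
(`default_confusable_map()`): dark↔light staining, a thin rim missed, a
watery texture read as homogeneous, a stand-out net granule read as a
grid, and so on. Two perceptual asymmetries are built into the default
map: omission is easier than hallucination (an absent rim is at most
mistaken for a partial crescent, never for a full rim), and the
calibrated default panel down-weights flips of the overall
staining-intensity judgment (weight 0.3) — dark-vs-light is a coarse
gestalt call, and letting it flip at the full per-feature rate would make
whole-branch switches (e.g. neuron→oligodendrocyte) dominate the
disagreement structure, which is not what rating panels report.
Perturbed profiles are invariant-repaired, so every simulated observation
is valid; θ = 0 reproduces ground truth exactly.

`simulate_ratings()` reproduces the two-test structure: test 1 with 236
cells rated by all eight raters (three experienced, θ = 0.04; five
inexperienced, θ = 0.10), test 2 with 114 cells rated by seven (one
inexperienced rater unavailable). The cell-type composition of the real
test sets was never published; the default is uniform over the five
rating categories with neurons split evenly between large and small,
realized by largest-remainder apportionment, and is configurable. One
master seed expands deterministically into per-stage, per-rater child
seeds, so (config, design, seed) fully determine the ratings table.

The default θ values are a calibration, not a reproduction: they were
chosen once so that the simulated aggregate alpha falls in the 0.7–0.95
band that such panels report, with experienced raters higher than
inexperienced ones. Under this calibration the simulated disagreements
concentrate on the four anticipated confusions — astrocyte–endothelial,
neuron–astrocyte, oligodendrocyte–microglia, astrocyte–oligodendrocyte —
rather than on implausible pairs such as neuron–microglia; the
acceptance tests check exactly this qualitative structure over 20 seeds,
never a specific published alpha.

```{r}
sim <- simulate_ratings(seed = 7)
reliability_report(sim$ratings)
```

### What the simulator does and does not emulate

It emulates categorical feature variability, independent per-rater
perception noise restricted to confusable values, and the two-test
missing-rater design. It does **not** emulate correlated section-level
staining noise (all raters viewing the same badly stained section err
together), rater learning between tests, pixel-level appearance, or the
unknown true composition of the original test sets. Passing tests
therefore show that the statistics and the rule engine behave correctly
and that the noise model reproduces the *structure* of observed
disagreement — not that real raters have θ = 0.04, and not the published
alpha values, whose raw ratings were never deposited and whose printed
coincidence matrix is incomplete.

## Numerical choices

* Alpha returns NA (never a number) when D_e = 0; units with one rating
  are excluded with a log line; the SEM of percent agreement is 0 when a
  single rater pair exists.
* Ranking ties are broken by the canonical category order
  (neuron, astrocyte, oligodendrocyte, microglia, endothelial).
* All CSV output is comma-separated UTF-8 with LF endings; an empty
  ratings cell is a missing value; accessory flags serialize as a
  `;`-joined string. JSON reports carry a schema version.
* Problem sizes in the test suite (215k-profile exhaustive sweep, 110
  random tables for the alpha oracle, 20 simulation seeds, a
  10,000 × 8 random table for the chance endpoint) were chosen as the
  smallest sizes at which the checked properties are statistically
  unambiguous.

## Known limitations

* The rule engine encodes the thick-section feature table; the semithin
  table differs in detail (e.g. microglial nucleolus visibility) and is
  reflected only in generator priors, not in the rules.
* Pericytes are rejected, not classified.
* The tie-break makes balanced profiles deterministic by fiat; flagged
  mode exists precisely because a human should review those cells.
* Rater errors are independent across features, raters and units — the
  simplest model consistent with the description of the noise sources; a
  shared section-level perturbation would require correlated draws that
  the current model does not implement.
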