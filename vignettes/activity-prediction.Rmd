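---
title: "Predicting cell-line growth inhibition from molecular descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cell-line growth inhibition from molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aapred)
```

## The problem

Large tumor cell-line screens report, for each tested compound and cell
line, a GI50: the molar concentration inhibiting cell growth by 50%.
Working on the `-log10` scale (pGI50), values effectively span ~4
(100 µM, inactive) to ~8 (10 nM, highly potent).  Screening is expensive
and most compounds are never tested, so a ligand-based model that maps a
chemical structure to a predicted pGI50 profile across the whole panel is
a practical triage tool.  `aapred` implements such a protocol: it needs
only molecular descriptors of the training compounds and their measured
activities, no structural biology and no target annotation.

## The model

Two scorers are combined.

**Similarity transfer (FP).**  A query descriptor vector is compared
against every training compound.  For each descriptor the query value
either falls inside the ±5% window around the training value or not;
the score is

$$S = \frac{\#\{i : |q_i - r_i| \le 0.05\,|r_i|\}}{\#\{i : \text{both present}\}} \in [0, 1].$$

The best-scoring training compound donates its *experimental* activity
row verbatim.  A compound that is itself in the training set gets
$S = 1$ and therefore reproduces its own measurements exactly.  The
window is relative to the training value, so the score is deliberately
asymmetric, and a training value of exactly 0 admits only an exact-zero
query value.  Descriptors missing on either side drop out of both the
numerator and the denominator.

**Activity templates (CL).**  Per cell line, training activities are
sorted into 42 bins: 40 bins of width 0.1 tiling $[4, 8]$, plus an
underflow (<4) and an overflow (>8) bin.  The boundary 8.0 belongs to the
last regular bin, since the regular range is stated as 4–8 and the
overflow as ">8".  Each (cell line, bin) template stores the
per-descriptor mean $\mu$ and population standard deviation $\sigma$ of
its member compounds.  A query is scored against every non-empty
template: per descriptor, with $z = (v - \mu)/\sigma$,

* mode `a`: the hard indicator $\mu - \sigma \le v \le \mu + \sigma$,
* mode `b`: the Gaussian kernel $e^{-z^2/2}$,
* mode `c`: a twice-as-wide Gaussian $e^{-z^2/8}$,

averaged over the selected descriptors.  The winning template's
representative value — the bin midpoint, or the assay clamps 4.0 / 8.0
for the edge bins — becomes the template prediction.

**Combination.**  The final value is the convex combination
$\mathrm{pGI50} = S \cdot \mathrm{pGI50}_{FP} + (1 - S) \cdot \mathrm{pGI50}_{CL}$,
falling back to the template value alone when the best match carries no
measurement for a cell line.  The combined value always lies between its
two parents.

## Parameters

* `N` (default 240): descriptors retained per cell line.  Descriptors
  are ranked by the mean, over non-empty templates, of the relative
  within-template dispersion $\sigma / (|\mu| + 10^{-9})$, ascending —
  a descriptor that is tight inside activity bins but varies between
  them is what makes a $\mu \pm \sigma$ profile discriminative.  Ties
  break by name so the ranking is deterministic.  `N` is clamped to the
  number of available descriptors.
* `Z` (default 50, percent): a descriptor column whose fraction of
  exactly-zero values among its non-missing entries exceeds `Z`% is
  dropped before any scoring.  Many count-type descriptors are zero for
  most molecules and carry no contrast.  The filter is idempotent and is
  applied globally (both modules see the same filtered set); the
  similarity module deliberately takes no further per-cell-line
  selection, because its score is defined over the full descriptor set in
  use.
* `G` (default `"a"`): the smoothing mode above.  `a` is the literal
  binary scoring; `b` and `c` are graded relaxations useful when bins are
  sparsely populated.
* `min_members` (default 1): templates with fewer members are treated as
  empty.  Sparse bins are the main source of large errors, so raising
  this trades coverage for reliability.

The default tuning grid crosses `N` ∈ {240, 360, 480, 600, 720, 800}
with the three modes at `Z = 50` — 18 runs, evaluated by the mean
absolute deviation |DTV(pGI50)| of template predictions on a held-back
validation sample, and aggregated per run, per cell line and per
subpanel (the subpanel mean is the unweighted mean of its cell-line
means).  The grid is a configuration default, not a constraint: `tune()`
accepts any data frame of combinations.

## Numerical choices

* **Bin assignment** uses `1 + floor((v - 4) * 10 + 1e-9)` with the
  `1e-9` nudge so values stored with representation error (4.3 as
  4.2999999999999998) land in their intended bin; exactly 8.0 maps to the
  last regular bin.
* **Sigma floor**: template standard deviations are floored at
  `1e-6 * max(|mu|, 1)`.  Single-member and constant templates would
  otherwise accept only exact equality in mode `a` and divide by zero in
  modes `b`/`c`.
* **Tie-breaks** are all deterministic: similarity ties prefer the
  training compound with more measured activities, then the smaller id;
  template-score ties prefer the larger member count, then the lower bin
  index; tuning ties prefer the lower run id.
* **Missing values**: `NA` is the only in-memory missing encoding;
  `NaN`/infinite inputs are coerced to `NA` on construction.  Files
  accept empty fields and `"NA"`, and emit empty fields.
* **Serialization** writes all doubles as `%.17g`, so a saved model
  reloads with bitwise-identical template statistics.

## The synthetic benchmark

Real screening corpora are large, partly proprietary in their descriptor
pipelines, and unavailable offline, so the package ships a generator
that emulates exactly the statistical structure the template module
assumes: compounds in the same activity bin share a latent descriptor
profile.

Latent bin centers sit at a fixed separation (default 4 descriptor-space
units) in random directions around a common baseline (coordinates near
5), compounds scatter around their center with independent per-descriptor
noise (default s.d. 0.4), activities are drawn uniformly inside the
compound's bin (edge bins draw from 3–4 and 8–9), a configurable share of
compounds is cloned with ≤1% multiplicative jitter to emulate
near-duplicate structures, and activity entries are knocked out at a
configurable missing rate.  Missingness is planted *before* cloning, so a
clone carries its parent's activity row — including its gaps — verbatim:
a duplicate is a copy of the whole record.

Two default choices matter and were fixed from the model's own geometry,
not from data: the descriptor noise (0.4) is large relative to the ±5%
similarity window at baseline magnitude (≈0.25), so two *distinct*
compounds essentially never tie at $S = 1$ over 40 descriptors, while
being small relative to the center separation, so bin recovery by the
template module stays easy.  Random center directions (rather than a
drift along one axis) keep coordinate magnitudes — and hence the relative
similarity window — comparable across bins.

What passing tests on this benchmark shows: the machinery (binning,
template statistics, scoring, combination, tuning, serialization) is
correct under the model's own assumptions.  What it does not show:
performance on real chemistry, where descriptors are correlated, bins do
not induce clean descriptor clusters, and activity distributions are
far from uniform.  The generator makes no attempt to emulate real
screening activity distributions or chemically valid structures.

Problem sizes used throughout the test-suite and the acceptance script —
up to ~200 training compounds, 40 descriptors, 6 cell lines in 3
subpanels, 300–500 queries — were chosen as the smallest sizes at which
the statistical checks (≥90% bin recovery, module comparisons) are
stable across seeds.

## Descriptor backends

The protocol is descriptor-agnostic; the exact descriptor set of the
original screening pipeline is not redistributable, so the engine is
pluggable.  The shipped `chemmine2d` backend computes ~20 2D
physicochemical descriptors (molecular weight, logP, TPSA, molar
refractivity, H-bond counts, element counts, ring counts) via ChemmineR
and OpenBabel; it performs no geometry optimization.  Any backend
registered with `register_backend()` can replace it, and precomputed
descriptor tables bypass backends entirely — this is also the
recommended route for descriptor sets with 3D terms.  Backend results
are cached by structure payload, so resubmitting a compound is a lookup.

```{r backend, eval = FALSE}
be <- new_descriptor_backend("mybackend", c("mw", "rings"),
                             function(rec) my_compute(rec$structure))
register_backend(be)
desc <- compute_descriptors(read_structures("library.sdf", "sdf"), "mybackend")
```

## A worked run

```{r worked}
spec <- synthetic_spec(n_compounds = 150, n_descriptors = 40,
                       duplicate_fraction = 0.1, missing_rate = 0.15,
                       seed = 42)
tr <- generate_training(spec)
model <- build_model(tr$desc, tr$act, cl_params(N = 40, Z = 50, G = "a"))
model

q <- generate_queries(spec, tr, 5)
head(predict_batch(q$desc, model), 6)
```

Internal validation and tuning:

```{r tuning}
vids <- validation_sample(rownames(tr$desc), fraction = 0.05, seed = 42)$ids
tuned <- tune(default_tuning_grid(), tr$desc, tr$act, vids)
tuned$best_overall
head(tuned$runs[order(tuned$runs$mean_dtv), ], 3)
```

## Known limitations

* The smoothing modes `b`/`c` and the representative value of a winning
  template are interpretations: the original protocol names the three
  modes and the binary scoring but defines neither the smooth variants
  nor the assigned value, and reference outputs are not available to
  calibrate against.  The choices here (Gaussian kernels of width 1σ/2σ;
  bin midpoints with edge clamps) are documented defaults, isolated in
  one place each.
* The similarity module transfers from the single best match; it has no
  notion of applicability domain, and a query far from all training
  compounds still receives a (low-S, template-dominated) prediction
  rather than an abstention.
* Per-cell-line errors degrade sharply for cell lines with little
  training data; `min_members` and the exclusion list are the available
  mitigations.
* Diagonal (per-descriptor) template statistics cannot represent
  correlated descriptor structure; a covariance-aware template is out of
  scope.
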