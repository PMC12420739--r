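---
title: "Benchmarking pathway analysis with simulated pathway knockouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking pathway analysis with simulated pathway knockouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why simulate knockouts?

Pathway analysis of metabolomics data is usually evaluated on real datasets
where the true disruption is unknown, so a method's false negatives are
invisible. `pabench` takes the opposite route: it *constructs* the ground
truth. Starting from a constraint-based metabolic model with pathway
(subsystem) annotations, it knocks out one entire pathway at a time, simulates
the exometabolomic profile that the knockout would produce, hands that profile
to the pathway-analysis methods, and checks whether they point back at the
pathway that was actually removed. Because the disruption is known by
construction, every scenario can be scored as a true positive (TP), false
negative (FN), or — for over-representation analysis — "not run".

## The simulation model

A metabolic model is a stoichiometric matrix `S` plus flux bounds: the
steady-state flux polytope is `{v : S v = 0, lb <= v <= ub}`. The observable
quantity is the *exometabolome*: the fluxes of exchange reactions, which move
single metabolites in and out of the extracellular medium. Exchange reactions
are normalised on load so that positive flux always means export.

The pipeline works in five stages:

1. **Preprocessing.** Blocked reactions — those whose flux-variability
   analysis (FVA) minimum and maximum are both numerically zero — are removed,
   along with metabolites they orphan; a pathway whose reactions are all
   blocked is recorded as `blocked` and excluded from the benchmark.
   Metabolite pathway sets are then read off the remaining network (each
   reaction's substrates and products belong to its pathway) and the
   *exchangeable background* is the set of metabolites with an exchange
   reaction.

2. **Knockout and feasibility.** A pathway knockout sets the bounds of all its
   reactions to `[0, 0]`. If the knocked-out model cannot reach at least 10%
   of the wild-type maximal biomass flux (`floor_fraction = 0.1`), the
   scenario is classified `infeasible` and produces no profile — a real cell
   with that knockout would not grow, so there is no steady-state
   exometabolome to measure.

3. **Flux sampling.** Both the wild type and each functional knockout are
   characterised by approximately uniform samples from their flux polytopes
   (constrained to the biomass floor), drawn with an artificially-centred
   hit-and-run sampler: warm-up points are the FVA optima, each step moves
   from the current point along the direction to a random warm-up/pool point
   relative to the running centre, and points are periodically re-projected
   onto the null space of `S` to stop numerical drift. Defaults are
   `n_samples = 5000` per state with `thinning = 100`; the examples and tests
   in this package use smaller chains because the bundled model is tiny and
   mixes quickly.

4. **z-score profiles.** For each exchangeable metabolite the knockout and
   wild-type exchange-flux samples are compared:
   `z = (mean_KO - mean_WT) / sqrt((sd_WT^2 + sd_KO^2) / 2)`, clipped to
   `±50`. Positive z means more of the metabolite in the medium. When both
   states have zero variance the z is 0 for equal means and a clipped `±50`
   otherwise. Duplicate exchange reactions for one metabolite are merged by
   summation.

5. **Enrichment and scoring.** Each profile is analysed by:
   * **ORA** — metabolite p-values from the normal survival function of the
     signed z (`p = 1 - Phi(z)`), thresholded at `alpha_da = 0.05` with no
     multiple-testing correction; a pathway is testable only with at least
     `min_hits = 3` differential metabolites, and testable pathways get a
     right-tailed Fisher's exact p-value against the exchangeable background.
   * **Pre-ranked GSEA** — the weighted Kolmogorov–Smirnov enrichment score
     over the list ranked by signed z (`gsea_signed`) or |z|
     (`gsea_absolute`), with `n_perm = 1000` metabolite-label permutations.

   The knocked-out pathway's result determines the scenario label: TP when
   testable with `p <= 0.05`, FN when testable but not significant. A
   non-testable target is `not_run` under ORA (the method refused to test) but
   FN under GSEA (GSEA always produces a ranking; failing to test the target
   means failing to detect it). Every other functional pathway contributes to
   the false-positive / true-negative counts. `TPR + FNR + not_run_rate = 1`
   by construction.

## What the toy generator emulates — and what it does not

`generate_toy_model()` builds a small model from fixed structural archetypes
stitched onto a common core (nutrient import → precursor pool → biomass), each
with an exactly known expected outcome:

| archetype         | design                                                 | expected outcome        |
|-------------------|--------------------------------------------------------|-------------------------|
| `essential`       | sole producer of a biomass precursor                   | infeasible knockout     |
| `unique_exporter` | forced-flux branch exporting a unique metabolite       | TP (ORA, GSEA-absolute) |
| `internal_only`   | futile cycle touching no exchangeable metabolite       | FN                      |
| `redundant_pair`  | two pathways sharing one route; either alone suffices  | weak/no signal          |
| `blocked`         | dead-end chain that can carry no steady-state flux     | pruned                  |

Randomness only permutes decoy bounds and ids; the archetype structure — and
therefore the ground truth — is deterministic. The generator emulates the
*mechanisms* that drive pathway-analysis behaviour (exchangeability,
uniqueness, redundancy, essentiality), not the statistical texture of a
genome-scale network: it has a handful of pathways, no cofactor coupling
beyond a small side-compound set, and flux ranges chosen so that designed
z-scores sit clearly on the intended side of the decision thresholds.

## Numerical choices

* **Linear programming.** FBA/FVA solve small dense LPs with a two-phase
  simplex using Bland's rule, written for this package (no LP solver
  dependency). Equality rows that are linearly dependent (conserved moieties)
  are removed by pivoted QR before solving, and solutions are verified against
  `|S v| <= 1e-6`.
* **Blocked-reaction tolerance** is `1e-9` on the FVA extrema.
* **Permutation p-values** use a +1 pseudo-count and are one-sided within the
  observed enrichment-score sign, normalised by the number of same-sign
  permutations — this keeps the null rejection rate at its nominal level in
  both directions (validated in the test suite: ~5% of null pathways reach
  `p <= 0.05`).
* **Per-scenario seeds** are derived as an order-independent hash of
  `(run seed, method, pathway id)`, so scenarios are reproducible
  independently of execution order.

## A complete run

```{r}
library(pabench)

toy <- generate_toy_model(toy_model_spec())
toy$model

config <- run_config(toy$model, n_samples = 500, thinning = 20, seed = 42)
run <- run_benchmark(config)
run$summary
```

The scenario ledger records why each pathway did or did not produce a profile:

```{r}
run$simulation$ledger
```

The unique-exporter knockout illustrates the designed signal: its substrates
accumulate in the medium (positive z) while its product disappears
(negative z):

```{r, fig.width = 6, fig.height = 4}
sets <- metabolite_pathway_sets(run$model)
own <- sets$metabolite[sets$pathway_id == "P02_unique_export"]
plot_zscore_profile(run$simulation$profiles, "P02_unique_export", highlight = own)
```

Rates per method, and the intrinsic pathway properties used to explain them:

```{r, fig.width = 6, fig.height = 4}
library(ggplot2)
autoplot(run$evaluations)
run$properties
```

Note the mechanism the benchmark is built to expose: the internal-only
pathway (exchangeable ratio 0) can never be recovered from an exometabolomic
profile, and GSEA on signed z-scores loses the unique exporter because its
members carry conflicting signs — the absolute-value ranking recovers it.

## Design decisions and limitations

* ORA's survival-function conversion is applied to the **signed** z by
  default, so only medium-increased metabolites become differential;
  `da_stat = "abs"` switches to two-sided calling. The default follows the
  procedure as conventionally written, and the switch exists because either
  reading is defensible.
* A non-testable target is `not_run` for ORA but **FN** for GSEA, as
  described above.
* Graph statistics (clustering coefficient, degree, neighbourhood
  connectivity) are computed on the **unweighted** overlap topology; shared
  metabolite counts are kept as edge weights for export only.
* Pathway size counts metabolites **including** side compounds
  (`size_include_side = FALSE` to change); the overlap graph and the
  exchangeable ratio always exclude them.
* The sampler is a single-chain ACHR without convergence diagnostics; for
  genome-scale models you should increase `n_samples`/`thinning` and check
  stability across seeds. The package's own problem sizes (toy fixture,
  hundreds to a few thousand samples) are chosen so the full pipeline runs in
  minutes on one CPU.
* p-values are reported uncorrected across pathways, matching the benchmark's
  design (a single knocked-out target per scenario); apply your own correction
  if you use the per-pathway tables for discovery.
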