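---
title: "Methods: the criss-cross ploidy signature and its phylostratigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the criss-cross ploidy signature and its phylostratigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyStrata)
```

## The design and its assumptions

The package analyses a two-species, two-tissue expression design in which
somatic ploidy inverts between species: species A (primate-like) has a
polyploid heart and diploid liver, species B (rodent-like) the reverse.
Two reciprocal contrasts are formed per gene, each oriented polyploid
minus diploid within a tissue pair:

* heart: species A (polyploid) minus species B (diploid);
* liver: species B (polyploid) minus species A (diploid).

A per-gene *tissue* effect is common to both groups inside each contrast
and cancels exactly. A per-gene *species* effect enters the two contrasts
with opposite signs, so a gene driven by species alone is discordant and
is excluded by the concordance rule ("up" requires both contrasts at or
above `log2(fold)`). This is the entire logic of the criss-cross filter:
it assumes (i) the ploidy table really does invert between the species,
which the `ploidy_expr` validator enforces structurally, and (ii) ploidy
effects of interest are consistent in sign across the two tissues. Genes
whose ploidy response is tissue-specific are invisible to the filter by
design.

The assumed observation model is additive on the log2 scale: gene
baseline + tissue effect + species effect + block batch offset + ploidy
effect (polyploid samples only) + Gaussian noise. Counts-level properties
(overdispersion, length bias) are out of scope; inputs are taken as
already-quantified expression on a linear scale.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `folds` | 2.0, 1.3 | linear fold | concordance thresholds; inclusive at the boundary |
| `pca_sd` | 2 | SD of standardized scores | ploidy-component gene selection (z-score rule) |
| `pseudocount` | 1 | linear expression | added before log2; handles zeros |
| `hub_degree` | 10 | degree | hub definition within a component |
| `r_min` | 0.5 | correlation | minimum loading/indicator correlation for a factor assignment |
| `n_reps` | 3 | samples/cell | replication per design cell in the generator |
| `noise_sd` | 0.3 | log2 | residual noise of the generator |
| `batch_sd` | 0.3 | log2 | per-gene, per-(species, tissue)-block offsets |
| `tissue_effect` | 1.0 | log2 (SD) | per-gene tissue effect scale |
| `species_effect` | 0.7 | log2 (SD) | per-gene species effect scale |
| `effect_range` | 1.0–2.5 | log2 | planted absolute ploidy effects |

The generator defaults state a world mirroring the magnitudes of the
motivating study: 14,093 ortholog-matched, stratum-annotated genes; 584
planted up-regulated and 711 down-regulated genes; background bivalency
3024/14093 (21.5%) rising to 0.457 among planted up genes; and
stratum-dependent sign probabilities of 0.8 for the unicellular strata
1–3, 0.5 for the transitional strata 4–5, and 0.2 for the multicellular
strata 6–16. The neutral 0.5 for strata 4–5 is deliberate: the two
analysis routes of the original report disagree on the direction of these
transitional strata (the contrast route sees no clear difference, the PCA
route sees up-regulation), so the generator plants no direction there and
exposes the probabilities as a parameter instead of guessing intent.

Noise and effect scales are not stated by the source analysis; they were
chosen once as values a transcriptomics practitioner would call ordinary
for bulk log2 data (replicate noise ≈ 0.3, tissue ≫ species ≫ ploidy
variance, matching the reported variance ordering of the four principal
components) and are not revisited.

## What the generator emulates, and what it does not

Planted structure gives every downstream stage a ground truth: planted
up/down memberships with known per-gene effects, stratum-dependent
direction structure, a bivalency rate lifted among planted-up genes, and
an interaction graph whose edge probability is boosted for planted-up
genes. Consequently a green test establishes that the pipeline recovers
*this additive, sign-consistent, Gaussian world* — it does not establish
robustness to count noise, unbalanced designs, annotation errors,
tissue-specific ploidy responses, or non-random interaction topology
(the graph is Erdős–Rényi, not scale-free). Two deliberate frictions are
kept: per-gene species effects attenuate recall of the fold filter (a
planted gene with `|species effect| > effect − log2(fold)` is missed in
one contrast), and quantile normalization redistributes values across
columns; both mimic conditions of the real analysis.

Tissue and species effects enter the simulated log2 values as symmetric
deviations (±half the drawn effect), so the drawn value is exactly the
condition contrast while the gene baseline keeps its meaning of a
condition average; this also keeps the design-factor directions of the
sample space orthogonal to the common-variation direction, which is what
makes the four-component PCA solution identifiable.

## Numerical choices

* **Binomial and hypergeometric tails** are exact and computed through
  `pbinom(..., log.p = TRUE)` / `phyper`; overlap results always carry
  `log10_p` alongside `p`, so claims at the 1e-16 scale (and far below
  double underflow) survive serialization. Tests verify the log-space
  route against an independent log-sum-exp summation over log pmf terms
  to six significant digits in log10(p) up to n = 1000, and against
  `choose()`-based enumeration for n ≤ 20.
* **Quantile normalization** maps each column onto the row-wise mean of
  the group's order statistics; exact ties receive the mean of the
  normalized values at their tied ranks. The transform is idempotent to
  1e-12. Normalization groups are the tissue pairs (all heart samples of
  both species together, likewise liver), matching the pairwise
  cross-species comparisons. Ortholog matching happens first,
  normalization second; the source description is ambiguous on this
  ordering, and matching-first keeps the normalized columns defined on a
  single shared gene universe.
* **The pseudocount** (log2(x + 1)) protects zeros but attenuates fold
  changes of weakly expressed genes; the exactness tests of the noiseless
  world therefore run with pseudocount 0, and the attenuation is a known
  property of the default pipeline, not a bug.
* **Boundary rule**: concordance and score selections include values
  exactly at the threshold (≥ / ≤) for determinism.
* **Component assignment** measures the correlation between a component's
  sample loadings and a centered factor indicator as the cosine of the
  loading direction itself. Centering the loadings too would let the
  dominant common-variation component — near-constant loadings plus a
  slight factor tilt — correlate almost perfectly with any factor; using
  the uncentered direction keeps it near zero and the assignment
  identifiable. Factors are assigned greedily in the order tissue,
  species, ploidy (descending expected variance), without reuse; the
  highest-variance leftover component is labelled batch; assignments
  below |r| = 0.5 stay unassigned. The ploidy component is sign-oriented
  so polyploid samples load positively.
* **Moderated testing** is a documented simplification, not a replica of
  precision-weighted linear modelling: per-gene pooled two-sample
  variances are shrunk towards a prior fitted by digamma/trigamma moment
  matching on log variances, and the posterior-variance t statistic uses
  d + d0 degrees of freedom. A simulation test holds its type-I error at
  the nominal 5% within [3%, 7%]. Fold-change concordance remains the
  primary selection; moderated p-values are an optional filter, because
  the published selections are described by fold contrasts.
* **Benjamini–Hochberg** q-values are the package's own step-up
  implementation (`adjust_fdr`), verified against `stats::p.adjust`.
  Within the stratum tests, correction is applied across the 16 strata
  within each list; in the ontology module, terms with zero list overlap
  are excluded from both the table and the multiplicity count.

## Resolved design questions

* *Fig-1-style asterisks*: each list is tested against the background
  stratum fractions (exact binomial, one-sided in the direction of
  deviation); an up-vs-down two-proportion variant is available via
  `compare = "updown"`. The binomial choice keeps the stratum tests
  consistent with the bivalency overlap test.
* *Per-contrast thresholds*: the fold rule applies to each reciprocal
  contrast separately (both must pass), not to their average.
* *PCA input*: normalized log2 values by default; `normalize = FALSE`
  exposes the raw-scale route, since the source description of a "raw
  data matrix" conflicts with its own normalization account.
* *Driver comparisons*: the under-specified "p < 0.02, binomial"
  comparison is implemented as a one-sided exact binomial of one group's
  bivalent count against the comparison group's fraction, with a
  two-sample Fisher variant under `method = "fisher"`.
* *Published percentage discrepancies*: fractions are always computed
  from counts, never transcribed — 222/711 is reported as 31.2% (not the
  sometimes-printed 31.6%), 3024/14093 as 21.5% (not 21.3%), and 63/222
  as 28% (not 24%).
* *Component floor*: an isolated node is not a connected component for
  retention purposes (floor 2); hubs are defined by a configurable
  absolute degree threshold, a documented stand-in for the clustering
  pipeline of the original network server, which is out of scope.

## Known limitations

* Only the Gaussian-on-log noise family is generated; count-level
  simulation is an extension point.
* Two species and two tissues are structural assumptions of the
  validators, not parameters.
* The ontology module consumes plain edge/assignment tables; OBO parsing
  and topology-aware enrichment algorithms are non-goals.
* Recall of the fold filter under the default species-noise world is
  substantially below 1 (by design); selection completeness claims hold
  only in the noiseless configuration.
* Hub counts depend on the degree threshold and are not comparable to
  clustering-derived hub definitions.
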