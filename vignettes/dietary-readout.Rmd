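---
title: "Reference-based dietary readout from untargeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-based dietary readout from untargeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodreadout)
```

## The problem

Self-reported dietary assessment (food diaries, frequency questionnaires,
24-hour recalls) is burdensome and biased. Untargeted LC-MS/MS metabolomics
of stool, urine or plasma offers an objective alternative: foods leave
thousands of molecular ion traces in biological samples, most of them
structurally unannotated ("nutritional dark matter"). `foodreadout`
implements a reference-based strategy that does not require annotation:

1. **Learn** food-category-specific MS/MS ion biomarkers from a reference
   dataset of single foods profiled by LC-MS/MS, organized in a
   hierarchical food ontology (e.g. plant → fruit → blueberry).
2. **Match** MS/MS spectra from unknown biological samples against the
   biomarker library by spectral similarity.
3. **Score** each sample per food category as the mean MS1 intensity of
   that category's matched biomarkers — a relative, ion-resolved dietary
   readout.
4. **Analyze** the score matrix with PCA, PERMANOVA and Pearson
   correlations against sample metadata.

Scores are *relative* (ion intensities), never absolute intake in grams or
calories: ionization efficiency, detector response and matrix effects
differ per compound, so only within-category comparisons across samples,
and per-level proportions, are meaningful.

## Learning biomarkers: OPLS-DA with VIP and fold-change co-filters

For every non-root ontology category a one-vs-rest contrast is formed:
positives are the reference samples assigned under the category's subtree,
negatives all other reference samples (`scope = "global"`; a `"siblings"`
scope restricted to the same parent is available because discriminating
"at each level" can be read either way). Internal nodes use the union of
their subtree leaves' samples, so a branch ("fleshy fruit") and its leaves
("blueberry") can each carry biomarkers. Contrasts with fewer than
`min_group_size = 3` samples on either side are dropped — a discriminant
model needs at least two samples per class plus one for variance.

Each contrast is fitted with orthogonal projections to latent structures
discriminant analysis (OPLS-DA) for a single ±1 response:

* the PLS weight is `w ∝ Xᵀy`, normalized to unit length;
* each orthogonal round removes from the loading `p` its projection on
  `w`, giving `w_o`, and deflates `X` by the orthogonal component
  `t_o p_oᵀ`;
* one final predictive component `(w, t, p, q)` is fitted on the deflated
  matrix.

With `n_ortho = 0` the model is exactly a one-component PLS (the test
suite verifies this against an independently implemented NIPALS PLS).
Orthogonal scores are uncorrelated with the class by construction; the
matrix is re-centered inside the fit so this holds for unbalanced classes
too. We default to `n_ortho = 1`, the minimal OPLS model; the component
count is configurable and early-stops when the data are perfectly
predictive. Component signs follow a fixed convention (largest-magnitude
weight positive), making results deterministic.

Variable importance in projection is computed on the predictive
component(s) only,

$$\mathrm{VIP}_j = \sqrt{p \; \frac{\sum_a \mathrm{SSY}_a (w_{aj}/\lVert w_a\rVert)^2}{\sum_a \mathrm{SSY}_a}},
\qquad \mathrm{SSY}_a = q_a^2\, t_a^\top t_a ,$$

so the squared VIPs average to 1 and the selection threshold acts on the
between-class axis, not on orthogonal (within-class) variation.

A feature becomes a biomarker for a category when **both** filters pass:
VIP strictly greater than 4.0 and fold-change of at least 6 in the
enrichment direction. The fold-change is the ratio of mean TIC-normalized
(but *unlogged*) intensities between target and rest — a "6-fold
enrichment" is a statement about abundance ratios, so the log transform
used for the discriminant fit is deliberately not applied here. A
pseudo-count equal to half the smallest nonzero TIC-normalized intensity
keeps ratios finite when a feature is absent from the rest; being
scale-aware, it does not depend on the intensity units of the instrument.
A feature qualifying for several categories is retained in each — levels
of the hierarchy overlap by design, and no exclusivity pruning is done.

### Preprocessing defaults

Upstream feature-finding pipelines differ, so every stage is explicit and
configurable via `preprocess_spec()`. The defaults are per-sample TIC
(total ion current) normalization — peak areas are compositional because
injected amount varies —, `log10(x + 1)` to stabilize the orders of
magnitude spanned by LC-MS intensities, and per-feature centering with
unit-variance scaling so the discriminant model is not dominated by
high-abundance ions. Zero-variance features get scale 1 and are flagged.
The exact preprocessing and thresholds used are recorded in the library's
`parameters` and audited when a library is reloaded.

## Spectral matching

Query spectra are compared to library reference spectra by the cosine
score on square-root-transformed intensities (damping base-peak
dominance, as in standard library search): admissible fragment pairs
differ by at most `fragment_tol` (default 0.02 Da), a one-to-one pairing
maximizing the summed weight is chosen, and the total is normalized by the
two spectra's intensity norms, giving a score in [0, 1]. The pairing is
solved exactly by branch and bound for spectra of up to 12 peaks and
greedily (descending pair weight, ties to the smaller m/z residual) above
that; the test suite measures the greedy gap against exhaustive
enumeration.

The **modified cosine** additionally admits pairs offset by the precursor
mass difference, so a parent compound still matches its host- or
microbially-modified derivatives (methylation, hydroxylation,
glucuronidation, deamination) whose fragments shift with the modified
moiety. With equal precursors it reduces exactly to the plain cosine.

`search_library()` defaults — precursor tolerance 0.01 Da (cosine mode),
analog window 200 Da (modified-cosine mode), minimum 4 matched peaks and
score ≥ 0.7 — are conventional library-search settings; all are recorded
per run since no single set suits every instrument.

## Dietary scores

Each matched biomarker is first linked to one MS1 feature of the query
table (explicit `FEATURE_ID` on the spectrum wins; otherwise nearest
feature within 0.01 Da and 30 s). The dietary score of sample *s* for
category *c* is the mean intensity of *c*'s biomarkers in *s*. Two
averaging modes exist because "mean of all biomarker intensities" is
ambiguous for undetected biomarkers:

* `fill = "zeros"` (default): undetected biomarkers contribute 0 and the
  mean runs over **all** biomarkers of the category. This rewards breadth
  of detection and makes scores shrink when a category's biomarkers are
  mostly absent.
* `fill = "detected_only"`: mean over matched biomarkers only; useful for
  sparse matrices but more volatile.

`normalize_scores()` converts the raw scores of one ontology level to
per-sample proportions (rows sum to 1, all-zero rows stay 0). The API
intentionally refuses to mix levels: proportions across mixed granularity
are not interpretable. Per-sample TIC normalization of the query table
before scoring is available (`tic_normalize`) and is advisable for fecal
and urine matrices where sample loading varies; it is off by default so
that raw scores remain exactly linear in measured intensity (this keeps
the scoring stage's behavior independent of the biospecimen, which the
package cannot know).

## Downstream statistics

* **PCA** via singular-value decomposition of the centered score matrix,
  with a deterministic sign convention; explained-variance ratios are
  fractions of total variance.
* **PERMANOVA** (one factor): with pairwise distances `d_ij`,
  `SS_total = (1/n) Σ_{i<j} d_ij²`,
  `SS_within = Σ_g (1/n_g) Σ_{i<j∈g} d_ij²`, pseudo-F =
  `(SS_between/(g−1)) / (SS_within/(n−g))`, `R² = SS_between/SS_total`,
  and `p = (1 + #{F_perm ≥ F_obs}) / (1 + n_permutations)` under seeded
  label permutations. When the requested permutation count reaches the
  number of distinct label arrangements the test switches to exact
  enumeration. Euclidean distance on per-level proportion scores is the
  default; Bray–Curtis (via `vegan::vegdist`) is offered because scores
  are composition-like. Repeated-measures or two-factor designs are out
  of scope: run one factor at a time and interpret accordingly.
* **Correlations**: per (category, variable) Pearson r with the two-sided
  t-test on n−2 degrees of freedom, pairwise-complete observations with
  per-pair n recorded, and Benjamini–Hochberg q-values over the whole
  grid (degenerate pairs are flagged and excluded from the adjustment).

## The synthetic data generator

Real reference food datasets are large and instrument-specific, so the
package ships a generator whose statistical shape mirrors what the
learning step needs to survive:

* a shared lognormal background intensity profile across categories
  (base intensities spanning orders of magnitude, `sdlog = 1`);
* planted category-specific features multiplied by `planted_fold`
  (default 10) in their home category, optionally also branch-level
  markers spanning several leaves;
* multiplicative lognormal noise (LC-MS intensity error is
  multiplicative, default CV 30%) and Bernoulli dropout (default 10%)
  emulating per-run detection failure;
* a reproducible random spectrum per feature (uniform fragment m/z,
  exponential intensities).

Mixtures are convex combinations of the component foods' mean profiles
plus noise, with spectra carried over but re-keyed to fresh feature ids,
and cohorts add a subject-level lognormal perturbation of each group's
category weights. Defaults: 8 leaf categories × 12 samples, 40 planted
features per category, 400 background features.

**What passing tests do and do not show.** The generator validates the
machinery — that planted enrichment is recovered (recall and precision
≥ 0.9 at VIP > 1.5, fold ≥ 6 under the default conditions), that mixture
scores track known fractions (r ≥ 0.95), and that diet groups separate —
under an idealized error model. It does *not* emulate adduct/multimer
networks, retention drift, chromatographic coelution, realistic
fragmentation chemistry, correlated backgrounds between related foods, or
microbial biotransformation of parent compounds. Performance on real data
therefore depends on reference coverage and instrument comparability in
ways these tests cannot certify.

## Numerical choices and degenerate inputs

* Fold-change pseudo-count: half the smallest nonzero TIC-normalized
  intensity (configurable).
* All-zero samples survive TIC normalization as zeros, with a warning.
* OPLS stops adding orthogonal components when the candidate weight norm
  falls below 1e-12 (perfectly predictive data) and errors when the
  predictive scores vanish.
* Greedy pairing ties break on the smaller m/z residual; VIP threshold is
  strict (`>`), fold threshold inclusive (`>=`), matching their usual
  phrasing ("VIP > 4.0", "≥ 6-fold").
* Exact PERMANOVA enumeration includes the observed arrangement, so
  `p ≥ 1/n_arrangements`.
* Validation problem sizes: 50 random discriminant fits, 200 random
  spectrum pairs against exhaustive enumeration, 10 generator seeds for
  recovery, 500 null simulations for PERMANOVA calibration, 25-sample
  mixture series, 20-sample cohorts. These sizes give stable estimates
  while keeping the whole suite fast.

## Worked example

```{r example, eval = FALSE}
library(foodreadout)

ref <- simulate_reference(synth_config(seed = 1))
lib <- learn_library(ref$table, ref$ontology, ref$spectra,
                     vip_threshold = 1.5, fold_threshold = 6)
lib

fractions <- rep(c(0, 0.25, 0.5, 0.75, 1), each = 5)
design <- cbind(cat_01 = fractions, cat_02 = 1 - fractions)
mix <- simulate_mixture(ref, design, noise_cv = 0.2, seed = 2)

matches <- search_library(mix$spectra, lib)
links <- link_matches_to_features(matches, mix$table, mix$spectra)
scores <- dietary_scores(mix$table, lib, matches, links)
cor(fractions, scores[, "cat_01"])
```

## Known limitations

* Relative readout only — no conversion to grams or calories.
* The reference library is only as good as the reference foods: foods
  absent from the reference cannot be read out, and shared chemistry
  between related foods limits leaf-level resolution (the hierarchy
  exists precisely to absorb this).
* One-factor PERMANOVA; longitudinal designs need external modeling.
* The analog (modified-cosine) mode broadens detection but can also match
  chemically unrelated compounds at the same precursor offset; inspect
  matched-peak counts and precursor deltas when using it.
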