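---
title: "Methods: adverse DDI networks and ATC-stratified enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adverse DDI networks and ATC-stratified enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sczddi)
```

## The analysis

`sczddi` characterizes adverse drug–drug interactions (DDIs) of a disease
drug cohort — schizophrenia antipsychotics in the motivating application —
through an undirected interaction network stratified by the WHO Anatomical
Therapeutic Chemical (ATC) classification.

An adverse DDI is an event in which one drug's effect is altered by
coadministration of another. Interaction records in curated databases are
directional and free-text; the model here deliberately discards both
direction and description semantics: a single undirected edge is formed
whenever either member of a pair declares the other as an adverse partner.
The resulting graph is simple (no self-loops, no multi-edges), and the
package asserts the handshake lemma after every construction.

Three statistical questions are asked of this network:

1. **Do cohort drugs interact more than others?** Node degree (number of
   adverse partners) is compared between drug sets with the Wilcoxon
   rank-sum test. The standard sets are the cohort, *other-N* drugs (ATC
   nervous-system code, cohort excluded), and *non-N* drugs (annotated, no
   N code); a one-vs-each comparison of the N group against the 13 other
   first-level groups is Bonferroni-corrected with family size equal to the
   number of groups present (14 when all are), a convention chosen to match
   the reference analysis this package reproduces.
2. **How does the cohort's interaction profile decompose?** Each
   cohort–partner edge is assigned to the partner drug's ATC classes at a
   chosen level (1 or 3 in standard runs). A partner with codes in *m*
   distinct classes contributes *m* classified links, so per-category counts
   sum to the classified total `N` — by design larger than the edge count
   when multi-class partners exist. Partners without codes are tallied as
   unclassified.
3. **Do two cohort subgroups differ per category?** For typical vs atypical
   antipsychotics, each category's table (*n*, *N*−*n*, *r*, *R*−*r*) is
   tested with a two-sided Fisher's exact test, Bonferroni-corrected over
   the emitted rows. Intra-cohort edges are excluded from this contrast by
   default because the subgroup denominators are defined over
   cohort–partner links; `include_intra = TRUE` enables an exploratory
   variant that classifies an intra-cohort edge by the partner cohort
   drug's own codes.

### Assumptions

* Interaction lists may be asymmetric or duplicated; merging to one
  undirected edge per unordered pair is a modeling convention, not a claim
  about pharmacology.
* Cohort membership is textual: keyword screening is plain case-insensitive
  substring matching with no word boundaries or stemming, so inflected
  keywords must be enumerated explicitly (the default list carries
  `schizophrenia`, `schizophrenic`, `schizotypal`, ...). Manual curation is
  modeled as declarative include/exclude override lists so a run is fully
  reproducible.
* Degrees are exchangeable within sets under the null of the rank-sum
  comparisons; no covariate adjustment is attempted.

## Statistical engines and numerical choices

**Fisher's exact test.** `fisher_exact_2x2()` computes the two-sided
p-value by the point-probability rule: the sum of hypergeometric masses of
all tables with the observed margins whose probability does not exceed the
observed table's. Ties at the boundary are accepted within relative
tolerance `1e-7` (masses whose floating-point values differ only by
rounding are treated as equal); the result is capped at 1. The test suite
checks the engine against an independent enumeration oracle for every table
with `N + R <= 60` and against `stats::fisher.test` on random larger
tables.

**Wilcoxon rank-sum.** `rank_sum_test()` uses the exact Mann–Whitney U null
distribution when both samples have at most 12 observations and the pooled
data are untied (`mode = "auto"`); otherwise a normal approximation with
midranks, tie-corrected variance and a 0.5 continuity correction. Forcing
`mode = "exact"` on tied data computes midrank U against the tie-free null
with a warning — useful for the degenerate identical-samples case, where
the two-sided p is 1 by symmetry. Two-sided p-values are twice the smaller
tail, capped at 1. Degree data are integer-valued with heavy ties, so the
tie-corrected normal path is the one exercised in realistic runs; the exact
path is validated against full permutation enumeration for
`n1 + n2 <= 10`.

**Sidedness.** All comparisons default to two-sided, the conservative
standard when the direction of an effect is part of the conclusion rather
than the hypothesis; one-sided alternatives are exposed as options.

**Bonferroni.** `bonferroni(p, m) = min(1, p * m)`. For the one-vs-each
degree analysis the family size is the number of groups (14), not the
number of tests (13) — the convention of the reference analysis — while
category enrichment uses the number of emitted rows at that level.

**Report formatting.** Percentages print to two decimals, rounding half up
from unrounded ratios; p-values are compared and stored unrounded and only
formatted on output.

## The synthetic generator

`generate_dataset()` emulates the structure of a large curated interaction
database without redistributing one:

* ~1087 interaction-involved drugs by default, of which a 28-drug cohort
  (18 typical / 10 atypical) carries antipsychotic `N05A*` codes and a
  disease keyword in its indication text;
* non-cohort drugs are annotated with first-level groups drawn from weights
  proportional to the observed sizes of the 14 ATC groups in such a
  database (8% carry a second code; 7.5% carry none);
* per-cohort-drug partner counts are Poisson with mean 948/28 ≈ 33.9 (a
  power-law option exists); partner identity is drawn within the selected
  category with heavy-tailed popularity, so a minority of drugs (enzyme
  inhibitors, QT-prolongers, ...) recur across the cohort;
* each cohort pair interacts independently with probability
  43/C(28,2) ≈ 0.114, and ~9940 background edges among non-cohort drugs
  (endpoint propensity heavy-tailed, boosted ×1.6 for N-annotated drugs)
  bring the full network to ≈10.9k edges, reproducing the higher
  connectivity of nervous-system drugs;
* the screening funnel is planted: 46 keyword hits of which 38 are
  indication hits — 28 interacting cohort drugs, 5 cohort-like drugs
  without interactions, and 5 decoys listed as exclusion overrides in the
  truth — mirroring a keyword → indication → manual-curation narrowing;
* **planted effects** multiply the selection odds of chosen categories for
  *typical* drugs only, leaving atypicals at baseline, so the 2×2 odds
  ratio is the natural recovery target and the truth is one parameter per
  category.

Randomness is consumed in fixed stage order from per-stage seeds derived
once from the configured seed, so datasets are byte-identical across runs
and robust to draw-count changes within a stage.

What the generator does *not* emulate: pharmacological text (descriptions
are template strings), correlated annotation (real multi-code drugs favor
related classes), degree–category interactions beyond the N boost, and
database quirks such as asymmetric or conflicting interaction declarations
beyond simple duplicates. Passing calibration tests on synthetic data
therefore validates the statistical machinery and plumbing, not the
biological fidelity of any particular database.

## Calibration experiments

Two properties are checked by simulation (also recomputed by
`scripts/acceptance.R`):

* **Null calibration.** With both subgroups drawing partner categories from
  the same distribution, the pooled fraction of categories with raw Fisher
  p < 0.05 is computed over 1000 generated datasets (10 typical + 10
  atypical cohort drugs, ~600 classified links per subgroup, uniform
  category weights). Uniform weights are used here because the property
  under test is the test's null behavior under identical selection
  distributions; skewed weights would mix in the well-known conservatism of
  exact tests at small expected counts. The observed rate is ≈0.036 —
  slightly conservative, as expected for a discrete exact test — within
  the 0.05 ± 0.02 acceptance band.
* **Power / recovery.** With a single category's selection odds multiplied
  by 6 for typical drugs at the same problem size, the planted category
  must be the top-ranked row with Bonferroni-adjusted p < 0.05; over 200
  seeded runs recovery is 100%.

These problem sizes keep the full simulation suite within a few minutes on
one CPU while leaving the binomial uncertainty of the estimated rates well
inside the acceptance bands.

## Design decisions on genuinely open points

* **Duplicate/asymmetric declarations** are merged to one undirected edge,
  concatenating both directions' descriptions in input order; validation
  reports (but does not drop) duplicates and dangling partners, and network
  construction drops both with a log message. A partial extract therefore
  never crashes the pipeline.
* **ATC codes from multiple sources** are unioned per drug; a drug
  contributes once per *distinct* class prefix even if several codes share
  it, preventing double-counting within a class.
* **The screening funnel's arithmetic** is not forced to close: overrides
  are explicit lists, and the audit trail tags every final member and every
  applied exclusion (`keyword+indication`, `manual-include`,
  `manual-exclude`).
* **Intra-cohort edges** count toward both endpoints' degrees; the cohort
  mean degree from partition counts is `(inter + 2*intra)/n`, an identity
  cross-checked against direct degree computation in the tests.

## Known limitations

* The packaged level-3 reference table is internally inconsistent: its
  percentage column divides both subgroups' counts by the typical total,
  and its reported Fisher p-values cannot be reproduced from its printed
  counts at the stated classified totals (637/251) under any standard
  two-sided convention — a grid search shows they are mutually consistent
  only with unexplained totals near (568, 270). The package treats the
  printed counts and stated totals as authoritative, recomputes p-values
  from them, and carries the reported values alongside for transparency;
  the corresponding acceptance check documents the discrepancy by failing.
* Interaction descriptions are stored and merged but never classified;
  severity grading and mechanism mining are out of scope.
* The rank-sum normal approximation is accurate to a few percent relative
  error for moderate p but, like all tail approximations, degrades for
  very small p; exact mode is size-limited by design.
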