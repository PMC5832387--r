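---
title: "Hierarchical anatomical coarse-graining for side-effect prediction"
author: "adrhier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical anatomical coarse-graining for side-effect prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrhier)
```

## The problem

Curated drug-label resources such as SIDER link on the order of a
thousand marketed drugs to thousands of distinct adverse-reaction terms.
Posing side-effect prediction directly on those labels is a multi-label
problem with more classes than training examples, and the label matrix
is extremely sparse — roughly 98% of drug–side-effect cells are zero.
Two consequences follow:

1. **Label degeneracy.** Many MedDRA preferred terms describe closely
   related clinical presentations of the same organ. Treating each as an
   independent class fragments the available signal.
2. **Mismeasured performance.** With so many true negatives, ranking
   metrics such as ROC AUC look excellent for classifiers that never
   usefully fire: a model can rank the few positives near the top of a
   label's score distribution while every score stays far below any
   practical decision threshold.

`adrhier` implements a response to both: side-effect labels are
*coarse-grained* through a curated three-level anatomical hierarchy
(side effect → organ → sub-system → system), and classifiers are scored
with a composite **Weighted Performance** metric,

$$\mathrm{WP} = \tfrac{1}{2}\left(F_2 + \mathrm{AUC}\right), \qquad
F_2 = \frac{5PR}{4P + R},$$

which demands both a good ranking *and* usable threshold behaviour. The
F2 score weights recall twice as heavily as precision, which is the
appropriate asymmetry when false negatives (missed adverse reactions)
are costlier than false positives.

Because any aggregation of labels makes the problem easier (coarser
labels are denser and more balanced), the value of the *anatomical*
grouping specifically is quantified against a size-matched
random-aggregation null: pseudo-categories drawn uniformly at random
with exactly the anatomical category-size multiset.

## Coarse-graining model

The anatomical schema is a flat curated table mapping each side-effect
term to exactly one organ, each organ to one sub-system, each
sub-system to one system — a tree. Terms too ambiguous for a single
organ live in miscellaneous bins (a global `MISC` plus per-system
`misc_*` classes) and are excluded before experiments
(`exclude_misc()`).

Aggregation is **logical OR**: a drug is positive for an organ if it has
at least one reported member side effect. The one-hot label encoding
records *presence* of an adverse reaction, and presence of any member
reaction is presence at the organ; no frequency weighting is attempted
(SIDER frequency annotations are parsed but unused). OR-aggregation
gives three useful invariants, all tested: monotonicity under adding
associations, nesting (organ-then-system equals direct system
aggregation), and non-increasing per-drug label counts as levels
coarsen.

## Classification pipeline

Features are real-valued molecular descriptors (any numeric drug ×
feature table; published analyses of this problem typically use a few
hundred 2D/3D physicochemical properties computed by proprietary
descriptor engines, which this package deliberately does not depend
on). The pipeline:

1. **Clean and standardize** — descriptors mix incommensurate units, so
   columns are centered and scaled to unit variance; columns with
   missing values or zero variance are dropped. Without scaling,
   large-magnitude descriptors (e.g. molecular weight) dominate the
   covariance and the leading components.
2. **PCA** to `pca_k` components (default 100, a standard choice for
   descriptor tables of this size). The rotation is fitted on training drugs only by default
   (`fit_ids`), because fitting on all drugs leaks test-set structure
   into the representation; `fit_ids = NULL` reproduces the
   fit-on-everything variant, and the provenance flag is recorded in
   every manifest.
3. **One-vs-rest classification** (binary relevance): one independent
   binary classifier per label. This is the only multi-label
   decomposition compatible with per-label metric reporting. Labels
   with fewer than two positives or two negatives in training cannot be
   fit or calibrated and are skipped with a recorded reason.
4. **Evaluation** on an 80:20 drug-level holdout, with 5-fold
   cross-validation available on the training side and LOOCV for small
   cohorts (held-out scores are pooled before computing ranking
   metrics, since per-fold AUC is undefined for a single item).

The classifier suite is the standard one for descriptor-based
prediction — L2-regularized logistic regression, RBF SVM, kNN, Gaussian
naive Bayes, random forest — plus a soft-voting ensemble that averages
member probabilities. Defaults (500 trees; k = 5; SVM C = 1 with
gamma = 1/(d·var(x)); ridge C = 1) are recorded in every manifest and
overridable. Ensemble
members should be chosen by training-side CV performance, never on test
data.

All fits are single-threaded and seeded per label, so a full experiment
is bit-reproducible from `(config, seed)`.

## Metrics and degenerate labels

- AUC uses the Mann–Whitney formulation with midrank ties; AUPR uses
  step-wise summation (precision at each recall change), not
  trapezoids.
- A per-label metric with a zero denominator, or a ranking metric on a
  single-class test label, is `NA`. Macro averages skip `NA`s and
  report how many labels were skipped; coercing to zero would
  systematically penalize sparse levels and bias the level-wise
  comparison. One deliberate exception: per-label F2 is computed in
  count form, $F_2 = 5TP/(5TP + 4FN + FP)$, which equals $5PR/(4P+R)$
  whenever both P and R are defined but remains defined (and zero) when
  nothing is predicted positive. Without this, Weighted Performance
  would be undefined exactly in the imbalanced regime the metric was
  designed to expose.
- Micro aggregation (pooled counts and pooled scores) is computed
  alongside macro in every experiment report; macro is the default for
  level-wise comparisons.
- The decision threshold (default 0.5) is an explicit, recorded
  parameter: F scores are *not* threshold-free, and the
  high-AUC/zero-F2 quadrant is realizable at 2% prevalence (this is a
  test in the suite).

## The synthetic data generator

Real SIDER-scale data plus proprietary descriptors cannot ship with a
package, so every stage is exercised on a generator that emulates the
relevant statistical structure. For drug $i$ and side effect $s$ with
organ $o(s)$:

$$P(y_{is} = 1) = \sigma\!\left(\mu + a_i + b_s +
\beta\,\langle x_i, w_{o(s)}\rangle\right),$$

with drug latents $x_i \sim N(0, I_d)$, organ weights
$w_o \sim N(0, I_d)/\sqrt{d}$, and offsets $a_i \sim N(0, \sigma_a^2)$,
$b_s \sim N(0, \sigma_b^2)$. Observed features are a fixed random
linear read-out of the latents plus Gaussian noise. Design notes:

- **Organ-coherent signal.** All side effects of an organ share one
  weight vector $w_o$. This is the minimal generative assumption under
  which anatomical aggregation can beat size-matched random
  aggregation — precisely the hypothesis the null control tests.
  Sub-system and system coherence arise automatically by nesting; no
  extra signal is injected at coarser levels.
- **Heavy tails** come from the Gaussian offsets on the logit scale
  (one parameter each for drugs and side effects) rather than explicit
  power-law fitting; this reproduces the qualitative skew of real
  degree distributions while keeping density calibration tractable.
- **Density calibration.** $\mu$ is found by bisection so that the
  *expected* density given all sampled parameters equals
  `target_density` (tolerance 1e-4, well inside the 0.002 the tests
  assert across targets 0.005–0.1).
- **Defaults** are the study conditions used throughout the tests and
  the acceptance script: 200 drugs × 400 side effects, a 61/30/12
  hierarchy with Dirichlet(1)-multinomial category sizes (uneven, every
  category non-empty, mirroring the real schema's range from ~6 to
  ~380 members per organ), density 0.02 (98% zeros), $d = 10$,
  387 features, noise sd 0.5, $\beta = 2$, $\sigma_a = \sigma_b = 1$.
  200×400 keeps a full multi-level experiment plus a 20-replicate
  control in the minutes range on one core while keeping per-label
  positives realistically scarce.

What the generator does **not** emulate: correlated side effects within
a drug beyond what the latent model induces, MedDRA's lexical
redundancy (LLT/PT synonymy), frequency annotations, chemically
structured descriptor correlations, and annotation biases of
label-derived data. Tests passing on synthetic data therefore establish
that the machinery is correct and that the method detects a planted
organ-coherent signal; they do not certify performance numbers on real
SIDER data.

## The random-aggregation null

`run_random_control()` holds the split, the PCA scores and all
classifier seeds fixed, and varies only the grouping: each replicate
draws a uniform random partition of the side effects with exactly the
anatomical size multiset (conservation is asserted every replicate).
The summary reports the replicate mean and sd of Weighted Performance
and $z = (\mathrm{WP}_{\mathrm{anat}} - \overline{\mathrm{WP}}_{\mathrm{rand}})/s_{\mathrm{rand}}$.
Reusing the split across replicates is deliberate: without it, split
noise would be confounded with the grouping effect the control is
meant to isolate. The full-run
default is 100 replicates; the test suite and acceptance script use 20,
which is ample for a z-score when the replicate sd is of order 0.01.

On the generator defaults, the planted-signal contrast behaves as the
design predicts — with $\beta = 0$ the anatomical grouping is
statistically indistinguishable from random ($|z| < 3$), and with
$\beta = 2$ it separates cleanly ($z > 3$) while Weighted Performance
rises monotonically (on multi-seed averages) from the side-effect level
through the system level. Those statements are computed, not assumed:
they are the heavyweight tests in the suite and the quantities the
acceptance script reports.

## Numerical and degenerate-input conventions

- Bisection for $\mu$ over $[-30, 30]$, at most 100 iterations;
  non-convergence is an error, not a warning.
- `pca_reduce` requires $k \le \min(n_{\mathrm{fit}} - 1, p)$; k = 0 is
  allowed only in `variance_explained`.
- Ties in kNN voting and SVM Platt scaling are made reproducible by
  per-label seeding; ranger runs with `num.threads = 1`.
- Empty schemas, all-MISC schemas, zero-record matrices, single-class
  labels, folds with no evaluable label, and sub-2-replicate controls
  all fail or flag loudly rather than returning silent zeros.
- Conflicting schema rows (one term, two organs) are errors by design:
  the schema declares single assignment, and silently keeping either
  row would change category sizes and hence the null control.

## A worked example

```{r example, eval = FALSE}
library(adrhier)

ds <- generate_dataset(synth_config(seed = 1))
ds

cfg <- experiment_config(
  synth = synth_config(seed = 1),
  levels = c("side_effect", "organ", "sub_system", "system"),
  classifiers = list(classifier_spec("random_forest")),
  n_random_reps = 20, seed = 1)
res <- run_experiment(cfg)
res
```

The same computation, stage by stage, is what
`scripts/acceptance.R` performs; see the README for the exact numbers
one seed produces.

## Known limitations

- Real-data performance depends on descriptor quality; the package
  ships no descriptor engine and takes any numeric feature table.
- No multilabel-stratified fold assignment (plain shuffled k-fold on
  drugs); with very rare labels some folds lose them, which the
  skipping machinery records. Iterative stratification would be a
  natural extension.
- The schema is a flat curated table; no MedDRA ontology reasoning and
  no automated (NLP or ontology-based) organ assignment.
- `meddra_freq` / indications files are parsed for completeness only;
  frequency-weighted aggregation is out of scope.
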