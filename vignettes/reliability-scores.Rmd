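---
title: "Generative AODE classification and reliability scores: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative AODE classification and reliability scores: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aodesrs)
```

## The model

`aodesrs` implements a generative classifier over continuous attributes in
the averaged one-dependence estimation (AODE) family. For each class, the
model learns a one-dimensional Gaussian mixture for every attribute,
$f(X_i = x_i \mid \text{class})$, and a two-dimensional Gaussian mixture for
every unordered attribute pair, $f(X_i, X_j \mid \text{class})$. Conditional
densities are derived from the pairwise joints, and the class likelihood of
an instance $x = (x_1, \dots, x_n)$ is estimated as

$$
L(\text{class} \mid x) \;\propto\; \sum_{j=1}^{n}
\Big[ f(X_j = x_j \mid \text{class})
\prod_{i \ne j} f(X_i = x_i \mid X_j = x_j, \text{class}) \Big].
$$

Each inner term is a one-dependence estimator: a product of conditionals
anchored on one attribute $j$. Summing over all anchors captures every
pairwise correlation without committing to a single dependence structure.
Posterior probabilities are prior-weighted likelihoods normalized across
classes; with two classes this is the familiar binary generative posterior,
and the implementation normalizes over however many classes are trained.

The **reliability score (SRS)** is computed from the same trained model:

$$
\mathrm{SRS}(x) = \log_{10} \max_{\text{class}} \;\sum_{j=1}^{n}
\Big[ f(x_j \mid \text{class}) \prod_{i \ne j} f(x_i \mid x_j, \text{class}) \Big].
$$

It measures how well the instance matches the *best-fitting* trained class
and ignores priors entirely. Posteriors are forced to sum to one, so an
instance resembling no trained class can still receive a confident-looking
posterior; the score exposes exactly those instances. Because its scale
depends on the attribute set and the trained densities, scores are
comparable only among instances scored under one trained model — result
files embed a model fingerprint, and the shift diagnostic refuses to compare
scores across fingerprints.

With one attribute the sum collapses to the marginal density and the score
is the maximum of the per-class log densities. The estimator is implemented
as the *sum* over anchors, not the mean as in classical AODE presentations.
The difference is a factor $n$ that cancels in the posterior normalization;
for the score it is a constant offset at fixed $n$, which matters only when
comparing instances with different numbers of *present* attributes — see
below.

### Missing values

Instances may have any pattern of missing attributes, and no imputation is
performed anywhere. Both the outer sum and the inner products run over the
present attributes only; with a single present attribute the product is
empty; with none, the instance abstains. This is the right behavior when
missingness is informative ("missing not at random"), where imputation is
unreliable by construction. The flip side: the score of a row with $k$
present attributes lives on a different scale than one with $k'$ present
attributes, so the missingness profile groups rows by their exact missing
set, and comparisons are most meaningful between groups of equal size
(the profiling workflow holds the number of removed attributes constant).

During training, each marginal is fitted on the present values of its
attribute within the class, and each pairwise joint on the rows where both
members are present (pairwise-complete). A class with fewer than
`min_samples` rows, or an attribute entirely missing within a class, is a
training error rather than a silent degradation.

## Fitting and its parameters

Component counts for every mixture are selected by BIC over
$k = 1, \dots,$ `max_components` (default 5), with EM fits delegated to
`mclust` (model "V" for marginals, "VVV" for joints). `mclust` initializes
EM from model-based hierarchical clustering, which is deterministic for a
given data vector — a stronger guarantee than seeded random restarts, and
the reason two trainings on the same table produce byte-identical model
files. The seed is still recorded in the model for provenance. When
`max_components = 1` the closed-form maximum-likelihood fit is used
directly.

Numerical safeguards, all tunable through `training_config()`:

* **Variance floor** (default $10^{-8} \times \text{range}^2$ per
  attribute): no component may collapse onto a repeated value.
* **Covariance ridge**: $10^{-6}$ is added to joint-fit diagonals and the
  smallest eigenvalue is lifted to the floor, keeping every 2×2 covariance
  positive definite.
* **Log-space evaluation**: all densities are computed as natural-log
  quantities combined by log-sum-exp and reported in $\log_{10}$; a value
  30 standard deviations into a tail is still finite. If every class
  underflows even in log space the record abstains rather than emitting
  NaN posteriors.
* **Conditionals from the joint's own marginal**: $f(x_i \mid x_j)$ divides
  the joint by the marginal *implied by the same joint mixture* (the mixture
  of its components' projections), not by the separately fitted 1-D
  marginal. This guarantees each conditional integrates to one, which the
  test suite verifies by quadrature.

Standardization (training mean 0, sd 1 per attribute, computed over present
values) is off by default; when enabled the parameters are stored in the
model and applied identically to application data. Priors default to
uniform and can be overridden at classification time; they never touch the
reliability score.

A practical note on tail evaluation: a density value several standard
deviations from a fitted mean is exquisitely sensitive to the fitted scale.
With $n$ training points the fitted sd carries sampling error
$\sigma/\sqrt{2n}$, which the log-density at $z$ standard deviations
amplifies by roughly $z^2/\sigma$. Point estimates of the score deep in the
valley between well-separated classes therefore fluctuate by a few tenths
of a $\log_{10}$ unit even at $n = 1000$ per class, while values near the
class means are stable to two decimals. Conclusions should rest on score
*comparisons* across many instances (as all three diagnostic workflows do),
not on a single tail value.

## The diagnostics

**Unknown-class detection.** Instances from a class absent from training
score systematically lower than instances of trained classes, even when the
unknown class is intermediate between two trained classes (no individual
attribute is extreme — only the joint configuration is unfamiliar).
`srs_roc_auc()` summarizes the separation; its trapezoid AUC is asserted
internally against the Mann-Whitney identity
$\mathrm{AUC} = 1 - U/(nm)$ on every call.

**Distribution-shift testing.** `srs_shift_test()` applies a two-sample test
(Welch's t by default, Mann-Whitney optionally) to the scores of two cohorts
scored under one model — the score acts as a one-dimensional projection of
"fit to the training distribution", so a systemic mismatch appears as a mean
shift. Both tests are two-sided; the direction (which cohort is lower) is
reported separately. The Mann-Whitney implementation counts 0.5 per tied
pair and computes the exact permutation p-value (full distribution of the
midrank sum, by dynamic programming over doubled midranks) whenever
$nm \le 200$, switching to the tie-corrected, continuity-corrected normal
approximation above that — exactness at the scale of small-sample
comparisons, speed for cohort-sized ones.

**Missingness profiling.** `missingness_profile()` groups rows by their
exact missing-attribute set and compares score distributions across groups,
plus a per-attribute absent-vs-present summary. Holding the number of
missing attributes fixed, rows missing class-informative attributes score
lower than rows missing uninformative ones, which supports filters on *what*
is missing rather than *how much*.

**Abstention.** `apply_abstention()` flags records below a score threshold.
There is deliberately no default threshold: an appropriate cutoff depends on
the application and the trained model, and should be set with domain
knowledge — for instance from the score distribution of held-out
training-like data. Rows with zero present attributes always abstain; the
behavior of the score at zero attributes is undefined by design (an error,
not a guessed value).

## The synthetic generators

The `gen_*` generators are first-class, seeded, pure functions of their
parameters; they exist so every workflow is testable end to end without
external data. What they emulate, and the defaults chosen where a value had
to be fixed:

* `gen_1d_two_class()`: two narrow Gaussian classes, $N(-1, 0.2^2)$ and
  $N(+1, 0.2^2)$, 1000 instances each — a minimal problem where the
  posterior sweeps monotonically from one class to the other while the
  score dips in the unsupported region between them.
* `gen_2d_classes()`: bivariate presets ("X-like" separated blobs, "Y-like"
  overlapping blobs, "Z-like" opposite ±0.9 correlations centered at the
  origin) exercising the qualitative contrasts between marginal and joint
  atypicality; all parameters overridable via `spec`.
* `gen_multiclass_unknown()`: a seed-morphology-like table — 7 attributes
  loading on one latent size factor (loadings 0.4–0.8, residual sd 0.3),
  three classes at factor centers −4, 0, +4 with class 1 componentwise
  intermediate; 70 instances per class. The single-factor construction
  compresses the traits onto one axis, so the factor-scale separation is
  set large enough that a held-out class is recoverable the way strongly
  separated real morphology varieties are (leave-one-class-out AUC above
  0.9 across seeds, including the intermediate class).
* `gen_cohort_shift()`: 22 correlated unit-variance attributes (random
  correlation matrix per seed), binary classes separated by +0.8 on the
  first 8 attributes, 800 rows per cohort. The mismatched cohort is
  translated by `shift` (default 0.4 sd on every attribute, the scale of
  typical between-sex blood-biomarker differences) and its class gap scaled
  by `separation_scale`. A shift component parallel to the class-effect
  direction is partly absorbed by the max-over-classes in the score —
  shifted instances of one class resemble the other class — so uniform
  shifts much below ~0.3 sd become hard to distinguish from class
  variation; the default sits above that regime.
* `gen_informative_noise()`: five informative attributes (class means 0 vs
  1.5, sd 0.5 — narrow and peaked, like standardized summary statistics)
  plus three noise attributes $N(0,1)$ identical across classes; 500 per
  class. The informative/noise density contrast is what makes their removal
  distinguishable.
* `inject_missingness()`: exact-set removal, per-row random removal from a
  candidate set, or a per-cell rate; a removal that would empty a row is
  refused.

What the generators do **not** emulate: real morphology covariance beyond
one factor, real biobank marginals (skew, heavy tails, measurement floors),
genuine selection-statistic distributions, or missingness that is itself
informative. Passing tests demonstrate that the machinery behaves as
designed under Gaussian conditions; they do not certify performance on any
particular real dataset.

Because the cohort and informative/noise generators draw each class from a
single Gaussian (and the morphology table from a single factor model), the
workflow examples and end-to-end tests cap `max_components` at the
generative structure (1 for the 22-attribute cohorts and informative/noise
tables, 2 for the three-class table); the 1-D scenario keeps the default 5
so BIC selection itself is exercised. Library defaults are unchanged. The
null-calibration property (shift p-values uniform under no shift) is checked
on scaled-down cohorts (100 rows, 5 attributes, 60 replicates), a problem
size chosen to make the Kolmogorov–Smirnov sanity check sharp without
dominating the test suite.

## Persistence and comparability

Models serialize to a single versioned JSON document with numbers at 17
significant digits — the minimum guaranteeing an exact double round trip —
so a saved and reloaded model reproduces bitwise-identical densities and an
identical fingerprint. The fingerprint (a hash of the full parameter
payload) is embedded in every result file (`#model=` header line) and
enforced by `srs_shift_test()`: scores produced under different trained
models are never compared.

## Known limitations

* Pairwise joints capture second-order structure only; with many attributes
  or higher-order dependence, the likelihood estimate degrades and other
  outlier detectors may be preferable. With strongly redundant attributes,
  reducing to a smaller, less correlated set first is advisable.
* If a distribution shift moves instances of one class onto the trained
  density of *another* class, the score cannot flag them — it measures fit
  to the best class, not label correctness. The shrunken-class-separation
  scenario of `gen_cohort_shift(separation_scale < 1)` constructs exactly
  this failure mode.
* Attributes must be continuous; discrete or ordinal attributes are out of
  scope, as are non-Gaussian mixture families and kernel estimates.
* Scores are not calibrated probabilities and have no absolute meaning;
  thresholds must be chosen per application.
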