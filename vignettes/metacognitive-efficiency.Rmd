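---
title: "Estimating metacognitive efficiency with mratio: model, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating metacognitive efficiency with mratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mratio)
```

## The problem

After a two-alternative forced choice (2AFC) decision, observers can rate
their confidence. *Metacognitive accuracy* is the degree to which those
ratings discriminate the observer's own correct from incorrect decisions
(type-2 sensitivity), as opposed to the primary task's discrimination of the
stimuli themselves (type-1 sensitivity, d′). Raw type-2 measures are
confounded by type-1 performance and by confidence biases: an observer with
a higher d′ will look "more metacognitive" on almost any naive measure even
if their confidence machinery is identical.

`mratio` implements the signal-detection-theoretic solution: **meta-d′**,
the type-1 sensitivity that an SDT-ideal metacognitive observer would need
to produce the observed confidence data, expressed in d′ units. The ratio
**meta-d′/d′** (the *M-ratio*, "metacognitive efficiency") is then 1 for an
ideal observer, below 1 when confidence carries less information than the
decision, and above 1 when it carries more. Because both quantities share
units, the ratio is insensitive to raw performance and response bias — the
property that makes it usable in patient studies where performance is
staircase-matched across groups.

## The type-2 model and its fit

The equal-variance Gaussian model places trial evidence at
$x \sim N(\mp \tilde d/2,\, 1)$ for the two stimulus classes (S1 = left,
S2 = right). Type-1 estimation (`compute_type1()`) treats S2 as signal:

$$d' = z(\mathrm{hit}) - z(\mathrm{fa}), \qquad
  c = -\tfrac{1}{2}\left[z(\mathrm{hit}) + z(\mathrm{fa})\right],$$

with extreme rates replaced by $1/(2N)$ and $1 - 1/(2N)$ per stimulus class
so both quantile transforms stay finite.

For the type-2 level (`fit_meta_d()`), continuous ratings are first reduced
to `nbins = 4` within-session empirical quantile bins pooled over responses
and blocks (`bin_confidence()`), and cross-classified by response and
accuracy into a 4 × 4 count table (`build_type2_counts()`), the model's
sufficient statistic. The fitted model has parameters meta-d′
($\tilde d$) and $2(K-1)$ response-conditional type-2 criteria; its type-1
criterion is not free but held at the *same relative position* as the
empirical one, $\tilde c = (c/d')\,\tilde d$, so that the meta-level
observer inherits the observer's response bias. The fit maximizes the
multinomial likelihood of the confidence bins *conditional on the
response*; percent correct and bias therefore constrain nothing beyond the
anchoring of $\tilde c$.

Numerical choices:

* criteria are parameterized as ordered log-spaced increments away from
  $\tilde c$, which makes the required mirror ordering (S2 criteria
  ascending, S1 descending) unviolable by construction;
* $1/(2K)$ is added to every cell before fitting, the conventional padding
  that keeps likelihoods finite for empty cells;
* the bounded quasi-Newton search (meta-d′ ∈ [−5, 5]) is restarted from
  three fixed initial points; hitting a bound sets a quality flag;
* the likelihood kernel is implemented in C++ for speed; the test suite
  validates the fit against an independently coded profiled grid search
  (criteria re-optimized at every meta-d′ grid value with a Nelder–Mead
  simplex), requiring agreement within 0.01 across randomized tables;
* negative fitted meta-d′ is retained (an unbounded ML estimate can go
  below zero by estimation error) but flagged: log-efficiency is undefined
  and the subject is excluded from log-based analyses in that domain.

Quantile ties are resolved deterministically: tied ratings share the bin of
the tie group's lowest rank, so a group straddling a boundary falls as a
whole into the lower bin; the mapping is monotone and order-invariant.
Bins are computed per subject and task over the whole 200-trial session
(not per block): confidence criteria are plausibly stable within a session,
and per-block binning at 25 trials per block would leave quantiles
badly determined.

## The domain-general index and group analysis

Per-subject efficiencies in the two task domains, perceptual
$M_p$ and memory $M_m$, are compared on the log scale: a log transform
weights deviations multiplicatively, so halving and doubling of efficiency
relative to the ideal value 1 count equally. The **domain-general index**

$$\mathrm{DGI} = \left|\log M_p - \log M_m\right|$$

is 0 for perfectly consistent metacognition across domains and grows with
any dissociation. Natural logarithms are the default; the index only
rescales under a change of base, which is exposed as a configuration
option.

Group-level machinery (`group_tests()`, `run_full_analysis()`):

* **Bootstrap CIs**: percentile intervals of the group mean from 100,000
  resamples drawn with replacement. The resampling unit is the *subject* —
  group-level claims concern the population of subjects, not of trials.
* **Tests**: one-way ANOVA and Kruskal–Wallis across groups, pooled-variance
  t and Wilcoxon rank-sum tests per group pair, all two-tailed at α = 0.05
  with no multiplicity adjustment (each contrast answers its own question).
* **Group × domain interaction**: every subject contributes exactly one
  value per domain, so the interaction collapses to a between-group
  contrast on the within-subject difference $\log M_p - \log M_m$. The
  one-way F on those differences is referenced to a permutation
  distribution obtained by shuffling group labels across subjects (10,000
  permutations by default). A mixed model could be written down instead,
  but with one observation per subject-domain cell no further
  random-effects structure is identifiable, and the permutation reference
  makes no distributional assumption.

Exclusions are data: a non-positive efficiency in one domain removes the
subject from log-based analyses in that domain and from the DGI, never from
raw-efficiency summaries, and every exclusion is logged with its reason.

## What the simulators emulate

The generative module exists because the package's validity claims are
parameter-recovery claims: every downstream stage is exercised on synthetic
cohorts with known ground truth.

**Perception task.** 200 recorded trials (8 blocks × 25). The comparison
circle differs from the 50-dot reference by Δd dots; mean evidence is
`evidence_per_dot * delta_d` decision-noise SDs. Δd follows a one-up
two-down staircase (one dot down after two consecutive correct, one dot up
after each error), which converges where $p^2 = 1/2$, i.e. 70.7% correct.
The default `evidence_per_dot = 0.147` puts the staircase equilibrium near
Δd ≈ 4 dots — the difficulty regime of staircase-controlled dot
discrimination — and recorded sessions sit at 71–72% correct with d′ ≈ 1.1.
Each session begins with 25 discarded staircase trials standing in for the
practice-phase titration, so recording starts in the stationary region; the
staircase state carries across blocks. Δd starts at 15 dots and is clamped
to [1, 49] so every displayed count stays within the 1–100 dot display
range.

**Memory task.** 200 trials (4 blocks × 50) of 2AFC old/new word
recognition. Study time per block (0.5, 1, 1, 1.5 minutes, order shuffled
per session) sets memory strength abstractly: each trial contrasts an
old-item strength draw with a new-item draw, calibrated so expected
accuracy hits the observer's `memory_accuracy` targets (defaults
0.67/0.73/0.76, rising with study time). Word identity, lexical properties
and list structure are not modelled — only the generative statistics that
reach the analysis.

**Metacognition.** The observer's decision uses the *decision channel*
`x + N(0, decision_extra_noise_sd)`; confidence reads the *confidence
channel* `x + N(0, confidence_noise_sd)`. Confidence noise alone produces
M-ratios below 1; extra decision noise (with confidence reading the cleaner
underlying evidence) is the standard generative route to M-ratios above 1.
With both zero the observer is SDT-ideal and fits to efficiency 1.00 ±
0.05 at 10^5 trials — the package's central calibration check.

The signed confidence evidence is mapped to the continuous 1–6 slider by a
strictly monotone piecewise-linear read-out anchored at five criteria
(criterion *j* ↦ slider position *j* + 0.5, exponential squash into the
scale ends). A categorical read-out with independent uniform jitter inside
each category was considered and rejected: independent jitter makes the
report non-monotone in confidence evidence within category, so four-bin
quantile splits cut category interiors at random, and even the ideal
observer then fits to ≈ 0.94 — a property of the report model, not of the
observer, and one that would contaminate every calibration claim. The
default criteria (−0.5, 0, 0.5, 1.1, 1.9) give mean reported confidence
near 4 at staircase-controlled performance, matching the upper-middle scale
use typical of confidence sliders.

**Calibration.** `calibrate_confidence_noise()` inverts the monotone map
from noise to *fitted* efficiency by bisection on simulated 10^5-trial
sessions, followed by a local linear refinement over the late bisection
points (each evaluation is a Monte-Carlo estimate, so the raw bisection
interval can sit ~0.02 off target) and a two-simulation verification that
is returned as the `achieved` attribute. Cohort generation inverts a
simulated noise-efficiency curve per domain instead of re-running the
bisection per subject.

**What passing recovery tests do not show.** The generator draws from the
same model family the fit assumes (equal-variance Gaussian, stable criteria,
independent trials). Recovery therefore validates the estimation machinery,
not the model's adequacy for real observers, whose confidence may drift,
depend on response time, or violate equal variance. Group means and
dispersions for the bundled three-group specification
(`example_cohort_spec()`: anterior-prefrontal-lesion-like, n = 7, Mp 0.46 /
Mm 1.04; temporal-lobe-like, n = 11, 0.84 / 0.92; healthy-control-like,
n = 19, 0.88 / 1.09; between-subject SD 0.15) emulate the headline pattern
of a lesion-study design — a domain-specific perceptual deficit with spared
memory metacognition — not any particular patient's data.

## Problem sizes in the test suite

The statistical-calibration tests run at sizes chosen to balance power
against runtime: ideal-observer and chance-floor checks at 10^5 trials;
oracle equivalence on 100 randomized 200-trial tables; recovery of the 0.46
and 1.04 targets with 50 subjects × 200 trials (the design's session
length); the permutation test's false-positive rate over 400 null cohorts
of 2 × 8 subjects at 500 permutations each; bootstrap coverage over 2,000
replications of n = 30 with 1,999 resamples. Package defaults (100,000
resamples, 10,000 permutations) are unaffected by these test-time sizes.

## Known limitations

* Response-conditional meta-d′ (separate values per response), hierarchical
  or Bayesian estimation, and unequal-variance SDT are out of scope.
* The M-ratio at 200 trials is a noisy estimate (between-subject SD of
  ~0.25–0.3 at four bins); single-subject values should be interpreted
  accordingly, and group designs should plan for that dispersion.
* Covariate adjustment (IQ, gender, lesion volume) is not implemented; the
  report states this explicitly.
* The staircase-controlled regime keeps accuracy near 70.7%; efficiencies
  are recovered within that regime and extreme d′ values (< 0.2 or > 3)
  are outside the calibrated range of the simulators.
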