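---
title: "Methods behind the LSM operational evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the LSM operational evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsmeval)
```

`lsmeval` evaluates drone- and AI-assisted larval source management (LSM)
against conventional practice from routine field logs. This vignette
explains the statistical machinery, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## The comparison design

The unit of comparison is the sub-district: four intervention units
(drone mapping, AI risk classification, selective spraying) and four
control units (manual scouting, blanket spraying). All indicators are
computed per sub-district, then compared between arms. With n = 4 per
arm nothing about these comparisons is asymptotic; everything downstream
is built for exact small-sample behaviour.

## Labour intensity and larvicide efficiency

Labour is summarised as Total Person-Days per Unit Area:
for phases $i = 1,\dots,N$ with $W_i$ workers and $D_i$ workdays over an
operation area $S$ (km²),
$$\mathrm{TPDUA} = \frac{1}{S}\sum_{i=1}^N W_i D_i .$$
The statistic is additive over phase lists and inversely proportional to
area; both properties are tested. An empty phase list contributes 0
person-days rather than an error, so partially logged districts
aggregate safely. Larvicide efficiency is sprayed sites per larvicide
pack; the drone detection benefit is the drone/manual found-site ratio
(undefined, and an error, when manual scouting found nothing).

Arm-level "average" rows are means of per-district indicator values, not
ratios of arm totals. The two definitions disagree (169 vs 169.2 sites
per pack in the intervention arm; 60 vs 79.1 in control) and the
per-district mean is the one the published tables use.

### Quartiles: Tukey hinges

Group summaries report hinge quartiles — medians of the lower and upper
half-samples, halves including the middle value at odd n; at n = 4 each
hinge is the midpoint of a pair. Linear-interpolation quantiles
(`quantile(type = 7)`) give 2.95/2.90 for the intervention TPDUA group
and cannot reproduce the published 2.91–5.09 interval, while hinges
reproduce all four published IQR pairs exactly. `stats::fivenum()`
computes the same hinges and serves as the independent cross-check in
the tests. One wrinkle: the published control-arm IQR (6.07) derives
from the 2-decimal displayed TPDUAs, not the full-precision values
(which give 6.06); the fixture audit therefore feeds the displayed
values to the quartile step, exactly as the published tables did.

### Display rounding

Indicators are computed at full precision and rounded only for
table-style display, half away from zero (`round_half_away()`:
2.905 → 2.91). Base R's banker's rounding would turn 2.905 into 2.9 and
break agreement with the printed cells.

## Exact inference

**Mann–Whitney.** `mann_whitney_exact()` reports the smaller of the two
one-sided U statistics, with mid-ranks for ties, and computes the
two-sided p by full enumeration of all $\binom{n_1+n_2}{n_1}$
assignments of the observed rank multiset to the first group:
$p = \min(1,\, 2\min(P(U \le u),\, P(U \ge u)))$. At 4-vs-4 with
complete separation this yields exactly $2/70 \approx 0.029$.
Enumeration is used up to a combined n of 20 (184,756 assignments,
well under a second); beyond that a tie-corrected normal approximation
is used and flagged in the result. The test-suite oracle recomputes U by
direct pairwise comparison counting — a different algorithm than the
rank-sum identity used in the implementation — over the same
enumeration.

**Chi-square.** Plain Pearson $\sum (O-E)^2/E$ with expected counts from
the margin products, no continuity correction (a Yates-corrected 3×2
statistic would not match the published 33.63). Zero margins are an
error rather than silently producing NaN cells.

## The risk classifier

The larval-risk stage is a gradient-boosted decision-tree binary
classifier over six categorical waterbody features, with defaults of
1000 maximum iterations, tree depth 10, a fixed 0.5 decision threshold,
and stratified 5-fold cross-validation. Design choices that the problem
statement leaves open:

- **Backend.** Any boosted-tree ensemble satisfies the contract;
  `xgboost` is used with one-hot encoding of the categorical levels.
  The training-time vocabulary is stored in the model, and unseen levels
  at prediction are an error naming the level — field-data hygiene over
  silent mapping.
- **Early stopping.** A 10% internal validation split (stratified by
  label) with patience 50 iterations and log-loss as the criterion. No
  protocol is prescribed by the source context; this one is simply
  recorded, not claimed to match.
- **Learning rate** defaults to 0.1, a conventional boosted-tree
  shrinkage for tabular data of this size.
- **Stratified folds** distribute each class's remainder onto the
  least-loaded folds, so overall fold sizes never differ by more than
  one while class counts per fold also differ by at most one.

The published cross-validation metrics of the original model
(accuracy 0.70, precision 0.70, recall 0.72) are *not* reproducible:
its training survey (4,021 waterbodies from Sierra Leone and Ghana) is
not publicly available. They are context, not targets. The package's
substitute check is parameter recovery on synthetic data, described
next.

## The synthetic-data generator

`generator_config()` defaults *are* the emulated study conditions:
4,021 labelled waterbodies; feature marginals over the full categorical
schema; an additive log-odds presence process whose weight magnitudes
rank waterbody type and visual turbidity highest (mirroring the
published feature-importance ordering) and whose intercept puts the
high-risk fraction near 0.5–0.65, echoing the observed field high-risk
ratios (0.557–0.747); arm-specific effort with intervention labour
around half of control; and a Culex-dominated genus mix
(0.909/0.047/0.043/0.001) at roughly the observed weekly catch scale.

The presence label is drawn as
$Y \sim \mathrm{Bernoulli}\!\big(\sigma(\beta_0 + \textstyle\sum_f
\beta_{f,\,x_f})\big)$, an additive logistic model over one-hot
categories — deliberately the simplest process a boosted tree should
recover, with an exactly computable Bayes rule. Because the feature
space is finite (7·2·4·2·2·3 = 672 cells), the generator returns the
full lattice with exact cell masses and presence probabilities, and
`bayes_rule_metrics()` marginalises it into the precision/recall/
accuracy the optimal classifier attains. The acceptance-level check
trains on 4,000 generated waterbodies and requires held-out CV recall
and precision within ±0.05 of that oracle.

Operation-log generation draws phase days as
$\max(1, \mathrm{Poisson}(\lambda))$ with $\lambda$ = expected workdays
per km² times district area — the floor encodes that a visited district
costs at least one workday. The floor biases small-area expectations
upward, so the recovery test's oracle uses the exact mean
$\lambda + e^{-\lambda}$ rather than $\lambda$. Found-site counts are
Poisson at arm-specific site densities (drone mapping ≈ 90 sites/km²,
manual ≈ 26, the observed order of magnitude); intervention districts
spray a configurable high-risk fraction (default 0.6) of found sites,
control districts spray everything.

What the generator does **not** emulate: spatial structure and
autocorrelation of habitats, seasonality and weather in the trap
series, inter-observer variation in turbidity grading, and any
dependence between features (marginals are independent). Passing the
recovery tests therefore shows the pipeline is correct and the learner
can recover a known conditional process at the study's scale — not that
the classifier would attain any particular performance on real survey
data.

## Economics

The daily wage compounds a base net monthly salary through ordered
annual adjustment fractions and divides by working days per month
(defaults 2,594 GHS, +30%, +23%, 20 days → 207.4 GHS/day). The
per-operation margin is $M = R\,S\,(E_c - E_p)$ with $E_c$, $E_p$ the
arm-mean TPDUAs (means, not medians, matching how the published
break-even figures are described). Break-even reports both the
continuous value $C/M$ and the smallest integer $n$ with $n M \ge C$;
with the default inputs these are 8.97 and 9 cycles, while the source
prose says "approximately ten" — plausibly medians or conservative
rounding on their side. Both readings are exposed; nothing is rounded
toward the prose.

## Entomological aggregation

Proportion denominators follow each published percentage's implied
base: genus and sex shares divide by the mosquito total, the mosquito
share divides by the all-insect total. The genus-by-site contingency
table drops genera below a count threshold (default 2) — a general rule
that excludes the single Mansonia specimen without hard-coding the
taxon. Weekly series report silent weeks as zeros: a trap week with no
captures is data.

The fixtures keep the source tables exactly as printed, including their
internal inconsistencies (two tables swap a pair of district counts;
one site total differs by one between text and table; three printed
high-risk ratios differ in the third decimal from the printed count
ratios). `fixture_notes()` lists them; nothing is silently corrected.

## Problem sizes and determinism

The test suite runs at desk scale by design: exact enumeration at
n₁+n₂ = 8, classifier checks at 120–4,000 rows, generator audits at
20,000 draws, and 200 replicates for the effort-recovery oracle —
about ten seconds end to end. All stochastic steps flow through
explicit seeds (`with_seed` restores the caller's RNG state), and
byte-identical regeneration under a fixed config is itself a tested
invariant.

## Known limitations

- The exact U test enumerates combinations; above a combined n of 20 it
  switches to the normal approximation rather than a shifted-algorithm
  exact computation.
- One-hot encoding discards any ordinal structure (e.g. turbidity,
  size class are arguably ordered); with six low-cardinality features
  this costs little, but a native categorical backend could differ.
- The economic model is a labour-cost margin only: no discounting,
  drone maintenance, training costs, or larvicide price modelling.
- The classifier's real-world performance claims are bounded by the
  synthetic recovery design, as discussed above.
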