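---
title: "Models and methods for the evolution of skilled foot use in birds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for the evolution of skilled foot use in birds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedex)
```

# The problem

Many birds manipulate objects with their feet — raptors pin and tear prey,
parrots lift food to the beak while rotating the foot, some songbirds clasp
insects against a perch. Systematic comparative data on this behavior can
be assembled from citizen-science photo and video repositories: every media
record of a species is scored for a fixed set of behavioral elements, and
species-level summaries feed phylogenetic comparative analyses. `pedex`
implements that pipeline end to end:

1. **Scoring** per-media behavior flags into species profiles and a
   dexterity index;
2. **Detection thresholds** separating "behavior truly absent" from "too
   few media to tell";
3. **Tree utilities** (maximum clade credibility summaries, genus-level
   pruning, midpoint grafting of unplaced taxa);
4. **Discrete-trait models** (ER/SYM/ARD and a hidden precursor-state
   model) with maximum-likelihood fitting, AIC comparison, marginal
   ancestral state reconstruction, and gain/loss counting;
5. **Continuous-trait comparative methods** (PGLS, Brownian ancestral
   reconstruction);
6. A **synthetic-data generator** producing complete studies with known
   ground truth, used throughout the test suite.

# Behavioral scoring

Each media record carries ten binary flags (`behavior_flags()`), from
`foot_use` (holding or pinning an object with the claw) through `grasping`,
`free_grasping`, `free_grasping_in_flight`, toe use, single-leg use,
foot-to-beak and foot-to-midline transport, and inward/outward foot
rotation. The flags are logically nested: grasping in flight entails free
grasping, free grasping entails grasping, and every element entails
`foot_use`. These implications are configuration
(`behavior_implications()`), not hard-coded: whether foot-to-beak transport
entails a closed-claw grasp is genuinely ambiguous (an object can be lifted
balanced on the claw), so that rule exists but defaults to off. Strict
parsing rejects violating rows; lenient parsing closes the implications
with a warning, which suits hand-curated tables with implicit hierarchy.

The **dexterity index** of a species is the size of the union of flags
over all its media — an integer in 0–10. It is deliberately a union, not an
average: a single unambiguous video of a rare behavior demonstrates
ability. The index is therefore monotone in data and saturates; it measures
repertoire breadth, not frequency of use.

A species with no media showing foot use is either `absent` or
`insufficient`, decided by comparing its total repository media count to
the clade's detection threshold (below). Species with zero scored media get
index 0 and are classified by the same rule, which keeps them inside the
detection framework instead of being silently dropped.

Diet handling follows the trophic-niche convention for EltonTraits-style
percentage tables: a species is assigned a niche when a single diet
category exceeds 60% (strictly), otherwise it is an omnivore. Since
published percentage tables are rounded, totals up to 100.5 are accepted.

# Detection thresholds

Absence of evidence is informative only with enough media. For each clade
we model the probability that foot use was detected for a species as a
logistic function of its media availability and define the **detection
threshold** as the smallest media count at which the lower 95% pointwise
Wald bound of the fitted curve reaches 75% detection probability.

Choices the data do not dictate, and their defaults:

* **Predictor scale** — `log10(media_count)` by default (counts span
  1–10^4; a logistic in raw counts puts all curvature in the first few
  hundred media); raw scale is available.
* **Confidence construction** — Wald band on the linear predictor mapped
  through the inverse logit, the standard GLM construction.
* **Rounding** — thresholds are reported conservatively rounded up
  (`round_up_to`, default plain ceiling); the crossing itself is found by
  integer scan over `[1, 10 x max observed media]`, which is exact because
  the bound is monotone when the slope is positive.
* **Separation** — clades in which every (or no) species was detected make
  the ML fit diverge; such fits automatically fall back to a
  Jeffreys-penalized (Firth) logistic fit and are flagged, keeping small
  clades estimable.

Using the lower confidence bound rather than the point estimate makes the
threshold deliberately conservative: it is never below the point-estimate
crossing, and at realistic sample sizes it retains a finite-sample upward
offset. Two clade-level rules from the empirical workflow are supported in
`clade_threshold_pipeline()`: an exclusion rule that removes species with
many media (e.g. >500) but no detection before fitting (such species
genuinely lack the behavior and would flatten the curve), and fallback
parents for clades with too few species to fit (the fallback graph is
checked for cycles). Families are codeable as absent only when their total
media reach a cutoff (default 1500, the upper range of clade thresholds);
otherwise they enter reconstructions as unknown (fully ambiguous) tips.

# Discrete-trait models and the precursor state

Trait evolution is modeled as a continuous-time Markov chain on the tree.
The generator `Q` is constrained by pattern: `ER` (one rate), `SYM`
(symmetric), `ARD` (all rates different), and `PREC` — a three-state hidden
precursor model with observed `absent`, hidden `precursor`, and observed
`used`. Under `PREC` the derived state is reachable only through the
precursor (ecologically: an arboreal, perching lifestyle from which foot
use can be recruited), so both direct `absent -> used` and `used -> absent`
rates are structurally zero. The reverse prohibition is a package choice —
it keeps losses interpretable as retreat to the precursor condition — and
is configurable through a custom observation map and pattern if the
asymmetric variant is wanted. The precursor is observationally identical to
absence: observed symbol `"0"` maps to `{absent, precursor}`, `"1"` to
`{used}`, and `"?"` (or a missing tip, when allowed) to all states.

The likelihood is computed by Felsenstein's post-order pruning with
per-node rescaling (the recursion itself is compiled code). Transition
matrices `exp(Qt)` for all branches come from one spectral decomposition of
`Q` per likelihood evaluation; when the eigenvector matrix is
ill-conditioned (reciprocal condition number below 1e-8) the code falls
back to scaling-and-squaring per branch. Probabilities are clamped to
`[0, 1]`; zero-length branches propagate the identity.

At the root the partial likelihoods are combined with a prior: `flat`
(default — the uninformative choice when the root state is genuinely
unknown), `stationary` (of the fitted `Q`), or `fitzjohn` (each state
weighted by its share of the data likelihood). The choice matters most for
shallow, unbalanced data; it is a single argument everywhere so
sensitivity is one rerun away.

**Fitting** maximizes the likelihood over log rates with bounded
quasi-Newton (`nlminb`) restarts. Hidden-state surfaces are multimodal and
ridged, so the default is 10 restarts: one from a deterministic heuristic
(rate = 1/tree height) and the rest jittered over several orders of
magnitude. Rates are bounded in `[1e-9, 1e3]` per unit branch length.
AIC is `2k - 2 logL` with `k` the number of free rates.

**Marginal ancestral states** are computed by the standard two-pass
(below/above) algorithm, so every node's posterior conditions on all tips.
Unambiguous tips reproduce their observation; collapsed tips apportion
between compatible hidden states. Nodes are assigned their max-posterior
state for reporting, with exact ties broken toward the earlier
(non-derived) state, and nodes with max posterior below 0.95 are flagged.

**Origin counting** classifies each branch by its endpoint states: a gain
is a branch from a non-derived parent to a derived child, a loss the
reverse. Tie-breaking toward the non-derived state makes the counts
conservative — in the spirit of reporting "at least N independent
origins".

# Continuous traits

`pgls_fit()` is a closed-form GLS under the Brownian trait covariance
(shared path lengths), optionally attenuated by Pagel's lambda (fixed, or
profiled by ML on `[0, 1]`). The default is pure Brownian (lambda = 1), the
minimal assumption when nothing else is specified. The reported F statistic
compares the full model to the intercept-only model under the same
covariance, giving the familiar `F(p-1, n-p)` shape; factor predictors use
treatment contrasts with the alphabetically first level as baseline, and
this coding choice is part of the reported model. Diet percentages are used
untransformed by default (they are bounded but typically far from the
bounds at the clade level); a logit transform can be applied by the caller.

`brownian_asr()` computes maximum-likelihood Brownian ancestral estimates
by solving the branch-weighted (weights `1/t`) Laplacian system in which
every internal node is the weighted average of its neighbors; for a
Gaussian model this joint mode equals each node's conditional mean. The
rate is estimated by REML from the whitened deviations around the GLS
mean, and node variances are the conditional variances under that rate.
Estimates are convex combinations of tip values, hence always inside the
observed range — a feature (no spurious extrapolation) and a limitation
(no trend reconstruction).

# The synthetic-data generator

`simulation_config()` fixes the study conditions once:

* **Tree** — pure-birth at 0.1/Myr (`ape::rphylo`); branch lengths are read
  as millions of years, so simulated clades are a few tens of Myr deep,
  like the avian radiations the pipeline targets.
* **Trait** — precursor model with rates `(0.05, 0.02, 0.1, 0.05)` per Myr
  for `absent->precursor`, `precursor->absent`, `precursor->used`,
  `used->precursor`; root state `absent` for study-like bundles. The
  character is simulated exactly (exponential waiting times along each
  branch) and every transition is logged, so downstream stages can be
  scored against event-level truth.
* **Media counts** — log-normal, meanlog 5 and sdlog 1.5: median about 150
  media per species with a heavy right tail spanning roughly 1–10^4,
  matching the shape of repository coverage.
* **Detection** — each media record of a foot-using species shows the
  behavior independently with probability 0.005, so species-level
  detection probability is `1 - (1 - p)^m`; the 75% point falls near 275
  media, inside the range of empirically plausible clade thresholds.
  A beta-heterogeneity option perturbs `p` per species for robustness
  experiments. Species in the absent and precursor states never show foot
  use — they are observationally identical, mirroring the hidden-state
  observation map.
* **Behavior flags** — conditional probabilities respecting the implication
  hierarchy (e.g. grasping in 60% of foot-use media, free grasping in 40%
  of grasping media), so every generated row passes strict validation.

What the generator does **not** emulate: geographic and observer bias in
media coverage, taxonomic error, misidentified behavior, non-independence
of media from the same event, and literature-based (non-media) evidence.
Passing tests on synthetic data therefore validate the estimators under
the stated model, not the field protocol.

# Validation design and problem sizes

The test suite validates each stage against an independent oracle:
exhaustive enumeration over node-state assignments for the pruning
likelihood and marginal posteriors (trees up to 6 tips, tolerance 1e-10);
closed forms for the two-state propagator, star-tree GLS and Brownian
roots; hand-counted clade frequencies (and `phangorn::maxCladeCred`) for
the MCC summary; `phytools::fitMk`, `nlme::gls` and `ape::ace` as
independent implementations of overlapping functionality.

Simulation-based checks use: 500-tip trees with 50 replicates for
precursor-rate recovery (roots drawn from the stationary distribution, the
standard design for parameter-recovery experiments; pooled median relative
error across free rates below 50%); 400-tip trees with 20 seeds for
PREC-vs-ER model recovery by AIC; 5000-species clades for detection
threshold recovery; and 400-tip studies at birth 0.3/Myr for end-to-end
origin counting. These sizes give stable verdicts at interactive runtimes;
the recovery experiments use 3–6 optimizer restarts (the user-facing
default is 10).

# Known limitations

* **Hidden-rate identifiability.** With a single binary observed
  character, the `precursor -> absent` rate is informed only indirectly;
  its estimates are much noisier than the other three rates, and the
  likelihood can develop ridges where very fast hidden cycling mimics a
  merged state. Multi-start optimization finds these modes honestly; they
  are a property of the model, not the optimizer.
* **Saturation and origin counting.** When the character flips several
  times per root-to-tip path, smoothed reconstructions merge adjacent true
  origins and undercount them (by design, the tie-break also counts
  conservatively). Counting is reliable in regimes like the empirical one
  — a handful of expected transitions per path; it degrades on much
  deeper trees at the same rates.
* **Detection thresholds are sampled quantities.** At a few thousand
  species the fitted 75% crossing carries a sampling error of a few
  percent; the lower-CI construction adds a deliberate conservative
  offset. Thresholds should be read at reporting precision, not as exact
  media counts.
* **Event-level truth vs node-level estimates.** Multiple transitions on
  one branch are invisible to any node-state method; scored against full
  event logs, all reconstruction-based counts are lower bounds.
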