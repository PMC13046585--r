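---
title: "Modeling dynamic risky choice: trees, true-and-error analysis, and a planning accumulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dynamic risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many consequential decisions unfold in stages: an early choice opens or
closes options that only matter after intervening chance events.  The
normative benchmark for such problems is *backward induction*: solve the
final decisions first, prune the branches a rational future self would
never take, and evaluate earlier options under those plans.  People often
do something simpler — for example, treating the whole problem as a single
choice between two many-outcome lotteries (*forward* evaluation), as if
future decisions were coin flips.

`dynchoice` implements a complete analysis pipeline for a two-stage
decision-tree experiment built to separate these strategies, including:

* decision-tree data structures with backward/forward solvers, stochastic
  dominance checks, and display scrambling;
* a synthetic-experiment generator (designs, trial records, simulated
  participants);
* a True-and-Error (TE) multinomial model of repeated-choice patterns with
  G² fitting and nested restriction tests;
* a sequential-sampling process model — an accumulator over noisy mental
  simulations of tree paths (a planning variant of decision field theory)
  — with simulation-based likelihood fitting and four-fold cross-validated
  model selection.

## The dominance-reversal tree design

A **full tree** has a first-stage decision (DN1) between two chance nodes;
each chance node leads (50/50) to one of two second-stage decisions (DN2),
each offering two two-outcome gambles (all two-outcome chance nodes are
fair).  That gives 5 decision nodes, 10 chance nodes, and 16 outcomes.
Templates are constructed so that three properties hold simultaneously:

1. at every DN2 one gamble first-order stochastically dominates its
   sibling — a planner prunes the dominated branch effortlessly;
2. the union of the right branch's eight outcomes stochastically dominates
   the union of the left branch's eight outcomes — a non-planner treating
   DN1 as a choice between two 8-outcome lotteries prefers right;
3. backward induction, after pruning, prefers **left**.

So planners and non-planners move in opposite directions at DN1.  The
package's canonical orientation puts the backward-induction branch first
("left"); on-screen layout is a recorded permutation (`scramble_map`) so
analyses are invariant to the scrambling used to disguise repeated trees.

The constructive template scheme places flat high/low gambles
({H,H} vs {L,L}) on the left and nearly-tied pairs ({H*+e, L} vs {H*, L})
on the right; this guarantees the three properties by construction, and an
integer jitter plus re-validation adds variety.  Derived trees:

* **half trees** replace one chance node per DN2 by a certain payoff equal
  to its expected value.  The package replaces the *dominated* node by
  default (configurable), which leaves every DN2 value — and hence the DN1
  solution — unchanged; the source experiment does not state which node
  was replaced.
* **single-stage trees** delete the second stage: one decision between the
  two 8-outcome branch unions at 1/8 each.
* templates 2–4 add 1, 2, 3 to every outcome of template 1: perceptually
  distinct, structurally identical.

The default outcome range is 0–120 points.  The experiment: 5 blocks × 8
trials; blocks 1–4 alternate full and half trees with four
Latin-square-counterbalanced block orders (participants cycle through the
orders; with 50 participants two orders occur one extra time); block 5 is
single-stage.  Each template appears twice per block, never back-to-back.

## True-and-Error modeling

Because each two-stage template is presented four times (twice in each of
two blocks), every participant × template yields a length-4 pattern of
first-stage choices, coded 1 when the choice matches backward induction.
The TE model explains the 16-cell pattern distribution with five
parameters:

* `B` — probability a decision maker truly holds backward-consistent
  preferences in the first half;
* `s_b`, `s_f` — probabilities the backward (resp. forward) profile
  persists into the second half;
* `e12`, `e34` — per-presentation "trembling hand" error rates in the two
  halves, each bounded by 0.5.

Errors are independent across presentations given the latent profile;
the basic one-error no-switch model is the special case
`s_b = s_f = 1`, `e12 = e34`.  The model-implied prevalence of backward
induction in the second half is `B·s_b + (1−B)·(1−s_f)`.

**Fitting.**  Multinomial maximum likelihood via bounded quasi-Newton on
logit-transformed parameters (errors mapped through `0.5·plogis`), with
multiple starts (default 20: one fixed interior start plus uniform draws);
transformed parameters are bounded at ±15, so boundary estimates such as a
persistence probability of 1.00 are representable and reported as-is.
Badness of fit is `G² = 2 Σ O·ln(O/E)` (empty cells contribute zero) with
`df = 15 − #free`, and nested models are compared by the G² difference
against the asymptotic chi-square reference.

**A calibration caveat.**  The substantively interesting restrictions
(`B = 1`, `s_b = 1`, `s_f = 1`) pin parameters to the *boundary* of their
range.  When such a restriction is true, the G² difference follows a
chi-bar-square mixture, not the nominal chi-square, and the test is
conservative (we measure ≈ 0.01–0.02 rejection at nominal .05 with
n = 200).  This is a property of boundary hypotheses, not of the fitter;
the calibration test in the acceptance suite therefore uses the interior
equality restriction `e12 = e34`, for which the chi-square reference
applies and the measured rejection rate is ≈ .05–.06.

The cross-condition equality-constrained model shares `B`, `s_b`, `s_f`
between full and half trees while freeing the error rates per condition;
by parameter counting this costs 3 df against the separate fits.

## The planning accumulator

At each deliberation step the decision maker mentally simulates one
outcome per alternative by tracing a path through the tree, takes the
valence `V = ν_i − ν_j`, and accumulates `P(t) = P(t−1) + V(t−1)` from
`P(0) = 0` until `|P|` reaches a threshold; the sign picks the
alternative.  Mechanisms:

* **Threshold shift** — a low threshold `θ_plan` for first-stage
  deliberation and for *simulated* future decisions, a higher `θ_final`
  for actual second-stage (and single-stage) choices.  The
  single-threshold variant ties them.
* **Sampling bias** `ϕ` — while planning, a two-outcome terminal chance
  node yields its larger-magnitude outcome with probability `ϕ`; final
  choices sample by the true probabilities.  Eight-outcome single-stage
  gambles are never biased (the mechanism is defined for the two-outcome
  terminal nodes).
* **Daydreaming** `δ` — with probability `δ`, a simulation is replaced by
  a uniform draw over the experiment-wide outcome range `(n, m)`.  The
  replacement applies at the entry of each alternative's simulation on
  each step — including the steps of nested simulated decisions — and in
  both planning and final modes (configuration inherited by all variants;
  only the sampling *bias* is restricted to planning).
* **Non-planning** — the no-plan variants resolve a future decision node
  by a fair coin instead of a simulated decision.
* **Switch point** — an integer 0–4 giving the block after which a
  non-planner starts planning (0 = always plans, 4 = never); only the
  non-planning → planning direction is modeled.

Numerical choices: deliberation is capped at 10,000 steps, after which the
choice is forced by the sign of `P` (fair coin at exactly zero) and the
event is counted; within one first-stage step the nested second-stage
simulation uses fresh randomness (no caching of plans); "higher magnitude"
is the larger absolute value (all design outcomes are nonnegative).

**Prediction and likelihood.**  Choice probabilities are estimated from
300 simulated decisions per choice and clipped to
`[1/(2·n_sims), 1 − 1/(2·n_sims)]`.  The likelihood of a participant's
data is the sum of log predicted probabilities of every observed choice
(first-stage on all trials, second-stage on two-stage trials; either stage
can be ablated).  Trials that repeat a template share predictions, so the
implementation computes one probability per distinct (condition, template,
node, planning-policy) combination; the random substream of each
combination depends only on that key — never on the parameters — giving
common random numbers across the parameter grid and exact reproducibility.

**Search.**  The simulated likelihood is noisy and non-smooth, so fitting
uses a coarse-to-fine full-factorial grid (default 8 points per free
dimension, one refinement pass bracketed by the incumbent's neighbors)
rather than gradient methods.  Default bounds: thresholds log-spaced on
[1, 200]; `ϕ ∈ [0.5, 1]` (bias toward higher magnitudes; widen to [0, 1]
by argument); `δ ∈ [0, 0.5]` (widen by argument).  The switch point is
enumerated exhaustively with continuous parameters refit per value.

**Identifiability and the outcome scale.**  Thresholds only shape behavior
when typical valences do not already exceed them: with fixture-scale
outcomes (≈100 points) almost every accumulation absorbs in one step for
any threshold in [1, 200], so `θ_final` is empirically unidentified there
(we verified the likelihood is flat in it).  The parameter-recovery study
therefore uses templates on a 0–40 point range with generating
`θ_plan = 5, θ_final = 40` and search bounds [1, 60] — thresholds then
govern how many noisy samples a decision integrates, and the
threshold *order* is recovered reliably.  Planning-status selection, by
contrast, rests on the direction of first-stage choices and works at any
scale; its study keeps the fixture world.

## Cross-validation and model selection

Per participant, trials are randomly allocated to four training sets with
exactly 25% of each condition's trials in each; each spec is fit on a
training set and scored on the complementary 75%.  Predictive accuracy is
the mean predicted probability assigned to observed validation choices
(primary; a .5-threshold hit rate is reported alongside — the source
analysis does not define its accuracy measure, so the probabilistic one,
which is strictly proper-scoring in spirit, is primary).  The winner has
the highest mean accuracy over folds; ties break toward fewer free
parameters, then input order.

## What the synthetic generator does and does not emulate

TE-mode participants draw one latent profile per experiment half (shared
across templates and both two-stage conditions — a participant is or is
not a planner) and flip first-stage responses with the half's error rate;
second-stage and single-stage choices maximize expected value with an
independent flip rate (default .05), a stand-in because the TE model only
describes DN1.  DFT-mode participants generate every choice from the
accumulator.  Chance nodes are realized as fair draws.  Not emulated:
response times, learning within blocks beyond the modeled preference
switches, payment incentives, on-screen animation, or the original
study's actual template values (the fixture's are validated synthetic
values).  A
green acceptance suite therefore establishes that the estimators recover
the structures they target in this stated world — not that the original
behavioral estimates are reproduced, which would require the original
data.

## Known limitations

* The G²-difference reference for boundary restrictions is conservative
  (see above); a parametric bootstrap would be the cross-check of choice.
* The shared-across-conditions test counts 3 df; the source reports the
  analogous test with 2, which we cannot reconcile from the printed
  information alone.
* Grid-search estimates are resolution-limited by design; refinement
  passes narrow but never leave the incumbent's bracket.
* Simulated TE participants' patterns are correlated across templates
  (one latent profile per half); pooled pattern counts remain marginally
  TE-distributed, matching the aggregate fitting strategy, but are not
  independent draws.
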