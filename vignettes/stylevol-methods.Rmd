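---
title: "Models and methods behind stylevol"
author: "stylevol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stylevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stylevol)
```

## The scientific problem

Style-length polymorphism — heterostyly and related discrete stylar
conditions — is a rare floral syndrome (roughly 2% of angiosperm genera)
that has evolved repeatedly across flowering plants. Reconstructing how
often it was gained and lost, when, and which floral and pollination traits
co-evolved with it requires three linked pieces of machinery on a
time-calibrated phylogeny:

1. a continuous-time Markov (Mk) model of a binary character, optionally
   with hidden rate categories to absorb lineage heterogeneity;
2. stochastic character mapping under the fitted model, to count and date
   individual gains and losses; and
3. Pagel-style four-state models of two binary characters, to compare
   dependent against independent evolution.

`stylevol` implements all three, plus the deterministic trait-coding rules
that turn raw floral measurements and pollinator records into binary
characters, and forward simulators that generate data with the same
statistical structure for calibration and validation.

## The Mk/HMM model

The character evolves on the composite state space observed x hidden.
With a binary character (M = monomorphic, P = polymorphic) and two rate
categories (R1, R2) the composite states are `M.R1, P.R1, M.R2, P.R2`,
ordered observed-fastest (`index = (hidden - 1) * n_obs + observed`). The
rate matrix \(Q\) holds instantaneous rates in events per Myr. Two
constraints are supported:

* **ER** (equal rates; for a binary trait this is the symmetric model):
  within each category the observed transitions share one rate; each
  category-switch direction is one parameter shared across observed states.
  Binary, 2 categories: 4 parameters.
* **ARD** (all rates different): every allowed transition has its own rate.
  Binary, 2 categories: 8 parameters (4 observed-state rates + 4 switch
  rates).

Simultaneous change of the observed state and the category is forbidden, a
standard identifiability restriction for hidden-rate models. The Pagel
models reuse exactly the same machinery on the joint state space
`(x, y) in {00, 01, 10, 11}` with simultaneous change of both traits
forbidden; "x depends on y" means x's rates vary with y's current state.

The likelihood is computed by Felsenstein's pruning algorithm over the
composite space. Missing or ambiguous tips contribute a partial likelihood
of 1 for every compatible composite state; an observed tip state is
compatible with every hidden category. Polytomies are handled as hard
multifurcations (the pruning product simply runs over all children).
Zero-length branches contribute an identity transition matrix.

**Root prior.** The default is flat over composite states; a
FitzJohn-style likelihood-weighted prior is available through
`root_prior = "fitzjohn"`. The flat prior is the conservative choice when
nothing is known about the root state, and the option is surfaced on every
fitting function because hidden-rate fits can be sensitive to it.

## Numerical choices

* **Transition probabilities.** \(P(t) = e^{Qt}\) is built from one
  eigendecomposition of \(Q\) per likelihood evaluation and reconstructed
  per branch, which is much cheaper than a matrix exponential per branch
  across thousands of edges; if \(Q\) is defective (repeated eigenvalues
  without a full eigenbasis, detected by a reconstruction-error check) the
  code falls back to a dense Padé `expmat` per branch. State spaces here
  are at most 8 x 8, so no sparse machinery is used.
* **Optimization.** Bounded quasi-Newton (`L-BFGS-B`) on log-rates. The
  first restarts are deterministic multi-scale starts (a heuristic rate of
  one expected event per root-to-tip path, times 1, 0.1 and 10), the rest
  random log-uniform; hidden-rate surfaces are multimodal and pure random
  restarts frequently missed the interior optimum. Ten restarts by default;
  the large simulation studies in the test suite use 1-6 restarts per fit
  to keep total runtime reasonable, which recovery results showed is
  sufficient at those problem sizes.
* **Rate bounds.** Rates are bounded in a box, by default
  \([10^{-9}, 100/H]\) events/Myr where \(H\) is the mean root-to-tip path
  length (i.e. at most 100 expected events per lineage). The upper bound is
  deliberately tree-scaled: unbounded hidden-rate likelihoods possess
  degenerate boundary optima in which one composite state flickers
  arbitrarily fast, mimicking a state mixture. Such fits can exceed interior
  optima in raw likelihood while carrying no biological meaning, and they
  inflate mapped transition counts without limit. Both bounds are
  user-settable.
* **Ultrametricity tolerance.** Node ages require equal root-to-tip paths
  within a relative tolerance, default `1e-3`, because published megatrees
  carry rounding noise. Tip-age noise below `1e-8` of tree depth is snapped
  to zero so present-day tallies are exact.
* **Ties and degenerate inputs.** AIC ties rank the model with fewer
  parameters first. Monomorphic tip data are fitted with a warning (the
  rate runs to the lower bound). Empty event samples are flagged rather
  than silently returned.

## Stochastic character mapping

Maps are sampled in two stages. Node states are drawn **jointly** by a
downward pass — the root from the posterior given the whole data, each
child conditional on its sampled parent and its own subtree partial
likelihoods — rather than independently from marginals, which would bias
transition counts. Branch paths are then drawn from the exact
endpoint-conditioned distribution by uniformization with dominating rate
\(\Omega = \max_i |Q_{ii}|\): the number of virtual jumps comes from its
exact conditional distribution, the jump states from the discretized chain
bridge, the jump times as uniform order statistics, and self-transitions
are discarded. Rejection sampling is not used anywhere; it is intractable
for rare-endpoint branches.

Gains and losses are defined on the observed layer only (M to P and P to M,
pooling hidden categories); category switches are counted separately.
Counts are summarized across maps as mean, median and percentile
(2.5/97.5, linear interpolation) intervals. Event ages are measured in Myr
before present; the age-density mode uses a Gaussian kernel with
Silverman's bandwidth on a 512-point grid over `[0, root age]` (the choice
of bandwidth rule is exposed). One master seed spawns one substream per
map, and each history records its map index and seed.

## Synthetic data: what it emulates and what it does not

`simulate_tree()` draws birth-death trees conditioned on the number of
extant tips (via `ape::rphylo`) and rescales them to a target crown age.
`simulate_traits()` runs the generative twin of the likelihood: a forward
Gillespie simulation of the composite-space chain down the tree, returning
tip states *and* the complete true history, so recovery tests can compare
inferred with true event counts.

`heterostyly_scenario()` bundles the study conditions: a 140-Myr crown age
(the approximate age of crown angiosperms), a binary trait starting
monomorphic in the slow category, and a two-category ARD truth with a
100-fold loss bias in the slow category R1 and a 2.7-fold loss bias in the
fast category R2 — the rate structure reported for style-length
polymorphism — with switch rates calibrated once, by forward simulation of
the generator alone, so that roughly 2% of tips are polymorphic (mean 2.4%,
range 1.5-3.7% over 15 seeds at 2000 tips). These defaults were frozen
before any estimator was run on the scenario and are not tuned to test
outcomes.

What the synthetic trees do **not** emulate: the topological imbalance of
real megatrees, fossil or extinct lineages, taxon-sampling artifacts, and
trait-dependent diversification (gains of the polymorphism do not alter
speciation or extinction here). Passing recovery tests therefore
demonstrates internal statistical correctness of the estimators under the
model class, not robustness to those real-data complications.

## Model selection and the correlated-evolution battery

The single-trait analysis fits the four-model grid (ER/ARD x 1/2 hidden
categories) and selects by AIC (`2k - 2 log L`). The correlated-evolution
analysis fits the eight-model Pagel battery: independent, x-on-y, y-on-x
and mutual dependence, each under ER and ARD. Dependent fits are
warm-started from the independent MLE of the same constraint, which both
speeds convergence and enforces the nesting inequality
\(\log L_{dep} \ge \log L_{indep}\). The "greater support" verdict uses a
\(\Delta AIC \ge 2\) margin by default (configurable); a likelihood-ratio
test of the nested ARD pair (mutual vs independent, 4 df) is reported as a
companion, since the AIC comparison alone has no size guarantee.

Problem sizes used by the validation suite: the likelihood oracle
enumerates all composite-state assignments on trees of up to 6 tips; rate
recovery uses 1000-tip trees over 20 seeds; the null-calibration study of
the dependence test uses 200 replicates of 300-tip trees; scenario recovery
uses 10 seeds at 2000 tips with 100 maps each. These sizes were chosen as
the smallest at which the Monte-Carlo tolerances of the corresponding
checks are meaningful.

## Known limitations

* Rates are maximum-likelihood point estimates; maps condition on the
  single best fit (as in the motivating analyses), so mapping intervals
  reflect mapping uncertainty only, not parameter uncertainty.
* Hidden-rate parameters are weakly identified when the derived state is
  rare; the AIC grid frequently (and correctly) prefers the one-category
  models at moderate tree sizes. Fitted rates from two-category models
  should be interpreted with care even when that model wins.
* The LRT's chi-squared reference is asymptotic; with boundary-adjacent
  rates it is conservative.
* Trait coding implements the published thresholds with a strict
  "greater than" boundary convention (>5% fusion, >10 stamens, >5 carpels,
  >66% visits); exact-boundary cases go to state 0. Thresholds are
  arguments, so sensitivity analyses only change the coded column, never
  the pipeline.
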