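---
title: "Methods: state-dependent diversification on time-calibrated trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-dependent diversification on time-calibrated trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

divergrass asks a classic macroevolutionary question: does a binary trait —
the motivating case is C4 photosynthesis in grasses, coded 0 = C3 (ancestral
pathway) and 1 = C4 (derived pathway) — change the rate at which lineages
speciate and go extinct?  It attacks the question three ways on the same
time-calibrated phylogeny, plus the tree-assembly bookkeeping and the
simulators needed to validate everything offline.  This vignette records the
models, the tunable parameters, the numerical choices, and what the
synthetic data do and do not establish.

Throughout, trees are rooted, ultrametric `phylo` objects with branch
lengths in million years (My); node ages run backward from the present
(tips at age 0) and all rates are events · lineage⁻¹ · My⁻¹.

## The BiSSE model

The binary-state speciation–extinction (BiSSE) process gives each lineage a
state-dependent speciation rate λᵢ, extinction rate μᵢ, and transition
rates q₀₁ (gain) and q₁₀ (reversal).  Along each branch, backward in time,
the package integrates

* Eᵢ′ = μᵢ − (λᵢ + μᵢ + qᵢⱼ)Eᵢ + qᵢⱼEⱼ + λᵢEᵢ²
* Dᵢ′ = −(λᵢ + μᵢ + qᵢⱼ)Dᵢ + qᵢⱼDⱼ + 2λᵢEᵢDᵢ

where Eᵢ is the probability that a lineage in state *i* leaves no sampled
descendant and Dᵢ the likelihood density of the observed subtree.  At each
node the daughters combine as Dᵢ ← λᵢ Dᵢᴸ Dᵢᴿ; the root applies one of four
treatments (likelihood-weighted state mixing by default, with flat,
transition-equilibrium and given-state options) and, optionally,
conditioning on survival of both root lineages.  The default is weighted
mixing with no survival conditioning; both are exposed as arguments because
different conventions circulate and the sensitivity is worth reporting in
any reanalysis.

Missing diversity is handled in the two standard ways:

* **proportional sampling** — every tip is one sampled species and a global
  sampling fraction `f` enters the tip initial conditions (Dᵢ = f·1[state],
  Eᵢ = 1 − f).  Grass-scale analyses use f ≈ 0.297 (fraction of accepted
  species present in the tree).
* **terminally unresolved clades** — a tip stands for a clade of known
  species richness (and, when known, per-state tallies).  Its initial
  condition at the stem is the probability of exactly those counts under
  the two-state linear birth–death-transition process, obtained by
  integrating the joint master equation over lineage counts (n₀, n₁)
  truncated at `cap = richness + 200` lineages.  Probability mass escaping
  the truncation above `mass_tol = 1e-7` raises an error rather than a
  silently wrong likelihood.  Because the richness distribution is
  geometric-tailed, the truncation is only adequate when
  (net rate) × (stem age) ≲ 2.5 at the default cap — comfortably satisfied
  by genus-level tips, which is the intended use; raising `cap_extra` buys
  deeper stems at quadratic cost in states.

The model family is the usual quartet: equal diversification (λ and μ both
shared; 4 free parameters), equal speciation (5), equal extinction (5) and
full (6).  Fitting maximizes the log-likelihood over log-rates with bounded
quasi-Newton (`L-BFGS-B`) from five deterministic starting points — fixed
multiplicative perturbations of a moment estimate (a Yule-flavoured net
rate, 50% relative extinction, and a parsimony-based transition rate).
Nested models are compared by likelihood-ratio tests (χ² with Δk degrees of
freedom) and by AIC/AICc; replicate tree sets yield the per-tree net-rate
and LRT histograms with χ² reference lines at α = 0.05, 0.01, 0.005.

### Numerical choices

* Branch ODEs: adaptive Dormand–Prince 5(4), `rtol = 1e-8`,
  `atol = 1e-10`, implemented in C++ (this is the hot loop; a 500-tip
  likelihood costs ~5 ms).  The step size is additionally capped at
  1/(Σ rates): beyond that kinetic scale the embedded error estimate can
  read small while the true error is large, which we observed as
  likelihood drift on branches hundreds of My long.
* D is renormalized whenever it leaves [1e-50, 1e+50], accumulating an
  exact log factor, so underflow on long branches or huge trees cannot
  occur; this replaces ad hoc clade-merging workarounds for "excessively
  small state probabilities".
* Tests verify the integrator against a fixed-step RK4 oracle, the
  analytic cherry likelihood, state-relabeling symmetry, and the reduction
  of the equal-rates model to the constant-rate birth–death closed form.

## Piecewise birth–death shift detection

The MEDUSA-style analysis models a (typically genus-level) tree whose tips
carry assigned species richness with piecewise constant birth–death
regimes, each parameterized by net diversification r = λ − μ and relative
extinction ε = μ/λ ∈ [0, 0.999].  With β(t) = (e^{rt} − 1)/(e^{rt} − ε) and
E(t) = εβ(t), a regime's log-likelihood is

* one log λ per internal branch end (the root split is conditioned upon,
  not counted),
* the reconstructed-process factor log Ψ(t_old) − log Ψ(t_young),
  Ψ(t) = (1 − E)(1 − β), per resolved internal branch,
* the unconditional clade-size probability Ψ(t) β^{n−1} per richness datum
  at stem age t — at n = 1 this is exactly the pendant-branch factor, so a
  tree with all richness 1 is an ordinary resolved birth–death fit,
* minus log(1 − E) per basal lineage when conditioning on survival
  (default on; under a pure-birth regime this term vanishes, giving the
  textbook Yule identity λ̂ = internal nodes / total branch length, which
  the tests verify to 1e-6).

The survival-conditional geometric law (1 − β)β^{n−1} is also exposed
directly as `richness_loglik()`.

A shift placed on a branch governs that branch and its entire subtree
(stem-inclusive) except where a more tipward shift takes over.  Model size
is k = 2 × regimes + (regimes − 1) shift locations, and AICc uses
n_obs = internal nodes + richness data.  `stepwise_search()` adds shifts
greedily: every candidate branch is scored by splitting its regime
(screening fits start from the parent regime's optimum), the winner is
refit from three deterministic starts, and the shift is accepted only if
AICc improves by at least the threshold.  Thresholds are always explicit;
8.4547, 10.5 and 17 are the conventional presets for genus-level and very
large trees.  Ties are broken toward older stem ages, then edge order, for
determinism.  Per-regime (r, ε) are maximized over (log r, logit ε) with
Nelder–Mead.

## Sister-clade contrasts

Under irreversible-gain parsimony every maximal connected set of
derived-state tips marks one origin.  For each origin whose sister clade
contains only ancestral-state tips (no derived, no unknown), the pair of
summed richnesses enters a Wilcoxon signed-rank test on log richness
differences.  Zero differences are dropped with n reduced; ties get
midranks.  For n ≤ 25 the null distribution is exact — the 2ⁿ sign
patterns are enumerated by convolution over the (doubled, integerized)
ranks — and above that a normal approximation with continuity and tie
corrections takes over.  One- and two-sided p-values are both reported
because published analyses are not always explicit about sidedness; the
p-value is invariant to the log base and to rescaling all richnesses, since
signs and ranks are unchanged.

## Tree assembly and richness bookkeeping

Composite trees are built by rescaling separately calibrated subtrees to a
target root age (every branch × target/current, preserving all age ratios)
and grafting them over two-tip placeholder cherries in a backbone, with the
stem age preserved and the inserted crown age explicit.  Genus collapsing
keeps one representative per genus carrying the genus's total richness,
with three refinements: mixed-state genera are divided into the minimum
number of state-pure monophyletic blocks (computed on the genus-induced
subtree); genera above 190 species are split among
⌈size/190⌉ representatives; and designated polyphyletic genera (the
*Panicum* situation) have their total spread equally over all their tips
before blocks are collapsed.  Where an even split is fractional, integer
richness is restored by largest-remainder division (550 over 3 → 184, 183,
183) because the richness likelihoods need integer counts; the
representative of a block is the lexicographically first label unless a
custom policy is supplied.  Every rule conserves summed richness exactly,
and the tests enforce this together with ultrametricity across random
compositions of scale/graft/collapse.

## Synthetic data: what it emulates, and what it does not

All validation runs on forward Gillespie simulations:

* `simulate_bisse_tree()` — state-dependent birth–death-transition
  simulation from a root split, run to a fixed age or a target tip count,
  with extinct lineages pruned and optional Bernoulli(f) subsampling.
  When stopping at a tip count, the run is cut at a uniformly drawn point
  of the sojourn interval at that count rather than at the event itself;
  cutting at the event systematically truncates the last waiting time and
  we measured it biasing relative-extinction estimates from ≈0.5 to ≈0.05
  on 300-tip trees.  Replicates with fewer than two surviving tips (or a
  dead root side, when stopping by age) are re-simulated by continuing the
  random stream, up to 1000 attempts.
* `simulate_piecewise_bd()` — single-character version with one planted
  regime shift at a given age on a uniformly chosen extant lineage,
  returning the ground-truth shifted clade and stem branch for power
  studies.
* `collapse_simulated_genera()` — deterministic genus emulation: maximal
  monophyletic blocks of at most `block_cap` tips become richness-carrying
  representatives (block sizes therefore vary naturally up to the cap).
* `perturb_tree_set()` — node-age jitter on the relative position of each
  internal node between the present and its parent's age, preserving the
  root age and all orderings: a cheap stand-in for posterior tree samples.

The default BiSSE simulation rates (λ = 0.69/0.57, μ = 0.55/0.33,
q₀₁ = 0.0068, q₁₀ = 1e-4) are the PACMAD-scale full-model estimates under
macrofossil dating, so that "default" synthetic trees look like the real
use case: high turnover, rare reversals, a faster derived state.  The
validation scenarios deliberately use milder, well-separated rates
(λ = 0.2/0.4, μ = 0.1/0.2, q = 0.05) so that every rate is of a magnitude
where relative error is meaningful.

Synthetic trees are exactly ultrametric, exactly binary, with exchangeable
tips — they do not emulate topological error, calibration uncertainty
beyond node-age jitter, gene-tree conflict, or non-random taxon sampling.
Passing tests therefore demonstrate correctness of the likelihoods and
estimators under their own generative assumptions, not robustness to the
violations real grass phylogenies contain.

### Problem sizes and what the validation shows

The test suite fits the full model on 20 simulated trees of ~500 tips,
calibrates the likelihood-ratio test on 200 null simulations of ~80 tips,
and runs 50 + 50 shift-detection replicates on trees of ~150–400 tips —
sizes at which each likelihood evaluation is milliseconds and each fit a
few seconds, chosen as the smallest scale at which the sampling properties
of interest are visible.  Two honest findings from this calibration are
worth recording:

* Speciation rates and the *direction* of the net-rate contrast recover
  well (median λ error ≲ 15%, sign of r₁ − r₀ right in ≳90% of
  replicates), and the LRT's type-I error sits inside its binomial band.
* Extinction-rate point estimates from single reconstructed trees of this
  size have very large sampling variance (median relative error ≈30–70%,
  two-sided across replicates, with the matched single-type (r, ε)
  estimator unbiased on the same simulations).  This is the well-known
  hardness of separating μ from λ in reconstructed phylogenies, not an
  implementation artifact; conclusions should rest on net-rate contrasts
  and model comparison, not on μ̂ itself.

## Known limitations

* Binary states only; no hidden states, multi-state characters, or
  cladogenetic state change.
* Unresolved-clade likelihoods are truncated-master-equation based and
  practical only for genus-scale richness and stem depths (see above).
* MEDUSA-style regimes are fit independently per piece, as is conventional;
  extinction probabilities are not propagated across regime boundaries.
* The stepwise search is greedy forward-only: no shift removal step.  Shift
  placement is stem-inclusive only (a shift governs its branch and subtree);
  a node-exclusive mode is not offered.
* Simulated "posterior" tree sets are age-jitters of one topology; they do
  not vary topology.
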