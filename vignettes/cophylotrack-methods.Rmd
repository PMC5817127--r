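---
title: "Testing phylogenetic tracking against host shifting: methods and design"
author: "cophylotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing phylogenetic tracking against host shifting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophylotrack)
```

## The scientific question

When a clade of host-associated organisms — here, the *Enchenopa
binotata* complex of treehoppers on North American host plants spanning
eight angiosperm orders — diversifies, two processes can generate an
association between the insect and plant phylogenies. Under
*phylogenetic tracking* (parallel cladogenesis), insect lineages
speciate with their hosts, so the two trees are congruent and ancestral
hosts carry ancestral insects. Under *host shifting*, insect lineages
colonize new host lineages; congruence is not expected, and shifts may
or may not favour closely related hosts. `cophylotrack` implements the
two complementary tests of these hypotheses:

1. an **event-based cophylogenetic reconciliation** of the symbiont tree
   onto the host tree under explicit event costs, with a
   random-tip-mapping permutation null; and
2. a **clade-rank co-phylogenesis test**: a Bayesian Poisson
   generalized linear mixed model (GLMM) asking whether more ancestral
   hosts (lower clade rank) carry more ancestral symbionts, with the
   host phylogeny as a structured random effect and the phylogenetic
   heritability H² as the summary of phylogenetic signal.

## The reconciliation model

A *tanglegram* is a rooted binary host tree, a rooted binary symbiont
tree, and a map from each symbiont tip to a non-empty set of host tips.
A *reconciliation* embeds the symbiont tree into the host tree,
assigning each internal symbiont node one of three events and charging
two further events along the way:

* **cospeciation** (phylogenetic tracking) — the symbiont speciates at a
  host speciation, its daughters descending into the two host daughter
  subtrees;
* **duplication** — the symbiont speciates on a single host lineage;
* **host switch** — one daughter stays, the other jumps to another host
  edge;
* **loss** — a host speciation crossed by a symbiont lineage without an
  event;
* **failure to diverge** — a symbiont tip associated with two or more
  hosts occupies the minimal host subtree spanning them: each internal
  node of that spanning subtree is charged one failure-to-diverge event
  and each edge leaving it one loss.

A reconciliation's cost is the dot product of its event counts with a
user-chosen cost vector ([`eventCosts()`]). The sensitivity analysis of
interest fixes cospeciation at 0 units and varies the host-switch cost
over 0, 1 and 2 units, with duplication, loss and failure to diverge at
1 unit (except the all-zero scheme, which also zeroes duplication —
[`costSchemes()`]). If phylogenetic tracking dominated the history,
optimal reconciliations should contain many cospeciations and few
switches at every cost setting.

### Exact dynamic program instead of heuristic search

The classic tools search reconciliation space with a genetic algorithm.
At the sizes relevant here (tens of tips), exact optimization is
affordable, so `reconcile()` is an exact dynamic program over
(symbiont node, host position) states with two auxiliary tables: an
*enter-subtree* table (minimum cost of placing a symbiont subtree at or
below a host position, accumulating one loss per host speciation
crossed) and a *jump-out* table (cheapest switch landing). Exactness is
strictly stronger than a search budget of "iterations × solutions", and
determinism makes every result reproducible. `enumerateOptima()`
backtracks through all optimal decision paths in a fixed order
(cospeciation < duplication < switch, host positions by canonical
label, "stop" before "descend"), so co-optimal reconciliations are
enumerated deterministically up to a cap.

Two design points deserve emphasis:

* **Timing.** The host tree is untimed. By default a switch may land
  only on a host position *incomparable* to its source (neither
  ancestor nor descendant) — the weakest constraint that forbids time
  travel along a single host lineage. Global time consistency across
  chains of switches is *not* enforced, as in most untimed
  reconciliation solvers; enforcing it is NP-hard. A flag
  (`switchConstraint = "unconstrained"`) removes the constraint.
* **The root.** The symbiont root may start anywhere on the host tree
  with no charges above its starting point; losses are only counted
  below it.

`bruteForceReconcile()` is an independent oracle: it exhaustively
enumerates complete placement vectors (every internal symbiont node on
every host position) and scores each locally, with no shared code path
with the dynamic program beyond elementary tree tables. The test suite
verifies exact agreement on hundreds of random instances; the oracle is
guard-railed to seven tips per tree.

### The permutation null

`permutationTest()` compares the observed optimal cost against the cost
distribution under *random tip mapping*: each symbiont tip is
independently reassigned to a uniform random host tip. The test is
one-sided (lower cost counts as more extreme). Monte-Carlo mode uses
add-one smoothing, `p = (1 + #{null <= obs}) / (B + 1)`, so p is never
exactly zero; exhaustive mode enumerates all |hosts|^|tips| mappings
(guarded at 10^6) and needs no smoothing. A `permute_observed` variant
of `randomTipMapping()` shuffles the observed host multiset instead,
for users who want to condition on observed host usage.

## The clade-rank GLMM

Divergence times are rarely available for both trees, so relative
taxon age is proxied by *clade rank*: the number of speciation events
(internal nodes) between the root and a tip. Under co-phylogenesis,
symbiont clade rank should increase with host clade rank. The model is

$$y_i \sim \mathrm{Poisson}(\exp(\beta_0 + \beta_1 x_i + a_{h(i)} +
g_{c(i)} + e_i))$$

with $y_i$ the symbiont clade rank, $x_i$ the host clade rank, $a \sim
N(0, V_{\mathrm{phylo}} C)$ a random effect structured by the host
phylogenetic correlation $C$, $g \sim N(0, V_{\mathrm{genus}} I)$ a
host-genus effect absorbing unbalanced sampling across genera, and
$e_i \sim N(0, V_{\mathrm{resid}})$ an observation-level residual
capturing overdispersion. Phylogenetic heritability is computed per
posterior draw as

$$H^2 = \frac{V_{\mathrm{phylo}}}{V_{\mathrm{phylo}} +
V_{\mathrm{genus}} + V_{\mathrm{resid}}},$$

the λ-analogue with all modeled variance components in the
denominator. Whether the genus variance belongs in the denominator is a
judgement call; both variants are reported
(`phylogeneticHeritability(fit, "noGenus")`).

The correlation matrix (`phyloCorrelation()`) has entries
"shared root-to-tip path length / maximum depth"; for cladograms,
Grafen's method first assigns node heights proportional to descendant
tip counts. When clade ranks are counted on an order-level tree, hosts
within an order share that order's taxon in $C$ (several records map to
one row), which keeps $C$ positive definite.

### Priors and sampling

Variance components get scaled inverse-chi-squared priors with scale
`V = 1` and degree of belief `nu = 0.02` (equivalently inverse-gamma
IG(ν/2, νV/2)), the weakly-informative default of the classic animal
model software; fixed effects get N(0, 10^10). The sampler
(`fitPoissonPGLMM()`, implemented in C++) is Metropolis-within-Gibbs:

* adaptive random-walk updates of every fixed and latent effect
  (step sizes tuned toward 44% acceptance during burn-in, frozen
  afterwards so the post-burn-in chain is a valid Markov chain);
* a *centered* slope proposal that shifts the intercept by
  $-d \bar{x}$ when the slope moves by $d$, walking along the weakly
  identified direction;
* likelihood-invariant *translation* moves that shift the intercept
  into each random-effect block (leaving every linear predictor
  unchanged, accepted on the prior ratio alone) — these are what make
  the intercept and the variance components mix well despite the
  intrinsic confounding of an intercept with random-effect means;
* conjugate inverse-gamma updates of the three variance components.

Default chain settings are 3 chains × 10^5 iterations, burn-in
2 × 10^4, thinning 50. This targets the identical posterior as an
arbitrarily long run and is sized so that a full 40-replicate
calibration study completes in about two minutes; Gelman–Rubin
potential scale reduction factors (`gelmanRubin()`, computed from the
within/between-chain variance decomposition) stay below 1.1 for all
reported parameters in the package's recovery simulations. Users who
want the heavy settings of classic analyses (5 × 10^6 iterations) can
simply pass them.

With zero records the sampler draws the variance components from their
priors — a prior-predictive check used by the test suite (with a prior
proper enough to have a mean: for ν ≤ 2 the scaled inverse-chi-squared
has infinite mean, so the default ν = 0.02 cannot be checked this way).

## The synthetic-data generators

`simulateHostTree()` draws ultrametric Yule trees with unit birth rate:
from the root split, k lineages wait Exp(k) to the next split; after
the n-th lineage the process holds a final Exp(n) before cutting all
tips, so the expected height is $\sum_{k=2}^{n} 1/k$ — a convention
chosen so the height has a simple closed form to test against. The
generator is hand-rolled rather than delegated because the joint
cophylogeny simulator needs the absolute event times.

`simulateCophylogeny()` is the generative converse of the
reconciliation model: one symbiont lineage enters at the host root;
at each host speciation it cospeciates with probability
`pCospeciation` (default 0.8) or follows one uniform daughter
(recording a loss); switches and duplications arrive along edges as
Poisson processes; on host cherries a lineage may instead persist on
both tips as one widespread tip (failure to diverge). Every event is
written to a ledger, so the true event counts are known and the
identity "cospeciations + duplications + switches = internal symbiont
nodes" holds by construction. Because the simulator knows true times,
its switch recipients are always contemporaneous — stricter than the
untimed solver's incomparability rule, which lets the tests measure the
cost of that relaxation. With `pCospeciation < 1` a realization can
collapse to a single surviving lineage; this degenerate single-tip
symbiont is returned as such and handled closed-form by the solver
(zero switches, which matches the zero switches in its ledger), so
fixed-seed replicate sweeps never abort.

`simulateCladeRankTable()` draws records from exactly the GLMM above:
host clade ranks from the tree, genus labels from the clades hanging
three splits below the root (small blocks of congeners, matching the
genus-to-host ratio of real association tables, e.g. 10 genera over 15
hosts in the packaged study table), and responses from the stated
Poisson model.

What the simulations do *not* emulate: host extinction and incomplete
sampling, within-host-lineage symbiont extinction, gene-tree error in
the symbiont phylogeny (the study's own symbiont tree has many weakly
supported nodes), and non-uniform switch target preferences. Passing
recovery tests therefore demonstrate correctness of the inference
machinery under the model, not robustness to tree error.

## Study conditions used by the automated checks

The acceptance checks (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run at these problem sizes, chosen once as
realistic desk-scale analogues of the study:

* solver-vs-oracle agreement: 200 random tanglegrams of 3–6 tips per
  tree with random integer costs in [0, 3];
* congruence identity: 50-tip identical trees under all three cost
  schemes;
* permutation exactness: the congruent 3-tip tanglegram (27 mappings
  exhaustively; 9,999 Monte-Carlo draws);
* switch recovery: 100 simulated tanglegrams on 10-tip hosts with
  switch rates {0, 0.5, 1, 2} and cospeciation probability 0.8;
* GLMM recovery: 20 replicates at β₀ = 1, β₁ = 0.5, V_phylo = 0.3,
  V_genus = 0.1, V_resid = 0.1, with 20 host taxa × 5 records
  (n = 100) — twenty taxa because the number of *taxa*, not records,
  is what identifies a cross-taxon slope; GLMM null calibration: 20
  replicates at β₁ = 0, V_phylo = 0 on 10 taxa × 5 records (n = 50).

## Numerical choices and edge cases

* Cost comparisons use an absolute tolerance of 10^-7; costs are
  user-supplied non-negative reals.
* Ties in backtracking are broken cospeciation < duplication < switch,
  then by canonical host position (smallest descendant tip label,
  ancestors first) — deterministic output for identical input.
* Polytomies are rejected at tanglegram construction, not silently
  resolved: reconciliation event semantics assume binary trees.
* Host names at genus level (e.g. "Carya") are single host taxa,
  matching the host tree's tips. Unknown-host records are retained in
  association tables, flagged `unmapped`, and excluded from
  tanglegrams via `dropUnmapped = TRUE` with a reported count.
* `phyloCorrelation()` forces an exact unit diagonal; for
  non-ultrametric input trees the off-diagonal entries remain raw
  shared-path fractions, so an ultrametric (or Grafen) tree is the
  intended input.
* The widespread-tip (failure-to-diverge) rule charges one event per
  internal node of the spanning subtree *including* pass-through
  nodes, plus one loss per leaving edge, which is the simplest
  costable reading; the simulator only generates cherry-spanning
  widespread tips, for which all readings coincide.

## Known limitations

* Reconciliations are untimed; histories requiring globally
  time-consistent switch chains may be scored optimistically.
* The brute-force oracle (and hence direct verification) stops at 7
  tips per tree; beyond that, correctness rests on the DP's invariants
  (monotonicity, congruence identity, event-count identity, recovery
  simulations).
* Exhaustive permutation mode is exponential in symbiont tips and
  guarded at 10^6 mappings.
* The GLMM assumes the host correlation is known without error and
  treats clade rank — a topology-only quantity sensitive to sampling —
  as the age proxy; these are properties of the study design, not of
  the implementation.
* Reproducing the original study's headline event counts requires its
  symbiont phylogeny, which is estimated from sequence data outside
  the scope of this package; the packaged fixtures cover the host tree
  and the association table only.
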