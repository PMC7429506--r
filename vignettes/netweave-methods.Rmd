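---
title: "Motif-based alignment and seasonal dynamics of bipartite networks"
author: "netweave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-based alignment and seasonal dynamics of bipartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netweave)
```

# The problem

Plant–pollinator communities reorganise constantly within a season: species
enter as they come into flower or emerge, change who they interact with, and
leave again. A weekly census of interactions yields a *time series of
weighted bipartite networks*, and the question netweave addresses is how the
*structural position* of each species — the way it is embedded in the web of
interactions — moves through that series. The pipeline has five stages:

1. **Weekly networks** (`load_records()`, `aggregate_weekly()`): interaction
   records are summed per (season, week, plant, pollinator); edge weight is
   the number of events observed that week. `to_binary()` produces the
   qualitative counterpart (all weights 1) for robustness comparisons.
2. **Motif roles** (`enumerate_motifs()`, `census_roles()`): each species is
   described by the number of times it occupies each *position* (orbit) in
   all connected guild-labelled bipartite motifs of 3–5 species.
3. **Alignment** (`align()`, `repeat_align()`): two networks are compared by
   pairing species whose roles correlate, via stochastic optimisation.
   Repeated self-alignments measure position *uniqueness*; repeated
   cross-week alignments measure position *variability*
   (`uniqueness()`, `variability()`, `fixed_pair_loss()`).
4. **Position groups** (`build_alignment_matrix()`, `detect_groups()`): all
   alignments are compiled into a similarity matrix over (network, species)
   occurrences, and short-random-walk community detection extracts recurring
   kinds of positions, characterised by relative-degree statistics
   (`group_properties()`).
5. **Structural dynamics** (`build_state_sequences()`,
   `fit_transition_model()`): per-week group memberships become state
   trajectories over `{group 1..n, pre, post}`, and a Bayesian multinomial
   logistic model estimates time-dependent transition probabilities among
   the states, including network entry and exit.

# Motif roles

A motif is a connected bipartite graph on 3–5 species in which plants and
pollinators are *never* interchangeable (a plant visited by two pollinators
is a different motif from a pollinator visiting two plants). Within a motif,
nodes that can be mapped onto each other by a guild-preserving automorphism
form one *position*. For sizes 3–5 there are 16 motifs carrying 44
positions:

```{r}
cat35 <- enumerate_motifs(3, 5)
cat35
table(cat35$positions$size)
```

Motifs are stored canonically (lexicographically minimal biadjacency
encoding over within-guild permutations), which keeps position indices
stable across networks and runs. Occurrences are counted on *induced*
connected subgraphs, the standard convention in bipartite motif analysis.
In weighted mode each occurrence contributes the arithmetic mean of its
edge weights (configurable to sum or geometric mean) rather than 1, so
roles carry interaction-strength information; a uniform re-weighting of the
whole network therefore rescales all role vectors linearly, and Pearson
role correlations are unaffected by the overall sampling intensity.

The census itself runs in compiled code (an ESU-style enumeration of
connected induced subgraphs with canonical-form lookup); the test suite
checks it against a brute-force subset census driven by igraph's VF2
isomorphism matching.

# Alignment

Given role matrices of networks A and B, the role correlation
$c_{ij} \in [-1, 1]$ of a candidate pair is the Pearson correlation of the
two role vectors (0 when either has no variance). A guild-respecting
one-to-one pairing $\lambda$ has cost

$$C_\lambda = \sum_{(i,j) \in \lambda} (1 - c_{ij}) +
  p \cdot \#\{\text{unmatched species}\},$$

with $p = 1$ by default — being unpaired costs as much as pairing with an
uncorrelated partner. With equal guild sizes a maximal pairing has no
unmatched species; with unequal sizes every surplus species on either side
counts once. The optimiser is simulated annealing over pairings: moves swap
the partners of two species of a guild (including swaps with unpaired
ones), temperature starts at `t0 = 1` and cools geometrically
(`0.995`/sweep, 500 sweeps), and the best pairing encountered is polished
by greedy descent. The guild sub-problems are independent, so each guild is
annealed separately.

Two numerical points matter. First, equally optimal pairings are common —
they are exactly the internal symmetries the uniqueness statistic is after —
so single runs are never trusted: ensembles of restarts
(`repeat_align()`, default 100, seeds `base_seed + 0..N-1`) expose the
alternatives. Ties are *not* broken deterministically; during annealing
equal-cost moves are accepted freely, and the best state is only replaced
on strict improvement, so restarts land on symmetric optima with
approximately equal frequency. Second, on small instances (≤ 6 species per
guild) the exhaustive optimum is computable, and the test suite requires
the 100-restart cost to reach it in ≥ 95% of fixtures.

**Uniqueness** of a species is the fraction of self-alignment runs pairing
it with itself: 1 for a structurally unique position, ≈ 1/k inside an
automorphic class of k species. **Variability** is the fraction of
(week-pair, run) alignments — over pairs of networks that both contain the
species — in which it is *not* paired with itself; species present in
fewer than two weeks are excluded. A species left unpaired in a run counts
toward variability (it did not retain its position) — the definition is
"not self-paired", which coincides with "paired to a different species"
whenever guild sizes match. **Fixed-pair loss** re-runs the optimisation
with one species forced to pair with itself and reports the increase of
the best cost over the same number of restarts.

# The alignment matrix and position groups

Every (network, species) occurrence is a row/column of the alignment
matrix M. For occurrences $i \in A$, $j \in B$,

$$m_{ij}^{AB} = \underbrace{\frac{\#\{\text{runs pairing } i,j\}}{N}}_{\text{frequency}}
  \times \underbrace{\overline{\max(c_{ij}, 0)}}_{\text{quality}}
  = \frac{1}{N} \sum_{\text{runs pairing } i,j} \max(c_{ij}, 0),$$

bounded in [0, 1], symmetric, exactly 0 across guilds; diagonal blocks come
from self-alignment ensembles. A frequency-only weighting is available for
sensitivity checks. Because M is block-diagonal by guild, community
detection runs per guild: `detect_groups()` applies walktrap (short random
walks, default length 4) to the weighted occurrence graph and cuts the
merge tree at maximal modularity. Agreement with any alternative partition
can be quantified with `compare_partitions()` (NMI, arithmetic-mean entropy
normalisation by default; min/max available).

Groups are characterised by weight-independent degree statistics computed
in each occurrence's own weekly network: relative degree
$k_i = l_i / l_{\max}$ (distinct partners over the network maximum), the
relative degree of the most connected partner $\max\{k^i\}$, and the mean
partner relative degree $\langle\{k^i\}\rangle$. Group labels A, B, C … are
assigned per guild by descending group mean of $\max\{k^i\}$ (ties by mean
$k_i$) — a stable, documented ordering; ecological readings such as
"specialists attached to generalists" are recovered descriptively from the
summaries, never assumed. `degree_sensitivity()` checks the robustness of
$k_i$ to random removal of interaction events, and
`abundance_regression()` reports how much relative-degree variation is
*not* explained by abundance.

# The transition model

For a guild with $n$ groups, each species occupies one of $n + 2$ states
per sampled week: its group, `pre` (not yet entered) or `post` (exited,
absorbing). Relative time is $t = w / W$ with $w$ the 1-based position
among the season's sampled weeks. The probability of moving to state $j$
from state $y_i$ at time $t$ is a softmax over linear scores

$$s_k(y_i, t) = \alpha_{k1} + \beta_{k1} t +
  \sum_{l \ge 2} (\alpha_{kl} + \beta_{kl} t)\, \delta_{il},$$

with the score of `post` fixed to 0 as the arbitrary baseline (inference
is invariant to this choice) and group 1 the reference origin carried by
the intercept column. Structural zeros are enforced by restricted choice
sets rather than penalised scores: from `pre` the destinations are the
groups or `pre` itself; from a group, the groups or `post`; `post` is
never an origin and `pre` never a destination after entry. Re-entry being
impossible by assumption, an observed presence–absence–presence pattern is
treated as a sampling artefact: the absent weeks are flagged as gaps and
every transition touching a gap week is excluded from the likelihood. A
species present in the final sampled week contributes no exit transition
(right-censored) — no observation can distinguish staying from leaving
after sampling stops.

All free $\alpha, \beta$ get independent Normal(0, 10) priors (weakly
informative). The constant variant fixes all $\beta = 0$. One direction of
the entry row (a joint shift of all pre-origin scores) is not identified by
data and is constrained only by the prior; predicted probabilities are
unaffected.

**Sampling.** The posterior is smooth and nearly Gaussian, so the fitter
finds the mode (BFGS with analytic gradients), takes the Laplace
approximation there, and runs adaptive Metropolis chains preconditioned on
its Cholesky factor, mixing in occasional independence proposals from the
scaled approximation (with exact Metropolis–Hastings correction). Defaults:
4 chains × 2000 iterations, half warm-up. Split-Rhat is computed per
parameter and a warning is raised above 1.1. The test suite cross-checks
posterior means against an independent Gibbs sampler (JAGS) and verifies
calibration by simulation: with data generated from a known constant
matrix, true probabilities fall in 95% credible intervals at the nominal
rate.

`waic()` computes $-2(\widehat{\text{lppd}} - p_\text{WAIC})$ from the
pointwise posterior log-likelihoods; `predict_curves()` returns posterior
means and quartiles of every origin → destination probability over a time
grid (rows sum to 1 per draw by construction). Season-replicate variants
can be fitted by passing per-season event subsets; the headline model
pools all seasons.

# The synthetic generator

`generate_series()` produces communities in which every pipeline stage has
known ground truth. Species evolve through the state space under a
configured transition law (a constant matrix or time-dependent scores), so
phenology windows *emerge* from entry and exit dynamics and the
no-re-entry rule holds in the latent truth by construction. Each week,
active species realise edges from group-specific degree regimes: a species
seeks `1 + Poisson` partners around its group's mean degree and samples
them proportionally to partner attractiveness raised to a per-group bias
exponent — positive for preferential attachment to well-connected
partners, negative for the anti-preferential regime. This reproduces the
three qualitative group signatures (few partners/high-degree partners,
many/high, few/low) without committing to mechanisms beyond degree.
Weights are `1 + Poisson(2)` by default. A lognormal abundance mark is
coupled to the per-species degree propensity with configurable strength
(`abundance_r2`), so abundance predicts degree only partially. Optional
detection dropout (default 2% per species-week) removes a present species'
observations for one week, creating exactly the interrupted-phenology
patterns the gap rule must discard — on top of continuous latent presence.

Default dimensions emulate the study system scale: 3 seasons of 12, 15 and
16 sampled weeks, 46 plants and 93 pollinators, 3 groups, entry
concentrated in the low-degree/high-partner-degree group. The default
constant law keeps the generalist group persistent (stay 0.70) and makes
exits most likely from the two specialist groups, echoing preferential
attachment and detachment.

What the generator does *not* emulate: taxonomic composition, the exact
empirical weight distribution, plant flowering-abundance seasonality, and
observation effort varying across weeks. Tests passing on synthetic data
therefore establish correctness of the algorithms and calibration of the
inference, not ecological conclusions about any particular system.

# Study sizes used by tests and the acceptance script

The scripted runs use reduced problem sizes chosen to keep the full
pipeline comfortably reproducible on a single CPU while leaving every
stage statistically meaningful: the alignment pipeline runs on 2 seasons ×
8 weeks with 12 plants and 20 pollinators at 50 restarts per network pair
(the per-pair restart default inside analyses remains 100, the value used
for all uniqueness/variability statistics); transition-model recovery uses
150 species-seasons per replicate with 4 chains × 3000 iterations; WAIC
comparisons use 100 species per replicate, 10 replicates per direction.
The exhaustive-search alignment oracles run on fixtures of at most 6
species per guild, where full enumeration over pairings is exact.

# Known limitations

- Annealing is heuristic; optimality is only guaranteed on the small
  fixtures where the exhaustive oracle verifies it. For large networks the
  ensemble-minimum cost is an upper bound on the true optimum.
- The cost functional and the frequency × quality weighting of M are
  package-defined conventions (monotone, bounded, zero at perfect
  self-alignment); other choices are plausible and the
  frequency-only mode is provided for sensitivity analysis.
- Group labels are per-guild orderings of *this* dataset's groups;
  comparing labels across datasets requires re-deriving the ordering.
- The transition model conditions on the detected grouping; uncertainty in
  the grouping itself is not propagated into the posterior.
- `pre`-row intercept/slope contrasts are only weakly identified (one flat
  direction constrained by the prior); report entry probabilities, not raw
  entry-row parameters.
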