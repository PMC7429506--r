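# netweave

Seasonal dynamics of bipartite ecological networks through motif-based
network alignment.

Plant–pollinator communities (and other bipartite mutualistic systems)
reorganise within a season: species enter as they emerge or flower, switch
interaction partners, and drop out again. Given weekly interaction records,
netweave treats the community as a **time series of weighted bipartite
networks** and asks how each species' *structural position* — the way it is
embedded in the web of interactions — moves through the season.

## The method

1. **Roles.** Every species is profiled by the number of times it occupies
   each position (automorphism orbit) of the connected guild-labelled
   bipartite motifs of 3–5 species — 16 motifs carrying 44 positions —
   with each motif occurrence weighted by its mean interaction strength.
2. **Alignment.** Two networks are aligned by a guild-respecting one-to-one
   pairing λ of their species minimising
   `C_λ = Σ_(i,j)∈λ (1 − c_ij) + #unpaired`, where `c_ij` is the Pearson
   correlation of the paired role vectors. The optimiser is simulated
   annealing; every pair of networks is aligned many times (default 100)
   because equally optimal pairings are informative, not noise:
   - **uniqueness** of a species = fraction of self-alignments pairing it
     with itself (internal symmetries give values near 1/k);
   - **variability** = fraction of cross-week alignments in which it does
     *not* keep its position.
3. **Position groups.** All alignments are compiled into a matrix `M` with
   entries `m_ij^{AB}` = pairing frequency × mean positive correlation over
   the ensemble; short-random-walk (walktrap) community detection on `M`
   yields recurring kinds of positions per guild, characterised by relative
   degree `k_i = l_i / l_max` and partner-degree statistics.
4. **Dynamics.** Per-week group memberships become state trajectories over
   `{group 1..n, pre, post}` (`pre` = not yet entered, `post` = exited,
   absorbing). Weekly transitions follow a Bayesian multinomial logistic
   model: `Pr(y_j | y_i, t) = exp s_j(y_i,t) / Σ_k exp s_k(y_i,t)` with
   linear scores `s_k(y_i,t) = α_k1 + β_k1 t + Σ_l (α_kl + β_kl t) δ_il`,
   `t ∈ [0,1]` the relative week, Normal(0, 10) priors, structural zeros for
   re-entry, and WAIC comparison against a constant-probability variant.

A synthetic-data generator with known ground truth (phenologies, planted
position groups, transition law, abundance–degree coupling) makes every
stage testable end to end.

## Worked example

```r
library(netweave)

# two seasons of weekly plant-pollinator networks with known ground truth
cfg <- synthetic_config(seasons = 2, weeks = c(8, 8),
                        n_plants = 12, n_pollinators = 20)
sim <- generate_series(cfg, seed = 1)
sim$series$S1
#> <network_series S1: 8 weekly networks (weeks 1,2,3,4,5,6,7,8)>

# motif catalogue and the role vector of one pollinator in week 3
cat35 <- enumerate_motifs(3, 5)
cat35
#> <motif_catalog sizes 3-5: 16 motifs, 44 positions>
net <- sim$series$S1$networks[[3]]
roles <- census_roles(net, cat35)
round(roles["A003", 1:8], 1)
#> pos1 pos2 pos3 pos4 pos5 pos6 pos7 pos8
#>  0.0 20.5  0.0  0.0  0.0 58.3  0.0  0.0

# position uniqueness within that week's network (100 self-alignments)
u <- uniqueness(net, roles, N = 100, seed = 1)
summary(u$value)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.5000  1.0000  1.0000  0.9565  1.0000  1.0000

# share of pollinators that change position between weeks (variability > 0.9)
ens <- align_week_pairs(sim$series$S1, N = 100, base_seed = 1)
v <- variability(ens)
round(mean(v$value[v$guild == "pollinator"] > 0.9), 2)
#> [1] 0.53
```

The uniqueness summary says most species occupy structurally unique
positions that week (value 1), while a minimum of 0.5 flags one pair of
species sharing a symmetric position. The role vector shows where species
`A003` sits inside 3–5-species motifs, strength-weighted. The last number
is the fraction of pollinators whose position is almost always different
when the same season's weeks are aligned against each other.

Downstream, `build_alignment_matrix()` + `detect_groups()` turn these
ensembles into position groups, `build_state_sequences()` +
`fit_transition_model()` estimate the entry/movement/exit probabilities,
and `predict_curves()` returns the posterior transition-probability curves
over the season. The methods vignette
(`vignettes/netweave-methods.Rmd`) documents the model, its assumptions,
all tunable parameters, and the numerical choices.

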