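# Synthetic bipartite network time series with known ground truth:
# phenology windows emerge from a latent state process over
# {group 1..n, pre, post} (post absorbing, no re-entry), weekly edges are
# realised from group-specific degree regimes with abundance-coupled but
# not abundance-determined degrees, and optional detection dropout injects
# the presence-absence-presence patterns the pipeline's gap rule must drop.

#' Configuration of the synthetic generator
#'
#' Defaults emulate the statistical structure of a subalpine
#' plant-pollinator study system: three summer seasons of 12, 15 and 16
#' sampled weeks, 46 plant and 93 pollinator species, three latent position
#' groups per guild with distinct degree regimes (group 1: few partners,
#' biased toward well-connected counterparts; group 2: many partners, also
#' biased toward well-connected counterparts; group 3: few partners, biased
#' toward poorly-connected counterparts), and entry concentrated in group 1.
#'
#' @param seasons number of seasons.
#' @param weeks integer vector (recycled) of sampled weeks per season.
#' @param n_plants,n_pollinators species pool sizes per guild.
#' @param n_groups number of latent position groups `n`.
#' @param transition either a constant row-stochastic matrix of dimension
#'   `(n+1) x (n+2)` (rows: origins groups 1..n then pre; columns:
#'   destinations groups, pre, post; structurally impossible cells must be
#'   0) or a list with `alpha`/`beta` matrices for time-dependent dynamics
#'   (see [score_linear()]).
#' @param init_probs length `n+1` probabilities of a species' state in the
#'   first week (groups 1..n, pre).
#' @param mean_degree per-group mean number of partners sought per week.
#' @param partner_bias per-group exponent of preferential (`> 0`) or
#'   anti-preferential (`< 0`) partner sampling on partner attractiveness.
#' @param attractiveness per-group plant attractiveness weights.
#' @param weight_lambda weekly interaction counts are `1 + Poisson(lambda)`.
#' @param abundance_r2 target share of relative-degree variance explained by
#'   (log) abundance; the generator couples a lognormal abundance mark to
#'   the per-species degree propensity with this strength.
#' @param dropout per-(species, week) probability that a present species
#'   goes unobserved, creating an apparent gap on top of continuous latent
#'   presence.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seasons = 3, weeks = c(12L, 15L, 16L),
                             n_plants = 46, n_pollinators = 93,
                             n_groups = 3,
                             transition = NULL,
                             init_probs = NULL,
                             mean_degree = c(1.6, 5.0, 1.4),
                             partner_bias = c(1.5, 1.0, -1.5),
                             attractiveness = c(2.0, 6.0, 1.5),
                             weight_lambda = 2,
                             abundance_r2 = 0.35,
                             dropout = 0.02) {
  n <- as.integer(n_groups)
  if (is.null(transition)) {
    stopifnot(n == 3)
    transition <- rbind(           # G1      G2    G3    pre  post
      c(0.55, 0.15, 0.05, 0.00, 0.25),   # from G1
      c(0.20, 0.70, 0.05, 0.00, 0.05),   # from G2
      c(0.30, 0.05, 0.45, 0.00, 0.20),   # from G3
      c(0.30, 0.08, 0.07, 0.55, 0.00))   # from pre
  }
  if (is.null(init_probs)) {
    stopifnot(n == 3)
    init_probs <- c(0.25, 0.12, 0.08, 0.55)
  }
  cfg <- list(seasons = as.integer(seasons),
              weeks = rep_len(as.integer(weeks), seasons),
              n_plants = as.integer(n_plants),
              n_pollinators = as.integer(n_pollinators),
              n_groups = n, transition = transition,
              init_probs = init_probs,
              mean_degree = rep_len(mean_degree, n),
              partner_bias = rep_len(partner_bias, n),
              attractiveness = rep_len(attractiveness, n),
              weight_lambda = weight_lambda,
              abundance_r2 = abundance_r2, dropout = dropout)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  n <- cfg$n_groups
  stopifnot(cfg$seasons >= 1, all(cfg$weeks >= 1), cfg$n_plants >= 1,
            cfg$n_pollinators >= 1, n >= 1,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$abundance_r2 >= 0, cfg$abundance_r2 <= 1)
  if (is.matrix(cfg$transition)) {
    P <- cfg$transition
    stopifnot(nrow(P) == n + 1L, ncol(P) == n + 2L,
              all(P >= 0), all(abs(rowSums(P) - 1) < 1e-8))
    if (any(P[seq_len(n), n + 1L] > 0))
      stop("re-entry (group -> pre) must have probability 0")
    if (P[n + 1L, n + 2L] > 0)
      stop("direct pre -> post transitions are not modelled")
  }
  stopifnot(length(cfg$init_probs) == n + 1L,
            abs(sum(cfg$init_probs) - 1) < 1e-8)
  invisible(cfg)
}

# transition probability vector from origin o at time t under the config law
.law_probs <- function(cfg, o, t) {
  n <- cfg$n_groups
  if (is.matrix(cfg$transition)) return(cfg$transition[o, ])
  s <- score_linear(cfg$transition, o, t)
  allow <- seq_len(n + 2L) %in% allowed_destinations(o, n)
  transition_probability(s, allow)
}

#' Simulate latent state trajectories from a transition law
#'
#' Draws per-species weekly state sequences over
#' `{group 1..n, pre, post}` from a configured transition law (constant
#' matrix or time-dependent scores), starting from `init_probs` in week 1.
#' The output has the same shape as [build_state_sequences()], so
#' [transition_events()] applies directly — the route used for parameter
#' recovery of the fitted model.
#'
#' @param n_species number of species (trajectories).
#' @param W number of weeks.
#' @param cfg a `synthetic_config`.
#' @param season season label.
#' @param guild guild label.
#' @param species optional species names.
#' @param seed RNG seed.
#' @return A `state_trajectories` data.frame.
#' @export
simulate_trajectories <- function(n_species, W, cfg, season = "S1",
                                  guild = "pollinator", species = NULL,
                                  seed = 1) {
  n <- cfg$n_groups
  if (is.null(species))
    species <- sprintf("%s%03d", if (guild == "plant") "P" else "A",
                       seq_len(n_species))
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_species)) {
    st <- integer(W)
    st[1] <- sample.int(n + 1L, 1, prob = cfg$init_probs)
    for (w in seq_len(W - 1L)) {
      o <- st[w]
      if (o == n + 2L) { st[w + 1L] <- n + 2L; next }
      st[w + 1L] <- sample.int(n + 2L, 1,
                               prob = .law_probs(cfg, o, (w + 1) / W))
    }
    out[[i]] <- data.frame(season = season, species = species[i],
                           guild = guild, week = seq_len(W),
                           widx = seq_len(W), W = W, t = seq_len(W) / W,
                           state = st, gap = FALSE)
  }
  traj <- do.call(rbind, out)
  structure(traj, class = c("state_trajectories", "data.frame"),
            n_groups = n, state_labels = state_labels(n))
}

#' Generate a synthetic network time series with ground truth
#'
#' Species enter, move among latent position groups and exit according to
#' the configured transition law; active species realise weekly edges
#' according to their group's degree regime; counts are drawn from the
#' configured weight distribution. The emitted records round-trip through
#' [aggregate_weekly()].
#'
#' @param cfg a `synthetic_config`.
#' @param seed RNG seed (mandatory; the same seed reproduces the series and
#'   truth exactly).
#' @return List with `records` (long-format interaction records), `series`
#'   (the aggregated `network_series` list) and `truth` (latent
#'   trajectories per guild, per-species abundance and degree propensity,
#'   and the configuration).
#' @export
generate_series <- function(cfg, seed = 1) {
  validate_synthetic_config(cfg)
  n <- cfg$n_groups
  plants <- sprintf("P%03d", seq_len(cfg$n_plants))
  polls <- sprintf("A%03d", seq_len(cfg$n_pollinators))

  set.seed(seed + 777L)
  # per-species degree propensity and abundance, coupled with strength r2
  prop_p <- rnorm(cfg$n_plants); prop_a <- rnorm(cfg$n_pollinators)
  r <- sqrt(cfg$abundance_r2)
  ab_p <- exp(r * prop_p + sqrt(1 - r^2) * rnorm(cfg$n_plants))
  ab_a <- exp(r * prop_a + sqrt(1 - r^2) * rnorm(cfg$n_pollinators))
  mult_p <- exp(0.35 * prop_p); mult_a <- exp(0.35 * prop_a)

  rec <- list(); truth_tr <- list()
  for (s in seq_len(cfg$seasons)) {
    sname <- sprintf("S%d", s)
    W <- cfg$weeks[s]
    tr_p <- simulate_trajectories(cfg$n_plants, W, cfg, sname, "plant",
                                  plants, seed = seed * 131L + s)
    tr_a <- simulate_trajectories(cfg$n_pollinators, W, cfg, sname,
                                  "pollinator", polls,
                                  seed = seed * 131L + 500L + s)
    truth_tr[[sname]] <- rbind(tr_p, tr_a)
    st_p <- matrix(tr_p$state, nrow = cfg$n_plants, byrow = TRUE)
    st_a <- matrix(tr_a$state, nrow = cfg$n_pollinators, byrow = TRUE)
    set.seed(seed * 977L + s)
    for (w in seq_len(W)) {
      ap <- which(st_p[, w] <= n); aa <- which(st_a[, w] <= n)
      if (!length(ap) || !length(aa)) next
      attract <- cfg$attractiveness[st_p[ap, w]] * mult_p[ap]
      edges <- list()
      for (i in aa) {
        g <- st_a[i, w]
        m <- min(1 + rpois(1, max(cfg$mean_degree[g] * mult_a[i] - 1, 0)),
                 length(ap))
        pr <- attract^cfg$partner_bias[g]
        sel <- if (length(ap) == 1) ap else
          ap[sample.int(length(ap), m, prob = pr)]
        edges[[length(edges) + 1L]] <- data.frame(
          plant = plants[sel], pollinator = polls[i],
          count = 1L + rpois(length(sel), cfg$weight_lambda))
      }
      ew <- do.call(rbind, edges)
      # detection dropout on top of continuous latent presence
      if (cfg$dropout > 0) {
        drop_sp <- c(plants[ap][runif(length(ap)) < cfg$dropout],
                     polls[aa][runif(length(aa)) < cfg$dropout])
        ew <- ew[!(ew$plant %in% drop_sp | ew$pollinator %in% drop_sp), ,
                 drop = FALSE]
      }
      if (nrow(ew))
        rec[[length(rec) + 1L]] <- cbind(season = sname, week = w, ew)
    }
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  list(records = records, series = aggregate_weekly(records),
       truth = list(trajectories = truth_tr,
                    abundance = setNames(c(ab_p, ab_a), c(plants, polls)),
                    degree_propensity = setNames(c(prop_p, prop_a),
                                                 c(plants, polls)),
                    config = cfg, seed = seed))
}

#' Small alignment fixture with known correspondence
#'
#' Builds a random connected weighted bipartite network and a copy whose
#' species labels are permuted within guilds, so the ground-truth
#' correspondence is known (up to automorphisms of the base network).
#' Optionally injects one automorphic pollinator pair (two species with
#' identical neighbourhoods and weights) to exercise uniqueness below 1.
#'
#' @param n_plants,n_pollinators guild sizes of the base network (keep <= 8
#'   per guild so exhaustive-search oracles stay tractable).
#' @param permute relabel the copy (if `FALSE` the copy is identical).
#' @param symmetric_pair add a twin of one pollinator to both networks.
#' @param seed RNG seed.
#' @return List with `net_A`, `net_B` (`weekly_network`s, weeks 1 and 2 of
#'   one season), `mapping` (named character vector: species of A ->
#'   corresponding species of B) and `twins` (the automorphic pair, or
#'   `NULL`).
#' @export
make_alignment_fixture <- function(n_plants = 4, n_pollinators = 5,
                                   permute = TRUE, symmetric_pair = FALSE,
                                   seed = 1) {
  stopifnot(n_plants <= 8, n_pollinators <= 8)
  for (attempt in 0:24) {
    fx <- .alignment_fixture_once(n_plants, n_pollinators, permute,
                                  symmetric_pair, seed + 1000L * attempt)
    # accept only fixtures whose planted symmetry is the sole one: all
    # weighted role vectors distinct except (when requested) the twins
    roles <- round(census_roles(fx$net_A), 9)
    dup <- duplicated(roles) | duplicated(roles, fromLast = TRUE)
    ok <- if (symmetric_pair)
      setequal(rownames(roles)[dup], fx$twins) else !any(dup)
    if (ok) return(fx)
  }
  stop("could not build a fixture with the requested symmetry structure")
}

.alignment_fixture_once <- function(n_plants, n_pollinators, permute,
                                    symmetric_pair, seed) {
  set.seed(seed)
  plants <- sprintf("P%d", seq_len(n_plants))
  polls <- sprintf("A%d", seq_len(n_pollinators))
  # connected scaffold: each pollinator attached to a random plant, each
  # plant to a random pollinator; then extra random edges
  e <- unique(rbind(
    data.frame(plant = sample(plants, n_pollinators, TRUE),
               pollinator = polls),
    data.frame(plant = plants,
               pollinator = sample(polls, n_plants, TRUE))))
  extra <- expand.grid(plant = plants, pollinator = polls,
                       stringsAsFactors = FALSE)
  extra <- extra[runif(nrow(extra)) < 0.25, ]
  e <- unique(rbind(e, extra))
  e$weight <- sample(1:9, nrow(e), TRUE)

  twins <- NULL
  if (symmetric_pair) {
    cand <- polls[1]
    twin <- "A_twin"
    te <- e[e$pollinator == cand, ]
    te$pollinator <- twin
    # remove any structural overlap risk: twin duplicates cand exactly
    e <- rbind(e[e$pollinator != twin, ], te)
    twins <- c(cand, twin)
  }
  net_A <- weekly_network("S", 1, e)

  g <- network_guilds(net_A)
  if (permute) {
    mapping <- unlist(lapply(split(names(g), g), function(sp)
      setNames(sample(sp), sp)))
    names(mapping) <- sub("^(plant|pollinator)\\.", "", names(mapping))
  } else {
    mapping <- setNames(names(g), names(g))
  }
  e2 <- data.frame(plant = unname(mapping[e$plant]),
                   pollinator = unname(mapping[e$pollinator]),
                   weight = e$weight)
  net_B <- weekly_network("S", 2, e2)
  list(net_A = net_A, net_B = net_B, mapping = mapping, twins = twins)
}
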