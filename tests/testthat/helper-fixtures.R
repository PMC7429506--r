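# Small fixtures built in code.

# destination rule of the transition model, restated independently of the
# package internals: groups may move among groups or exit; pre may stay or
# enter a group
allowed_destinations_vec <- function(origin, n)
  if (origin <= n) c(seq_len(n), n + 2L) else c(seq_len(n), n + 1L)

# star: one plant with na pollinators (or reversed), given weights
toy_star <- function(na = 2, weights = rep(1, na), reverse = FALSE,
                     season = "S", week = 1) {
  if (!reverse)
    weekly_network(season, week,
                   data.frame(plant = "P1",
                              pollinator = paste0("A", seq_len(na)),
                              weight = weights))
  else
    weekly_network(season, week,
                   data.frame(plant = paste0("P", seq_len(na)),
                              pollinator = "A1", weight = weights))
}

# random connected weighted bipartite network
toy_random <- function(n_plants, n_pollinators, p_edge = 0.4, max_w = 5,
                       seed = 1, season = "S", week = 1) {
  set.seed(seed)
  repeat {
    plants <- paste0("P", seq_len(n_plants))
    polls <- paste0("A", seq_len(n_pollinators))
    grid <- expand.grid(plant = plants, pollinator = polls,
                        stringsAsFactors = FALSE)
    e <- grid[runif(nrow(grid)) < p_edge, , drop = FALSE]
    # keep every species attached
    miss_p <- setdiff(plants, e$plant)
    miss_a <- setdiff(polls, e$pollinator)
    if (length(miss_p))
      e <- rbind(e, data.frame(plant = miss_p,
                               pollinator = sample(polls, length(miss_p),
                                                   TRUE)))
    if (length(miss_a))
      e <- rbind(e, data.frame(plant = sample(plants, length(miss_a), TRUE),
                               pollinator = miss_a))
    e <- unique(e)
    e$weight <- sample.int(max_w, nrow(e), TRUE)
    net <- weekly_network(season, week, e)
    if (igraph::is_connected(oracle_net_igraph(net))) return(net)
  }
}

# records data.frame for data_io tests
toy_records <- function() {
  data.frame(season = "S1", week = c(1, 1, 3),
             plant = c("P1", "P1", "P2"),
             pollinator = c("A1", "A2", "A1"),
             count = c(2L, 1L, 4L), stringsAsFactors = FALSE)
}

# a position_grouping built directly (for transition tests)
manual_grouping <- function(df, n_groups_by_guild = NULL) {
  structure(df, class = c("position_grouping", "data.frame"),
            n_groups = n_groups_by_guild)
}

# planted-partition alignment_matrix: per guild, `blocks` dense blocks of
# `per_block` occurrences; within-block weight 0.9, between 0.05 (with a
# little seeded jitter)
planted_matrix <- function(blocks = 3, per_block = 20, within = 0.9,
                           between = 0.05, seed = 1) {
  set.seed(seed)
  occ <- do.call(rbind, lapply(c("plant", "pollinator"), function(g) {
    n <- blocks * per_block
    data.frame(occurrence = sprintf("%s%03d", substr(g, 1, 2), seq_len(n)),
               network = "X.w01", season = "X", week = 1,
               species = sprintf("%s%03d", substr(g, 1, 2), seq_len(n)),
               guild = g, block = rep(seq_len(blocks), each = per_block))
  }))
  n <- nrow(occ)
  M <- matrix(0, n, n, dimnames = list(occ$occurrence, occ$occurrence))
  for (g in c("plant", "pollinator")) {
    sel <- which(occ$guild == g)
    same <- outer(occ$block[sel], occ$block[sel], "==")
    base <- ifelse(same, within, between)
    jit <- matrix(runif(length(sel)^2, -0.02, 0.02), length(sel))
    jit <- (jit + t(jit)) / 2
    M[sel, sel] <- pmin(pmax(base + jit, 0), 1)
  }
  diag(M) <- 1
  truth <- occ$block
  occ$block <- NULL
  list(amat = structure(list(M = M, occurrences = occ,
                             quality_weighting = "frequency_x_correlation"),
                        class = "alignment_matrix"),
       truth = truth)
}

# hand-built alignment ensemble (runs crafted directly) for matrix tests
manual_ensemble <- function(net_A, net_B, runs) {
  structure(runs, class = "alignment_ensemble",
            net_A = network_id(net_A), net_B = network_id(net_B),
            season_A = net_A$season, week_A = net_A$week,
            season_B = net_B$season, week_B = net_B$week,
            species_A = network_guilds(net_A),
            species_B = network_guilds(net_B),
            N = length(runs))
}

manual_alignment <- function(net_A, net_B, pairs, cost = 0, seed = 1) {
  structure(list(net_A = network_id(net_A), net_B = network_id(net_B),
                 pairs = pairs,
                 unpaired = data.frame(network = character(),
                                       guild = character(),
                                       species = character()),
                 cost = cost, seed = seed),
            class = "network_alignment")
}
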