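#' Position uniqueness within a network
#'
#' Aligns a weekly network to itself `N` times and reports, per species, the
#' proportion of best-of-run alignments in which the species is paired to
#' itself. Values near 1 indicate a unique position; values near `1/k`
#' reveal an internal symmetry shared by `k` species.
#'
#' @param net a `weekly_network`.
#' @param roles optional role matrix for `net` (computed when `NULL`).
#' @param N number of self-alignments (default 100).
#' @param seed base seed.
#' @param ... passed on to [align()].
#' @return `data.frame` with columns `network`, `guild`, `species`, `value`,
#'   `n_runs`.
#' @export
uniqueness <- function(net, roles = NULL, N = 100, seed = 1, ...) {
  if (is.null(roles)) roles <- census_roles(net)
  ens <- repeat_align(net, net, roles = list(A = roles, B = roles),
                      N = N, base_seed = seed, ...)
  uniqueness_from_ensemble(ens)
}

#' Uniqueness scores from an existing self-alignment ensemble
#' @param ens an `alignment_ensemble` whose two networks are the same.
#' @return Same as [uniqueness()].
#' @export
uniqueness_from_ensemble <- function(ens) {
  stopifnot(attr(ens, "net_A") == attr(ens, "net_B"))
  guilds <- attr(ens, "species_A")
  hits <- setNames(numeric(length(guilds)), names(guilds))
  for (al in ens) {
    self <- al$pairs$species_A[al$pairs$species_A == al$pairs$species_B]
    hits[self] <- hits[self] + 1
  }
  data.frame(network = attr(ens, "net_A"), guild = unname(guilds),
             species = names(guilds), value = unname(hits) / length(ens),
             n_runs = length(ens), row.names = NULL)
}

#' Align all week pairs of a season
#'
#' Builds alignment ensembles for every unordered pair of distinct weekly
#' networks of a season (and, optionally, for every network with itself,
#' as needed by [build_alignment_matrix()]).
#'
#' @param series a `network_series`.
#' @param N runs per network pair.
#' @param base_seed base seed; every pair uses an independent seed block.
#' @param include_self also align every network to itself.
#' @param catalog,mode,weight_stat role computation settings
#'   (see [census_roles()]).
#' @param ... passed on to [align()].
#' @return List of `alignment_ensemble` objects.
#' @export
align_week_pairs <- function(series, N = 100, base_seed = 1,
                             include_self = FALSE,
                             catalog = enumerate_motifs(3, 5),
                             mode = "weighted", weight_stat = "mean", ...) {
  nets <- series$networks
  roles <- lapply(nets, census_roles, catalog = catalog, mode = mode,
                  weight_stat = weight_stat)
  out <- list()
  block <- 0L
  for (i in seq_along(nets)) {
    jrange <- if (include_self) i:length(nets) else
      if (i < length(nets)) (i + 1L):length(nets) else integer()
    for (j in jrange) {
      out[[length(out) + 1L]] <- repeat_align(
        nets[[i]], nets[[j]], roles = list(A = roles[[i]], B = roles[[j]]),
        N = N, base_seed = base_seed + block * N, ...)
      block <- block + 1L
    }
  }
  out
}

#' Position variability across networks
#'
#' For every species present in at least two weekly networks of a season,
#' the fraction of (network-pair, run) alignments between networks that both
#' contain the species in which the species is *not* paired to itself
#' (i.e. it is paired to a different species, or left unpaired). Species
#' present in fewer than two networks are excluded.
#'
#' @param ensembles list of `alignment_ensemble` objects covering the
#'   distinct-week pairs of a season (see [align_week_pairs()]); self-pair
#'   ensembles are ignored.
#' @return `data.frame` with columns `season`, `guild`, `species`, `value`,
#'   `n_obs`.
#' @export
variability <- function(ensembles) {
  cross <- Filter(function(e) attr(e, "net_A") != attr(e, "net_B"), ensembles)
  if (!length(cross)) stop("no distinct-network ensembles supplied")
  obs <- list(); nonself <- list(); guild <- character(); season <- character()
  for (e in cross) {
    gA <- attr(e, "species_A"); gB <- attr(e, "species_B")
    common <- intersect(names(gA), names(gB))
    if (!length(common)) next
    guild[common] <- gA[common]
    season[common] <- attr(e, "season_A")
    for (al in e) {
      selfpaired <- with(al$pairs, species_A[species_A == species_B])
      for (s in common) {
        obs[[s]] <- (obs[[s]] %||% 0) + 1
        if (!(s %in% selfpaired))
          nonself[[s]] <- (nonself[[s]] %||% 0) + 1
      }
    }
  }
  sp <- sort(names(obs))
  data.frame(season = season[sp], guild = unname(guild[sp]), species = sp,
             value = vapply(sp, function(s)
               (nonself[[s]] %||% 0) / obs[[s]], 1.0),
             n_obs = vapply(sp, function(s) obs[[s]], 1.0),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Alignment-quality loss from fixing a species pairing
#'
#' For each species common to two networks, compares the best alignment cost
#' when the species is forced to pair with itself against the unconstrained
#' best cost over the same number of runs. Large positive differences mean
#' the species changed position between the two networks.
#'
#' @param A,B `weekly_network` objects.
#' @param roles list with role matrices `A` and `B` (computed when `NULL`).
#' @param common species to fix (default: all species present in both
#'   networks).
#' @param N runs per optimisation.
#' @param seed base seed.
#' @param ... passed on to [align()].
#' @return `data.frame` with columns `net_A`, `net_B`, `guild`, `species`,
#'   `delta` (constrained minus unconstrained best cost; >= 0 up to
#'   optimiser noise).
#' @export
fixed_pair_loss <- function(A, B, roles = NULL, common = NULL, N = 100,
                            seed = 1, ...) {
  if (is.null(roles))
    roles <- list(A = census_roles(A), B = census_roles(B))
  gA <- network_guilds(A); gB <- network_guilds(B)
  if (is.null(common)) common <- intersect(names(gA), names(gB))
  if (!all(common %in% names(gA)) || !all(common %in% names(gB)))
    stop("species absent from one of the networks: ",
         paste(setdiff(common, intersect(names(gA), names(gB))),
               collapse = ", "))
  free <- repeat_align(A, B, roles, N = N, base_seed = seed, ...)
  c_free <- min(vapply(free, `[[`, 1.0, "cost"))
  rows <- lapply(seq_along(common), function(k) {
    s <- common[k]
    ens <- repeat_align(A, B, roles, N = N, base_seed = seed + k * N,
                        fixed_pairs = list(c(s, s)), ...)
    data.frame(net_A = network_id(A), net_B = network_id(B),
               guild = unname(gA[s]), species = s,
               delta = min(vapply(ens, `[[`, 1.0, "cost")) - c_free)
  })
  do.call(rbind, rows)
}
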