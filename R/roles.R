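#' Motif-position census: species role vectors
#'
#' Counts, for every species of a weekly network, the number of times it
#' occupies each distinct motif position of the catalogue, over all connected
#' *induced* subgraphs of the motif sizes. In `"binary"` mode every
#' occurrence contributes 1; in `"weighted"` mode each occurrence contributes
#' a summary of that occurrence's edge weights (arithmetic mean by default)
#' credited identically to all of its nodes, so that roles carry information
#' about interaction strengths.
#'
#' @param net a `weekly_network`.
#' @param catalog a `motif_catalog` (default sizes 3-5).
#' @param mode `"weighted"` or `"binary"`.
#' @param weight_stat per-occurrence weight summary used in weighted mode:
#'   `"mean"` (arithmetic mean), `"sum"`, or `"gmean"` (geometric mean).
#' @return A numeric matrix with one row per species (rownames = species) and
#'   one column per catalogue position, with attributes `guild` (named guild
#'   vector) and `network` (the [network_id()]).
#' @examples
#' net <- weekly_network("S", 1, data.frame(
#'   plant = "P1", pollinator = c("A1", "A2"), weight = c(2, 4)))
#' census_roles(net, enumerate_motifs(3, 3), mode = "weighted")
#' @export
census_roles <- function(net, catalog = enumerate_motifs(3, 5),
                         mode = c("weighted", "binary"),
                         weight_stat = c("mean", "sum", "gmean")) {
  mode <- match.arg(mode)
  weight_stat <- match.arg(weight_stat)
  stopifnot(inherits(net, "weekly_network"), inherits(catalog, "motif_catalog"))

  guilds <- network_guilds(net)
  sp <- names(guilds)
  n <- length(sp)
  W <- matrix(0, n, n, dimnames = list(sp, sp))
  pi <- match(net$edges$plant, sp)
  ai <- match(net$edges$pollinator, sp)
  W[cbind(pi, ai)] <- net$edges$weight
  W[cbind(ai, pi)] <- net$edges$weight
  adj <- lapply(seq_len(n), function(i) which(W[i, ] > 0) - 1L)

  cmode <- if (mode == "binary") 0L else
    match(weight_stat, c("mean", "sum", "gmean"))
  res <- .census_cpp(adj, as.integer(guilds == "pollinator"), W,
                     catalog$min_size, catalog$max_size,
                     vapply(catalog$motifs, `[[`, 1, "key"),
                     lapply(catalog$motifs,
                            function(m) as.integer(m$orbit_global - 1L)),
                     catalog$n_positions, cmode)
  dimnames(res) <- list(sp, paste0("pos", seq_len(catalog$n_positions)))
  attr(res, "guild") <- guilds
  attr(res, "network") <- network_id(net)
  res
}

#' Normalize role vectors
#'
#' @param roles a role matrix from [census_roles()].
#' @param mode `"none"` (identity), `"unit_sum"` (each non-zero row scaled to
#'   sum 1; zero rows unchanged) or `"zscore"` (each position column centred
#'   and scaled; constant columns set to 0).
#' @return A role matrix of the same shape and attributes.
#' @export
normalize_roles <- function(roles, mode = c("none", "unit_sum", "zscore")) {
  mode <- match.arg(mode)
  out <- roles
  if (mode == "unit_sum") {
    s <- rowSums(out)
    nz <- s > 0
    out[nz, ] <- out[nz, , drop = FALSE] / s[nz]
  } else if (mode == "zscore") {
    mu <- colMeans(out)
    sdv <- apply(out, 2, sd)
    out <- sweep(out, 2, mu, "-")
    pos <- sdv > 0
    out[, pos] <- sweep(out[, pos, drop = FALSE], 2, sdv[pos], "/")
    out[, !pos] <- 0
  }
  attr(out, "guild") <- attr(roles, "guild")
  attr(out, "network") <- attr(roles, "network")
  out
}

# role matrices for every network of one or more series, by network id
roles_for_networks <- function(nets, catalog = enumerate_motifs(3, 5),
                               mode = "weighted", weight_stat = "mean") {
  lapply(nets, census_roles, catalog = catalog, mode = mode,
         weight_stat = weight_stat)
}
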