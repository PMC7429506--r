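#' Compile alignments into the alignment matrix M
#'
#' Every occurrence is a (network, species) pair. For two occurrences `i` of
#' network A and `j` of network B, the entry `m_ij^{AB}` combines how often
#' `i` and `j` were paired over the ensemble of alignments between A and B
#' with the quality of that pairing: by default the pairing frequency times
#' the mean positive role correlation of the paired runs (equivalently the
#' run-mean of `max(c_ij, 0)` over paired runs). Diagonal blocks (A = B)
#' come from self-alignment ensembles. The matrix is symmetric, bounded in
#' \[0, 1\], and exactly 0 between guilds.
#'
#' @param ensembles list of `alignment_ensemble` objects covering *every*
#'   unordered pair (including self-pairs) of the networks involved.
#' @param quality_weighting `"frequency_x_correlation"` (default) or
#'   `"frequency"`.
#' @return Object of class `alignment_matrix`: list with dense symmetric
#'   matrix `M` (occurrence ids as dimnames), `occurrences` data.frame
#'   (occurrence, network, season, week, species, guild), and settings.
#' @export
build_alignment_matrix <- function(ensembles,
                                   quality_weighting =
                                     c("frequency_x_correlation", "frequency")) {
  quality_weighting <- match.arg(quality_weighting)

  # occurrence index over all networks involved
  seen <- new.env(parent = emptyenv())
  occ <- list()
  for (e in ensembles) {
    for (side in c("A", "B")) {
      id <- attr(e, paste0("net_", side))
      if (is.null(seen[[id]])) {
        seen[[id]] <- TRUE
        g <- attr(e, paste0("species_", side))
        occ[[id]] <- data.frame(
          occurrence = paste0(id, "::", names(g)), network = id,
          season = attr(e, paste0("season_", side)),
          week = attr(e, paste0("week_", side)),
          species = names(g), guild = unname(g))
      }
    }
  }
  occ <- do.call(rbind, occ)
  rownames(occ) <- NULL

  nets <- sort(unique(occ$network))
  have <- unique(vapply(ensembles, function(e)
    paste(sort(c(attr(e, "net_A"), attr(e, "net_B"))), collapse = "|"), ""))
  want <- unique(c(outer(nets, nets, function(a, b)
    ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|")))))
  missing <- setdiff(want, have)
  if (length(missing))
    stop("missing alignment ensemble(s) for network pair(s): ",
         paste(missing, collapse = "; "))

  n <- nrow(occ)
  M <- matrix(0, n, n, dimnames = list(occ$occurrence, occ$occurrence))
  for (e in ensembles) {
    idA <- attr(e, "net_A"); idB <- attr(e, "net_B")
    N <- length(e)
    self <- idA == idB
    for (al in e) {
      if (!nrow(al$pairs)) next
      i <- paste0(idA, "::", al$pairs$species_A)
      j <- paste0(idB, "::", al$pairs$species_B)
      v <- if (quality_weighting == "frequency") 1 else pmax(al$pairs$c, 0)
      ii <- match(i, occ$occurrence); jj <- match(j, occ$occurrence)
      idx <- cbind(ii, jj)
      M[idx] <- M[idx] + v / N
      if (!self) {
        idx2 <- cbind(jj, ii)
        M[idx2] <- M[idx2] + v / N
      }
    }
  }
  M <- (M + t(M)) / 2
  structure(list(M = M, occurrences = occ,
                 quality_weighting = quality_weighting),
            class = "alignment_matrix")
}

#' @export
print.alignment_matrix <- function(x, ...) {
  cat(sprintf("<alignment_matrix: %d occurrences over %d networks (%s)>\n",
              nrow(x$occurrences), length(unique(x$occurrences$network)),
              x$quality_weighting))
  invisible(x)
}

#' Detect groups of species positions
#'
#' Runs short-random-walk community detection (walktrap) on each guild's
#' block of the alignment matrix, cutting the merge tree at maximal
#' modularity. The matrix is exactly block-diagonal by guild, so plants and
#' pollinators are partitioned separately.
#'
#' @param amat an `alignment_matrix`.
#' @param steps random-walk length (default 4, the algorithm's conventional
#'   default).
#' @return Object of class `position_grouping`: the occurrence data.frame
#'   augmented with an integer `group` column (numbered within guild), plus
#'   an `n_groups` attribute (named by guild).
#' @export
detect_groups <- function(amat, steps = 4) {
  stopifnot(inherits(amat, "alignment_matrix"), steps >= 1)
  occ <- amat$occurrences
  occ$group <- NA_integer_
  ngroups <- c()
  for (g in unique(occ$guild)) {
    sel <- which(occ$guild == g)
    if (!length(sel)) stop("empty guild block: ", g)
    sub <- amat$M[sel, sel, drop = FALSE]
    gr <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    if (igraph::ecount(gr) == 0) {
      occ$group[sel] <- 1L
      ngroups[g] <- 1L
      next
    }
    wt <- igraph::cluster_walktrap(gr, steps = steps,
                                   weights = igraph::E(gr)$weight)
    mem <- igraph::membership(wt)
    occ$group[sel] <- as.integer(mem)
    ngroups[g] <- max(as.integer(mem))
  }
  structure(occ, class = c("position_grouping", "data.frame"),
            n_groups = ngroups, steps = steps)
}

#' Normalized mutual information between two partitions
#'
#' @param p1,p2 `position_grouping` objects over the same occurrence set, or
#'   plain membership vectors of equal length (factor/integer/character).
#' @param normalization entropy normalization: `"mean"` (arithmetic mean of
#'   the two entropies, the default), `"min"` or `"max"`.
#' @return NMI in \[0, 1\]. Two identical partitions give 1; a single-group
#'   partition against any other gives 0 (unless both are single-group).
#' @export
compare_partitions <- function(p1, p2,
                               normalization = c("mean", "min", "max")) {
  normalization <- match.arg(normalization)
  as_membership <- function(p) {
    if (inherits(p, "position_grouping")) {
      setNames(paste(p$guild, p$group), p$occurrence)
    } else p
  }
  m1 <- as_membership(p1); m2 <- as_membership(p2)
  if (!is.null(names(m1)) && !is.null(names(m2))) {
    if (!setequal(names(m1), names(m2)))
      stop("partitions cover different occurrence sets")
    m2 <- m2[names(m1)]
  }
  if (length(m1) != length(m2))
    stop("partitions cover different occurrence sets")
  n <- length(m1)
  tab <- table(m1, m2) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h1 <- h(rowSums(tab)); h2 <- h(colSums(tab))
  pij <- tab[tab > 0]
  pi. <- rowSums(tab)[row(tab)][tab > 0]
  p.j <- colSums(tab)[col(tab)][tab > 0]
  mi <- sum(pij * log(pij / (pi. * p.j)))
  denom <- switch(normalization, mean = (h1 + h2) / 2,
                  min = min(h1, h2), max = max(h1, h2))
  if (denom == 0) return(if (identical(unname(as.integer(factor(m1))),
                                       unname(as.integer(factor(m2))))) 1 else 0)
  max(0, min(1, mi / denom))
}

#' Relative degree of every species in a network
#'
#' `k_i = l_i / l_max`, where `l_i` is the number of distinct interaction
#' partners of species `i` (qualitative degree, weight-independent) and
#' `l_max` the maximum over all species of the network.
#'
#' @param net a `weekly_network`.
#' @return Named numeric vector in (0, 1\].
#' @export
relative_degree <- function(net) {
  e <- unique(net$edges[c("plant", "pollinator")])
  l <- c(table(e$plant), table(e$pollinator))
  l <- setNames(as.numeric(l), names(l))
  l[sort(names(l))] / max(l)
}

#' Degree-based properties of position groups
#'
#' For every occurrence, computed in its own weekly network: the species'
#' relative degree `k_i`, the relative degree of its most connected partner
#' `max{k^i}`, and the mean partner relative degree `<{k^i}>`. Groups are
#' then labelled per guild (`"A"`, `"B"`, ...) by descending group mean of
#' `max{k^i}`, ties broken by descending mean `k_i`, giving a stable and
#' documented ordering.
#'
#' @param grouping a `position_grouping`.
#' @param networks named list of `weekly_network` objects keyed by
#'   [network_id()] (see [network_index()]).
#' @return List with `occurrence_stats` (per-occurrence statistics and group
#'   `label`), `group_summary` (per guild x label: means of the three
#'   statistics and size), and `grouping` (the input with a `label` column).
#' @export
group_properties <- function(grouping, networks) {
  stopifnot(inherits(grouping, "position_grouping"))
  st <- as.data.frame(grouping)
  st$k <- st$max_pk <- st$mean_pk <- NA_real_
  for (id in unique(st$network)) {
    net <- networks[[id]]
    if (is.null(net)) stop("network not supplied: ", id)
    k <- relative_degree(net)
    rows <- which(st$network == id)
    if (!all(st$species[rows] %in% names(k)))
      stop("occurrence references species absent from its network")
    st$k[rows] <- k[st$species[rows]]
    e <- unique(net$edges[c("plant", "pollinator")])
    for (r in rows) {
      partners <- if (st$guild[r] == "plant")
        e$pollinator[e$plant == st$species[r]]
      else e$plant[e$pollinator == st$species[r]]
      pk <- k[partners]
      st$max_pk[r] <- max(pk)
      st$mean_pk[r] <- mean(pk)
    }
  }
  agg <- aggregate(cbind(k, max_pk, mean_pk) ~ guild + group, data = st,
                   FUN = mean)
  agg$n <- aggregate(k ~ guild + group, data = st, FUN = length)$k
  agg$label <- NA_character_
  for (g in unique(agg$guild)) {
    sel <- agg$guild == g
    ord <- order(-agg$max_pk[sel], -agg$k[sel])
    agg$label[sel][ord] <- LETTERS[seq_len(sum(sel))]
  }
  st$label <- agg$label[match(paste(st$guild, st$group),
                              paste(agg$guild, agg$group))]
  grouping$label <- st$label
  agg <- agg[order(agg$guild, agg$label),
             c("guild", "group", "label", "n", "k", "max_pk", "mean_pk")]
  rownames(agg) <- NULL
  list(occurrence_stats = st, group_summary = agg, grouping = grouping)
}

#' Sensitivity of relative degree to record removal
#'
#' Treats each unit of edge weight as one observed interaction event,
#' removes a given fraction of events uniformly at random, and reports the
#' mean absolute change in relative degree among surviving species and the
#' mean fraction of distinct (qualitative) links lost.
#'
#' @param net a weighted `weekly_network`.
#' @param removal_fractions fractions of events to remove, each in \[0, 1\].
#' @param reps replicates per fraction.
#' @param seed RNG seed.
#' @return `data.frame` with columns `fraction`, `mean_abs_dk`,
#'   `mean_link_loss`.
#' @export
degree_sensitivity <- function(net, removal_fractions = seq(0, 0.5, 0.1),
                               reps = 20, seed = 1) {
  if (any(removal_fractions < 0 | removal_fractions > 1))
    stop("removal fractions must lie in [0, 1]")
  k0 <- relative_degree(net)
  ne <- nrow(net$edges)
  events <- rep(seq_len(ne), net$edges$weight)
  out <- lapply(removal_fractions, function(f) {
    set.seed(seed + round(f * 1e6))
    dk <- loss <- numeric(reps)
    for (r in seq_len(reps)) {
      keep <- sample(events, length(events) - round(f * length(events)))
      surv <- sort(unique(keep))
      loss[r] <- 1 - length(surv) / ne
      if (!length(surv)) { dk[r] <- NA; next }
      sub <- net$edges[surv, , drop = FALSE]
      sub$weight <- as.numeric(table(factor(keep, levels = surv)))
      k1 <- relative_degree(weekly_network(net$season, net$week, sub))
      common <- intersect(names(k0), names(k1))
      dk[r] <- mean(abs(k1[common] - k0[common]))
    }
    data.frame(fraction = f, mean_abs_dk = mean(dk, na.rm = TRUE),
               mean_link_loss = mean(loss))
  })
  do.call(rbind, out)
}

#' Regression of relative degree on abundance
#'
#' Ordinary least squares of `k` on abundance; the unexplained variance
#' share is `1 - R^2`.
#'
#' @param k numeric vector of relative degrees.
#' @param abundance numeric vector of the same length.
#' @return List with `slope`, `intercept`, `unexplained` (share of variance
#'   in `k` not explained by abundance).
#' @export
abundance_regression <- function(k, abundance) {
  if (length(k) != length(abundance) || length(k) < 3)
    stop("need >= 3 paired observations")
  if (var(abundance) == 0) stop("zero variance in abundance")
  fit <- lm(k ~ abundance)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       unexplained = 1 - summary(fit)$r.squared)
}
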