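# Independent oracles used across the suite. These deliberately take
# different routes from the package internals: graph isomorphism and
# automorphism questions go through igraph's VF2 with guild colours, and
# optimal alignments come from exhaustive enumeration over permutations.

# igraph with guild colours from a biadjacency matrix (rows = plants)
oracle_igraph_from_biadj <- function(mat) {
  p <- nrow(mat); a <- ncol(mat)
  el <- which(mat == 1, arr.ind = TRUE)
  g <- igraph::make_empty_graph(p + a, directed = FALSE)
  if (nrow(el)) g <- igraph::add_edges(g, rbind(el[, 1], p + el[, 2]))
  igraph::V(g)$color <- c(rep(1L, p), rep(2L, a))
  g
}

oracle_iso <- function(g1, g2) {
  igraph::is_isomorphic_to(g1, g2, method = "vf2",
                           vertex.color1 = igraph::V(g1)$color,
                           vertex.color2 = igraph::V(g2)$color)
}

# brute-force motif enumeration: all connected guild-labelled bipartite
# graphs in a size range, deduplicated with igraph VF2; orbits from the
# union of all colour-preserving automorphisms
oracle_enumerate_motifs <- function(min_size, max_size) {
  out <- list()
  for (s in min_size:max_size) for (p in 1:(s - 1)) {
    a <- s - p
    for (mask in 0:(2^(p * a) - 1)) {
      mat <- matrix(as.integer(intToBits(mask)[seq_len(p * a)]), p, a,
                    byrow = TRUE)
      if (any(rowSums(mat) == 0) || any(colSums(mat) == 0)) next
      g <- oracle_igraph_from_biadj(mat)
      if (!igraph::is_connected(g)) next
      dup <- FALSE
      for (m in out)
        if (m$p == p && m$a == a && oracle_iso(g, m$g)) { dup <- TRUE; break }
      if (!dup)
        out[[length(out) + 1L]] <- list(p = p, a = a, size = s, mat = mat,
                                        g = g,
                                        orbits = oracle_orbits(g))
    }
  }
  out
}

# orbit partition of a coloured graph from all its automorphisms
oracle_orbits <- function(g) {
  auts <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = igraph::V(g)$color,
                               vertex.color2 = igraph::V(g)$color)
  n <- igraph::vcount(g)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in auts) for (v in seq_len(n)) {
    rv <- find(v); rm_ <- find(as.integer(a[v]))
    if (rv != rm_) parent[max(rv, rm_)] <- min(rv, rm_)
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

# weight-respecting automorphism orbits of a weekly network by brute force
# over within-guild permutations (guild sizes <= 8)
oracle_weighted_orbits <- function(net) {
  g <- network_guilds(net)
  sp <- names(g)
  W <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  W[cbind(match(net$edges$plant, sp), match(net$edges$pollinator, sp))] <-
    net$edges$weight
  W <- W + t(W)
  ip <- which(g == "plant"); ia <- which(g == "pollinator")
  parent <- seq_along(sp)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  pr <- netweave:::.perms(length(ip)); pc <- netweave:::.perms(length(ia))
  for (i in seq_len(nrow(pr))) for (j in seq_len(nrow(pc))) {
    perm <- seq_along(sp)
    perm[ip] <- ip[pr[i, ]]; perm[ia] <- ia[pc[j, ]]
    if (isTRUE(all.equal(unname(W[perm, perm]), unname(W)))) {
      for (v in seq_along(sp)) {
        rv <- find(v); rm_ <- find(perm[v])
        if (rv != rm_) parent[max(rv, rm_)] <- min(rv, rm_)
      }
    }
  }
  roots <- vapply(seq_along(sp), find, 1L)
  setNames(match(roots, unique(roots)), sp)
}

# igraph (coloured) representation of a weekly network; vertex order =
# names(network_guilds(net))
oracle_net_igraph <- function(net) {
  g <- network_guilds(net)
  sp <- names(g)
  gr <- igraph::make_empty_graph(length(sp), directed = FALSE)
  gr <- igraph::add_edges(gr, rbind(match(net$edges$plant, sp),
                                    match(net$edges$pollinator, sp)))
  igraph::V(gr)$color <- ifelse(g == "plant", 1L, 2L)
  igraph::V(gr)$name <- sp
  gr
}

# brute-force orbit census over every connected induced subgraph of sizes
# kmin..kmax; matches census_roles() output shape for the same catalogue
oracle_census <- function(net, catalog, kmin = 3, kmax = 5,
                          mode = c("binary", "weighted"),
                          weight_stat = "mean") {
  mode <- match.arg(mode)
  guilds <- network_guilds(net)
  sp <- names(guilds)
  gnet <- oracle_net_igraph(net)
  # per-motif igraph + global orbit ids per node (via oracle orbits but
  # aligned to the catalogue's position numbering through VF2 matching)
  mot <- lapply(catalog$motifs, function(m) {
    list(g = oracle_igraph_from_biadj(m$mat), glob = m$orbit_global,
         p = m$n_plants, a = m$n_pollinators)
  })
  wmat <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  wmat[cbind(match(net$edges$plant, sp), match(net$edges$pollinator, sp))] <-
    net$edges$weight
  wmat <- wmat + t(wmat)
  res <- matrix(0, length(sp), catalog$n_positions,
                dimnames = list(sp, paste0("pos", seq_len(catalog$n_positions))))
  for (k in kmin:kmax) {
    if (length(sp) < k) next
    for (subset in combn(length(sp), k, simplify = FALSE)) {
      gi <- igraph::induced_subgraph(gnet, subset)
      if (!igraph::is_connected(gi)) next
      hit <- NULL
      for (m in mot)
        if (igraph::vcount(m$g) == k && oracle_iso(gi, m$g)) { hit <- m; break }
      if (is.null(hit)) stop("no catalogue match for an induced subgraph")
      map <- igraph::isomorphisms(gi, hit$g, method = "vf2",
                                  vertex.color1 = igraph::V(gi)$color,
                                  vertex.color2 = igraph::V(hit$g)$color)[[1]]
      # isomorphisms() indexes the mapping by graph2's vertices; invert it
      # so inv[v] is the motif position of gi vertex v
      inv <- match(seq_len(k), as.integer(map))
      ew <- wmat[cbind(match(igraph::tail_of(gi, igraph::E(gi))$name, sp),
                       match(igraph::head_of(gi, igraph::E(gi))$name, sp))]
      contrib <- if (mode == "binary") 1 else switch(weight_stat,
        mean = mean(ew), sum = sum(ew), gmean = exp(mean(log(ew))))
      for (v in seq_len(k)) {
        node <- igraph::V(gi)$name[v]
        res[node, hit$glob[inv[v]]] <- res[node, hit$glob[inv[v]]] + contrib
      }
    }
  }
  res
}

# exhaustive optimal alignment: minimum of sum(1 - c) over all maximal
# guild-respecting pairings (guilds are independent); returns the optimum
# cost and all optimal pairings per guild
oracle_align <- function(roles_A, roles_B, fixed = NULL, tol = 1e-9) {
  gA <- attr(roles_A, "guild"); gB <- attr(roles_B, "guild")
  total <- 0
  opt_pairings <- list()
  for (g in c("plant", "pollinator")) {
    spA <- names(gA)[gA == g]; spB <- names(gB)[gB == g]
    nA <- length(spA); nB <- length(spB)
    if (nA == 0 || nB == 0) { total <- total + nA + nB; next }
    C <- suppressWarnings(cor(t(roles_A[spA, , drop = FALSE]),
                              t(roles_B[spB, , drop = FALSE])))
    C[!is.finite(C)] <- 0
    D <- 1 - matrix(C, nA, nB, dimnames = list(spA, spB))
    swap <- nA > nB
    if (swap) D <- t(D)
    ns <- min(nA, nB); nl <- max(nA, nB)
    small <- rownames(D); large <- colnames(D)
    perms <- netweave:::.perms(nl)
    best <- Inf; argmins <- list()
    for (r in seq_len(nrow(perms))) {
      assign_ <- perms[r, seq_len(ns)]
      if (!is.null(fixed)) {
        okc <- TRUE
        for (fp in fixed) {
          fa <- if (swap) fp[2] else fp[1]; fb <- if (swap) fp[1] else fp[2]
          ia <- match(fa, small)
          if (!is.na(ia) && large[assign_[ia]] != fb) { okc <- FALSE; break }
          # fixed species on the large side must be matched accordingly
          ib <- match(fb, large)
          if (is.na(ia) && !is.na(ib)) { okc <- FALSE; break }
        }
        if (!okc) next
      }
      cost <- sum(D[cbind(seq_len(ns), assign_)])
      if (cost < best - tol) {
        best <- cost
        argmins <- list(setNames(large[assign_], small))
      } else if (cost < best + tol) {
        cand <- setNames(large[assign_], small)
        if (!any(vapply(argmins, identical, TRUE, cand)))
          argmins[[length(argmins) + 1L]] <- cand
      }
    }
    total <- total + best + (nl - ns)  # unit penalty per unmatched species
    opt_pairings[[g]] <- list(pairings = argmins, swapped = swap)
  }
  list(cost = total, optima = opt_pairings)
}
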