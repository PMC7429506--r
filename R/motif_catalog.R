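# Motif catalogue: every connected guild-labelled bipartite graph of 3-5
# species (sizes configurable), unique up to guild-preserving isomorphism,
# with its node orbits under guild-preserving automorphism. Motifs are stored
# as canonical biadjacency matrices (rows = plants, columns = pollinators);
# the canonical form is the lexicographically minimal row-major bit encoding
# over within-guild permutations, which keeps orbit indices stable across
# runs and networks.

# all permutations of 1..n as a matrix (rows)
.perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# row-major bit code of a 0/1 biadjacency matrix (bit (r-1)*a + (c-1))
.biadj_code <- function(mat) {
  v <- as.integer(t(mat))
  sum(v * 2^(seq_along(v) - 1))
}

# minimal code over guild-preserving permutations; returns the canonical
# matrix, its code and one minimising permutation pair
.canonical_biadj <- function(mat) {
  p <- nrow(mat); a <- ncol(mat)
  pr <- .perms(p); pc <- .perms(a)
  best <- Inf; bpr <- NULL; bpc <- NULL
  for (i in seq_len(nrow(pr))) for (j in seq_len(nrow(pc))) {
    code <- .biadj_code(mat[pr[i, ], pc[j, ], drop = FALSE])
    if (code < best) { best <- code; bpr <- pr[i, ]; bpc <- pc[j, ] }
  }
  list(mat = mat[bpr, bpc, drop = FALSE], code = best,
       row_perm = bpr, col_perm = bpc)
}

.biadj_connected <- function(mat) {
  p <- nrow(mat); a <- ncol(mat); n <- p + a
  seen <- rep(FALSE, n); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- if (v <= p) p + which(mat[v, ] == 1) else which(mat[, v - p] == 1)
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

# orbit partition of the p+a nodes (plants first) under guild-preserving
# automorphisms; returns integer orbit id per node, numbered by first node
.biadj_orbits <- function(mat) {
  p <- nrow(mat); a <- ncol(mat); n <- p + a
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  unite <- function(x, y) {
    rx <- find(x); ry <- find(y)
    if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry)
  }
  pr <- .perms(p); pc <- .perms(a)
  for (i in seq_len(nrow(pr))) for (j in seq_len(nrow(pc))) {
    if (identical(mat[pr[i, ], pc[j, ], drop = FALSE], mat)) {
      for (r in seq_len(p)) unite(r, pr[i, r])
      for (c in seq_len(a)) unite(p + c, p + pc[j, c])
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Enumerate the bipartite motif catalogue
#'
#' Builds every connected guild-labelled bipartite graph with between
#' `min_size` and `max_size` species, unique up to guild-preserving
#' isomorphism, together with the node orbits ("positions") of each motif.
#' Plants and pollinators are distinguishable throughout, so e.g. a star of
#' pollinators around one plant and a star of plants around one pollinator
#' are different motifs. Catalogues are memoised per size range.
#'
#' @param min_size,max_size species counts delimiting the motif sizes
#'   (default 3-5; supported range 2-6).
#' @return An object of class `motif_catalog`: a list with `motifs` (each
#'   holding the canonical biadjacency matrix `mat`, its `code`, per-node
#'   local orbit ids `orbit_local` and global position ids `orbit_global`),
#'   a `positions` data.frame (one row per distinct position), `n_positions`
#'   and the size range.
#' @examples
#' cat3 <- enumerate_motifs(3, 3)
#' length(cat3$motifs)   # 2 motifs on 3 species
#' cat3$n_positions      # 4 positions
#' @export
enumerate_motifs <- function(min_size = 3, max_size = 5) {
  min_size <- as.integer(min_size); max_size <- as.integer(max_size)
  if (min_size < 2 || max_size > 6 || min_size > max_size)
    stop("supported motif size range is 2 <= min_size <= max_size <= 6")
  key <- sprintf("catalog_%d_%d", min_size, max_size)
  if (!is.null(.netweave_env[[key]])) return(.netweave_env[[key]])

  motifs <- list()
  for (s in min_size:max_size) {
    for (p in 1:(s - 1)) {
      a <- s - p
      seen <- new.env(parent = emptyenv())
      for (mask in 0:(2^(p * a) - 1)) {
        mat <- matrix(as.integer(intToBits(mask)[seq_len(p * a)]), p, a,
                      byrow = TRUE)
        if (any(rowSums(mat) == 0) || any(colSums(mat) == 0)) next
        if (!.biadj_connected(mat)) next
        can <- .canonical_biadj(mat)
        ck <- as.character(can$code)
        if (is.null(seen[[ck]])) {
          seen[[ck]] <- TRUE
          motifs[[length(motifs) + 1L]] <- list(
            size = s, n_plants = p, n_pollinators = a,
            mat = can$mat, code = can$code,
            key = (p * 6 + a) * 2^20 + can$code)
        }
      }
    }
  }
  ord <- order(vapply(motifs, `[[`, 1L, "size"),
               vapply(motifs, `[[`, 1L, "n_plants"),
               vapply(motifs, `[[`, 1, "code"))
  motifs <- motifs[ord]

  pos_rows <- list()
  next_pos <- 1L
  for (m in seq_along(motifs)) {
    mo <- motifs[[m]]
    orb <- .biadj_orbits(mo$mat)
    glob <- integer(length(orb))
    for (o in seq_len(max(orb))) {
      nodes <- which(orb == o)
      glob[nodes] <- next_pos
      pos_rows[[next_pos]] <- data.frame(
        position = next_pos, motif = m, size = mo$size,
        n_plants = mo$n_plants, n_pollinators = mo$n_pollinators,
        guild = if (nodes[1] <= mo$n_plants) "plant" else "pollinator",
        orbit_size = length(nodes))
      next_pos <- next_pos + 1L
    }
    motifs[[m]]$orbit_local <- orb
    motifs[[m]]$orbit_global <- glob
  }

  cat <- structure(list(motifs = motifs,
                        positions = do.call(rbind, pos_rows),
                        n_positions = next_pos - 1L,
                        min_size = min_size, max_size = max_size),
                   class = "motif_catalog")
  .netweave_env[[key]] <- cat
  cat
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("<motif_catalog sizes %d-%d: %d motifs, %d positions>\n",
              x$min_size, x$max_size, length(x$motifs), x$n_positions))
  invisible(x)
}

#' Export a motif catalogue as text
#'
#' One block per motif with its guild-labelled edge list and the position
#' (orbit) id of every node. Plants are named `p1..`, pollinators `a1..` in
#' canonical order.
#'
#' @param catalog a `motif_catalog`.
#' @param path output text file.
#' @return Invisibly, the path.
#' @export
export_catalog <- function(catalog, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(catalog$motifs)) {
    mo <- catalog$motifs[[m]]
    writeLines(sprintf("motif %d size %d (%d plants, %d pollinators)",
                       m, mo$size, mo$n_plants, mo$n_pollinators), con)
    for (r in seq_len(mo$n_plants)) for (c in seq_len(mo$n_pollinators))
      if (mo$mat[r, c] == 1)
        writeLines(sprintf("  edge p%d a%d", r, c), con)
    labs <- c(paste0("p", seq_len(mo$n_plants)),
              paste0("a", seq_len(mo$n_pollinators)))
    writeLines(sprintf("  position %s -> %d", labs, mo$orbit_global), con)
  }
  invisible(path)
}
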