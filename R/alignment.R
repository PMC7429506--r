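#' Role correlation between two species
#'
#' Pearson correlation between two role vectors over the same motif
#' catalogue. When either vector has zero variance (e.g. a species too
#' peripheral to enter any motif) the correlation is defined as 0.
#'
#' @param r_i,r_j numeric role vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
role_correlation <- function(r_i, r_j) {
  if (length(r_i) != length(r_j))
    stop("role vectors computed on different catalogues (length mismatch)")
  if (sd(r_i) == 0 || sd(r_j) == 0) return(0)
  cor(r_i, r_j)
}

# correlation matrix between the rows of two role matrices; zero-variance
# fallback 0, as in role_correlation()
role_cor_matrix <- function(RA, RB) {
  if (ncol(RA) != ncol(RB))
    stop("role matrices computed on different catalogues")
  C <- suppressWarnings(cor(t(RA), t(RB)))
  C[!is.finite(C)] <- 0
  matrix(C, nrow(RA), nrow(RB), dimnames = list(rownames(RA), rownames(RB)))
}

#' Cost of a guild-respecting pairing
#'
#' The alignment cost is `sum(1 - c_ij)` over the paired species plus
#' `unpaired_penalty` for every species (on either network's side of a
#' guild) left unmatched. A maximal pairing of a network with itself by the
#' identity has cost 0.
#'
#' @param pairing `data.frame` with columns `species_A`, `species_B`.
#' @param roles_A,roles_B role matrices of the two networks
#'   (see [census_roles()]).
#' @param unpaired_penalty non-negative penalty per unmatched species
#'   (default 1, i.e. equivalent to pairing with an uncorrelated partner).
#' @return The cost (non-negative real), with attribute `correlations`.
#' @export
alignment_cost <- function(pairing, roles_A, roles_B, unpaired_penalty = 1) {
  gA <- attr(roles_A, "guild"); gB <- attr(roles_B, "guild")
  if (nrow(pairing)) {
    if (!all(pairing$species_A %in% rownames(roles_A)) ||
        !all(pairing$species_B %in% rownames(roles_B)))
      stop("pairing references species absent from the role matrices")
    if (anyDuplicated(pairing$species_A) || anyDuplicated(pairing$species_B))
      stop("pairing is not injective")
    if (any(gA[pairing$species_A] != gB[pairing$species_B]))
      stop("pairing crosses guilds")
  }
  cc <- vapply(seq_len(nrow(pairing)), function(r)
    role_correlation(roles_A[pairing$species_A[r], ],
                     roles_B[pairing$species_B[r], ]), 1.0)
  n_unpaired <- (nrow(roles_A) - nrow(pairing)) +
    (nrow(roles_B) - nrow(pairing))
  structure(sum(1 - cc) + unpaired_penalty * n_unpaired, correlations = cc)
}

#' Align two weekly networks
#'
#' Finds a guild-respecting one-to-one pairing between the species of two
#' networks that minimises the role-dissimilarity cost
#' `sum(1 - c_ij) + penalty * #unpaired`, by simulated annealing over
#' pairings (partner swaps within a guild, including swaps with unpaired
#' species), geometric cooling, and a final greedy descent. The best pairing
#' encountered during the run is returned; repeated runs with different
#' seeds ([repeat_align()]) expose equally optimal alternatives.
#'
#' @param A,B `weekly_network` objects.
#' @param roles list with role matrices `A` and `B` (computed with
#'   [census_roles()] on a common catalogue). Computed on the fly from a
#'   3-5 weighted-mode catalogue when `NULL`.
#' @param seed integer seed for this run.
#' @param fixed_pairs optional list of `c(species_in_A, species_in_B)` pairs
#'   to hold fixed during the optimisation.
#' @param schedule annealing parameters: `t0` (initial temperature),
#'   `cooling` (geometric factor per sweep), `sweeps`.
#' @param unpaired_penalty penalty per unmatched species.
#' @return An object of class `network_alignment`: `pairs` (data.frame with
#'   `guild`, `species_A`, `species_B`, `c`), `unpaired`, `cost`, `seed`.
#' @export
align <- function(A, B, roles = NULL, seed = 1, fixed_pairs = NULL,
                  schedule = list(t0 = 1.0, cooling = 0.995, sweeps = 500L),
                  unpaired_penalty = 1) {
  if (is.null(roles))
    roles <- list(A = census_roles(A), B = census_roles(B))
  RA <- roles$A; RB <- roles$B
  gA <- attr(RA, "guild"); gB <- attr(RB, "guild")

  # validate fixed pairs
  if (length(fixed_pairs)) {
    fp <- do.call(rbind, lapply(fixed_pairs, function(x)
      data.frame(species_A = x[1], species_B = x[2])))
    if (!all(fp$species_A %in% names(gA)) || !all(fp$species_B %in% names(gB)))
      stop("fixed pair references a species absent from a network")
    if (anyDuplicated(fp$species_A) || anyDuplicated(fp$species_B))
      stop("infeasible fixed pairs: duplicate endpoint")
    if (any(gA[fp$species_A] != gB[fp$species_B]))
      stop("fixed pair crosses guilds")
  } else fp <- NULL

  pairs <- list(); unpaired <- list(); cost <- 0
  for (g in c("plant", "pollinator")) {
    spA <- names(gA)[gA == g]; spB <- names(gB)[gB == g]
    nA <- length(spA); nB <- length(spB)
    if (nA == 0 || nB == 0) {
      if (nA + nB > 0)
        unpaired[[g]] <- data.frame(
          network = rep(if (nA > 0) "A" else "B", nA + nB), guild = g,
          species = c(spA, spB))
      next
    }
    C <- role_cor_matrix(RA[spA, , drop = FALSE], RB[spB, , drop = FALSE])
    m <- max(nA, nB)
    D <- matrix(0, m, m)
    D[seq_len(nA), seq_len(nB)] <- 1 - C

    init <- 0:(m - 1)
    frozen <- rep(FALSE, m)
    if (!is.null(fp)) {
      fg <- fp[gA[fp$species_A] == g, , drop = FALSE]
      for (r in seq_len(nrow(fg))) {
        ri <- match(fg$species_A[r], spA) - 1L
        cj <- match(fg$species_B[r], spB) - 1L
        r2 <- which(init == cj) - 1L
        init[c(ri, r2) + 1L] <- init[c(r2, ri) + 1L]
        frozen[ri + 1L] <- TRUE
      }
    }
    res <- .anneal_cpp(D, as.integer(init), frozen,
                       as.integer(schedule$sweeps), schedule$t0,
                       schedule$cooling,
                       as.numeric(seed) * 4 + (g == "pollinator"))
    perm <- res$perm + 1L
    ri <- seq_len(nA)
    real <- perm[ri] <= nB
    if (any(real))
      pairs[[g]] <- data.frame(
        guild = g, species_A = spA[ri[real]], species_B = spB[perm[ri][real]],
        c = C[cbind(ri[real], perm[ri][real])])
    upA <- spA[ri[!real]]
    upB <- setdiff(spB, spB[perm[ri][real]])
    if (length(upA) + length(upB))
      unpaired[[g]] <- data.frame(
        network = c(rep("A", length(upA)), rep("B", length(upB))),
        guild = g, species = c(upA, upB))
    cost <- cost + res$cost + unpaired_penalty * (length(upA) + length(upB))
  }

  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(guild = character(), species_A = character(),
               species_B = character(), c = numeric())
  unpaired <- if (length(unpaired)) do.call(rbind, unpaired) else
    data.frame(network = character(), guild = character(),
               species = character())
  rownames(pairs) <- rownames(unpaired) <- NULL
  structure(list(net_A = network_id(A), net_B = network_id(B),
                 pairs = pairs, unpaired = unpaired,
                 cost = cost, seed = seed),
            class = "network_alignment")
}

#' @export
print.network_alignment <- function(x, ...) {
  cat(sprintf("<network_alignment %s ~ %s: %d pairs, %d unpaired, cost %.4f>\n",
              x$net_A, x$net_B, nrow(x$pairs), nrow(x$unpaired), x$cost))
  invisible(x)
}

#' Repeated independent alignments of a network pair
#'
#' Runs [align()] `N` times with seeds `base_seed .. base_seed + N - 1` and
#' keeps every best-of-run alignment. Because equally optimal pairings are
#' frequent (symmetric positions), the ensemble over restarts is the device
#' that exposes them.
#'
#' @inheritParams align
#' @param N number of independent runs (the pipeline default is 100).
#' @param base_seed seed of the first run.
#' @param ... passed on to [align()].
#' @return An object of class `alignment_ensemble`: list of
#'   `network_alignment` runs with network metadata attributes.
#' @export
repeat_align <- function(A, B, roles = NULL, N = 100, base_seed = 1, ...) {
  stopifnot(N >= 1)
  if (is.null(roles))
    roles <- list(A = census_roles(A), B = census_roles(B))
  runs <- lapply(seq_len(N) - 1L,
                 function(k) align(A, B, roles, seed = base_seed + k, ...))
  structure(runs, class = "alignment_ensemble",
            net_A = network_id(A), net_B = network_id(B),
            season_A = A$season, week_A = A$week,
            season_B = B$season, week_B = B$week,
            species_A = network_guilds(A), species_B = network_guilds(B),
            N = N)
}

#' @export
print.alignment_ensemble <- function(x, ...) {
  cat(sprintf("<alignment_ensemble %s ~ %s: %d runs, best cost %.4f>\n",
              attr(x, "net_A"), attr(x, "net_B"), length(x),
              min(vapply(x, `[[`, 1.0, "cost"))))
  invisible(x)
}
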