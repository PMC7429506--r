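test_that("alignment-matrix entries combine pairing frequency and quality", {
  A <- toy_star(2, weights = c(2, 3), week = 1)
  B <- toy_star(2, weights = c(2, 3), week = 2)
  mk <- function(pA, pB, cc) data.frame(guild = "pollinator",
                                        species_A = pA, species_B = pB,
                                        c = cc)
  # 2 of 4 runs pair (A1, A2) with correlations 0.9 and 0.7 -> 0.5 * 0.8
  runsAB <- list(
    manual_alignment(A, B, mk(c("A1", "A2"), c("A2", "A1"), c(0.9, 0.9))),
    manual_alignment(A, B, mk(c("A1", "A2"), c("A2", "A1"), c(0.7, 0.7))),
    manual_alignment(A, B, mk(c("A1", "A2"), c("A1", "A2"), c(1, 1))),
    manual_alignment(A, B, mk(c("A1", "A2"), c("A1", "A2"), c(1, 1))))
  selfruns <- function(net) list(
    manual_alignment(net, net, mk(c("A1", "A2"), c("A1", "A2"), c(1, 1))),
    manual_alignment(net, net, mk(c("A1", "A2"), c("A1", "A2"), c(1, 1))),
    manual_alignment(net, net, mk(c("A1", "A2"), c("A2", "A1"), c(-0.2, -0.2))),
    manual_alignment(net, net, mk(c("A1", "A2"), c("A2", "A1"), c(0.4, 0.4))))
  ens <- list(manual_ensemble(A, B, runsAB),
              manual_ensemble(A, A, selfruns(A)),
              manual_ensemble(B, B, selfruns(B)))
  am <- build_alignment_matrix(ens)
  M <- am$M
  expect_equal(M["S.w01::A1", "S.w02::A2"], 0.5 * 0.8)
  expect_equal(M["S.w01::A1", "S.w02::A1"], 0.5 * 1.0)
  # self block: paired half the runs; negative correlation clipped at 0
  expect_equal(M["S.w01::A1", "S.w01::A2"], 0.1)   # (0 + 0.4) / 4
  expect_equal(M["S.w01::A1", "S.w01::A1"], 0.5)
  # symmetry, range, cross-guild zeros
  expect_true(isSymmetric(M))
  expect_true(all(M >= 0 & M <= 1))
  occ <- am$occurrences
  cross <- outer(occ$guild, occ$guild, "!=")
  expect_true(all(M[cross] == 0))
  # frequency-only weighting ignores correlations
  am2 <- build_alignment_matrix(ens, quality_weighting = "frequency")
  expect_equal(am2$M["S.w01::A1", "S.w02::A2"], 0.5)
  # only the four observed pairings touch B's A1 (cross pair, identity
  # pair, self diagonal, within-B swap); all other entries stay zero
  expect_equal(sum(M[, "S.w02::A1"] > 0), 4)
})

test_that("a missing network-pair ensemble is reported", {
  A <- toy_star(2, week = 1); B <- toy_star(2, week = 2)
  mk <- function(pA, pB, cc) data.frame(guild = "pollinator",
                                        species_A = pA, species_B = pB,
                                        c = cc)
  ens <- list(manual_ensemble(A, B, list(
    manual_alignment(A, B, mk("A1", "A1", 1)))))
  expect_error(build_alignment_matrix(ens), "missing alignment ensemble")
})

test_that("walktrap recovers a planted partition exactly", {
  pm <- planted_matrix(blocks = 3, per_block = 20, seed = 2)
  gr <- detect_groups(pm$amat, steps = 4)
  expect_s3_class(gr, "position_grouping")
  expect_equal(unname(attr(gr, "n_groups")), c(3L, 3L))
  for (g in c("plant", "pollinator")) {
    sel <- gr$guild == g
    expect_equal(compare_partitions(gr$group[sel], pm$truth[sel]), 1)
  }
})

test_that("a structureless matrix yields a single group per guild", {
  pm <- planted_matrix(blocks = 1, per_block = 12, within = 0.5,
                       between = 0.5, seed = 3)
  gr <- detect_groups(pm$amat)
  expect_true(all(tapply(gr$group, gr$guild, max) == 1))
})

test_that("NMI matches the closed form and igraph's implementation", {
  expect_equal(compare_partitions(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(compare_partitions(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(compare_partitions(rep(1, 4), c(1, 1, 2, 2)), 0)
  # hand-built 2x2 contingency: (2,1 | 1,2) over n = 6
  p1 <- c(1, 1, 1, 2, 2, 2); p2 <- c(1, 1, 2, 1, 2, 2)
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  tab <- matrix(c(2, 1, 1, 2), 2) / 6
  mi <- sum(tab * log(tab / outer(rowSums(tab), colSums(tab))))
  expect_equal(compare_partitions(p1, p2), mi / h(c(0.5, 0.5)))
  set.seed(9)
  a <- sample(1:3, 40, TRUE); b <- sample(1:4, 40, TRUE)
  expect_equal(compare_partitions(a, b),
               igraph::compare(a, b, method = "nmi"))
  expect_error(compare_partitions(c(1, 2), c(1, 2, 3)), "occurrence sets")
})

test_that("relative degree follows the qualitative-degree definition", {
  star <- toy_star(4)
  k <- relative_degree(star)
  expect_equal(unname(k["P1"]), 1)
  expect_equal(unname(k["A1"]), 0.25)
  # weight invariance
  star$edges$weight <- c(9, 1, 5, 2)
  expect_equal(relative_degree(star), k)
  # all-degree-2 network
  net <- weekly_network("S", 1, data.frame(
    plant = c("P1", "P1", "P2", "P2"),
    pollinator = c("A1", "A2", "A1", "A2"), weight = 1))
  expect_true(all(relative_degree(net) == 1))
})

test_that("group properties label groups by partner-degree convention", {
  net1 <- toy_random(5, 6, seed = 41, week = 1)
  occ <- data.frame(network = network_id(net1), season = "S", week = 1,
                    species = names(network_guilds(net1)),
                    guild = unname(network_guilds(net1)))
  occ$occurrence <- paste0(occ$network, "::", occ$species)
  set.seed(4)
  occ$group <- ifelse(occ$guild == "plant", 1L,
                      sample(1:2, nrow(occ), TRUE))
  gr <- manual_grouping(occ)
  gp <- group_properties(gr, setNames(list(net1), network_id(net1)))
  k <- relative_degree(net1)
  expect_equal(gp$occurrence_stats$k,
               unname(k[gp$occurrence_stats$species]))
  expect_true(all(gp$occurrence_stats$max_pk >=
                    gp$occurrence_stats$mean_pk - 1e-12))
  # labels ordered by descending mean max_pk within guild
  sm <- gp$group_summary
  for (g in unique(sm$guild)) {
    sg <- sm[sm$guild == g, ]
    expect_true(all(diff(sg$max_pk[order(sg$label)]) <= 1e-12))
  }
  # degenerate single-edge network: all three statistics are 1
  net2 <- weekly_network("S", 2, data.frame(plant = "P1", pollinator = "A1",
                                            weight = 2))
  occ2 <- data.frame(occurrence = paste0(network_id(net2), "::",
                                         c("P1", "A1")),
                     network = network_id(net2), season = "S", week = 2,
                     species = c("P1", "A1"),
                     guild = c("plant", "pollinator"), group = 1L)
  gp2 <- group_properties(manual_grouping(occ2),
                          setNames(list(net2), network_id(net2)))
  expect_true(all(unlist(gp2$occurrence_stats[c("k", "max_pk", "mean_pk")]) == 1))
})

test_that("degree sensitivity accounts for removed events and lost links", {
  net <- toy_random(4, 5, seed = 55, max_w = 8)
  out <- degree_sensitivity(net, removal_fractions = c(0, 0.5), reps = 10,
                            seed = 3)
  expect_equal(out$mean_abs_dk[out$fraction == 0], 0)
  expect_equal(out$mean_link_loss[out$fraction == 0], 0)
  # weight concentration: removing half the events loses well under half
  # the distinct links
  expect_lt(out$mean_link_loss[out$fraction == 0.5], 0.5)
  expect_error(degree_sensitivity(net, removal_fractions = 1.5), "0, 1")
  # removing the only event of a weight-1 edge removes that link
  tiny <- weekly_network("S", 1, data.frame(
    plant = c("P1", "P1"), pollinator = c("A1", "A2"), weight = c(1L, 9L)))
  res <- degree_sensitivity(tiny, removal_fractions = 0.1, reps = 50,
                            seed = 8)
  expect_gt(res$mean_link_loss, 0)   # the weight-1 link is sometimes lost
  expect_lt(res$mean_link_loss, 0.5) # but never the weight-9 one
})

test_that("abundance regression reports the unexplained variance share", {
  out <- suppressWarnings(abundance_regression(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(out$slope, 1)
  expect_equal(out$unexplained, 0, tolerance = 1e-12)
  set.seed(12)
  k <- runif(400); ab <- runif(400)
  expect_gt(abundance_regression(k, ab)$unexplained, 0.9)
  expect_error(abundance_regression(c(1, 2, 3), c(2, 2, 2)), "zero variance")
  expect_error(abundance_regression(1:2, 1:2), ">= 3")
})
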