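# two pollinators on a carrier plant: "Z" present all weeks in group 1,
# "X" with a configurable presence/group pattern
traj_toy <- function(x_weeks, x_groups, W) {
  nets <- lapply(seq_len(W), function(w) {
    polls <- c("Z", if (w %in% x_weeks) "X")
    weekly_network("S1", w, data.frame(plant = "P1", pollinator = polls,
                                       weight = 1))
  })
  series <- list(S1 = structure(list(season = "S1", networks = nets, W = W),
                                class = "network_series"))
  occ <- do.call(rbind, lapply(seq_len(W), function(w) {
    ids <- network_id(nets[[w]])
    sp <- c("Z", if (w %in% x_weeks) "X")
    data.frame(occurrence = paste0(ids, "::", sp), network = ids,
               season = "S1", week = w, species = sp, guild = "pollinator",
               group = c(1L, if (w %in% x_weeks)
                 x_groups[match(w, x_weeks)]))
  }))
  list(grouping = manual_grouping(occ), series = series)
}

test_that("state sequences assign pre, groups, post and relative time", {
  toy <- traj_toy(x_weeks = 2:4, x_groups = c(1L, 1L, 2L), W = 5)
  traj <- build_state_sequences(toy$grouping, toy$series, "pollinator")
  expect_equal(attr(traj, "n_groups"), 2L)
  x <- traj[traj$species == "X", ]
  expect_equal(x$state, c(3L, 1L, 1L, 2L, 4L))   # pre, G1, G1, G2, post
  expect_equal(x$t, (1:5) / 5)
  expect_false(any(x$gap))

  ev <- transition_events(traj)
  xe <- ev[ev$species == "X", ]
  expect_equal(nrow(xe), 4)
  expect_equal(xe$origin, c(3L, 1L, 1L, 2L))
  expect_equal(xe$dest,   c(1L, 1L, 2L, 4L))
  expect_equal(xe$t, c(2, 3, 4, 5) / 5)
  expect_true(all(xe$usable))
  # Z is present through the final week: right-censored, no exit event
  ze <- ev[ev$species == "Z", ]
  expect_equal(nrow(ze), 4)
  expect_true(all(ze$origin == 1L & ze$dest == 1L))
})

test_that("interrupted presence drops both steps around the gap", {
  toy <- traj_toy(x_weeks = c(1, 3), x_groups = c(1L, 2L), W = 3)
  traj <- build_state_sequences(toy$grouping, toy$series, "pollinator")
  x <- traj[traj$species == "X", ]
  expect_true(x$gap[2])
  ev <- transition_events(traj)
  xe <- ev[ev$species == "X", ]
  expect_equal(sum(xe$usable), 0)
  # the unusable steps never reach the likelihood
  mf <- netweave:::.model_frame(ev, 2L)
  expect_equal(mf$N, sum(ev$usable))
})

test_that("a species entering late first accumulates pre -> pre steps", {
  toy <- traj_toy(x_weeks = 4:5, x_groups = c(2L, 2L), W = 5)
  ev <- transition_events(build_state_sequences(toy$grouping, toy$series,
                                                "pollinator"))
  xe <- ev[ev$species == "X", ]
  expect_equal(xe$origin, c(3L, 3L, 3L, 2L))
  expect_equal(xe$dest, c(3L, 3L, 2L, 2L))
})

test_that("softmax probabilities behave as the closed form dictates", {
  expect_equal(transition_probability(rep(0, 5)), rep(0.2, 5))
  expect_equal(transition_probability(c(0, log(2))), c(1, 2) / 3)
  p <- transition_probability(c(1, -2, 0.5))
  expect_equal(transition_probability(c(1, -2, 0.5) + 7), p)
  expect_equal(sum(p), 1)
  # structural zeros via the allowed mask
  pz <- transition_probability(c(1, 2, 3), allowed = c(TRUE, FALSE, TRUE))
  expect_equal(pz[2], 0)
  expect_equal(sum(pz), 1)
})

test_that("linear scores reduce correctly at t = 0 and with zero parameters", {
  n <- 2
  zero <- list(alpha = matrix(0, n + 2, n + 1),
               beta = matrix(0, n + 2, n + 1))
  expect_equal(score_linear(zero, origin = 1, t = 0.3), rep(0, 4))
  set.seed(5)
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(12), 4, 3)
  a[4, ] <- b[4, ] <- 0
  pars <- list(alpha = a, beta = b)
  expect_equal(score_linear(pars, origin = 2, t = 0),
               unname(a[, 1] + a[, 2]))
  # hand substitution for origin 2 at t = 0.5
  expect_equal(score_linear(pars, origin = 2, t = 0.5),
               unname(a[, 1] + 0.5 * b[, 1] + a[, 2] + 0.5 * b[, 2]))
})

test_that("constant-model posterior concentrates on the generating matrix", {
  P <- rbind(c(0.7, 0.0, 0.3),    # from G1: stay, (pre impossible), exit
             c(0.4, 0.6, 0.0))    # from pre: enter, stay
  cfg <- synthetic_config(seasons = 1, weeks = 10, n_plants = 4,
                          n_pollinators = 4, n_groups = 1,
                          transition = P, init_probs = c(0.3, 0.7),
                          mean_degree = 2, partner_bias = 1,
                          attractiveness = 2)
  traj <- simulate_trajectories(200, 10, cfg, seed = 31)
  ev <- transition_events(traj)
  fit <- suppressWarnings(
    fit_transition_model(ev, n_groups = 1, form = "constant", chains = 2,
                         iter = 1500, seed = 9))
  ok <- 0; total <- 0
  for (o in 1:2) {
    allow <- allowed_destinations_vec(o, 1)
    pm <- sapply(seq_len(nrow(fit$draws)), function(s)
      transition_probability(score_linear(draw_params(fit, s), o, 0.5),
                             seq_len(3) %in% allow))
    est <- rowMeans(pm)[allow]
    qs <- apply(pm[allow, , drop = FALSE], 1, quantile, c(0.025, 0.975))
    truth <- P[o, allow]
    expect_equal(unname(est), unname(truth), tolerance = 0.08)
    total <- total + length(allow)
    ok <- ok + sum(truth >= qs[1, ] & truth <= qs[2, ])
  }
  expect_gte(ok / total, 0.75)
})

test_that("sampling is reproducible under a fixed seed", {
  cfg <- synthetic_config(seasons = 1, weeks = 8, n_plants = 4,
                          n_pollinators = 4)
  traj <- simulate_trajectories(40, 8, cfg, seed = 3)
  ev <- transition_events(traj)
  f1 <- suppressWarnings(fit_transition_model(ev, 3, form = "constant",
                                              chains = 1, iter = 400,
                                              seed = 11))
  f2 <- suppressWarnings(fit_transition_model(ev, 3, form = "constant",
                                              chains = 1, iter = 400,
                                              seed = 11))
  expect_equal(f1$draws, f2$draws)
})

test_that("WAIC matches a direct computation from the stored draws", {
  cfg <- synthetic_config(seasons = 1, weeks = 8, n_plants = 4,
                          n_pollinators = 4)
  traj <- simulate_trajectories(30, 8, cfg, seed = 13)
  ev <- transition_events(traj)
  fit <- suppressWarnings(fit_transition_model(ev, 3, form = "constant",
                                               chains = 1, iter = 300,
                                               warmup = 250, seed = 21))
  w <- waic(fit)
  # independent route: event likelihoods via the exported formula helpers
  evu <- as.data.frame(ev)[ev$usable & ev$origin != 5, ]
  S <- nrow(fit$draws)
  LL <- matrix(NA_real_, S, nrow(evu))
  for (s in seq_len(S)) {
    pars <- draw_params(fit, s)
    LL[s, ] <- log(vapply(seq_len(nrow(evu)), function(i) {
      allow <- seq_len(5) %in% allowed_destinations_vec(evu$origin[i], 3)
      transition_probability(score_linear(pars, evu$origin[i], evu$t[i]),
                             allow)[evu$dest[i]]
    }, 1.0))
  }
  lppd <- sum(log(colMeans(exp(LL))))
  p_waic <- sum(apply(LL, 2, var))
  expect_equal(w$lppd, lppd, tolerance = 1e-8)
  expect_equal(w$p_waic, p_waic, tolerance = 1e-8)
  expect_equal(w$waic, -2 * (lppd - p_waic), tolerance = 1e-8)
  # identical fits give identical WAIC
  fit2 <- suppressWarnings(fit_transition_model(ev, 3, form = "constant",
                                                chains = 1, iter = 300,
                                                warmup = 250, seed = 21))
  expect_equal(waic(fit2)$waic, w$waic)
})

test_that("the adaptive sampler agrees with an independent Gibbs route (JAGS)", {
  P <- rbind(c(0.65, 0.0, 0.35),
             c(0.45, 0.55, 0.0))
  cfg <- synthetic_config(seasons = 1, weeks = 10, n_plants = 4,
                          n_pollinators = 4, n_groups = 1, transition = P,
                          init_probs = c(0.3, 0.7), mean_degree = 2,
                          partner_bias = 1, attractiveness = 2)
  traj <- simulate_trajectories(150, 10, cfg, seed = 61)
  ev <- transition_events(traj)
  fit <- suppressWarnings(fit_transition_model(ev, 1, form = "constant",
                                               chains = 2, iter = 3000,
                                               seed = 3))
  my <- sapply(1:2, function(o) {
    allow <- 1:3 %in% allowed_destinations_vec(o, 1)
    rowMeans(sapply(seq_len(nrow(fit$draws)), function(s)
      transition_probability(score_linear(draw_params(fit, s), o, 0.5),
                             allow)))
  })
  evu <- as.data.frame(ev)[ev$usable & ev$origin != 3, ]
  allow <- rbind(c(1, 0, 1), c(1, 1, 0))
  mod <- "
  model {
    for (k in 1:2) { for (l in 1:2) { A[k,l] ~ dnorm(0, 0.01) } }
    for (l in 1:2) { A[3,l] <- 0 }
    for (i in 1:N) {
      for (k in 1:3) {
        w[i,k] <- allow[orig[i],k] * exp(A[k,1] + A[k,2] * step(orig[i]-2))
      }
      y[i] ~ dcat(w[i,1:3])
    }
  }"
  jm <- rjags::jags.model(textConnection(mod),
                          data = list(N = nrow(evu), orig = evu$origin,
                                      y = evu$dest, allow = allow),
                          n.chains = 2, n.adapt = 1000, quiet = TRUE)
  dr <- do.call(rbind, rjags::coda.samples(jm, "A", n.iter = 4000))
  jp <- sapply(1:2, function(o) {
    rowMeans(sapply(seq_len(nrow(dr)), function(s) {
      A <- matrix(dr[s, c("A[1,1]", "A[2,1]", "A[3,1]",
                          "A[1,2]", "A[2,2]", "A[3,2]")], 3, 2)
      w <- allow[o, ] * exp(A[, 1] + A[, 2] * (o == 2))
      w / sum(w)
    }))
  })
  expect_lt(max(abs(my - jp)), 0.02)
})

test_that("posterior curves are flat for the constant form and row-stochastic", {
  cfg <- synthetic_config(seasons = 1, weeks = 8, n_plants = 4,
                          n_pollinators = 4)
  traj <- simulate_trajectories(60, 8, cfg, seed = 17)
  ev <- transition_events(traj)
  fit <- suppressWarnings(fit_transition_model(ev, 3, form = "constant",
                                               chains = 2, iter = 600,
                                               seed = 23))
  pc <- predict_curves(fit, t_grid = c(0, 0.5, 1))
  for (o in unique(pc$origin)) {
    po <- pc[pc$origin == o, ]
    # flat in t
    expect_equal(tapply(po$mean, po$destination, function(v) max(v) - min(v)),
                 tapply(po$mean, po$destination, function(v) 0),
                 tolerance = 1e-12)
    # means sum to one over allowed destinations at each t
    expect_equal(as.numeric(tapply(po$mean, po$t, sum)), rep(1, 3))
    expect_true(all(po$q25 <= po$mean + 1e-9 & po$mean <= po$q75 + 1e-9))
  }
  # structural zeros: pre is no destination from groups; post no origin
  expect_false(any(pc$origin %in% "post"))
  expect_false(any(pc$origin != "pre" & pc$destination == "pre"))
  expect_false(any(pc$origin == "pre" & pc$destination == "post"))
})
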