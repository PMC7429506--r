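# Species structural dynamics across position groups: per-species weekly
# state sequences over {group 1..n, pre, post} and a Bayesian multinomial
# logistic model of the weekly transitions, with optional linear time
# dependence of the scores.
#
# State coding for a guild with n groups: 1..n = position groups,
# n+1 = pre (not yet entered), n+2 = post (exited; absorbing). The score of
# the post state is fixed to 0 as the arbitrary baseline. Destination
# support is restricted: from pre a species may stay pre or enter a group;
# from a group it may move among groups or exit to post; pre is never a
# destination after entry and post never an origin (structural zeros).

state_labels <- function(n) c(paste0("G", seq_len(n)), "pre", "post")

# allowed destination states by origin (origins: 1..n groups, n+1 pre)
allowed_destinations <- function(origin, n) {
  if (origin <= n) c(seq_len(n), n + 2L) else c(seq_len(n), n + 1L)
}

#' Build per-species weekly state trajectories
#'
#' Converts group memberships of (network, species) occurrences into one
#' state per sampled week and species: the group when present, `pre` for all
#' weeks before first presence, `post` from the week after last presence
#' onward. Weeks inside the activity period in which the species was not
#' observed (presence-absence-presence) are treated as likely sampling
#' errors: they are flagged as gaps, and every transition touching a gap
#' week is dropped from the likelihood. Relative time is `t = w / W` with
#' `w` the 1-based position among the season's sampled weeks.
#'
#' @param grouping a `position_grouping` (with a `label` column if group
#'   letters should define the state order; otherwise the raw group numbers
#'   do).
#' @param series_list named list of `network_series`.
#' @param guild `"pollinator"` or `"plant"`; each guild has its own groups
#'   and is modelled separately.
#' @return `data.frame` of class `state_trajectories` with columns `season`,
#'   `species`, `guild`, `week`, `widx`, `W`, `t`, `state` (integer code),
#'   `gap`; attributes `n_groups` and `state_labels`.
#' @export
build_state_sequences <- function(grouping, series_list, guild) {
  stopifnot(inherits(grouping, "position_grouping"))
  gr <- as.data.frame(grouping)
  gr <- gr[gr$guild == guild, , drop = FALSE]
  if (!nrow(gr)) stop("no occurrences for guild ", guild)
  if (!is.null(gr$label)) {
    labs <- sort(unique(gr$label))
    gr$state <- match(gr$label, labs)
  } else {
    gr$state <- gr$group
    labs <- paste0("G", sort(unique(gr$group)))
  }
  n <- length(unique(gr$state))
  pre <- n + 1L; post <- n + 2L

  out <- list()
  for (s in names(series_list)) {
    series <- series_list[[s]]
    W <- series$W
    ids <- vapply(series$networks, network_id, "")
    present <- lapply(series$networks, function(net)
      network_species(net, guild))
    species <- sort(unique(unlist(present)))
    key <- paste(gr$network, gr$species)
    for (sp in species) {
      inw <- vapply(present, function(p) sp %in% p, TRUE)
      first <- which(inw)[1]; last <- max(which(inw))
      st <- integer(W)
      for (w in seq_len(W)) {
        if (inw[w]) {
          hit <- match(paste(ids[w], sp), key)
          if (is.na(hit))
            stop("no group assignment for ", sp, " in ", ids[w])
          st[w] <- gr$state[hit]
        } else if (w < first) st[w] <- pre
        else if (w > last) st[w] <- post
        else st[w] <- NA_integer_   # gap inside the activity period
      }
      out[[length(out) + 1L]] <- data.frame(
        season = s, species = sp, guild = guild,
        week = vapply(series$networks, function(x) x$week, 1L),
        widx = seq_len(W), W = W, t = seq_len(W) / W,
        state = st, gap = is.na(st))
    }
  }
  traj <- do.call(rbind, out)
  rownames(traj) <- NULL
  structure(traj, class = c("state_trajectories", "data.frame"),
            n_groups = n, state_labels = c(labs, "pre", "post"))
}

#' Weekly transition events from state trajectories
#'
#' One row per consecutive-week step of each species-season, with the origin
#' and destination states and the relative time `t` of the destination week.
#' Steps out of `post` are structurally excluded; steps touching a gap week
#' are kept but flagged unusable (they never enter the likelihood). A
#' species present in the final sampled week contributes no exit transition
#' (right-censored).
#'
#' @param trajectories a `state_trajectories` object.
#' @return `data.frame` of class `transition_events` with columns `season`,
#'   `species`, `guild`, `t`, `origin`, `dest`, `usable`; attributes
#'   `n_groups`, `state_labels`.
#' @export
transition_events <- function(trajectories) {
  n <- attr(trajectories, "n_groups")
  post <- n + 2L
  tr <- as.data.frame(trajectories)
  tr <- tr[order(tr$season, tr$species, tr$widx), ]
  out <- list()
  for (grp in split(tr, paste(tr$season, tr$species))) {
    W <- grp$W[1]
    for (w in seq_len(nrow(grp) - 1L)) {
      o <- grp$state[w]; d <- grp$state[w + 1L]
      if (!is.na(o) && o == post) next
      out[[length(out) + 1L]] <- data.frame(
        season = grp$season[1], species = grp$species[1],
        guild = grp$guild[1], t = grp$t[w + 1L],
        origin = o, dest = d, usable = !is.na(o) && !is.na(d))
    }
  }
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  structure(ev, class = c("transition_events", "data.frame"),
            n_groups = n, state_labels = attr(trajectories, "state_labels"))
}

#' Softmax transition probabilities from scores
#'
#' @param scores numeric vector of finite scores, one per candidate
#'   destination.
#' @param allowed optional logical vector; disallowed destinations get
#'   probability 0 and are excluded from the normalisation.
#' @return Probability vector summing to 1 (overflow-safe).
#' @export
transition_probability <- function(scores, allowed = NULL) {
  if (is.null(allowed)) allowed <- rep(TRUE, length(scores))
  s <- ifelse(allowed, scores, -Inf)
  e <- exp(s - max(s))
  e / sum(e)
}

#' Linear score functions of the transition model
#'
#' `s_k(y_i, t) = alpha[k,1] + beta[k,1] t + sum_l (alpha[k,l] + beta[k,l] t)
#' delta_{il}` with Kronecker origin indicators `delta` (origin 1 is the
#' reference origin carried by the intercept column `l = 1`). The baseline
#' destination's rows of `alpha`/`beta` are all 0.
#'
#' @param params list with matrices `alpha` and `beta`, each
#'   `(n+2) x (n+1)`: rows = destination states, columns = intercept plus
#'   one offset per non-reference origin.
#' @param origin integer origin state (1..n groups or n+1 = pre).
#' @param t relative time in \[0, 1\].
#' @return Numeric vector of n+2 scores.
#' @export
score_linear <- function(params, origin, t) {
  a <- params$alpha; b <- params$beta
  stopifnot(is.matrix(a), identical(dim(a), dim(b)),
            origin >= 1, origin <= ncol(a), t >= 0, t <= 1)
  s <- a[, 1] + b[, 1] * t
  if (origin >= 2) s <- s + a[, origin] + b[, origin] * t
  unname(s)
}

# ---- likelihood internals ----------------------------------------------

# combined per-origin score coefficients from a parameter vector.
# theta = c(A) or c(A, B); A, B are (n+1) x (n+1): rows = free destinations
# (groups 1..n, pre), cols = intercept + origin offsets (origins 2..n+1)
.theta_mats <- function(theta, n, time_dep) {
  d <- (n + 1L) * (n + 1L)
  A <- matrix(theta[seq_len(d)], n + 1L, n + 1L)
  B <- if (time_dep) matrix(theta[d + seq_len(d)], n + 1L, n + 1L) else
    matrix(0, n + 1L, n + 1L)
  comb <- function(M) {
    out <- M
    if (ncol(M) >= 2)
      out[, 2:ncol(M)] <- M[, 2:ncol(M)] + M[, 1]
    out
  }
  list(A = A, B = B, Acomb = comb(A), Bcomb = comb(B))
}

# model frame: integer origins/destinations/times plus allowed mask
.model_frame <- function(events, n) {
  ev <- as.data.frame(events)
  ev <- ev[ev$usable & ev$origin != n + 2L, , drop = FALSE]
  K <- n + 2L
  allow <- matrix(FALSE, n + 1L, K)
  for (o in seq_len(n + 1L)) allow[o, allowed_destinations(o, n)] <- TRUE
  bad <- !allow[cbind(ev$origin, ev$dest)]
  if (any(bad))
    stop("structurally impossible transition(s) in the data, e.g. origin ",
         ev$origin[which(bad)[1]], " -> dest ", ev$dest[which(bad)[1]])
  list(o = ev$origin, d = ev$dest, t = ev$t, N = nrow(ev), K = K,
       allow = allow)
}

# log-likelihood (and optionally per-event values / gradient) at theta
.loglik <- function(theta, mf, n, time_dep, pointwise = FALSE,
                    grad = FALSE) {
  m <- .theta_mats(theta, n, time_dep)
  Sf <- t(m$Acomb)[mf$o, , drop = FALSE] +
    mf$t * t(m$Bcomb)[mf$o, , drop = FALSE]
  S <- cbind(Sf, 0)
  AM <- mf$allow[mf$o, , drop = FALSE]
  S[!AM] <- -Inf
  mx <- S[, 1]
  for (k in 2:mf$K) mx <- pmax(mx, S[, k])
  lse <- mx + log(rowSums(exp(S - mx)))
  ll_i <- S[cbind(seq_len(mf$N), mf$d)] - lse
  if (pointwise) return(ll_i)
  if (!grad) return(sum(ll_i))
  P <- exp(S - lse)
  G <- -P[, seq_len(n + 1L), drop = FALSE]
  free_hit <- mf$d <= n + 1L
  G[cbind(which(free_hit), mf$d[free_hit])] <-
    G[cbind(which(free_hit), mf$d[free_hit])] + 1
  dA <- matrix(0, n + 1L, n + 1L)
  dA[, 1] <- colSums(G)
  agg <- rowsum(G, mf$o)
  lvl <- as.integer(rownames(agg))
  off <- lvl >= 2L
  if (any(off)) dA[, lvl[off]] <- t(agg[off, , drop = FALSE])
  gr <- as.vector(dA)
  if (time_dep) {
    Gt <- G * mf$t
    dB <- matrix(0, n + 1L, n + 1L)
    dB[, 1] <- colSums(Gt)
    aggt <- rowsum(Gt, mf$o)
    if (any(off)) dB[, lvl[off]] <- t(aggt[off, , drop = FALSE])
    gr <- c(gr, as.vector(dB))
  }
  list(value = sum(ll_i), grad = gr)
}

# ---- fitting ------------------------------------------------------------

#' Fit the Bayesian multinomial transition model
#'
#' Models each usable weekly transition with the softmax of linear score
#' functions (time-dependent, or constant with all slopes fixed to 0), with
#' independent Normal(0, `prior_sd`) priors on all free parameters. The
#' posterior is sampled with an adaptive random-walk Metropolis sampler
#' preconditioned on the Laplace approximation at the posterior mode (the
#' posterior of this model is smooth and close to Gaussian); split-Rhat
#' convergence diagnostics are reported and a warning is raised if any
#' exceeds 1.1.
#'
#' @param events a `transition_events` object (or data.frame with columns
#'   `origin`, `dest`, `t`, `usable`).
#' @param n_groups number of position groups `n`; taken from `events` when
#'   available.
#' @param form `"time_dependent"` or `"constant"`.
#' @param prior_sd prior standard deviation (default 10, weakly
#'   informative).
#' @param chains,iter,warmup MCMC settings; `iter` counts total iterations
#'   per chain including `warmup`.
#' @param seed RNG seed.
#' @return Object of class `transition_fit`: posterior `draws` (matrix,
#'   named columns `alpha[k,l]`/`beta[k,l]`), `chain` index, the posterior
#'   mode `map`, `rhat`, acceptance rates, model metadata and the model
#'   frame used.
#' @export
fit_transition_model <- function(events, n_groups = attr(events, "n_groups"),
                                 form = c("time_dependent", "constant"),
                                 prior_sd = 10, chains = 4, iter = 2000,
                                 warmup = floor(iter / 2), seed = 1) {
  form <- match.arg(form)
  if (is.null(n_groups)) stop("n_groups must be supplied")
  n <- as.integer(n_groups)
  time_dep <- form == "time_dependent"
  mf <- .model_frame(events, n)
  if (mf$N == 0) stop("no usable transitions")
  d1 <- (n + 1L) * (n + 1L)
  npar <- if (time_dep) 2L * d1 else d1

  nlpost <- function(theta)
    -(.loglik(theta, mf, n, time_dep) - sum(theta^2) / (2 * prior_sd^2))
  nlgrad <- function(theta) {
    g <- .loglik(theta, mf, n, time_dep, grad = TRUE)$grad
    -(g - theta / prior_sd^2)
  }

  opt <- optim(rep(0, npar), nlpost, nlgrad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  map <- opt$par
  H <- optimHess(map, nlpost, nlgrad)
  Sig <- tryCatch(solve(H), error = function(e) NULL)
  ch <- NULL
  if (!is.null(Sig)) {
    Sig <- (Sig + t(Sig)) / 2
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
  }
  if (is.null(ch)) ch <- diag(sqrt(1 / pmax(diag(H), 1e-6)))

  keep <- iter - warmup
  if (keep < 1) stop("iter must exceed warmup")
  draws <- matrix(NA_real_, chains * keep, npar)
  chain_id <- rep(seq_len(chains), each = keep)
  accept <- numeric(chains)
  base_scale <- 2.38 / sqrt(npar)
  # log-density of the (scaled) Laplace approximation, used for occasional
  # independence proposals that decorrelate the random walk
  ind_scale <- 1.3
  chi <- backsolve(ch, diag(npar))     # ch is upper-tri with Sig = ch'ch
  laplace_ld <- function(x) {
    z <- as.vector((x - map) %*% chi) / ind_scale
    -sum(z^2) / 2
  }
  set.seed(seed)
  for (c_ in seq_len(chains)) {
    x <- map + as.vector(0.5 * (rnorm(npar) %*% ch))
    lp <- -nlpost(x)
    lsc <- 0
    acc_w <- 0; n_w <- 0; acc_k <- 0
    for (it in seq_len(iter)) {
      if (it %% 5 == 0) {  # independence proposal from the Laplace approx
        prop <- map + ind_scale * as.vector(rnorm(npar) %*% ch)
        lp2 <- -nlpost(prop)
        ratio <- (lp2 - lp) + (laplace_ld(x) - laplace_ld(prop))
      } else {             # preconditioned random-walk proposal
        prop <- x + base_scale * exp(lsc) * as.vector(rnorm(npar) %*% ch)
        lp2 <- -nlpost(prop)
        ratio <- lp2 - lp
      }
      if (is.finite(lp2) && log(runif(1)) < ratio) {
        x <- prop; lp <- lp2
        if (it <= warmup) acc_w <- acc_w + 1 else acc_k <- acc_k + 1
      }
      if (it <= warmup) {
        n_w <- n_w + 1
        if (n_w == 50) {  # adapt walk scale toward ~30% acceptance
          lsc <- lsc + (acc_w / 50 - 0.3)
          acc_w <- 0; n_w <- 0
        }
      } else {
        draws[(c_ - 1L) * keep + (it - warmup), ] <- x
      }
    }
    accept[c_] <- acc_k / keep
  }

  kl_names <- function(stem) {
    kk <- rep(seq_len(n + 1L), n + 1L)
    ll <- rep(seq_len(n + 1L), each = n + 1L)
    sprintf("%s[%d,%d]", stem, kk, ll)
  }
  colnames(draws) <- if (time_dep) c(kl_names("alpha"), kl_names("beta")) else
    kl_names("alpha")

  rhat <- .split_rhat(draws, chain_id)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning(sprintf(
      "sampler convergence questionable: max split-Rhat = %.3f (param %s); consider more iterations",
      max(rhat, na.rm = TRUE), colnames(draws)[which.max(rhat)]))

  structure(list(draws = draws, chain = chain_id, n_groups = n, form = form,
                 prior_sd = prior_sd, baseline = "post", map = map,
                 model_frame = mf, events = events, rhat = rhat,
                 accept = accept, seed = seed,
                 state_labels = attr(events, "state_labels") %||%
                   state_labels(n)),
            class = "transition_fit")
}

.split_rhat <- function(draws, chain_id) {
  apply(draws, 2, function(x) {
    halves <- unlist(lapply(split(x, chain_id), function(xc) {
      h <- floor(length(xc) / 2)
      list(xc[seq_len(h)], xc[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(halves); nn <- length(halves[[1]])
    if (nn < 2) return(NA_real_)
    means <- vapply(halves, mean, 1.0)
    vars <- vapply(halves, var, 1.0)
    B <- nn * var(means); Wv <- mean(vars)
    if (Wv == 0) return(1)
    sqrt(((nn - 1) / nn * Wv + B / nn) / Wv)
  })
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf(
    "<transition_fit (%s): n = %d groups, %d transitions, %d draws, max Rhat %.3f>\n",
    x$form, x$n_groups, x$model_frame$N, nrow(x$draws),
    max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

# full (n+2) x (n+1) alpha/beta matrices (baseline post row of zeros) from
# one posterior draw
#' Extract full score-parameter matrices from a posterior draw
#' @param fit a `transition_fit`.
#' @param draw draw index (default 1).
#' @return List with `alpha` and `beta` matrices suitable for
#'   [score_linear()].
#' @export
draw_params <- function(fit, draw = 1) {
  n <- fit$n_groups
  m <- .theta_mats(fit$draws[draw, ], n, fit$form == "time_dependent")
  alpha <- rbind(m$A, 0)  # destinations: groups 1..n, pre, post(=0)
  beta <- rbind(m$B, 0)
  list(alpha = alpha, beta = beta)
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 (lppd - p_waic)` with the pointwise log predictive density
#' `lppd` and the effective parameter count `p_waic` equal to the sum of
#' posterior variances of the per-transition log-likelihoods.
#'
#' @param fit a `transition_fit`.
#' @param events transition events to evaluate (defaults to the fitted
#'   ones).
#' @return List of class `waic` with `waic`, `lppd`, `p_waic`.
#' @export
waic <- function(fit, events = NULL) {
  n <- fit$n_groups
  mf <- if (is.null(events)) fit$model_frame else .model_frame(events, n)
  time_dep <- fit$form == "time_dependent"
  S <- nrow(fit$draws)
  LL <- matrix(NA_real_, S, mf$N)
  for (s in seq_len(S))
    LL[s, ] <- .loglik(fit$draws[s, ], mf, n, time_dep, pointwise = TRUE)
  mx <- apply(LL, 2, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(LL, 2, mx)))))
  p_waic <- sum(apply(LL, 2, var))
  structure(list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic),
            class = "waic")
}

#' @export
print.waic <- function(x, ...) {
  cat(sprintf("WAIC = %.2f (lppd %.2f, p_waic %.2f)\n",
              x$waic, x$lppd, x$p_waic))
  invisible(x)
}

#' Posterior transition-probability curves
#'
#' For every origin state (groups and the entry row `pre`) and every allowed
#' destination (groups, `pre` stay, and the exit column `post`), the
#' posterior mean and first/third quartiles of the transition probability
#' over a grid of relative times.
#'
#' @param fit a `transition_fit`.
#' @param t_grid grid of relative times in \[0, 1\].
#' @param max_draws cap on the number of posterior draws used (evenly
#'   thinned).
#' @return `data.frame` with columns `origin`, `destination` (state
#'   labels), `t`, `mean`, `q25`, `q75`. Per draw and time, each origin row
#'   sums to 1 over its allowed destinations.
#' @export
predict_curves <- function(fit, t_grid = seq(0, 1, by = 0.05),
                           max_draws = 1000) {
  n <- fit$n_groups
  K <- n + 2L
  labs <- fit$state_labels
  idx <- unique(round(seq(1, nrow(fit$draws),
                          length.out = min(max_draws, nrow(fit$draws)))))
  time_dep <- fit$form == "time_dependent"
  out <- list()
  for (o in seq_len(n + 1L)) {
    allow <- seq_len(K) %in% allowed_destinations(o, n)
    probs <- array(NA_real_, c(length(idx), K, length(t_grid)))
    for (s in seq_along(idx)) {
      m <- .theta_mats(fit$draws[idx[s], ], n, time_dep)
      a <- c(m$Acomb[, o], 0)   # free destinations then post baseline
      b <- c(m$Bcomb[, o], 0)
      Sm <- a + outer(b, t_grid)          # K x G
      Sm[!allow, ] <- -Inf
      E <- exp(sweep(Sm, 2, apply(Sm, 2, max)))
      probs[s, , ] <- sweep(E, 2, colSums(E), "/")
    }
    for (k in which(allow)) {
      pm <- probs[, k, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        origin = labs[o], destination = labs[k], t = t_grid,
        mean = apply(pm, 3, mean),
        q25 = apply(pm, 3, quantile, 0.25),
        q75 = apply(pm, 3, quantile, 0.75))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
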