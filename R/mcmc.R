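#' MCMC configuration
#'
#' @param n_burnin Burn-in iterations per chain.
#' @param n_sampling Post-burn-in iterations per chain.
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param n_chains Number of independent chains (pooled).
#' @param seed Integer seed; each chain derives its own sub-seed.
#' @param n_aux Auxiliary components for the non-conjugate Dirichlet-process
#'   assignment update.
#' @param proposal_scales Named list of random-walk proposal standard
#'   deviations (`mu_a`, `delta`, `loglam`, `gamma`, `logeps`); adapted
#'   during burn-in toward a 0.2--0.5 acceptance rate and frozen afterwards.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_burnin = 2000, n_sampling = 2000, thin = 10,
                        n_chains = 2, seed = 1, n_aux = 3,
                        proposal_scales = NULL) {
  stopifnot(n_burnin >= 0, n_sampling >= 0, thin >= 1, n_chains >= 1,
            n_aux >= 1)
  scales <- list(mu_a = 0.3, delta = 0.3, loglam = 0.4, gamma = 0.3,
                 logeps = 0.4, shift = 0.3)
  if (!is.null(proposal_scales)) scales[names(proposal_scales)] <- proposal_scales
  structure(list(n_burnin = as.integer(n_burnin),
                 n_sampling = as.integer(n_sampling),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed), n_aux = as.integer(n_aux),
                 proposal_scales = scales),
            class = "mcmc_config")
}

#' Full-study MCMC protocol preset
#'
#' Eight independent chains, 10,000 burn-in iterations, then every 10th
#' state over 5,000 further iterations, pooled to 4,000 posterior samples.
#'
#' @param seed Integer seed.
#' @return An [mcmc_config()].
#' @export
mcmc_config_paper_protocol <- function(seed = 1) {
  mcmc_config(n_burnin = 10000, n_sampling = 5000, thin = 10, n_chains = 8,
              seed = seed)
}

#' Pooled retained-sample count implied by a configuration
#'
#' `n_chains * floor(n_sampling / thin)`.
#'
#' @param config An [mcmc_config()].
#' @return Integer.
#' @export
retained_sample_count <- function(config) {
  config$n_chains * (config$n_sampling %/% config$thin)
}

## ---------------------------------------------------------------------------
## Internal signature representation: random-walk increments + switches.
## Levels are derived; inactive increments are identically zero, so the
## equality ties of the dimensionality switches hold exactly.

isig <- function(mu_a, d_b, d_ac, d_cd, d_ce, llc, lle, s_ac, s_ce, s_l) {
  list(mu_a = mu_a, d_b = d_b, d_ac = if (s_ac) d_ac else 0,
       d_cd = d_cd, d_ce = if (s_ce) d_ce else 0,
       llc = llc, lle = if (s_l) lle else llc,
       s_ac = s_ac, s_ce = s_ce, s_l = s_l)
}

isig_prior_draw <- function(hyper) {
  s_ac <- stats::runif(1) < hyper$switch_prob
  s_ce <- stats::runif(1) < hyper$switch_prob
  s_l <- stats::runif(1) < hyper$switch_prob
  isig(stats::rnorm(1, hyper$mu_a_mean, hyper$mu_a_sd),
       stats::rnorm(1, 0, hyper$delta_sd),
       if (s_ac) stats::rnorm(1, 0, hyper$delta_sd) else 0,
       stats::rnorm(1, 0, hyper$delta_sd),
       if (s_ce) stats::rnorm(1, 0, hyper$delta_sd) else 0,
       stats::rnorm(1, hyper$loglambda_mean, hyper$loglambda_sd),
       stats::rnorm(1, hyper$loglambda_mean, hyper$loglambda_sd),
       s_ac, s_ce, s_l)
}

# log prior of the free coordinates (log-lambdas measured on the log scale)
isig_log_prior <- function(g, hyper) {
  lp <- stats::dnorm(g$mu_a, hyper$mu_a_mean, hyper$mu_a_sd, log = TRUE) +
    stats::dnorm(g$d_b, 0, hyper$delta_sd, log = TRUE) +
    stats::dnorm(g$d_cd, 0, hyper$delta_sd, log = TRUE) +
    stats::dnorm(g$llc, hyper$loglambda_mean, hyper$loglambda_sd, log = TRUE)
  if (g$s_ac) lp <- lp + stats::dnorm(g$d_ac, 0, hyper$delta_sd, log = TRUE)
  if (g$s_ce) lp <- lp + stats::dnorm(g$d_ce, 0, hyper$delta_sd, log = TRUE)
  if (g$s_l) {
    lp <- lp + stats::dnorm(g$lle, hyper$loglambda_mean, hyper$loglambda_sd,
                            log = TRUE)
  }
  p <- hyper$switch_prob
  lp + sum(ifelse(c(g$s_ac, g$s_ce, g$s_l), log(p), log1p(-p)))
}

isig_to_signature <- function(g) {
  signature_from_increments(g$mu_a, g$d_b, g$d_ac, g$d_cd, g$d_ce,
                            g$llc, g$lle, c(g$s_ac, g$s_ce), g$s_l)
}

signature_to_isig <- function(theta) {
  inc <- signature_increments(theta)
  isig(inc$mu_a, inc$delta_b, inc$delta_ac, inc$delta_cd, inc$delta_ce,
       inc$loglam_c, inc$loglam_e, theta$c_mu[1], theta$c_mu[2],
       theta$c_lambda)
}

# log-amplitude profile of an internal signature on a subject's time grid
isig_profile <- function(g, sg) {
  mu_c <- g$mu_a + g$d_ac
  X_b <- g$mu_a + g$d_b
  X_d <- mu_c + g$d_cd
  mu_e <- mu_c + g$d_ce
  f <- numeric(sg$T)
  f[sg$iv == 1L] <- g$mu_a
  f[sg$iv == 2L] <- X_b
  f[sg$iv == 4L] <- X_d
  ic <- sg$iv == 3L
  if (any(ic)) f[ic] <- mu_c + (X_b - mu_c) * exp(-sg$dtc[ic] / exp(g$llc))
  ie <- sg$iv == 5L
  if (any(ie)) f[ie] <- mu_e + (X_d - mu_e) * exp(-sg$dte[ie] / exp(g$lle))
  f
}

## ---------------------------------------------------------------------------
## Model data: flattened (subject, refOTU) units plus per-subject grids.

build_model_data <- function(dataset, schedules) {
  stopifnot(inherits(dataset, "counts_dataset"))
  if (is.null(schedules)) stop("schedules are required", call. = FALSE)
  if (inherits(schedules, "perturbation_schedule")) {
    schedules <- stats::setNames(rep(list(schedules), length(dataset$subjects)),
                                 dataset$subjects)
  }
  phi <- compute_read_depth_offsets(dataset)
  subj <- list(); Y <- list()
  unit_subject <- integer(0); unit_col <- integer(0); unit_id <- character(0)
  for (si in seq_along(dataset$subjects)) {
    s <- dataset$subjects[[si]]
    sched <- schedules[[s]]
    tt <- dataset$times[[s]]
    iv <- interval_of(sched, tt)
    subj[[si]] <- list(
      name = s, times = tt, T = length(tt), iv = iv,
      dtc = tt - sched$breaks[3], dte = tt - sched$breaks[5],
      phi = phi[[s]], pulse = iv %in% c(2L, 4L), schedule = sched)
    Y[[si]] <- t(dataset$counts[[s]])  # T x O
    O_s <- nrow(dataset$counts[[s]])
    unit_subject <- c(unit_subject, rep.int(si, O_s))
    unit_col <- c(unit_col, seq_len(O_s))
    unit_id <- c(unit_id, rownames(dataset$counts[[s]]))
  }
  n <- length(unit_subject)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  list(subjects = dataset$subjects, S = length(dataset$subjects),
       subj = subj, Y = Y, LGY1 = lapply(Y, lgamma1p_counts), n = n,
       unit_subject = unit_subject, unit_col = unit_col, unit_id = unit_id,
       subj_units = split(seq_len(n), unit_subject),
       taxonomy = dataset$taxonomy)
}

lgamma1p_counts <- function(Y) lgamma(Y + 1)

# per-time-point inverse shape for one subject
eps_vec <- function(sg, eps1, eps2) {
  e <- rep(eps1, sg$T)
  e[sg$pulse] <- eps2
  e
}

## NB log-pmf via cached sufficient statistics. With size r = 1/eps fixed,
## log NB(y; r, m) = [lgamma(y+r) - lgamma(r) - lgamma(y+1) + r log r]
##                   - (r + y) log(r + m) + y log m,
## and the bracketed term depends only on (y, eps): cache it per subject and
## refresh it only when a dispersion update is accepted.
nb_const_subject <- function(md, si, eps1, eps2) {
  sg <- md$subj[[si]]
  r <- 1 / eps_vec(sg, eps1, eps2)
  A <- lgamma(md$Y[[si]] + r) - (lgamma(r) - r * log(r)) - md$LGY1[[si]]
  list(r = r, A = A)
}

nb_const_all <- function(md, eps1, eps2) {
  lapply(seq_len(md$S), nb_const_subject, md = md, eps1 = eps1, eps2 = eps2)
}

# log-likelihood of selected units (columns) of subject si under profile f,
# given a per-subject constant cache nbc = list(r, A)
ll_cols <- function(md, si, nbc, cols, f, gamma_cols) {
  Y <- md$Y[[si]][, cols, drop = FALSE]
  sg <- md$subj[[si]]
  M <- exp(outer(f + sg$phi, gamma_cols, "+"))
  r <- nbc$r
  colSums(nbc$A[, cols, drop = FALSE] - (r + Y) * log(r + M) + Y * log(M))
}

# log-likelihood of every unit of subject si under profile f (vectorized)
ll_subject_profile <- function(st, md, si, f, gamma_units) {
  ll_cols(md, si, st$nbc[[si]], seq_len(ncol(md$Y[[si]])), f, gamma_units)
}

# log-likelihood of a single unit under profile f
ll_unit_profile <- function(st, md, u, f, gamma_u) {
  si <- md$unit_subject[u]
  sg <- md$subj[[si]]
  nbc <- st$nbc[[si]]
  y <- md$Y[[si]][, md$unit_col[u]]
  m <- exp(f + sg$phi + gamma_u)
  r <- nbc$r
  sum(nbc$A[, md$unit_col[u]] - (r + y) * log(r + m) + y * log(m))
}

## ---------------------------------------------------------------------------
## Sampler state: environment with z, sigs (internal signatures), cached
## per-subject profiles F, nuisance parameters and adaptation bookkeeping.

state_profiles <- function(st, md, k) {
  lapply(seq_len(md$S), function(si) isig_profile(st$sigs[[k]], md$subj[[si]]))
}

init_state <- function(md, hyper, config, likelihood) {
  st <- new.env(parent = emptyenv())
  st$sigs <- list(isig_prior_draw(hyper))
  st$z <- rep(1L, md$n)
  st$gamma <- numeric(md$n)
  st$eps1 <- exp(hyper$eps_meanlog)
  st$eps2 <- exp(hyper$eps_meanlog)
  st$alpha <- hyper$alpha_shape / hyper$alpha_rate
  st$nbc <- nb_const_all(md, st$eps1, st$eps2)
  st$F <- lapply(seq_along(st$sigs), function(k) state_profiles(st, md, k))
  st$likelihood <- likelihood
  st$scales <- config$proposal_scales
  st$acc <- list(); st$try <- list()
  for (nm in names(st$scales)) { st$acc[[nm]] <- 0; st$try[[nm]] <- 0 }
  st
}

# cluster log-likelihood of one unit (0 when the likelihood is disabled)
st_ll_unit <- function(st, md, u, f) {
  if (!st$likelihood) return(0)
  ll_unit_profile(st, md, u, f, st$gamma[u])
}

# n x K matrix of unit log-likelihoods under each active cluster
st_ll_matrix <- function(st, md) {
  K <- length(st$sigs)
  LL <- matrix(0, md$n, K)
  if (!st$likelihood) return(LL)
  for (k in seq_len(K)) {
    for (si in seq_len(md$S)) {
      us <- md$subj_units[[si]]
      LL[us, k] <- ll_subject_profile(st, md, si, st$F[[k]][[si]],
                                      st$gamma[us])
    }
  }
  LL
}

# members log-likelihood of cluster k under an arbitrary internal signature
st_ll_members <- function(st, md, k, g) {
  if (!st$likelihood) return(0)
  tot <- 0
  for (si in seq_len(md$S)) {
    us <- md$subj_units[[si]]
    us <- us[st$z[us] == k]
    if (!length(us)) next
    f <- isig_profile(g, md$subj[[si]])
    tot <- tot + sum(ll_cols(md, si, st$nbc[[si]], md$unit_col[us], f,
                             st$gamma[us]))
  }
  tot
}

## --- Dirichlet-process assignment sweep (non-conjugate, auxiliary
## components in the style of the standard algorithm-8 scheme) -------------

sweep_crp <- function(st, md, hyper, config) {
  m_aux <- config$n_aux
  LL <- st_ll_matrix(st, md)
  nvec <- tabulate(st$z, nbins = length(st$sigs))
  for (u in seq_len(md$n)) {
    si <- md$unit_subject[u]
    k_old <- st$z[u]
    nvec[k_old] <- nvec[k_old] - 1L
    singleton <- NULL
    if (nvec[k_old] == 0L) singleton <- st$sigs[[k_old]]
    aux <- vector("list", m_aux)
    aux_ll <- numeric(m_aux)
    for (j in seq_len(m_aux)) {
      aux[[j]] <- if (j == 1L && !is.null(singleton)) singleton
        else isig_prior_draw(hyper)
      aux_ll[j] <- st_ll_unit(st, md, u, isig_profile(aux[[j]], md$subj[[si]]))
    }
    logw <- c(ifelse(nvec > 0, log(nvec), -Inf) + LL[u, ],
              log(st$alpha / m_aux) + aux_ll)
    w <- exp(logw - max(logw))
    pick <- sample.int(length(w), 1L, prob = w)
    K <- length(st$sigs)
    if (pick > K) {
      g <- aux[[pick - K]]
      st$sigs[[K + 1L]] <- g
      st$F[[K + 1L]] <- state_profiles(st, md, K + 1L)
      newcol <- numeric(md$n)
      if (st$likelihood) {
        for (sj in seq_len(md$S)) {
          us <- md$subj_units[[sj]]
          newcol[us] <- ll_subject_profile(st, md, sj, st$F[[K + 1L]][[sj]],
                                           st$gamma[us])
        }
      }
      LL <- cbind(LL, newcol)
      nvec <- c(nvec, 0L)
      pick <- K + 1L
    }
    st$z[u] <- pick
    nvec[pick] <- nvec[pick] + 1L
  }
  # prune empty clusters and relabel compactly
  occ <- which(nvec > 0L)
  st$sigs <- st$sigs[occ]
  st$F <- st$F[occ]
  st$z <- match(st$z, occ)
  invisible(st)
}

## --- Metropolis-Hastings parameter updates --------------------------------

mh_bookkeep <- function(st, type, accepted) {
  st$try[[type]] <- st$try[[type]] + 1
  if (accepted) st$acc[[type]] <- st$acc[[type]] + 1
}

# prior log-density of one free coordinate of an internal signature
coord_log_prior <- function(g, coord, hyper) {
  switch(coord,
    mu_a = stats::dnorm(g$mu_a, hyper$mu_a_mean, hyper$mu_a_sd, log = TRUE),
    d_b = stats::dnorm(g$d_b, 0, hyper$delta_sd, log = TRUE),
    d_ac = stats::dnorm(g$d_ac, 0, hyper$delta_sd, log = TRUE),
    d_cd = stats::dnorm(g$d_cd, 0, hyper$delta_sd, log = TRUE),
    d_ce = stats::dnorm(g$d_ce, 0, hyper$delta_sd, log = TRUE),
    llc = stats::dnorm(g$llc, hyper$loglambda_mean, hyper$loglambda_sd, log = TRUE),
    lle = stats::dnorm(g$lle, hyper$loglambda_mean, hyper$loglambda_sd, log = TRUE))
}

sweep_signature_params <- function(st, md, hyper) {
  for (k in seq_along(st$sigs)) {
    g <- st$sigs[[k]]
    cur_ll <- st_ll_members(st, md, k, g)
    coords <- c("mu_a", "d_b", if (g$s_ac) "d_ac", "d_cd",
                if (g$s_ce) "d_ce", "llc", if (g$s_l) "lle")
    for (coord in coords) {
      type <- switch(coord, mu_a = "mu_a", llc = "loglam", lle = "loglam",
                     "delta")
      prop <- g
      prop[[coord]] <- g[[coord]] + stats::rnorm(1, 0, st$scales[[type]])
      if (coord == "llc" && !g$s_l) prop$lle <- prop$llc  # tied lambda moves too
      new_ll <- st_ll_members(st, md, k, prop)
      logr <- new_ll - cur_ll +
        coord_log_prior(prop, coord, hyper) - coord_log_prior(g, coord, hyper)
      ok <- log(stats::runif(1)) < logr
      mh_bookkeep(st, type, ok)
      if (ok) { g <- prop; cur_ll <- new_ll }
    }
    # translation move: mu_a + c, member gammas - c leaves every mean
    # count unchanged (the whole trajectory shifts with mu_a), so the
    # acceptance ratio is a pure prior ratio; it decouples cluster levels
    # from member offsets and lets units migrate between clusters.
    members <- which(st$z == k)
    cshift <- stats::rnorm(1, 0, st$scales$shift)
    gam <- st$gamma[members]
    logr <- stats::dnorm(g$mu_a + cshift, hyper$mu_a_mean, hyper$mu_a_sd, log = TRUE) -
      stats::dnorm(g$mu_a, hyper$mu_a_mean, hyper$mu_a_sd, log = TRUE) +
      sum(stats::dnorm(gam - cshift, 0, hyper$gamma_sd, log = TRUE)) -
      sum(stats::dnorm(gam, 0, hyper$gamma_sd, log = TRUE))
    ok <- log(stats::runif(1)) < logr
    mh_bookkeep(st, "shift", ok)
    if (ok) {
      g$mu_a <- g$mu_a + cshift
      st$gamma[members] <- gam - cshift
    }
    if (!identical(g, st$sigs[[k]])) {
      st$sigs[[k]] <- g
      st$F[[k]] <- state_profiles(st, md, k)
    }
  }
  invisible(st)
}

## --- Reversible-jump dimensionality switch toggles ------------------------
## Birth moves draw the new increment (or new log-lambda) from its prior, so
## the acceptance ratio reduces to the likelihood ratio times the prior odds
## of the switch (Jacobian 1).

sweep_switches <- function(st, md, hyper) {
  lodds <- log(hyper$switch_prob) - log1p(-hyper$switch_prob)
  for (k in seq_along(st$sigs)) {
    g <- st$sigs[[k]]
    cur_ll <- st_ll_members(st, md, k, g)
    # a->c equilibrium increment
    prop <- g
    if (g$s_ac) { prop$s_ac <- FALSE; prop$d_ac <- 0 }
    else { prop$s_ac <- TRUE; prop$d_ac <- stats::rnorm(1, 0, hyper$delta_sd) }
    new_ll <- st_ll_members(st, md, k, prop)
    logr <- new_ll - cur_ll + if (prop$s_ac) lodds else -lodds
    if (log(stats::runif(1)) < logr) { g <- prop; cur_ll <- new_ll }
    # c->e equilibrium increment
    prop <- g
    if (g$s_ce) { prop$s_ce <- FALSE; prop$d_ce <- 0 }
    else { prop$s_ce <- TRUE; prop$d_ce <- stats::rnorm(1, 0, hyper$delta_sd) }
    new_ll <- st_ll_members(st, md, k, prop)
    logr <- new_ll - cur_ll + if (prop$s_ce) lodds else -lodds
    if (log(stats::runif(1)) < logr) { g <- prop; cur_ll <- new_ll }
    # distinct second relaxation time
    prop <- g
    if (g$s_l) { prop$s_l <- FALSE; prop$lle <- g$llc }
    else {
      prop$s_l <- TRUE
      prop$lle <- stats::rnorm(1, hyper$loglambda_mean, hyper$loglambda_sd)
    }
    new_ll <- st_ll_members(st, md, k, prop)
    logr <- new_ll - cur_ll + if (prop$s_l) lodds else -lodds
    if (log(stats::runif(1)) < logr) g <- prop
    if (!identical(g, st$sigs[[k]])) {
      st$sigs[[k]] <- g
      st$F[[k]] <- state_profiles(st, md, k)
    }
  }
  invisible(st)
}

## --- Nuisance updates: gamma_so, eps1/eps2, DP concentration --------------

sweep_nuisance <- function(st, md, hyper) {
  # per-unit offsets
  for (u in seq_len(md$n)) {
    f <- st$F[[st$z[u]]][[md$unit_subject[u]]]
    cur <- st_ll_unit(st, md, u, f) +
      stats::dnorm(st$gamma[u], 0, hyper$gamma_sd, log = TRUE)
    gam_new <- st$gamma[u] + stats::rnorm(1, 0, st$scales$gamma)
    new <- (if (st$likelihood)
              ll_unit_profile(st, md, u, f, gam_new) else 0) +
      stats::dnorm(gam_new, 0, hyper$gamma_sd, log = TRUE)
    ok <- log(stats::runif(1)) < new - cur
    mh_bookkeep(st, "gamma", ok)
    if (ok) st$gamma[u] <- gam_new
  }
  # dispersions (joint data likelihood; eps1 on quiescent, eps2 on pulses)
  total_ll <- function(e1, e2) {
    if (!st$likelihood) return(0)
    tot <- 0
    for (si in seq_len(md$S)) {
      us <- md$subj_units[[si]]
      nbc <- nb_const_subject(md, si, e1, e2)
      for (k in unique(st$z[us])) {
        uk <- us[st$z[us] == k]
        tot <- tot + sum(ll_cols(md, si, nbc, md$unit_col[uk],
                                 st$F[[k]][[si]], st$gamma[uk]))
      }
    }
    tot
  }
  cur_ll <- total_ll(st$eps1, st$eps2)
  for (which_eps in 1:2) {
    old <- if (which_eps == 1) st$eps1 else st$eps2
    new_eps <- old * exp(stats::rnorm(1, 0, st$scales$logeps))
    new_ll <- if (which_eps == 1) total_ll(new_eps, st$eps2)
      else total_ll(st$eps1, new_eps)
    logr <- new_ll - cur_ll +
      stats::dnorm(log(new_eps), hyper$eps_meanlog, hyper$eps_sdlog, log = TRUE) -
      stats::dnorm(log(old), hyper$eps_meanlog, hyper$eps_sdlog, log = TRUE)
    ok <- log(stats::runif(1)) < logr
    mh_bookkeep(st, "logeps", ok)
    if (ok) {
      if (which_eps == 1) st$eps1 <- new_eps else st$eps2 <- new_eps
      st$nbc <- nb_const_all(md, st$eps1, st$eps2)
      cur_ll <- new_ll
    }
  }
  # DP concentration: Escobar-West auxiliary-variable update
  st$alpha <- update_alpha_escobar_west(st$alpha, length(st$sigs), md$n,
                                        hyper$alpha_shape, hyper$alpha_rate)
  invisible(st)
}

# Gibbs update of the DP concentration given the number of occupied
# clusters k and sample size n, under a Gamma(a, b) prior.
update_alpha_escobar_west <- function(alpha, k, n, a, b) {
  eta <- stats::rbeta(1, alpha + 1, n)
  odds <- (a + k - 1) / (n * (b - log(eta)))
  shape <- if (stats::runif(1) < odds / (1 + odds)) a + k else a + k - 1
  stats::rgamma(1, shape = shape, rate = b - log(eta))
}

adapt_scales <- function(st) {
  for (nm in names(st$scales)) {
    if (st$try[[nm]] < 20) next
    rate <- st$acc[[nm]] / st$try[[nm]]
    if (rate < 0.2) st$scales[[nm]] <- st$scales[[nm]] * 0.7
    if (rate > 0.5) st$scales[[nm]] <- st$scales[[nm]] * 1.4
    st$acc[[nm]] <- 0; st$try[[nm]] <- 0
  }
}

mcmc_sweep <- function(st, md, hyper, config) {
  sweep_crp(st, md, hyper, config)
  sweep_signature_params(st, md, hyper)
  sweep_switches(st, md, hyper)
  sweep_nuisance(st, md, hyper)
  invisible(st)
}

snapshot_state <- function(st, md, chain, iter) {
  list(z = st$z,
       signatures = lapply(st$sigs, isig_to_signature),
       gamma = st$gamma, eps1 = st$eps1, eps2 = st$eps2, alpha = st$alpha,
       n_clusters = length(st$sigs), chain = chain, iter = iter)
}

resolve_hyper <- function(hyper, md) {
  if (is.null(hyper$mu_a_mean)) {
    logmeans <- vapply(seq_len(md$n), function(u) {
      log(mean(md$Y[[md$unit_subject[u]]][, md$unit_col[u]]) + 0.5)
    }, numeric(1))
    hyper$mu_a_mean <- mean(logmeans)
  }
  hyper
}

#' Fit the infinite-mixture trajectory model by MCMC
#'
#' Runs `n_chains` independent chains of the blocked sampler: Gibbs
#' reassignment of (subject, refOTU) units over the Dirichlet-process
#' mixture using auxiliary fresh components (non-conjugate scheme),
#' random-walk Metropolis-Hastings updates of the signature parameters,
#' reversible-jump toggles of the dimensionality switches (birth proposals
#' from the prior), Metropolis updates of the per-unit offsets and the two
#' dispersion parameters, and a Gibbs update of the DP concentration.
#' Proposal scales adapt during burn-in only. Fully reproducible given
#' `config$seed`.
#'
#' @param dataset A (typically [filter_refotus()]-ed) [counts_dataset()].
#' @param schedules Named list of per-subject [perturbation_schedule()]s, or
#'   a single schedule shared by all subjects.
#' @param config An [mcmc_config()].
#' @param hyper A [default_hyperparams()]; `mu_a_mean = NULL` is replaced by
#'   the mean log mean count across refOTUs.
#' @param likelihood Internal switch; `FALSE` disables the data likelihood
#'   so every update targets the prior (used for sampler validation).
#' @return A `posterior_samples` object: list of retained state snapshots
#'   plus unit/subject metadata.
#' @export
run_mcmc <- function(dataset, schedules, config = mcmc_config(),
                     hyper = default_hyperparams(), likelihood = TRUE) {
  md <- build_model_data(dataset, schedules)
  hyper <- resolve_hyper(hyper, md)
  samples <- list()
  rates <- list()
  for (chain in seq_len(config$n_chains)) {
    set.seed((config$seed * 11L + 7919L * chain) %% 2147483587L)
    st <- init_state(md, hyper, config, likelihood)
    for (iter in seq_len(config$n_burnin + config$n_sampling)) {
      mcmc_sweep(st, md, hyper, config)
      if (iter <= config$n_burnin) {
        if (iter %% 100L == 0L) adapt_scales(st)
      } else if ((iter - config$n_burnin) %% config$thin == 0L) {
        samples[[length(samples) + 1L]] <- snapshot_state(st, md, chain, iter)
      }
    }
    rates[[chain]] <- mapply(function(a, t) if (t > 0) a / t else NA_real_,
                             st$acc, st$try)
  }
  structure(
    list(samples = samples,
         units = data.frame(subject = md$subjects[md$unit_subject],
                            refotu = md$unit_id, stringsAsFactors = FALSE),
         subjects = md$subjects,
         O_s = stats::setNames(lengths(md$subj_units), md$subjects),
         schedules = stats::setNames(lapply(md$subj, `[[`, "schedule"),
                                     md$subjects),
         taxonomy = md$taxonomy, config = config, hyper = hyper,
         acceptance_rates = rates),
    class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("Posterior samples: J=%d (%d chain(s)), %d unit(s), %d subject(s)\n",
              length(x$samples), x$config$n_chains, nrow(x$units),
              length(x$subjects)))
  if (length(x$samples)) {
    ks <- vapply(x$samples, `[[`, integer(1), "n_clusters")
    cat(sprintf("  occupied signatures: mean %.2f (range %d-%d)\n",
                mean(ks), min(ks), max(ks)))
  }
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-free PSRF of a scalar chain summary across independent chains:
#' `sqrt(((n-1)/n * W + B/n) / W)` with between- and within-chain variances
#' `B` and `W`, floored at 1 (identical chains give exactly 1).
#'
#' @param chains Matrix with one column per chain (equal lengths >= 2), or a
#'   list of equal-length numeric vectors.
#' @return The statistic (>= 1 up to floating point).
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    if (length(unique(lengths(chains))) != 1L) {
      stop("chains must have equal lengths", call. = FALSE)
    }
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("at least two chains are required", call. = FALSE)
  n <- nrow(chains)
  if (n < 2L) stop("chains must have length >= 2", call. = FALSE)
  means <- colMeans(chains)
  B <- n * stats::var(means)
  W <- mean(apply(chains, 2, stats::var))
  if (W == 0) return(1)
  # floored at 1: with no between-chain spread the raw ratio is (n-1)/n
  sqrt(max(1, ((n - 1) / n * W + B / n) / W))
}

#' Posterior-mean count predictions
#'
#' Posterior mean of `m_sot = exp(f + gamma + phi)` at arbitrary
#' time-points, averaging over retained samples.
#'
#' @param samples A `posterior_samples` object.
#' @param times Named list of day vectors (per subject).
#' @param phi Named list of read-depth offsets matching `times` (default 0).
#' @return Named list of refOTU x time matrices of predicted mean counts.
#' @export
predict_counts <- function(samples, times, phi = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  out <- list()
  for (si in seq_along(samples$subjects)) {
    s <- samples$subjects[[si]]
    tt <- times[[s]]
    ph <- if (is.null(phi)) numeric(length(tt)) else phi[[s]]
    us <- which(samples$units$subject == s)
    acc <- matrix(0, length(us), length(tt))
    for (smp in samples$samples) {
      fk <- lapply(smp$signatures, evaluate_signature, t = tt,
                   schedule = samples$schedules[[s]])
      for (i in seq_along(us)) {
        u <- us[i]
        acc[i, ] <- acc[i, ] + exp(fk[[smp$z[u]]] + smp$gamma[u] + ph)
      }
    }
    acc <- acc / length(samples$samples)
    rownames(acc) <- samples$units$refotu[us]
    out[[s]] <- acc
  }
  out
}
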