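make_md <- function(n_otu = 3, times = c(0, 5, 12, 20, 33, 40), seed = 1) {
  ds <- toy_dataset(n_otu = n_otu, times = times, seed = seed)
  trajmix:::build_model_data(ds, list(S1 = toy_schedule()))
}

test_that("assignment sweep reproduces the CRP cluster-count closed form", {
  # likelihood disabled, alpha fixed at 1: E[K] = sum_{i=1}^{n} 1/i
  md <- make_md(n_otu = 3)
  hyper <- default_hyperparams(mu_a_mean = 0)
  cfg <- mcmc_config(n_aux = 3, seed = 1)
  set.seed(42)
  st <- trajmix:::init_state(md, hyper, cfg, likelihood = FALSE)
  st$alpha <- 1
  ks <- replicate(4000, {
    trajmix:::sweep_crp(st, md, hyper, cfg)
    length(st$sigs)
  })
  expect_equal(mean(ks), 1 + 1 / 2 + 1 / 3, tolerance = 0.04)
})

test_that("a single refOTU always occupies exactly one cluster", {
  ds <- toy_dataset(n_otu = 1)
  fit <- run_mcmc(ds, toy_schedule(),
                  mcmc_config(n_burnin = 50, n_sampling = 100, thin = 5,
                              n_chains = 1, seed = 2))
  expect_true(all(vapply(fit$samples, `[[`, integer(1), "n_clusters") == 1L))
  expect_true(all(vapply(fit$samples, function(s) s$z, integer(1)) == 1L))
})

test_that("co-assignment of an identical pair dominates, matching a partition oracle", {
  sched <- toy_schedule()
  tt <- c(2, 6, 18, 25, 38, 45)
  eps <- 0.2
  set.seed(7)
  f1 <- 3; f3 <- 6   # flat trajectories, far apart
  y1 <- rnbinom(6, size = 1 / eps, mu = exp(f1))
  y2 <- rnbinom(6, size = 1 / eps, mu = exp(f1))
  y3 <- rnbinom(6, size = 1 / eps, mu = exp(f3))
  Y <- rbind(otu1 = y1, otu2 = y2, otu3 = y3)
  ds <- counts_dataset(list(S1 = Y), list(S1 = tt),
                       totals = list(S1 = rep(1e5, 6)))
  hyper <- default_hyperparams(mu_a_mean = 4.5, gamma_sd = 0.05,
                               eps_meanlog = log(eps), eps_sdlog = 0.1)
  fit <- run_mcmc(ds, sched,
                  mcmc_config(n_burnin = 500, n_sampling = 1000, thin = 5,
                              n_chains = 1, seed = 3), hyper)
  P <- coassignment_matrix(fit)

  # oracle: exhaustive partitions of {1,2,3} with Monte-Carlo block marginal
  # likelihoods under the same signature prior (gamma = 0, eps fixed)
  set.seed(99)
  draws <- replicate(20000, trajmix:::isig_prior_draw(hyper), simplify = FALSE)
  sg <- list(T = 6L, iv = interval_of(sched, tt),
             dtc = tt - sched$breaks[3], dte = tt - sched$breaks[5])
  block_ml <- function(ys) {
    mean(vapply(draws, function(g) {
      f <- trajmix:::isig_profile(g, sg)
      exp(sum(vapply(ys, function(y) {
        sum(dnbinom(y, size = 1 / eps, mu = exp(f), log = TRUE))
      }, numeric(1))))
    }, numeric(1)))
  }
  parts <- list(list(1:3), list(1:2, 3), list(c(1, 3), 2), list(c(2, 3), 1),
                list(1, 2, 3))
  ylist <- list(y1, y2, y3)
  crp_w <- function(p) prod(vapply(p, function(b) factorial(length(b) - 1),
                                   numeric(1)))  # alpha = 1
  post <- vapply(parts, function(p) {
    crp_w(p) * prod(vapply(p, function(b) block_ml(ylist[b]), numeric(1)))
  }, numeric(1))
  post <- post / sum(post)
  p12_oracle <- sum(post[c(1, 2)])
  p13_oracle <- sum(post[c(1, 3)])
  expect_gt(p12_oracle, p13_oracle)
  expect_gt(P["S1:otu1", "S1:otu2"], 0.8)
  expect_lt(P["S1:otu1", "S1:otu3"], 0.4)
  expect_equal(P["S1:otu1", "S1:otu2"], p12_oracle, tolerance = 0.2)
})

test_that("with the likelihood disabled every marginal reproduces its prior", {
  ds <- toy_dataset(n_otu = 5, seed = 4)
  hyper <- default_hyperparams(mu_a_mean = 1)
  fit <- run_mcmc(ds, toy_schedule(),
                  mcmc_config(n_burnin = 300, n_sampling = 2000, thin = 4,
                              n_chains = 2, seed = 5),
                  hyper, likelihood = FALSE)
  # switch frequencies ~ Bernoulli(0.5)
  on_mu1 <- mean(vapply(fit$samples, function(s) s$signatures[[s$z[1]]]$c_mu[1],
                        logical(1)))
  on_lam <- mean(vapply(fit$samples, function(s) s$signatures[[s$z[1]]]$c_lambda,
                        logical(1)))
  expect_equal(on_mu1, 0.5, tolerance = 0.07)
  expect_equal(on_lam, 0.5, tolerance = 0.07)
  # lambda_c quantiles ~ LogNormal(log 7, 1)
  lam <- vapply(fit$samples, function(s) s$signatures[[s$z[1]]]$lambda_c,
                numeric(1))
  expect_equal(median(log(lam)), log(7), tolerance = 0.25)
  expect_equal(sd(log(lam)), 1, tolerance = 0.15)
  # dispersion ~ LogNormal(-1, 1), offsets ~ N(0, 1)
  expect_equal(mean(log(vapply(fit$samples, `[[`, numeric(1), "eps1"))), -1,
               tolerance = 0.25)
  gam <- vapply(fit$samples, function(s) s$gamma[2], numeric(1))
  expect_equal(mean(gam), 0, tolerance = 0.15)
  expect_equal(sd(gam), 1, tolerance = 0.15)
  # cluster count ~ CRP with Gamma(1,1)-mixed concentration
  ref <- trajmix:::prior_reference_draws(4000, n_units = 5, hyper = hyper,
                                         seed = 11)
  ks <- vapply(fit$samples, `[[`, integer(1), "n_clusters")
  expect_equal(mean(ks), mean(ref$K), tolerance = 0.25)
})

test_that("joint-distribution (successive-conditional) check leaves the prior invariant", {
  # absolute bounds ~3 Monte-Carlo sigma at the observed effective sample
  # sizes; the slow-mixing level/offset pair gets a loose bound, the
  # informative margins (switches, lambda, dispersion, offsets, clusters)
  # tight ones
  hyper <- default_hyperparams(mu_a_mean = 2)
  gw <- trajmix:::geweke_successive_conditional(
    n_cycles = 6000, n_units = 4, times = seq(0, 13, length.out = 10),
    hyper = hyper, seed = 8)
  gw <- gw[-(1:400), ]   # transient
  ref <- trajmix:::prior_reference_draws(4000, n_units = 4, hyper = hyper,
                                         seed = 9)
  expect_lt(abs(mean(gw$s_ac) - 0.5), 0.08)
  expect_lt(abs(mean(gw$s_l) - 0.5), 0.08)
  expect_lt(abs(mean(gw$loglam_c) - log(7)), 0.25)
  expect_lt(abs(mean(log(gw$eps1)) + 1), 0.3)
  expect_lt(abs(mean(gw$gamma1)), 0.25)
  expect_lt(abs(sd(gw$gamma1) - 1), 0.25)
  expect_lt(abs(mean(gw$K) - mean(ref$K)), 0.35)
  expect_lt(abs(mean(gw$mu_a) - mean(ref$mu_a)), 1.2)
  expect_lt(abs(sd(gw$mu_a) - sd(ref$mu_a)), 0.5)
})

test_that("chains are bit-reproducible and bookkeeping is exact", {
  ds <- toy_dataset(n_otu = 4, seed = 6)
  cfg <- mcmc_config(n_burnin = 100, n_sampling = 200, thin = 10,
                     n_chains = 2, seed = 17)
  f1 <- run_mcmc(ds, toy_schedule(), cfg)
  f2 <- run_mcmc(ds, toy_schedule(), cfg)
  expect_identical(f1$samples, f2$samples)
  expect_length(f1$samples, retained_sample_count(cfg))
  # occupancy: every sample's assignments tabulate to the unit count
  for (s in f1$samples) {
    expect_equal(sum(tabulate(s$z)), 4)
    expect_true(all(tabulate(s$z, nbins = s$n_clusters) > 0))
    expect_length(s$signatures, s$n_clusters)
  }
  # empty sampling phase
  f0 <- run_mcmc(ds, toy_schedule(),
                 mcmc_config(n_burnin = 10, n_sampling = 0, n_chains = 1,
                             seed = 1))
  expect_length(f0$samples, 0)
  expect_error(run_mcmc(counts_dataset(list(), list()), toy_schedule()))
})

test_that("constant-signature posterior matches the Poisson log-link mean", {
  # one refOTU observed on the pre-antibiotic interval at near-Poisson noise:
  # the posterior of mu_a + gamma concentrates at log(mean(y)) - mean(phi)
  set.seed(21)
  tt <- seq(0.2, 9.8, length.out = 200)
  sched <- toy_schedule()
  y <- rpois(200, 120)
  ds <- counts_dataset(list(S1 = matrix(y, 1, 200,
                                        dimnames = list("otu1", NULL))),
                       list(S1 = tt), totals = list(S1 = rep(1e5, 200)))
  hyper <- default_hyperparams(mu_a_mean = log(100),
                               eps_meanlog = -5, eps_sdlog = 0.5)
  fit <- run_mcmc(ds, sched,
                  mcmc_config(n_burnin = 400, n_sampling = 600, thin = 5,
                              n_chains = 1, seed = 4), hyper)
  level <- vapply(fit$samples, function(s) {
    s$signatures[[s$z[1]]]$mu_a + s$gamma[1]
  }, numeric(1))
  expect_equal(mean(level), log(mean(y)), tolerance = 0.05)
})

test_that("zero-step proposals leave the parameter state unchanged", {
  md <- make_md(n_otu = 3)
  hyper <- default_hyperparams(mu_a_mean = 3)
  cfg <- mcmc_config(seed = 1)
  set.seed(5)
  st <- trajmix:::init_state(md, hyper, cfg, likelihood = TRUE)
  for (nm in names(st$scales)) st$scales[[nm]] <- 0
  sigs0 <- st$sigs; gamma0 <- st$gamma; e10 <- st$eps1
  trajmix:::sweep_signature_params(st, md, hyper)
  expect_equal(st$sigs, sigs0)
  trajmix:::sweep_nuisance(st, md, hyper)
  expect_equal(st$gamma, gamma0)
  expect_equal(st$eps1, e10)
})

test_that("strong equilibrium shift forces the c->e switch on (quadrature oracle)", {
  sched <- toy_schedule()
  tt <- c(1, 5, 16, 20, 25, 29, 36, 40, 44, 48)
  th_true <- prototype_signature(4, 4, 4, 2, 4, 7, 2,
                                 c_mu = c(FALSE, TRUE), c_lambda = FALSE)
  set.seed(31)
  f <- evaluate_signature(th_true, tt, sched)
  eps <- 0.1
  Y <- t(vapply(1:4, function(i) rnbinom(length(tt), size = 1 / eps,
                                         mu = exp(f)), numeric(length(tt))))
  rownames(Y) <- paste0("otu", 1:4)
  ds <- counts_dataset(list(S1 = Y), list(S1 = tt),
                       totals = list(S1 = rep(1e5, length(tt))))
  hyper <- default_hyperparams(mu_a_mean = 4, gamma_sd = 0.05,
                               eps_meanlog = log(eps), eps_sdlog = 0.15)
  fit <- run_mcmc(ds, sched,
                  mcmc_config(n_burnin = 400, n_sampling = 600, thin = 5,
                              n_chains = 1, seed = 13), hyper)
  p_on <- mean(vapply(fit$samples, function(s) s$signatures[[s$z[1]]]$c_mu[2],
                      logical(1)))
  expect_gt(p_on, 0.95)
  # quadrature on the 1-signature toy: marginal likelihood of the shift
  # increment under its prior vs the tied model (all else at truth)
  ll_of <- function(delta_ce) {
    th <- prototype_signature(4, 4, 4, 2, 4, 4 + delta_ce, 2,
                              c_mu = c(FALSE, delta_ce != 0),
                              c_lambda = FALSE)
    fv <- evaluate_signature(th, tt, sched)
    sum(dnbinom(t(Y), size = 1 / eps, mu = exp(rep(fv, nrow(Y))), log = TRUE))
  }
  grid <- seq(-5, 8, length.out = 801)
  ml_on <- sum(exp(vapply(grid, ll_of, numeric(1)) - ll_of(3)) *
                 dnorm(grid, 0, 1)) * diff(grid[1:2])
  ml_off <- exp(ll_of(0) - ll_of(3))
  p_oracle <- ml_on / (ml_on + ml_off)   # even prior odds
  expect_gt(p_oracle, 0.95)
  expect_equal(p_on, p_oracle, tolerance = 0.05)
})

test_that("Escobar-West concentration kernel matches the grid conditional", {
  set.seed(77)
  a <- 1; b <- 1; k <- 3; n <- 10
  draws <- numeric(20000)
  alpha <- 1
  for (i in seq_along(draws)) {
    alpha <- trajmix:::update_alpha_escobar_west(alpha, k, n, a, b)
    draws[i] <- alpha
  }
  grid <- seq(1e-4, 30, length.out = 20000)
  dens <- dgamma(grid, a, b) * grid^k * exp(lgamma(grid) - lgamma(grid + n))
  dens <- dens / sum(dens)
  expect_equal(mean(draws), sum(grid * dens), tolerance = 0.05)
  expect_equal(median(draws),
               grid[which.min(abs(cumsum(dens) - 0.5))], tolerance = 0.07)
})

test_that("Gelman-Rubin statistic matches the direct formula", {
  set.seed(15)
  x <- cbind(rnorm(500), rnorm(500))
  direct <- function(ch) {
    n <- nrow(ch)
    B <- n * var(colMeans(ch))
    W <- mean(apply(ch, 2, var))
    sqrt(max(1, ((n - 1) / n * W + B / n) / W))
  }
  expect_equal(gelman_rubin(x), direct(x), tolerance = 1e-12)
  expect_gte(gelman_rubin(x), 1)
  # identical chains
  expect_equal(gelman_rubin(cbind(x[, 1], x[, 1])), 1)
  # well-separated chains are flagged
  y <- cbind(rnorm(500), rnorm(500, 5))
  expect_gt(gelman_rubin(y), 1.5)
  expect_equal(gelman_rubin(y), direct(y), tolerance = 1e-12)
  # affine invariance
  expect_equal(gelman_rubin(3 * y - 7), gelman_rubin(y), tolerance = 1e-9)
  expect_error(gelman_rubin(x[, 1, drop = FALSE]), "two chains")
  expect_error(gelman_rubin(list(1:3, 1:4)), "equal")
})

test_that("two accepted flips of one switch restore the tie structure", {
  g <- trajmix:::isig(1, 0.5, 0.7, -0.3, 0.2, log(5), log(9),
                      s_ac = TRUE, s_ce = TRUE, s_l = TRUE)
  # death then birth in increment space: death forces the tie exactly
  g_off <- g; g_off$s_ac <- FALSE; g_off$d_ac <- 0
  th_off <- trajmix:::isig_to_signature(g_off)
  expect_identical(th_off$mu_c, th_off$mu_a)
  g_on <- g_off; g_on$s_ac <- TRUE; g_on$d_ac <- 0.7
  expect_equal(trajmix:::isig_to_signature(g_on),
               trajmix:::isig_to_signature(g))
  # same for the relaxation-time switch
  g_loff <- g; g_loff$s_l <- FALSE; g_loff$lle <- g$llc
  th <- trajmix:::isig_to_signature(g_loff)
  expect_identical(th$lambda_e, th$lambda_c)
})
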