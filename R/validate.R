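## Sampler self-validation utilities.

# Successive-conditional (Geweke-style) joint-distribution check: alternate
# one full posterior sweep with re-simulation of the data given the current
# state. If every transition targets its correct conditional, the recorded
# parameter marginals equal the prior marginals. Returns a data frame of
# recorded scalars, one row per cycle.
geweke_successive_conditional <- function(n_cycles = 2000, n_units = 5,
                                          times = seq(0, 13, length.out = 12),
                                          schedule = perturbation_schedule(c(0, 3, 5, 9, 11, 14)),
                                          hyper = default_hyperparams(mu_a_mean = 2),
                                          config = mcmc_config(),
                                          seed = 1) {
  counts <- list(S1 = matrix(1L, n_units, length(times),
                             dimnames = list(paste0("otu", seq_len(n_units)), NULL)))
  totals <- list(S1 = rep(1000, length(times)))  # equal depth -> phi = 0
  dataset <- counts_dataset(counts, list(S1 = times), totals = totals)
  md <- build_model_data(dataset, list(S1 = schedule))
  set.seed(seed %% 2147483647L)
  st <- init_state(md, hyper, config, likelihood = TRUE)
  rec <- matrix(NA_real_, n_cycles, 8)
  colnames(rec) <- c("mu_a", "loglam_c", "s_ac", "s_l", "eps1", "alpha",
                     "gamma1", "K")
  for (cycle in seq_len(n_cycles)) {
    # data step: y | state
    for (u in seq_len(md$n)) {
      si <- md$unit_subject[u]
      sg <- md$subj[[si]]
      f <- st$F[[st$z[u]]][[si]]
      m <- exp(f + sg$phi + st$gamma[u])
      md$Y[[si]][, md$unit_col[u]] <-
        stats::rnbinom(sg$T, size = 1 / eps_vec(sg, st$eps1, st$eps2), mu = m)
    }
    md$LGY1 <- lapply(md$Y, lgamma1p_counts)      # Y changed
    st$nbc <- nb_const_all(md, st$eps1, st$eps2)
    # parameter step: state | y
    mcmc_sweep(st, md, hyper, config)
    g1 <- st$sigs[[st$z[1]]]
    rec[cycle, ] <- c(g1$mu_a, g1$llc, g1$s_ac, g1$s_l, st$eps1, st$alpha,
                      st$gamma[1], length(st$sigs))
  }
  as.data.frame(rec)
}

# Direct draws of the same scalars from the prior (matched marginals for
# the successive-conditional check). Cluster structure follows the CRP with
# alpha ~ Gamma prior.
prior_reference_draws <- function(n_draws = 2000, n_units = 5,
                                  hyper = default_hyperparams(mu_a_mean = 2),
                                  seed = 2) {
  set.seed(seed %% 2147483647L)
  rec <- matrix(NA_real_, n_draws, 8)
  colnames(rec) <- c("mu_a", "loglam_c", "s_ac", "s_l", "eps1", "alpha",
                     "gamma1", "K")
  for (i in seq_len(n_draws)) {
    alpha <- stats::rgamma(1, hyper$alpha_shape, hyper$alpha_rate)
    z <- crp_partition_draw(n_units, alpha)
    g <- isig_prior_draw(hyper)  # signature of unit 1's cluster
    rec[i, ] <- c(g$mu_a, g$llc, g$s_ac, g$s_l,
                  stats::rlnorm(1, hyper$eps_meanlog, hyper$eps_sdlog),
                  alpha, stats::rnorm(1, 0, hyper$gamma_sd), max(z))
  }
  as.data.frame(rec)
}

# One draw of a CRP partition of n items at concentration alpha.
crp_partition_draw <- function(n, alpha) {
  z <- integer(n)
  z[1] <- 1L
  K <- 1L
  for (i in seq_len(n)[-1]) {
    counts <- tabulate(z[seq_len(i - 1L)], nbins = K)
    p <- c(counts, alpha)
    pick <- sample.int(K + 1L, 1L, prob = p)
    if (pick > K) K <- K + 1L
    z[i] <- pick
  }
  z
}
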