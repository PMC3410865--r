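# Shared fixtures: small schedules, datasets and hand-built posterior
# sample objects. Everything is generated in code at test time.

toy_schedule <- function() {
  perturbation_schedule(c(0, 10, 15, 30, 35, 50))
}

toy_signature <- function(mu_a = 2, X_b = 0, mu_c = 3, lambda_c = 4,
                          X_d = 5, mu_e = 2.5, lambda_e = 8,
                          c_mu = c(TRUE, TRUE), c_lambda = TRUE) {
  prototype_signature(mu_a, X_b, mu_c, lambda_c, X_d, mu_e, lambda_e,
                      c_mu, c_lambda)
}

# small random dataset with known structure
toy_dataset <- function(n_otu = 3, times = c(0, 5, 12, 20, 33, 40),
                        seed = 1, subjects = "S1") {
  set.seed(seed)
  counts <- list(); tl <- list(); totals <- list()
  for (s in subjects) {
    m <- matrix(rpois(n_otu * length(times), 50), n_otu,
                dimnames = list(paste0("otu", seq_len(n_otu)), NULL))
    counts[[s]] <- m
    tl[[s]] <- times
    totals[[s]] <- colSums(m) + rpois(length(times), 5000)
  }
  counts_dataset(counts, tl, totals = totals)
}

# hand-built posterior_samples object from explicit assignment lists
make_samples <- function(z_list, subjects, O_s, signatures_list = NULL,
                         schedule = toy_schedule(), taxonomy = NULL) {
  units <- data.frame(
    subject = rep(subjects, O_s),
    refotu = unlist(lapply(O_s, function(o) paste0("otu", seq_len(o)))),
    stringsAsFactors = FALSE)
  n <- nrow(units)
  samples <- lapply(seq_along(z_list), function(j) {
    z <- as.integer(z_list[[j]])
    K <- max(z)
    sigs <- if (is.null(signatures_list)) {
      replicate(K, toy_signature(), simplify = FALSE)
    } else signatures_list[[j]]
    list(z = z, signatures = sigs, gamma = numeric(n), eps1 = 0.3,
         eps2 = 0.3, alpha = 1, n_clusters = K, chain = 1L, iter = j)
  })
  structure(
    list(samples = samples, units = units, subjects = subjects,
         O_s = stats::setNames(O_s, subjects),
         schedules = stats::setNames(rep(list(schedule), length(subjects)),
                                     subjects),
         taxonomy = trajmix:::normalize_taxonomy(taxonomy, unique(units$refotu)),
         config = mcmc_config(n_chains = 1, seed = 1),
         hyper = default_hyperparams(mu_a_mean = 0)),
    class = "posterior_samples")
}

# signature whose every switch is off (fully tied)
flat_signature <- function(mu = 1, lambda = 5) {
  prototype_signature(mu, mu + 1, mu, lambda, mu - 1, mu, lambda,
                      c_mu = c(FALSE, FALSE), c_lambda = FALSE)
}
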