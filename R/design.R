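## Bayesian D-optimal selection of sampling days, and design-strategy
## evaluation by held-out prediction error.

# Linear basis of the level parameters of a signature, conditional on its
# relaxation times and switch states. Columns: mu_a, delta_b, (delta_ac),
# delta_cd, (delta_ce); inactive increments are dropped.
signature_design_basis <- function(theta, times, schedule) {
  stopifnot(inherits(theta, "prototype_signature"))
  iv <- interval_of(schedule, times)
  b <- schedule$breaks
  wc <- exp(-(times - b[3]) / theta$lambda_c)
  we <- exp(-(times - b[5]) / theta$lambda_e)
  cols <- list(
    mu_a = rep(1, length(times)),
    delta_b = ifelse(iv == 2L, 1, ifelse(iv == 3L, wc, 0)),
    delta_ac = if (theta$c_mu[1]) {
      ifelse(iv == 3L, 1 - wc, ifelse(iv %in% c(4L, 5L), 1, 0))
    } else NULL,
    delta_cd = ifelse(iv == 4L, 1, ifelse(iv == 5L, we, 0)),
    delta_ce = if (theta$c_mu[2]) ifelse(iv == 5L, 1 - we, 0) else NULL)
  X <- do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
  rownames(X) <- format(times, trim = TRUE)
  X
}

#' Fisher information of a design under the NB GLM
#'
#' Conditioning on a signature's relaxation times and switch states, the
#' trajectory is linear in its level parameters with basis `x_t`; under the
#' log-link negative binomial observation model the Fisher information of a
#' design is `sum_t w_t x_t x_t'` with GLM weight `w_t = m_t / (1 + eps *
#' m_t)` and `m_t` the mean count at `t`. Additive over disjoint designs,
#' symmetric positive semidefinite. `eps = 0` is the Poisson limit
#' (`w_t = m_t`).
#'
#' @param theta A [prototype_signature()].
#' @param design Numeric vector of sampling days.
#' @param schedule A [perturbation_schedule()].
#' @param eps1,eps2 Inverse shape on quiescent / pulse intervals.
#' @param gamma,phi Offsets entering the mean (default 0: a hypothetical
#'   future experiment with unknown depth and baseline).
#' @return Information matrix (p x p).
#' @export
nb_glm_fisher_information <- function(theta, design, schedule,
                                      eps1 = 0, eps2 = eps1,
                                      gamma = 0, phi = 0) {
  if (!length(design)) stop("design must contain at least one day", call. = FALSE)
  X <- signature_design_basis(theta, design, schedule)
  f <- evaluate_signature(theta, design, schedule)
  m <- exp(f + gamma + phi)
  iv <- interval_of(schedule, design)
  eps <- ifelse(iv %in% c(2L, 4L), eps2, eps1)
  w <- m / (1 + eps * m)
  crossprod(X, w * X)
}

#' Bayesian D-optimality of a design
#'
#' Expected log-determinant of the (ridge-regularized) Fisher information,
#' averaged over posterior parameter samples used as the prior for a future
#' experiment, and over their active signatures weighted by occupancy:
#' `g(T) = mean_j sum_k (n_k/n) log det(IM(theta_k^(j), T) + r I)`.
#'
#' @param design Numeric vector of sampling days.
#' @param prior_samples A `posterior_samples` object (or its `$samples`
#'   list with an attached schedule, see `schedule`).
#' @param schedule Schedule of the future experiment; defaults to the first
#'   subject's schedule in `prior_samples`.
#' @param ridge Ridge added to the information matrix so rank-deficient
#'   (budget < parameter count) designs remain evaluable.
#' @return Scalar g value.
#' @export
bayesian_d_optimality <- function(design, prior_samples, schedule = NULL,
                                  ridge = 1e-6) {
  smp_list <- if (inherits(prior_samples, "posterior_samples")) {
    prior_samples$samples
  } else prior_samples
  if (!length(smp_list)) stop("empty prior sample set", call. = FALSE)
  if (is.null(schedule)) {
    stopifnot(inherits(prior_samples, "posterior_samples"))
    schedule <- prior_samples$schedules[[1]]
  }
  g <- vapply(smp_list, function(smp) {
    nk <- tabulate(smp$z, nbins = length(smp$signatures))
    wk <- nk / sum(nk)
    tot <- 0
    for (k in seq_along(smp$signatures)) {
      if (wk[k] == 0) next
      IM <- nb_glm_fisher_information(smp$signatures[[k]], design, schedule,
                                      eps1 = smp$eps1, eps2 = smp$eps2)
      tot <- tot + wk[k] * determinant(IM + ridge * diag(nrow(IM)),
                                       logarithm = TRUE)$modulus
    }
    tot
  }, numeric(1))
  mean(g)
}

#' Greedy D-optimal design
#'
#' Forward greedy selection: starting from the empty design, repeatedly add
#' the candidate day maximizing [bayesian_d_optimality()] until the budget
#' is reached. Ties are broken by the earliest day, so the output is
#' deterministic and independent of candidate ordering.
#'
#' @param candidates Candidate sampling days.
#' @param budget Number of days to select (> 0, <= number of candidates).
#' @param prior_samples,schedule,ridge Passed to [bayesian_d_optimality()].
#' @return List of class `design`: `times` (sorted selected days), `budget`,
#'   `g_trace` (g value after each greedy addition).
#' @export
greedy_design <- function(candidates, budget, prior_samples, schedule = NULL,
                          ridge = 1e-6) {
  if (budget <= 0) stop("budget must be positive", call. = FALSE)
  candidates <- sort(unique(candidates))
  if (length(candidates) < budget) {
    stop("fewer candidates than budget", call. = FALSE)
  }
  chosen <- numeric(0)
  g_trace <- numeric(0)
  for (step in seq_len(budget)) {
    remaining <- setdiff(candidates, chosen)
    gs <- vapply(remaining, function(d) {
      bayesian_d_optimality(c(chosen, d), prior_samples, schedule, ridge)
    }, numeric(1))
    best <- remaining[which.max(gs)]  # which.max takes the first = earliest day
    chosen <- c(chosen, best)
    g_trace <- c(g_trace, max(gs))
  }
  structure(list(times = sort(chosen), budget = budget, g_trace = g_trace,
                 strategy = "greedy"),
            class = "design")
}

#' Evenly dispersed design
#'
#' `budget` days as evenly spaced over the study range as possible,
#' including both endpoints, snapped to the candidate grid (nearest unused
#' candidate).
#'
#' @param range Length-2 numeric: study start and end days.
#' @param budget Number of days (>= 2).
#' @param candidates Optional candidate grid to snap to.
#' @return A `design` object.
#' @export
dispersed_design <- function(range, budget, candidates = NULL) {
  stopifnot(budget >= 2, length(range) == 2, range[2] > range[1])
  ideal <- seq(range[1], range[2], length.out = budget)
  if (is.null(candidates)) {
    times <- ideal
  } else {
    candidates <- sort(unique(candidates))
    times <- numeric(0)
    for (x in ideal) {
      free <- setdiff(candidates, times)
      times <- c(times, free[which.min(abs(free - x))])
    }
  }
  structure(list(times = sort(times), budget = budget, g_trace = NULL,
                 strategy = "dispersed"),
            class = "design")
}

#' @export
print.design <- function(x, ...) {
  cat(sprintf("%s design, %d day(s): %s\n", x$strategy, length(x$times),
              paste(format(x$times, trim = TRUE), collapse = ", ")))
  invisible(x)
}

# square root of the mean squared residual over all (refOTU, time) cells
rmse_of_residuals <- function(resid) sqrt(mean(resid^2))

# restrict a dataset to (approximately) the given days of each subject
restrict_to_times <- function(dataset, keep_times) {
  counts <- list(); times <- list(); totals <- list()
  for (s in dataset$subjects) {
    sel <- which(dataset$times[[s]] %in% keep_times[[s]])
    counts[[s]] <- dataset$counts[[s]][, sel, drop = FALSE]
    times[[s]] <- dataset$times[[s]][sel]
    totals[[s]] <- dataset$totals[[s]][sel]
  }
  counts_dataset(counts, times, dataset$taxonomy, totals)
}

#' Held-out prediction error of a design
#'
#' Fits the model on the training data restricted to the design days,
#' predicts the held-out counts as the posterior mean of `m_sot`, and
#' returns the root mean square error over refOTUs and held-out
#' time-points. Held-out read-depth offsets are centred with the training
#' log-total mean.
#'
#' @param training_data A [counts_dataset()] (full observation grid).
#' @param design A `design` (days to keep for fitting) or numeric day
#'   vector, applied to every subject.
#' @param heldout_data A [counts_dataset()] with the held-out samples
#'   (times disjoint from the design).
#' @param schedules Per-subject schedules.
#' @param mcmc_config An [mcmc_config()] for the fit.
#' @param hyper Hyperparameters.
#' @return List `rmse`, `samples` (the fit), `predicted` (per-subject
#'   matrices).
#' @export
evaluate_design_rmse <- function(training_data, design, heldout_data,
                                 schedules, mcmc_config = NULL,
                                 hyper = default_hyperparams()) {
  days <- if (inherits(design, "design")) design$times else design
  keep <- stats::setNames(rep(list(days), length(training_data$subjects)),
                          training_data$subjects)
  for (s in heldout_data$subjects) {
    if (any(heldout_data$times[[s]] %in% keep[[s]])) {
      stop("held-out time-points must be disjoint from the design", call. = FALSE)
    }
    if (!length(heldout_data$times[[s]])) {
      stop("no held-out time-points for subject ", s, call. = FALSE)
    }
  }
  train <- restrict_to_times(training_data, keep)
  if (is.null(mcmc_config)) mcmc_config <- mcmc_config()
  fit <- run_mcmc(train, schedules, mcmc_config, hyper)
  phi_held <- list()
  for (s in heldout_data$subjects) {
    phi_held[[s]] <- log(heldout_data$totals[[s]]) -
      mean(log(train$totals[[s]]))
  }
  pred <- predict_counts(fit, heldout_data$times, phi_held)
  resid <- unlist(lapply(heldout_data$subjects, function(s) {
    y <- heldout_data$counts[[s]]
    y - pred[[s]][rownames(y), , drop = FALSE]
  }))
  list(rmse = rmse_of_residuals(resid), samples = fit, predicted = pred)
}

#' Strategy-level design generation
#'
#' `sequential`: fit on a subset of the subject's own time-points, then
#' select future days greedily. `cross_subject`: fit on all data from a
#' donor subject, then design for the recipient. `dispersed`: evenly
#' spaced days, no data used.
#'
#' @param strategy `"sequential"`, `"cross_subject"` or `"dispersed"`.
#' @param dataset A [counts_dataset()] supplying the input data (ignored by
#'   `dispersed`).
#' @param schedules Per-subject schedules.
#' @param candidates Candidate days.
#' @param budget Number of days to select.
#' @param input_subject Subject whose data feed the design (donor for
#'   `cross_subject`).
#' @param input_times For `sequential`: the days already observed (subset
#'   used for the pilot fit); default all.
#' @param n_prior_samples Posterior samples retained as the design prior
#'   (uniform thinning; default 500).
#' @param mcmc_config Config for the pilot fit.
#' @param hyper Hyperparameters.
#' @param ridge Ridge for the optimality criterion.
#' @return A `design` object.
#' @export
design_strategy <- function(strategy, dataset = NULL, schedules = NULL,
                            candidates, budget, input_subject = NULL,
                            input_times = NULL, n_prior_samples = 500,
                            mcmc_config = NULL, hyper = default_hyperparams(),
                            ridge = 1e-6) {
  if (!strategy %in% c("sequential", "cross_subject", "dispersed")) {
    stop("unknown design strategy: ", strategy, call. = FALSE)
  }
  if (strategy == "dispersed") {
    return(dispersed_design(range(candidates), budget, candidates))
  }
  stopifnot(!is.null(dataset), !is.null(schedules))
  if (is.null(input_subject)) input_subject <- dataset$subjects[[1]]
  sub <- counts_dataset(dataset$counts[input_subject],
                        dataset$times[input_subject],
                        dataset$taxonomy, dataset$totals[input_subject])
  if (strategy == "sequential" && !is.null(input_times)) {
    sub <- restrict_to_times(sub, stats::setNames(list(input_times),
                                                  input_subject))
  }
  if (is.null(mcmc_config)) mcmc_config <- mcmc_config()
  fit <- run_mcmc(sub, schedules[input_subject], mcmc_config, hyper)
  # uniform thinning of the pooled posterior to the design prior size
  J <- length(fit$samples)
  if (J > n_prior_samples) {
    idx <- unique(round(seq(1, J, length.out = n_prior_samples)))
    fit$samples <- fit$samples[idx]
  }
  out <- greedy_design(candidates, budget, fit,
                       schedule = schedules[[input_subject]], ridge = ridge)
  out$strategy <- strategy
  out
}
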