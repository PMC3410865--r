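## Synthetic-data generator: datasets drawn from the generative model, with
## the generating configuration retained as ground truth for recovery
## benchmarking.

# RMS distance between two signatures' mean-centred daily trajectories.
# Per-unit baseline offsets make absolute levels unidentifiable, so library
# separation is measured in shape space.
signature_shape_distance <- function(th1, th2, schedule) {
  grid <- seq(schedule$breaks[1], schedule$breaks[6], by = 1)
  f1 <- evaluate_signature(th1, grid, schedule)
  f2 <- evaluate_signature(th2, grid, schedule)
  sqrt(mean(((f1 - mean(f1)) - (f2 - mean(f2)))^2))
}

# A library candidate is kept only if its dynamics are well resolved:
# every active equilibrium increment, the log-lambda contrast of an active
# second relaxation time, and both pulse contrasts |X - mu| (which drive the
# identifiability of the relaxation processes) exceed their floors, and the
# relaxation times lie on the observable day-to-weeks scale of the study
# design. A switch that is "on" with a negligible increment would make the
# generating dimensionality meaningless as a recovery target.
signature_resolved <- function(theta, min_effect, min_switch_effect,
                               lambda_range = c(0.5, 60)) {
  if (theta$lambda_c < lambda_range[1] || theta$lambda_c > lambda_range[2] ||
      theta$lambda_e < lambda_range[1] || theta$lambda_e > lambda_range[2]) {
    return(FALSE)
  }
  inc <- signature_increments(theta)
  if (abs(theta$X_b - theta$mu_c) < min_effect) return(FALSE)
  if (abs(theta$X_d - theta$mu_e) < min_effect) return(FALSE)
  if (theta$c_mu[1] && abs(inc$delta_ac) < min_switch_effect) return(FALSE)
  if (theta$c_mu[2] && abs(inc$delta_ce) < min_switch_effect) return(FALSE)
  if (theta$c_lambda &&
      abs(log(theta$lambda_e) - log(theta$lambda_c)) < min_switch_effect) {
    return(FALSE)
  }
  TRUE
}

#' Sample a library of prototype signatures from the prior
#'
#' Draws K signatures from the hierarchical prior conditioned on resolved
#' dynamics: each candidate is resampled until (i) its mean-centred
#' trajectory is at least `min_separation` (RMS log-amplitude on a daily
#' grid) away from every accepted signature, (ii) both pulse contrasts
#' `|X - mu|` reach `min_effect` (the antibiotic responses are real), and
#' (iii) every active switch carries an increment of at least
#' `min_switch_effect` (the generating dimensionality is well defined).
#'
#' @param K Number of signatures (>= 1).
#' @param hyper Hyperparameters (`mu_a_mean` must be set).
#' @param seed Integer seed.
#' @param schedule Schedule on which separation is measured.
#' @param min_separation Minimum pairwise shape distance (log units).
#' @param min_effect Minimum pulse-transient contrast (log units).
#' @param min_switch_effect Minimum magnitude of active increments /
#'   log-relaxation-time contrasts.
#' @param max_tries Resampling attempts per signature before erroring.
#' @return List of [prototype_signature()]s.
#' @export
sample_prototype_library <- function(K, hyper = default_hyperparams(mu_a_mean = log(100)),
                                     seed = 1, schedule = default_schedule(),
                                     min_separation = 0.5, min_effect = 1,
                                     min_switch_effect = 0.75,
                                     max_tries = 1000) {
  stopifnot(K >= 1)
  if (is.null(hyper$mu_a_mean)) {
    stop("hyper$mu_a_mean must be set for library sampling", call. = FALSE)
  }
  set.seed(seed %% 2147483647L)
  library <- list()
  for (k in seq_len(K)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- sample_signature_prior(hyper)
      if (!signature_resolved(cand, min_effect, min_switch_effect)) next
      dmin <- if (length(library) == 0) Inf else {
        min(vapply(library, signature_shape_distance, numeric(1),
                   th2 = cand, schedule = schedule))
      }
      if (dmin >= min_separation) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not satisfy the separation constraint in ", max_tries,
           " resamples", call. = FALSE)
    }
    library[[k]] <- cand
  }
  library
}

#' Simulation configuration
#'
#' Defaults emulate the study geometry: 3 subjects, 20 refOTUs each,
#' roughly 40 irregular observation days per subject (daily around the two
#' five-day antibiotic pulses, about two-weekly elsewhere), negative
#' binomial counts at a target coefficient of variation of 0.6.
#'
#' @param S Number of subjects.
#' @param O refOTUs per subject.
#' @param K Library size.
#' @param schedule Perturbation schedule shared by the subjects.
#' @param times Optional named list of per-subject day vectors; `NULL`
#'   generates the default irregular grid.
#' @param cv_target Target count coefficient of variation (sets the
#'   dispersion via `cv^2 = 1/m + eps` at the median true mean).
#' @param hyper Hyperparameters for the library and offsets (default
#'   `mu_a_mean = log(100)`).
#' @param min_separation Library shape-separation (see
#'   [sample_prototype_library()]).
#' @param depth_meanlog,depth_sdlog Log-normal per-sample total read depth
#'   (the whole-community sequencing total; the default keeps the modeled
#'   refOTUs a small fraction of it, as in real 16S tables, so the
#'   read-depth offsets stay independent of the signatures).
#' @param seed Integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(S = 3, O = 20, K = 8, schedule = default_schedule(),
                       times = NULL, cv_target = 0.6,
                       hyper = default_hyperparams(mu_a_mean = log(100)),
                       min_separation = 0.5,
                       depth_meanlog = log(1e5), depth_sdlog = 0.3,
                       seed = 1) {
  structure(list(S = S, O = O, K = K, schedule = schedule, times = times,
                 cv_target = cv_target, hyper = hyper,
                 min_separation = min_separation,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# default irregular sampling grid: daily around the pulses, sparse elsewhere
default_sim_times <- function(schedule, jitter = 0) {
  b <- schedule$breaks
  dense1 <- seq(b[2] - 3, b[3] + 8)
  dense2 <- seq(b[4] - 3, b[5] + 8)
  sparse <- seq(b[1], b[6] - 1, by = 14)
  tt <- sort(unique(c(sparse, dense1, dense2)))
  tt <- tt[tt >= b[1] & tt < b[6]]
  if (jitter > 0) {
    shift <- sample(seq(-jitter, jitter), length(tt), replace = TRUE)
    keep <- !(tt %in% c(dense1, dense2))
    tt[keep] <- tt[keep] + shift[keep]
    tt <- sort(unique(pmax(b[1], pmin(tt, b[6] - 1))))
  }
  tt
}

#' Generate a count dataset from the generative model
#'
#' Samples a separated prototype library, assigns each (subject, refOTU)
#' unit to a signature (shared Dirichlet-weighted proportions across
#' subjects, so signatures are shared between ecosystems), draws per-unit
#' offsets `gamma`, per-sample sequencing depths and read-depth offsets
#' `phi`, calibrates the dispersion so the count coefficient of variation
#' at the median true mean equals `cv_target` (`eps = cv^2 - 1/m_median`),
#' and samples negative binomial counts at every observation day.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a [counts_dataset()]), `schedules`, and
#'   `truth` (a `simulation_truth`: library, assignments, offsets,
#'   dispersions, seed).
#' @export
generate_counts_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  hyper <- config$hyper
  library <- sample_prototype_library(config$K, hyper, seed = config$seed,
                                      schedule = config$schedule,
                                      min_separation = config$min_separation)
  set.seed((config$seed + 999983L) %% 2147483647L)
  subjects <- paste0("S", seq_len(config$S))
  # shared mixing weights induce cross-subject signature sharing
  weights <- stats::rgamma(config$K, 1, 1)
  weights <- weights / sum(weights)
  z <- list(); gamma <- list(); times <- list()
  counts <- list(); totals <- list(); phis <- list()
  means <- list()
  for (s in subjects) {
    tt <- if (is.null(config$times)) {
      default_sim_times(config$schedule, jitter = 2)
    } else config$times[[s]]
    times[[s]] <- tt
    z[[s]] <- sample.int(config$K, config$O, replace = TRUE, prob = weights)
    gamma[[s]] <- stats::rnorm(config$O, 0, hyper$gamma_sd)
    tot <- round(stats::rlnorm(length(tt), config$depth_meanlog,
                               config$depth_sdlog))
    lt <- log(tot)
    phis[[s]] <- lt - mean(lt)
    M <- matrix(0, config$O, length(tt))
    for (o in seq_len(config$O)) {
      f <- evaluate_signature(library[[z[[s]][o]]], tt, config$schedule)
      M[o, ] <- exp(f + gamma[[s]][o] + phis[[s]])
    }
    means[[s]] <- M
    totals[[s]] <- tot
  }
  m_med <- stats::median(unlist(means))
  eps <- config$cv_target^2 - 1 / m_med
  if (eps <= 0) {
    stop("cv_target unattainable: cv^2 <= 1/m at the median mean (",
         format(m_med), ")", call. = FALSE)
  }
  for (s in subjects) {
    M <- means[[s]]
    Y <- matrix(stats::rnbinom(length(M), size = 1 / eps, mu = M), nrow(M))
    rownames(Y) <- paste0("otu", seq_len(config$O))
    counts[[s]] <- Y
    totals[[s]] <- pmax(totals[[s]], colSums(Y))
  }
  taxonomy <- simulate_taxonomy(paste0("otu", seq_len(config$O)),
                                seed = config$seed)
  dataset <- counts_dataset(counts, times, taxonomy, totals)
  schedules <- stats::setNames(rep(list(config$schedule), config$S), subjects)
  truth <- structure(
    list(library = library, z = z, gamma = gamma, phi = phis,
         eps1 = eps, eps2 = eps, weights = weights,
         schedule = config$schedule, seed = config$seed,
         cv_target = config$cv_target),
    class = "simulation_truth")
  list(dataset = dataset, schedules = schedules, truth = truth)
}

# taxonomy labels drawn from a small fixed pool so enrichment is testable
simulate_taxonomy <- function(refotus, seed = 1) {
  pool <- data.frame(
    order = c("Bacteroidales", "Bacteroidales", "Clostridiales",
              "Clostridiales", "Clostridiales", "Lactobacillales"),
    family = c("Bacteroidaceae", "Porphyromonadaceae", "Lachnospiraceae",
               "Ruminococcaceae", "Clostridiaceae", "Streptococcaceae"),
    genus = c("Bacteroides", "Parabacteroides", "Blautia",
              "Faecalibacterium", "Clostridium", "Streptococcus"),
    stringsAsFactors = FALSE)
  set.seed((seed + 424243L) %% 2147483647L)
  pick <- sample.int(nrow(pool), length(refotus), replace = TRUE)
  data.frame(refotu = refotus, pool[pick, ], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: K=%d signatures, %d subject(s), eps=%.3f (CV target %.2f)\n",
              length(x$library), length(x$z), x$eps1, x$cv_target))
  invisible(x)
}

# Truth-implied diversity scores: the generating configuration treated as a
# single degenerate posterior sample.
truth_implied_scores <- function(truth, units) {
  subjects <- unique(units$subject)
  multi_mu <- vapply(truth$library, function(th) any(th$c_mu), logical(1))
  multi_lam <- vapply(truth$library, function(th) th$c_lambda, logical(1))
  sd1 <- do.call(rbind, lapply(subjects, function(s) {
    zs <- truth_assignments(truth, units, s)
    data.frame(subject = s, sd1_mu = mean(multi_mu[zs]),
               sd1_lambda = mean(multi_lam[zs]), stringsAsFactors = FALSE)
  }))
  sd2 <- vapply(subjects, function(s) {
    zs <- truth_assignments(truth, units, s)
    100 / length(zs) * exp(shannon_entropy(tabulate(zs)))
  }, numeric(1))
  z_all <- unlist(lapply(subjects, truth_assignments, truth = truth,
                         units = units))
  n <- length(z_all)
  sd2_d <- 100 / n * exp(shannon_entropy(tabulate(z_all)))
  w <- vapply(subjects, function(s) sum(units$subject == s), numeric(1)) / n
  list(sd1 = sd1, sd2 = stats::setNames(sd2, subjects),
       sd3 = sd2_d / sum(w * sd2))
}

# generating assignments for the units (by refOTU name) of one subject
truth_assignments <- function(truth, units, subject) {
  ot <- units$refotu[units$subject == subject]
  idx <- as.integer(sub("^otu", "", ot))
  truth$z[[subject]][idx]
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Integer/factor membership vectors of equal length.
#' @return ARI in [-1, 1]; 1 iff the partitions coincide.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Recovery benchmark against simulation truth
#'
#' Compares a fit on synthetic data with its generating configuration:
#' relative errors of the SD1/SD2/SD3 diversity scores against the
#' truth-implied scores, median relative error of the per-refOTU posterior
#' median relaxation constants on intervals (c) and (e), and the adjusted
#' Rand index between the consensus-signature-group partition and the true
#' partition.
#'
#' @param truth A `simulation_truth`.
#' @param samples A `posterior_samples` fitted to data generated from
#'   `truth` (possibly after filtering).
#' @return List of class `recovery_report`: `sd_errors` (percent relative
#'   errors), `lambda_c_error`, `lambda_e_error` (percent medians),
#'   `ari`, plus the underlying estimated and true quantities.
#' @export
recovery_benchmark <- function(truth, samples) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(samples, "posterior_samples"))
  if (!all(samples$subjects %in% names(truth$z))) {
    stop("fitted subjects do not match the simulation truth", call. = FALSE)
  }
  ts <- truth_implied_scores(truth, samples$units)
  est_sd1 <- sd1_scores(samples)
  est_sd2 <- vapply(samples$subjects, function(s) sd2_score(samples, s),
                    numeric(1))
  rel <- function(est, true) {
    err <- abs(est - true)
    out <- 100 * err / abs(true)
    out[err == 0] <- 0   # exact agreement counts as zero error even at 0
    out
  }
  sd_errors <- c(
    sd1_mu = max(rel(est_sd1$sd1_mu, ts$sd1$sd1_mu)),
    sd1_lambda = max(rel(est_sd1$sd1_lambda, ts$sd1$sd1_lambda)),
    sd2 = max(rel(est_sd2, ts$sd2[samples$subjects])))
  sd3_err <- if (length(samples$subjects) >= 2) {
    rel(sd3_score(samples)$sd3, ts$sd3)
  } else NA_real_
  # per-unit true and estimated relaxation constants
  true_lam <- function(field) {
    unlist(lapply(samples$subjects, function(s) {
      zs <- truth_assignments(truth, samples$units, s)
      vapply(truth$library[zs], `[[`, numeric(1), field)
    }))
  }
  lam_err_units <- function(interval, field) {
    est <- relaxation_constants(samples, interval)
    tr <- true_lam(field)
    100 * abs(est - tr) / tr
  }
  lam_units <- list(c = lam_err_units("c", "lambda_c"),
                    e = lam_err_units("e", "lambda_e"))
  # assignment consistency: CSG partition vs generating partition
  true_part <- unlist(lapply(samples$subjects, truth_assignments,
                             truth = truth, units = samples$units))
  csgs <- build_csgs(coassignment_matrix(samples), samples)
  membership <- integer(nrow(samples$units))
  for (g in seq_along(csgs)) membership[csgs[[g]]$members$unit] <- g
  structure(
    list(sd_errors = sd_errors, sd3_error = sd3_err,
         lambda_c_error = stats::median(lam_units$c),
         lambda_e_error = stats::median(lam_units$e),
         lambda_unit_errors = lam_units,
         ari = adjusted_rand_index(membership, true_part),
         estimated = list(sd1 = est_sd1, sd2 = est_sd2),
         truth_implied = ts),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery vs simulation truth:\n")
  cat(sprintf("  SD score errors (max over subjects, %%): SD1_mu %.1f, SD1_lambda %.1f, SD2 %.1f\n",
              x$sd_errors["sd1_mu"], x$sd_errors["sd1_lambda"],
              x$sd_errors["sd2"]))
  cat(sprintf("  relaxation-time errors (median, %%): interval c %.1f, interval e %.1f\n",
              x$lambda_c_error, x$lambda_e_error))
  cat(sprintf("  assignment ARI vs truth: %.3f\n", x$ari))
  invisible(x)
}

#' End-to-end synthetic recovery experiment
#'
#' Generates a dataset at the default study-like conditions (matched-noise
#' CV 0.6), filters it, fits the desk-scale MCMC protocol, and benchmarks
#' recovery. The workhorse behind the robustness evaluation.
#'
#' @param seed Integer seed (drives both generation and fitting).
#' @param config A [sim_config()]; its seed is overridden by `seed`.
#' @param mcmc An [mcmc_config()]; its seed is overridden by `seed`.
#' @param filter Apply [filter_refotus()] at default thresholds first.
#' @return A `recovery_report` (with the fit attached as `$samples`).
#' @export
recovery_experiment <- function(seed = 1, config = sim_config(),
                                mcmc = mcmc_config(), filter = TRUE) {
  config$seed <- as.integer(seed)
  mcmc$seed <- as.integer(seed)
  sim <- generate_counts_dataset(config)
  dat <- if (filter) filter_refotus(sim$dataset) else sim$dataset
  fit <- run_mcmc(dat, sim$schedules, mcmc, config$hyper)
  rep <- recovery_benchmark(sim$truth, fit)
  rep$samples <- fit
  rep$truth <- sim$truth
  rep
}
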