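#' Prototype signature
#'
#' A prototype signature is a continuous-time log-amplitude trajectory,
#' piecewise defined over the five perturbation intervals: constant at
#' `mu_a` on (a), at the transient level `X_b` during the first pulse (b)
#' and `X_d` during the second (d), and an exponential relaxation on the
#' post-pulse intervals (c) and (e): starting from the transient level the
#' trajectory approaches the equilibrium level (`mu_c`, `mu_e`) with
#' e-folding relaxation time (`lambda_c`, `lambda_e`) in days.
#'
#' Binary dimensionality switches tie parameters across intervals and so
#' control the effective dimension of the signature: when `c_mu[1]` is off
#' `mu_c` equals `mu_a` exactly (no equilibrium shift after pulse 1), when
#' `c_mu[2]` is off `mu_e` equals `mu_c`, and when `c_lambda` is off
#' `lambda_e` equals `lambda_c`.
#'
#' @param mu_a Pre-treatment equilibrium log-level.
#' @param X_b,X_d Transient log-levels during pulses 1 and 2.
#' @param mu_c,mu_e Equilibrium log-levels on intervals (c) and (e).
#' @param lambda_c,lambda_e Relaxation times (days, > 0).
#' @param c_mu Logical length-2: are the a->c and c->e equilibrium
#'   increments active?
#' @param c_lambda Logical: is `lambda_e` distinct from `lambda_c`?
#' @return An object of class `prototype_signature`.
#' @export
prototype_signature <- function(mu_a, X_b, mu_c, lambda_c, X_d, mu_e,
                                lambda_e, c_mu = c(TRUE, TRUE),
                                c_lambda = TRUE) {
  c_mu <- as.logical(c_mu); c_lambda <- as.logical(c_lambda)
  stopifnot(length(c_mu) == 2L, length(c_lambda) == 1L,
            !anyNA(c(mu_a, X_b, mu_c, lambda_c, X_d, mu_e, lambda_e, c_mu, c_lambda)))
  if (lambda_c <= 0 || lambda_e <= 0) {
    stop("relaxation times must be positive", call. = FALSE)
  }
  if (!c_mu[1] && abs(mu_c - mu_a) > 1e-12) {
    stop("inactive a->c switch requires mu_c == mu_a", call. = FALSE)
  }
  if (!c_mu[2] && abs(mu_e - mu_c) > 1e-12) {
    stop("inactive c->e switch requires mu_e == mu_c", call. = FALSE)
  }
  if (!c_lambda && abs(lambda_e - lambda_c) > 1e-12) {
    stop("inactive lambda switch requires lambda_e == lambda_c", call. = FALSE)
  }
  structure(
    list(mu_a = mu_a, X_b = X_b, mu_c = mu_c, lambda_c = lambda_c,
         X_d = X_d, mu_e = mu_e, lambda_e = lambda_e,
         c_mu = c_mu, c_lambda = c_lambda),
    class = "prototype_signature")
}

#' @export
print.prototype_signature <- function(x, ...) {
  eff <- effective_parameters(x)
  cat(sprintf(
    "Prototype signature: mu_a=%.3g X_b=%.3g mu_c=%.3g X_d=%.3g mu_e=%.3g\n",
    x$mu_a, x$X_b, x$mu_c, x$X_d, x$mu_e))
  cat(sprintf("  lambda_c=%.3g lambda_e=%.3g days; %d equilibrium level(s), %d relaxation time(s)\n",
              x$lambda_c, x$lambda_e, eff$n_levels, eff$n_lambda))
  invisible(x)
}

# Construct a signature from its random-walk increments. Inactive increments
# are forced to zero so the equality ties hold exactly.
signature_from_increments <- function(mu_a, delta_b, delta_ac, delta_cd,
                                      delta_ce, loglam_c, loglam_e,
                                      c_mu, c_lambda) {
  if (!c_mu[1]) delta_ac <- 0
  if (!c_mu[2]) delta_ce <- 0
  if (!c_lambda) loglam_e <- loglam_c
  mu_c <- mu_a + delta_ac
  prototype_signature(
    mu_a = mu_a, X_b = mu_a + delta_b, mu_c = mu_c,
    lambda_c = exp(loglam_c), X_d = mu_c + delta_cd,
    mu_e = mu_c + delta_ce, lambda_e = exp(loglam_e),
    c_mu = c_mu, c_lambda = c_lambda)
}

# Inverse of signature_from_increments().
signature_increments <- function(theta) {
  list(mu_a = theta$mu_a,
       delta_b = theta$X_b - theta$mu_a,
       delta_ac = theta$mu_c - theta$mu_a,
       delta_cd = theta$X_d - theta$mu_c,
       delta_ce = theta$mu_e - theta$mu_c,
       loglam_c = log(theta$lambda_c),
       loglam_e = log(theta$lambda_e))
}

#' Evaluate a prototype signature
#'
#' The log-amplitude trajectory f(t, theta): constant `mu_a`/`X_b`/`X_d` on
#' intervals (a)/(b)/(d); on (c), `mu_c + (X_b - mu_c) exp(-(t - t_c0) /
#' lambda_c)` where `t_c0` is the end of pulse 1 (so the trajectory is
#' continuous at the pulse end and decays monotonically toward the
#' equilibrium level); analogously on (e) with `X_d`, `mu_e`, `lambda_e`.
#'
#' @param theta A [prototype_signature()].
#' @param t Days (vectorized); must lie within the schedule's study range.
#' @param schedule A [perturbation_schedule()].
#' @return Numeric vector of log-amplitudes.
#' @export
evaluate_signature <- function(theta, t, schedule) {
  stopifnot(inherits(theta, "prototype_signature"))
  iv <- interval_of(schedule, t)
  b <- schedule$breaks
  f <- numeric(length(t))
  f[iv == 1L] <- theta$mu_a
  f[iv == 2L] <- theta$X_b
  f[iv == 4L] <- theta$X_d
  in_c <- iv == 3L
  if (any(in_c)) {
    f[in_c] <- theta$mu_c +
      (theta$X_b - theta$mu_c) * exp(-(t[in_c] - b[3]) / theta$lambda_c)
  }
  in_e <- iv == 5L
  if (any(in_e)) {
    f[in_e] <- theta$mu_e +
      (theta$X_d - theta$mu_e) * exp(-(t[in_e] - b[5]) / theta$lambda_e)
  }
  f
}

#' Mean of the count model
#'
#' `m_sot = exp(f + gamma_so + phi_st)`: the prototype log-amplitude is
#' customized to an individual signature by a subject-and-refOTU offset
#' `gamma_so` (baseline scaling) and a subject-and-time offset `phi_st`
#' (read depth), then exponentiated.
#'
#' @param f_value Log-amplitude(s) from [evaluate_signature()].
#' @param gamma_so Per-(subject, refOTU) log offset.
#' @param phi_st Per-sample read-depth log offset.
#' @return Strictly positive mean count(s).
#' @export
mean_counts <- function(f_value, gamma_so, phi_st) {
  stopifnot(all(is.finite(f_value + gamma_so + phi_st)))
  exp(f_value + gamma_so + phi_st)
}

#' Negative binomial log-pmf (mean / inverse-shape parameterization)
#'
#' Log-probability of count `y` under a negative binomial with mean `m` and
#' inverse shape `eps`, so that `Var = m + eps * m^2`. `eps = 0` is the
#' Poisson limit and is evaluated exactly as Poisson.
#'
#' @param y Non-negative integer count(s).
#' @param m Mean(s), > 0.
#' @param eps Inverse shape parameter(s), >= 0.
#' @return Log-probability vector.
#' @export
nb_log_pmf <- function(y, m, eps) {
  if (any(m <= 0)) stop("mean of the count model must be positive", call. = FALSE)
  if (any(eps < 0)) stop("inverse shape must be non-negative", call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  n <- max(length(y), length(m), length(eps))
  y <- rep_len(y, n); m <- rep_len(m, n); eps <- rep_len(eps, n)
  out <- numeric(n)
  pois <- eps == 0
  if (any(pois)) out[pois] <- stats::dpois(y[pois], m[pois], log = TRUE)
  if (any(!pois)) {
    out[!pois] <- stats::dnbinom(y[!pois], size = 1 / eps[!pois],
                                 mu = m[!pois], log = TRUE)
  }
  out
}

#' Effective parameter pattern of a signature
#'
#' Applies the equality ties implied by the dimensionality switches and
#' reports how many distinct equilibrium levels (1--3) and relaxation times
#' (1--2) the signature effectively uses. The four reachable equality
#' patterns over (mu_a, mu_c, mu_e) are: all equal; a = c != e; a != c = e;
#' all distinct.
#'
#' @param theta A [prototype_signature()].
#' @return List with `theta` (ties applied), `n_levels`, `n_lambda`, and
#'   `pattern` (character, e.g. `"a=c,e"`).
#' @export
effective_parameters <- function(theta) {
  stopifnot(inherits(theta, "prototype_signature"))
  inc <- signature_increments(theta)
  tied <- signature_from_increments(
    inc$mu_a, inc$delta_b, inc$delta_ac, inc$delta_cd, inc$delta_ce,
    inc$loglam_c, inc$loglam_e, theta$c_mu, theta$c_lambda)
  n_levels <- 1L + sum(theta$c_mu)
  pattern <- if (!theta$c_mu[1] && !theta$c_mu[2]) "a=c=e"
    else if (theta$c_mu[1] && !theta$c_mu[2]) "a,c=e"
    else if (!theta$c_mu[1] && theta$c_mu[2]) "a=c,e"
    else "a,c,e"
  list(theta = tied, n_levels = n_levels,
       n_lambda = 1L + as.integer(theta$c_lambda), pattern = pattern)
}

#' Model hyperparameters
#'
#' Priors of the hierarchical model: `mu_a ~ N(mu_a_mean, mu_a_sd^2)` with
#' `mu_a_mean` defaulting at fit time to the mean log mean count across
#' refOTUs (empirical Bayes); random-walk increments `delta ~ N(0,
#' delta_sd^2)`; `log lambda ~ N(loglambda_mean, loglambda_sd^2)` (median
#' one week by default); `eps1, eps2 ~ LogNormal(eps_meanlog, eps_sdlog)`;
#' `gamma_so ~ N(0, gamma_sd^2)`; switch-on prior `switch_prob`; Dirichlet
#' process concentration `alpha ~ Gamma(alpha_shape, alpha_rate)`.
#'
#' @param mu_a_mean Prior mean of `mu_a`; `NULL` = set empirically at fit.
#' @param mu_a_sd,delta_sd,loglambda_mean,loglambda_sd,eps_meanlog,eps_sdlog
#'   Scale/location parameters, see description.
#' @param gamma_sd Prior sd of per-refOTU offsets.
#' @param switch_prob Prior on-probability of each dimensionality switch.
#' @param alpha_shape,alpha_rate Gamma prior of the DP concentration.
#' @return List of class `trajmix_hyperparams`.
#' @export
default_hyperparams <- function(mu_a_mean = NULL, mu_a_sd = 2, delta_sd = 1,
                                loglambda_mean = log(7), loglambda_sd = 1,
                                eps_meanlog = -1, eps_sdlog = 1,
                                gamma_sd = 1, switch_prob = 0.5,
                                alpha_shape = 1, alpha_rate = 1) {
  stopifnot(mu_a_sd > 0, delta_sd > 0, loglambda_sd > 0, eps_sdlog > 0,
            gamma_sd > 0, switch_prob > 0, switch_prob < 1,
            alpha_shape > 0, alpha_rate > 0)
  structure(list(mu_a_mean = mu_a_mean, mu_a_sd = mu_a_sd,
                 delta_sd = delta_sd, loglambda_mean = loglambda_mean,
                 loglambda_sd = loglambda_sd, eps_meanlog = eps_meanlog,
                 eps_sdlog = eps_sdlog, gamma_sd = gamma_sd,
                 switch_prob = switch_prob, alpha_shape = alpha_shape,
                 alpha_rate = alpha_rate),
            class = "trajmix_hyperparams")
}

#' Log prior density of a prototype signature
#'
#' Sum of the `mu_a` normal density, the normal densities of the active
#' random-walk increments (X_b from mu_a, mu_c from mu_a, X_d from mu_c,
#' mu_e from mu_c), log-normal densities of the active relaxation times,
#' and Bernoulli switch priors. Inactive increments carry no density mass;
#' a state whose inactive increments are non-zero is inconsistent and is an
#' error.
#'
#' @param theta A [prototype_signature()].
#' @param hyper A [default_hyperparams()] list (with `mu_a_mean` set).
#' @return Log prior density (scalar).
#' @export
signature_log_prior <- function(theta, hyper) {
  stopifnot(inherits(theta, "prototype_signature"))
  if (is.null(hyper$mu_a_mean)) {
    stop("hyper$mu_a_mean must be set (it defaults empirically at fit time)",
         call. = FALSE)
  }
  inc <- signature_increments(theta)
  if (!theta$c_mu[1] && abs(inc$delta_ac) > 1e-12) {
    stop("inconsistent state: inactive a->c increment is non-zero", call. = FALSE)
  }
  if (!theta$c_mu[2] && abs(inc$delta_ce) > 1e-12) {
    stop("inconsistent state: inactive c->e increment is non-zero", call. = FALSE)
  }
  lp <- stats::dnorm(theta$mu_a, hyper$mu_a_mean, hyper$mu_a_sd, log = TRUE) +
    stats::dnorm(inc$delta_b, 0, hyper$delta_sd, log = TRUE) +
    stats::dnorm(inc$delta_cd, 0, hyper$delta_sd, log = TRUE) +
    stats::dlnorm(theta$lambda_c, hyper$loglambda_mean, hyper$loglambda_sd,
                  log = TRUE)
  if (theta$c_mu[1]) {
    lp <- lp + stats::dnorm(inc$delta_ac, 0, hyper$delta_sd, log = TRUE)
  }
  if (theta$c_mu[2]) {
    lp <- lp + stats::dnorm(inc$delta_ce, 0, hyper$delta_sd, log = TRUE)
  }
  if (theta$c_lambda) {
    lp <- lp + stats::dlnorm(theta$lambda_e, hyper$loglambda_mean,
                             hyper$loglambda_sd, log = TRUE)
  }
  p <- hyper$switch_prob
  lp + sum(ifelse(c(theta$c_mu, theta$c_lambda), log(p), log1p(-p)))
}

# Draw one signature from the prior. Uses the current RNG stream.
sample_signature_prior <- function(hyper) {
  c_mu <- stats::runif(2) < hyper$switch_prob
  c_lambda <- stats::runif(1) < hyper$switch_prob
  signature_from_increments(
    mu_a = stats::rnorm(1, hyper$mu_a_mean, hyper$mu_a_sd),
    delta_b = stats::rnorm(1, 0, hyper$delta_sd),
    delta_ac = if (c_mu[1]) stats::rnorm(1, 0, hyper$delta_sd) else 0,
    delta_cd = stats::rnorm(1, 0, hyper$delta_sd),
    delta_ce = if (c_mu[2]) stats::rnorm(1, 0, hyper$delta_sd) else 0,
    loglam_c = stats::rnorm(1, hyper$loglambda_mean, hyper$loglambda_sd),
    loglam_e = stats::rnorm(1, hyper$loglambda_mean, hyper$loglambda_sd),
    c_mu = c_mu, c_lambda = c_lambda)
}

#' Serialize / deserialize a signature as JSON
#'
#' @param theta A [prototype_signature()].
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string or (invisibly) the path written.
#' @export
signature_to_json <- function(theta, path = NULL) {
  stopifnot(inherits(theta, "prototype_signature"))
  x <- unclass(theta)
  if (is.null(path)) {
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname signature_to_json
#' @param json JSON string or path to a JSON file.
#' @export
signature_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  prototype_signature(x$mu_a, x$X_b, x$mu_c, x$lambda_c, x$X_d, x$mu_e,
                      x$lambda_e, x$c_mu, x$c_lambda)
}
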