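## JSON persistence of posterior samples (fit -> summarize round trip).

#' Write / read posterior samples as JSON
#'
#' Snapshots, unit table, schedules, and configuration are stored in a
#' single JSON document sufficient to recompute every summary.
#'
#' @param samples A `posterior_samples` object.
#' @param path Output path.
#' @return The path (write) or a `posterior_samples` object (read).
#' @export
write_posterior_samples <- function(samples, path) {
  stopifnot(inherits(samples, "posterior_samples"))
  doc <- list(
    samples = lapply(samples$samples, function(smp) {
      list(z = smp$z,
           signatures = lapply(smp$signatures, unclass),
           gamma = smp$gamma, eps1 = smp$eps1, eps2 = smp$eps2,
           alpha = smp$alpha, n_clusters = smp$n_clusters,
           chain = smp$chain, iter = smp$iter)
    }),
    units = samples$units,
    subjects = samples$subjects,
    O_s = as.list(samples$O_s),
    schedules = lapply(samples$schedules, function(s) s$breaks),
    taxonomy = samples$taxonomy,
    config = unclass(samples$config),
    hyper = unclass(samples$hyper))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_posterior_samples
#' @export
read_posterior_samples <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  samples <- lapply(doc$samples, function(smp) {
    list(z = vapply(smp$z, as.integer, integer(1)),
         signatures = lapply(smp$signatures, function(x) {
           prototype_signature(x$mu_a, x$X_b, x$mu_c, x$lambda_c, x$X_d,
                               x$mu_e, x$lambda_e,
                               vapply(x$c_mu, isTRUE, logical(1)),
                               isTRUE(x$c_lambda))
         }),
         gamma = vapply(smp$gamma, as.numeric, numeric(1)),
         eps1 = smp$eps1, eps2 = smp$eps2,
         alpha = smp$alpha, n_clusters = as.integer(smp$n_clusters),
         chain = smp$chain, iter = smp$iter)
  })
  cfg <- doc$config
  units <- data.frame(
    subject = vapply(doc$units, function(u) u$subject, ""),
    refotu = vapply(doc$units, function(u) u$refotu, ""),
    stringsAsFactors = FALSE)
  taxonomy <- do.call(rbind, lapply(doc$taxonomy, function(r) {
    data.frame(refotu = r$refotu, order = r$order, family = r$family,
               genus = r$genus, stringsAsFactors = FALSE)
  }))
  hyper_args <- doc$hyper[!vapply(doc$hyper, is.null, logical(1))]
  structure(
    list(samples = samples,
         units = units,
         subjects = unlist(doc$subjects),
         O_s = unlist(doc$O_s),
         schedules = lapply(doc$schedules, function(b) perturbation_schedule(unlist(b))),
         taxonomy = taxonomy,
         config = mcmc_config(cfg$n_burnin, cfg$n_sampling, cfg$thin,
                              cfg$n_chains, cfg$seed, cfg$n_aux,
                              cfg$proposal_scales),
         hyper = do.call(default_hyperparams, hyper_args)),
    class = "posterior_samples")
}
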