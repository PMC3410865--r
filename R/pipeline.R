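## End-to-end orchestration: simulate / filter / fit / summarize / design
## with a reproducibility manifest.

pipeline_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "trajmix_error")))
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      pipeline_error(paste0("config file not found: ", config),
                     "trajmix_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    pipeline_error("config must be a list or a YAML path", "trajmix_config_error")
  }
  config
}

config_hyper <- function(cfg) {
  args <- cfg$model
  if (is.null(args)) return(default_hyperparams())
  do.call(default_hyperparams,
          args[names(args) %in% names(formals(default_hyperparams))])
}

config_mcmc <- function(cfg, seed) {
  args <- cfg$mcmc
  if (identical(args$preset, "paper")) return(mcmc_config_paper_protocol(seed))
  args <- args[names(args) %in% names(formals(mcmc_config))]
  args$seed <- seed
  do.call(mcmc_config, args)
}

file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full analysis pipeline
#'
#' Stages: obtain data (load TSVs or simulate), apply the abundance filter,
#' fit the mixture model by MCMC, compute the posterior summaries
#' (diversity scores, relaxation-time distributions, consensus signature
#' groups, enrichment), and optionally generate an optimized sampling
#' design. All artifacts plus a reproducibility manifest are written to
#' `out_dir`; no stage mutates its inputs and all randomness flows from the
#' configured seed.
#'
#' @param config List or YAML path with sections `data` (or `simulate`),
#'   `filter`, `model`, `mcmc`, `summaries`, `design`, and top-level `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the fitted samples, summaries and
#'   manifest.
#' @export
run_full_analysis <- function(config, out_dir) {
  cfg <- read_run_config(config)
  seed <- as.integer(cfg$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, package_version = as.character(utils::packageVersion("trajmix")),
                   stages = list())
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      if (inherits(e, "trajmix_error")) stop(e)
      pipeline_error(paste0("stage ", name, ": ", conditionMessage(e)),
                     "trajmix_numerical_error")
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  # --- data ---------------------------------------------------------------
  truth <- NULL
  got <- t_stage("data", {
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args <- args[names(args) %in% names(formals(sim_config))]
      args$seed <- seed
      sim <- generate_counts_dataset(do.call(sim_config, args))
      truth <- sim$truth
      simdir <- file.path(out_dir, "sim")
      write_counts_dataset(sim$dataset, simdir, sim$schedules)
      list(dataset = sim$dataset, schedules = sim$schedules)
    } else if (!is.null(cfg$data)) {
      got <- tryCatch(
        load_counts_table(unlist(cfg$data$counts), cfg$data$taxonomy,
                          unlist(cfg$data$schedule)),
        error = function(e) pipeline_error(conditionMessage(e),
                                           "trajmix_data_error"))
      got
    } else {
      pipeline_error("config needs a `data` or `simulate` section",
                     "trajmix_config_error")
    }
  })
  manifest$data_digest <- if (!is.null(cfg$data)) {
    file_digests(unlist(cfg$data$counts))
  } else list(simulated = TRUE, sim_seed = seed)

  # --- filter + fit -------------------------------------------------------
  fcfg <- cfg$filter %||% list()
  dat <- t_stage("filter", {
    filter_refotus(got$dataset, fcfg$min_count %||% 5,
                   fcfg$min_timepoints %||% 10)
  })
  hyper <- config_hyper(cfg)
  mcfg <- config_mcmc(cfg, seed)
  fit <- t_stage("fit", run_mcmc(dat, got$schedules, mcfg, hyper))
  write_posterior_samples(fit, file.path(out_dir, "samples.json"))

  # --- summaries ----------------------------------------------------------
  summaries <- t_stage("summarize", {
    sd1 <- sd1_scores(fit)
    sd2 <- vapply(fit$subjects, function(s) sd2_score(fit, s), numeric(1))
    sd3 <- if (length(fit$subjects) >= 2) sd3_score(fit) else NULL
    scores <- list(sd1 = sd1, sd2 = as.list(sd2),
                   sd3 = if (!is.null(sd3)) sd3$sd3)
    jsonlite::write_json(scores, file.path(out_dir, "sd_scores.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    rtd_c <- relaxation_time_density(fit, "c")
    rtd_e <- relaxation_time_density(fit, "e")
    rtd <- data.frame(day = rtd_c$density$x, density_c = rtd_c$density$y,
                      density_e = stats::approx(rtd_e$density$x,
                                                rtd_e$density$y,
                                                xout = rtd_c$density$x,
                                                rule = 2)$y)
    utils::write.table(rtd, file.path(out_dir, "rtd.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    P <- coassignment_matrix(fit)
    utils::write.table(round(P, 4), file.path(out_dir, "coassignment.tsv"),
                       sep = "\t", quote = FALSE)
    csgs <- build_csgs(P, fit)
    jsonlite::write_json(
      lapply(seq_along(csgs), function(g) {
        traj <- consensus_trajectory(csgs[[g]], fit)
        list(csg = g, members = csgs[[g]]$members,
             lambda_c = attr(traj, "lambda_c"),
             lambda_e = attr(traj, "lambda_e"))
      }),
      file.path(out_dir, "csgs.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    enr <- csg_enrichment_table(csgs, fit)
    utils::write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(sd1 = sd1, sd2 = sd2, sd3 = sd3, csgs = csgs, enrichment = enr)
  })

  # --- optional design ----------------------------------------------------
  design <- NULL
  if (!is.null(cfg$design)) {
    design <- t_stage("design", {
      dcfg <- cfg$design
      sched <- got$schedules[[1]]
      cand <- dcfg$candidates %||%
        seq(sched$breaks[1], sched$breaks[6] - 1, by = 1)
      d <- design_strategy(dcfg$strategy %||% "sequential", dat,
                           got$schedules, cand,
                           budget = dcfg$budget %||% 20,
                           input_subject = dcfg$input_subject,
                           n_prior_samples = dcfg$n_prior_samples %||% 500,
                           mcmc_config = mcfg, hyper = hyper)
      jsonlite::write_json(list(strategy = d$strategy, times = d$times,
                                g_trace = d$g_trace),
                           file.path(out_dir, "design.json"),
                           auto_unbox = TRUE, digits = NA)
      d
    })
  }

  manifest$config <- sanitize_for_json(cfg)
  manifest$mcmc <- unclass(mcfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(samples = fit, summaries = summaries, design = design,
                 truth = truth, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip S3 classes recursively so arbitrary config objects serialize
sanitize_for_json <- function(x) {
  if (is.list(x)) lapply(unclass(x), sanitize_for_json) else unclass(x)
}
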