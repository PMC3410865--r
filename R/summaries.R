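## Signature-diversity scores, relaxation-time distributions, consensus
## signature groups and taxon enrichment, all pure functions of a
## posterior_samples object.

unit_indices <- function(samples, subject) {
  which(samples$units$subject == subject)
}

#' Intra-signature diversity (SD1)
#'
#' Per subject, the expected fraction of refOTUs whose assigned prototype
#' signature effectively uses more than one equilibrium level (`SD1_mu`)
#' or more than one relaxation time constant (`SD1_lambda`), averaged over
#' posterior samples. Both components lie in [0, 1].
#'
#' @param samples A `posterior_samples` object.
#' @return Data frame with columns `subject`, `sd1_mu`, `sd1_lambda`.
#' @export
sd1_scores <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"), length(samples$samples) > 0)
  res <- lapply(samples$subjects, function(s) {
    us <- unit_indices(samples, s)
    mu_frac <- lambda_frac <- numeric(length(samples$samples))
    for (j in seq_along(samples$samples)) {
      smp <- samples$samples[[j]]
      multi_mu <- vapply(smp$signatures, function(th) any(th$c_mu), logical(1))
      multi_lam <- vapply(smp$signatures, function(th) th$c_lambda, logical(1))
      mu_frac[j] <- mean(multi_mu[smp$z[us]])
      lambda_frac[j] <- mean(multi_lam[smp$z[us]])
    }
    data.frame(subject = s, sd1_mu = mean(mu_frac),
               sd1_lambda = mean(lambda_frac), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

shannon_entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log(p))
}

#' Intra-ecosystem diversity (SD2)
#'
#' Expected equivalent number of prototype signatures per 100 refOTUs for
#' one subject: `(100 / O_s) * mean_j exp(H_s(n_s^(j)))` where `H_s` is the
#' Shannon entropy (natural log) of the subject-restricted signature
#' occupancy distribution in sample j. Bounded by `[100 / O_s, 100]`.
#'
#' @param samples A `posterior_samples` object.
#' @param subject Subject identifier.
#' @return Scalar SD2 score.
#' @export
sd2_score <- function(samples, subject) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!subject %in% samples$subjects) stop("unknown subject: ", subject, call. = FALSE)
  us <- unit_indices(samples, subject)
  eh <- vapply(samples$samples, function(smp) {
    exp(shannon_entropy(tabulate(smp$z[us])))
  }, numeric(1))
  100 / length(us) * mean(eh)
}

#' Inter-ecosystem diversity (SD3)
#'
#' Ratio `SD2^D / SD2^I` of the SD2 score of the hypothetical combined
#' ecosystem (pooled occupancy distribution over all subjects) to the
#' occupancy-weighted average of the per-subject SD2 scores. Ranges from
#' `1/S` (all signatures fully shared with identical occupancy) to 1
#' (per-subject signature sets disjoint).
#'
#' @param samples A `posterior_samples` object (>= 2 subjects).
#' @return List with `sd3`, `sd2_combined`, `sd2_independent`.
#' @export
sd3_score <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (length(samples$subjects) < 2L) {
    stop("SD3 requires at least two subjects", call. = FALSE)
  }
  n <- nrow(samples$units)
  eh <- vapply(samples$samples, function(smp) exp(shannon_entropy(tabulate(smp$z))),
               numeric(1))
  sd2_d <- 100 / n * mean(eh)
  sd2_s <- vapply(samples$subjects, function(s) sd2_score(samples, s), numeric(1))
  w <- samples$O_s[samples$subjects] / n
  sd2_i <- sum(w * sd2_s)
  list(sd3 = sd2_d / sd2_i, sd2_combined = sd2_d, sd2_independent = sd2_i)
}

#' Permutation test of cross-subject signature sharing
#'
#' Null hypothesis: independent ecosystems. For each permutation, every
#' subject's occupied signature labels are independently and injectively
#' relabelled into the sample's global active-label set, preserving each
#' subject's occupancy vector while destroying systematic cross-subject
#' sharing (labels can still collide by chance). The one-sided p-value is
#' `(1 + #{SD3_perm <= SD3_obs}) / (n_perm + 1)` since sharing lowers SD3.
#'
#' @param samples A `posterior_samples` object.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return List with `p_value`, `sd3_observed`, `sd3_null` (vector).
#' @export
sd3_permutation_test <- function(samples, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  obs <- sd3_score(samples)$sd3
  # per-sample per-subject occupancy vectors
  occ <- lapply(samples$samples, function(smp) {
    lapply(samples$subjects, function(s) {
      tab <- table(smp$z[unit_indices(samples, s)])
      as.integer(tab)
    })
  })
  n <- nrow(samples$units)
  O_s <- samples$O_s[samples$subjects]
  w <- O_s / n
  set.seed(seed %% 2147483647L)
  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    eh_pool <- numeric(length(occ))
    for (j in seq_along(occ)) {
      kj <- sum(lengths(occ[[j]]))  # global label space size
      pooled <- numeric(kj)
      for (si in seq_along(occ[[j]])) {
        ks <- length(occ[[j]][[si]])
        lab <- sample.int(kj, ks)
        pooled[lab] <- pooled[lab] + occ[[j]][[si]]
      }
      eh_pool[j] <- exp(shannon_entropy(pooled))
    }
    sd2_d <- 100 / n * mean(eh_pool)
    # per-subject SD2 is invariant under relabeling
    sd2_i <- sum(w * vapply(seq_along(samples$subjects), function(si) {
      100 / O_s[si] * mean(vapply(occ, function(o) exp(shannon_entropy(o[[si]])),
                                  numeric(1)))
    }, numeric(1)))
    null[p] <- sd2_d / sd2_i
  }
  list(p_value = (1 + sum(null <= obs)) / (n_perm + 1),
       sd3_observed = obs, sd3_null = null)
}

#' Posterior median relaxation-time constants
#'
#' One constant per (subject, refOTU): the posterior median across samples
#' of the assigned signature's relaxation time on the requested post-pulse
#' interval.
#'
#' @param samples A `posterior_samples` object.
#' @param interval `"c"` (first post-antibiotic) or `"e"` (second).
#' @return Numeric vector (days), one per unit, named `subject:refotu`.
#' @export
relaxation_constants <- function(samples, interval = c("c", "e")) {
  interval <- match.arg(interval)
  field <- if (interval == "c") "lambda_c" else "lambda_e"
  n <- nrow(samples$units)
  lam <- matrix(NA_real_, length(samples$samples), n)
  for (j in seq_along(samples$samples)) {
    smp <- samples$samples[[j]]
    lk <- vapply(smp$signatures, `[[`, numeric(1), field)
    lam[j, ] <- lk[smp$z]
  }
  stats::setNames(apply(lam, 2, stats::median),
                  paste(samples$units$subject, samples$units$refotu, sep = ":"))
}

#' Relaxation-time distribution (RTD)
#'
#' Gaussian kernel density estimate over the per-refOTU posterior median
#' relaxation constants of all subjects, with Silverman's rule-of-thumb
#' bandwidth by default.
#'
#' @param samples A `posterior_samples` object.
#' @param interval `"c"` or `"e"`.
#' @param bw Bandwidth (days); default Silverman's rule.
#' @return List of class `relaxation_time_density`: `constants`, `density`
#'   (a [stats::density()] object), `interval`.
#' @export
relaxation_time_density <- function(samples, interval = c("c", "e"), bw = "nrd0") {
  interval <- match.arg(interval)
  constants <- relaxation_constants(samples, interval)
  dens <- stats::density(constants, bw = bw, cut = 6)
  structure(list(constants = constants, density = dens, interval = interval),
            class = "relaxation_time_density")
}

#' @export
print.relaxation_time_density <- function(x, ...) {
  cat(sprintf("Relaxation-time distribution, interval (%s): %d constants, median %.2f days, bw %.3f\n",
              x$interval, length(x$constants), stats::median(x$constants),
              x$density$bw))
  invisible(x)
}

#' Posterior co-assignment matrix
#'
#' `p[uo, u'o'] = (1/J) * #{j : z_uo^(j) = z_u'o'^(j)}`: the fraction of
#' posterior samples in which two (subject, refOTU) units share a prototype
#' signature. Symmetric, unit diagonal, entries in [0, 1].
#'
#' @param samples A `posterior_samples` object.
#' @return n x n numeric matrix with `subject:refotu` dimnames.
#' @export
coassignment_matrix <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"), length(samples$samples) > 0)
  n <- nrow(samples$units)
  P <- matrix(0, n, n)
  for (smp in samples$samples) {
    Z <- outer(smp$z, smp$z, `==`)
    P <- P + Z
  }
  P <- P / length(samples$samples)
  nm <- paste(samples$units$subject, samples$units$refotu, sep = ":")
  dimnames(P) <- list(nm, nm)
  P
}

# Average-linkage agglomeration on a similarity matrix, explicit
# lowest-pair-index tie-break, stopping at n_groups clusters.
average_linkage_groups <- function(similarity, n_groups) {
  n <- nrow(similarity)
  stopifnot(n_groups >= 1, n_groups <= n)
  groups <- as.list(seq_len(n))
  sim <- similarity
  diag(sim) <- -Inf
  while (length(groups) > n_groups) {
    best <- which(sim == max(sim), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    gi <- groups[[i]]; gj <- groups[[j]]
    merged <- c(gi, gj)
    # average linkage: size-weighted mean of the two merged rows
    newrow <- (length(gi) * sim[i, ] + length(gj) * sim[j, ]) /
      (length(gi) + length(gj))
    keep <- setdiff(seq_along(groups), c(i, j))
    groups <- c(groups[keep], list(merged))
    m <- length(groups)
    newsim <- matrix(-Inf, m, m)
    if (length(keep)) newsim[seq_along(keep), seq_along(keep)] <- sim[keep, keep]
    newsim[m, seq_along(keep)] <- newrow[keep]
    newsim[seq_along(keep), m] <- newrow[keep]
    sim <- newsim
  }
  membership <- integer(n)
  # deterministic group order: by smallest member index
  groups <- groups[order(vapply(groups, min, integer(1)))]
  for (g in seq_along(groups)) membership[groups[[g]]] <- g
  membership
}

#' Consensus signature groups (CSGs)
#'
#' Average-linkage agglomerative clustering of (subject, refOTU) units with
#' the posterior co-assignment probability as similarity. Merging stops when
#' the number of clusters reaches the expected number of prototype
#' signatures, the across-sample mean of the occupied-signature count
#' rounded to the nearest integer. Ties in the linkage are broken by the
#' lowest pair index, so the result is deterministic and independent of
#' unit ordering.
#'
#' @param coassignment Matrix from [coassignment_matrix()].
#' @param samples The `posterior_samples` the matrix came from.
#' @param n_groups Optional override of the stopping cluster count.
#' @return List of CSG objects, each with `members` (data frame `subject`,
#'   `refotu`, `unit`), ordered by smallest member index.
#' @export
build_csgs <- function(coassignment, samples, n_groups = NULL) {
  if (is.null(n_groups)) {
    ks <- vapply(samples$samples, `[[`, integer(1), "n_clusters")
    n_groups <- max(1L, round(mean(ks)))
  }
  n_groups <- min(n_groups, nrow(coassignment))
  membership <- average_linkage_groups(coassignment, n_groups)
  lapply(seq_len(max(membership)), function(g) {
    us <- which(membership == g)
    structure(list(
      members = data.frame(subject = samples$units$subject[us],
                           refotu = samples$units$refotu[us],
                           unit = us, stringsAsFactors = FALSE)),
      class = "consensus_signature_group")
  })
}

#' @export
print.consensus_signature_group <- function(x, ...) {
  cat(sprintf("Consensus signature group: %d member(s) across %d subject(s)\n",
              nrow(x$members), length(unique(x$members$subject))))
  invisible(x)
}

#' Consensus trajectory of a CSG
#'
#' For every member and posterior sample, the assigned prototype signature
#' is evaluated on a reference day grid (member time-scales are aligned via
#' [map_to_common_timescale()]), amplitude-normalized (pre-treatment level
#' subtracted, scaled to unit maximum absolute deviation), and summarized
#' pointwise by the median and the 2.5/97.5 percentiles.
#'
#' @param csg A CSG from [build_csgs()].
#' @param samples The `posterior_samples` object.
#' @param ref_subject Subject whose schedule defines the common time-scale
#'   (default: first subject).
#' @param grid Reference days (default: daily over the reference study range).
#' @return Data frame `day`, `median`, `lower`, `upper`; also medians of the
#'   members' relaxation constants as attributes `lambda_c`, `lambda_e`.
#' @export
consensus_trajectory <- function(csg, samples, ref_subject = NULL, grid = NULL) {
  stopifnot(inherits(csg, "consensus_signature_group"))
  if (is.null(ref_subject)) ref_subject <- samples$subjects[[1]]
  ref_sched <- samples$schedules[[ref_subject]]
  if (is.null(grid)) {
    grid <- seq(ref_sched$breaks[1], ref_sched$breaks[6], by = 1)
  }
  trajs <- list()
  for (i in seq_len(nrow(csg$members))) {
    u <- csg$members$unit[i]
    s <- csg$members$subject[i]
    t_subj <- map_to_common_timescale(samples$schedules[[s]], ref_sched,
                                      grid, inverse = TRUE)
    for (smp in samples$samples) {
      th <- smp$signatures[[smp$z[u]]]
      f <- evaluate_signature(th, t_subj, samples$schedules[[s]])
      dev <- f - th$mu_a
      scale <- max(abs(dev))
      trajs[[length(trajs) + 1L]] <- if (scale > 0) dev / scale else dev
    }
  }
  Tm <- do.call(rbind, trajs)
  qs <- apply(Tm, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  out <- data.frame(day = grid, median = qs[2, ], lower = qs[1, ], upper = qs[3, ])
  lam_c <- relaxation_constants(samples, "c")[csg$members$unit]
  lam_e <- relaxation_constants(samples, "e")[csg$members$unit]
  attr(out, "lambda_c") <- stats::median(lam_c)
  attr(out, "lambda_e") <- stats::median(lam_e)
  out
}

#' Hypergeometric taxon enrichment of a CSG
#'
#' For each taxonomic label at the requested rank, the upper-tail
#' hypergeometric probability `P(X >= x)` of drawing `x` or more labelled
#' members in a group of size n from N units of which K carry the label.
#'
#' @param csg A CSG from [build_csgs()].
#' @param samples The `posterior_samples` object (provides the unit universe).
#' @param rank `"order"`, `"family"` or `"genus"`.
#' @return Data frame `rank`, `label`, `overlap`, `group_size`,
#'   `label_total`, `universe`, `p_value`.
#' @export
taxon_enrichment <- function(csg, samples, rank = c("order", "family", "genus")) {
  rank <- match.arg(rank)
  tax <- samples$taxonomy
  labels_all <- tax[[rank]][match(samples$units$refotu, tax$refotu)]
  labels_csg <- labels_all[csg$members$unit]
  N <- length(labels_all)
  n_g <- length(labels_csg)
  out <- lapply(unique(labels_csg), function(L) {
    K <- sum(labels_all == L)
    x <- sum(labels_csg == L)
    data.frame(rank = rank, label = L, overlap = x, group_size = n_g,
               label_total = K, universe = N,
               p_value = stats::phyper(x - 1, K, N - K, n_g, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment.
#'
#' @param pvalues Numeric vector in [0, 1].
#' @return Adjusted q-values (same length), each <= 1.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment table across all CSGs and ranks
#'
#' Hypergeometric tests for every (CSG, rank, label) combination with a
#' single pooled BH-FDR correction; `significant` flags q < `fdr`.
#'
#' @param csgs List from [build_csgs()].
#' @param samples The `posterior_samples` object.
#' @param ranks Taxonomic ranks to test.
#' @param fdr Significance threshold on q (default 0.05).
#' @return Data frame with one row per test, including `csg`, `q_value`,
#'   `significant`.
#' @export
csg_enrichment_table <- function(csgs, samples,
                                 ranks = c("order", "family", "genus"),
                                 fdr = 0.05) {
  rows <- list()
  for (g in seq_along(csgs)) {
    for (r in ranks) {
      tab <- taxon_enrichment(csgs[[g]], samples, r)
      if (!is.null(tab) && nrow(tab)) {
        tab$csg <- g
        rows[[length(rows) + 1L]] <- tab
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < fdr
  out[order(out$q_value), ]
}
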