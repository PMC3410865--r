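#' Multi-subject taxon-by-time count dataset
#'
#' Container for per-subject refOTU x time-point sequencing count matrices,
#' observation days, per-sample total read depths, and refOTU taxonomy.
#' Sampling may be irregular and differ between subjects; missing samples are
#' simply absent columns.
#'
#' @param counts Named list (one element per subject) of non-negative integer
#'   matrices, refOTUs in rows (rownames = refOTU ids), time-points in
#'   columns.
#' @param times Named list of strictly increasing observation days, one
#'   vector per subject, matching the columns of `counts`.
#' @param taxonomy Data frame with columns `refotu`, `order`, `family`,
#'   `genus`; refOTUs absent from it are labelled `"unclassified"` at every
#'   rank.
#' @param totals Named list of positive per-sample total read counts (one
#'   vector per subject). Defaults to the column sums of `counts`.
#' @return An object of class `counts_dataset` with fields `subjects`,
#'   `counts`, `times`, `taxonomy`, `totals`.
#' @export
counts_dataset <- function(counts, times, taxonomy = NULL, totals = NULL) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("`counts` must be a named list (one matrix per subject)", call. = FALSE)
  }
  subjects <- names(counts)
  if (!identical(sort(names(times)), sort(subjects))) {
    stop("`times` must be named like `counts`", call. = FALSE)
  }
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    if (anyNA(m) || any(m < 0) || any(m != round(m))) {
      stop("counts must be non-negative integers", call. = FALSE)
    }
    storage.mode(m) <- "integer"
    if (is.null(rownames(m))) {
      rownames(m) <- paste0("otu", seq_len(nrow(m)))
    }
    m
  })
  if (is.null(totals)) {
    totals <- lapply(counts, colSums)
  }
  for (s in subjects) {
    tt <- times[[s]]
    if (length(tt) != ncol(counts[[s]])) {
      stop("subject ", s, ": times length does not match count columns", call. = FALSE)
    }
    if (any(diff(tt) <= 0)) {
      stop("subject ", s, ": observation days must be strictly increasing", call. = FALSE)
    }
    tot <- totals[[s]]
    if (length(tot) != ncol(counts[[s]]) || any(tot <= 0)) {
      stop("subject ", s, ": totals must be positive, one per sample", call. = FALSE)
    }
    if (any(tot < colSums(counts[[s]]))) {
      stop("subject ", s, ": per-sample totals below the refOTU column sum", call. = FALSE)
    }
  }
  all_otus <- unique(unlist(lapply(counts, rownames)))
  taxonomy <- normalize_taxonomy(taxonomy, all_otus)
  structure(
    list(subjects = subjects, counts = counts, times = times,
         taxonomy = taxonomy, totals = totals),
    class = "counts_dataset")
}

normalize_taxonomy <- function(taxonomy, refotus) {
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(refotu = character(0), order = character(0),
                           family = character(0), genus = character(0),
                           stringsAsFactors = FALSE)
  }
  need <- c("refotu", "order", "family", "genus")
  if (!all(need %in% names(taxonomy))) {
    stop("taxonomy must have columns refotu, order, family, genus", call. = FALSE)
  }
  taxonomy <- taxonomy[, need]
  taxonomy[] <- lapply(taxonomy, as.character)
  missing <- setdiff(refotus, taxonomy$refotu)
  if (length(missing)) {
    taxonomy <- rbind(taxonomy,
                      data.frame(refotu = missing, order = "unclassified",
                                 family = "unclassified", genus = "unclassified",
                                 stringsAsFactors = FALSE))
  }
  taxonomy[is.na(taxonomy)] <- "unclassified"
  rownames(taxonomy) <- NULL
  taxonomy
}

#' @export
print.counts_dataset <- function(x, ...) {
  cat("Count dataset:", length(x$subjects), "subject(s)\n")
  for (s in x$subjects) {
    cat(sprintf("  %s: %d refOTUs x %d time-points (days %g-%g)\n",
                s, nrow(x$counts[[s]]), ncol(x$counts[[s]]),
                min(x$times[[s]]), max(x$times[[s]])))
  }
  invisible(x)
}

#' Read count tables, taxonomy and perturbation schedules
#'
#' Counts are TSV files with refOTU ids in the first column and one column
#' per observation day (column names are the day labels). Taxonomy is a TSV
#' with columns `refotu`, `order`, `family`, `genus`. Schedules are key-value
#' configs with one `interval = start end` line per interval a--e.
#'
#' @param counts_paths Named character vector of per-subject count TSV paths
#'   (names are subject ids).
#' @param taxonomy_path Path to the taxonomy TSV, or `NULL`.
#' @param schedule_paths Named character vector of per-subject schedule
#'   config paths; a single unnamed path is recycled for all subjects.
#' @return List with elements `dataset` (a [counts_dataset()]) and
#'   `schedules` (named list of [perturbation_schedule()]s).
#' @export
load_counts_table <- function(counts_paths, taxonomy_path = NULL,
                              schedule_paths = NULL) {
  if (is.null(names(counts_paths))) {
    names(counts_paths) <- paste0("S", seq_along(counts_paths))
  }
  counts <- list(); times <- list(); totals <- list()
  for (s in names(counts_paths)) {
    tab <- utils::read.delim(counts_paths[[s]], check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    # read the day labels before subsetting: `[.data.frame` would repair
    # duplicated column names and mask duplicate time-points
    day <- suppressWarnings(as.numeric(sub("^[Xx]", "", colnames(tab)[-1])))
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (anyNA(day)) {
      stop("subject ", s, ": count columns must be labelled by day", call. = FALSE)
    }
    if (anyDuplicated(day)) {
      stop("subject ", s, ": duplicate time-point columns", call. = FALSE)
    }
    if (anyNA(m) || any(m != round(m)) || any(m < 0)) {
      bad <- which(apply(m, 1, function(r) anyNA(r) || any(r != round(r)) || any(r < 0)))
      stop("subject ", s, ": non-integer or negative counts in row(s) ",
           paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
    }
    o <- order(day)
    rownames(m) <- ids
    colnames(m) <- NULL
    tot <- NULL
    if ("__total__" %in% ids) {
      tot <- as.numeric(m["__total__", o])
      m <- m[ids != "__total__", , drop = FALSE]
    }
    counts[[s]] <- m[, o, drop = FALSE]
    times[[s]] <- day[o]
    totals[[s]] <- if (is.null(tot)) colSums(counts[[s]]) else tot
  }
  taxonomy <- if (is.null(taxonomy_path)) NULL else {
    utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
  }
  dataset <- counts_dataset(counts, times, taxonomy, totals)
  schedules <- NULL
  if (!is.null(schedule_paths)) {
    if (length(schedule_paths) == 1L && is.null(names(schedule_paths))) {
      schedule_paths <- stats::setNames(rep(schedule_paths, length(counts)),
                                        names(counts))
    }
    schedules <- lapply(schedule_paths, read_schedule)[dataset$subjects]
  }
  list(dataset = dataset, schedules = schedules)
}

#' Write a dataset back to per-subject TSV files
#'
#' Inverse of [load_counts_table()]; row `__total__` carries the per-sample
#' total read depth.
#'
#' @param dataset A [counts_dataset()].
#' @param dir Output directory (created if needed).
#' @param schedules Optional named list of schedules to write alongside.
#' @return Named character vector of written count paths, invisibly.
#' @export
write_counts_dataset <- function(dataset, dir, schedules = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in dataset$subjects) {
    m <- rbind(dataset$counts[[s]],
               `__total__` = dataset$totals[[s]])
    tab <- data.frame(refotu = rownames(m), m, check.names = FALSE)
    colnames(tab) <- c("refotu", format(dataset$times[[s]], trim = TRUE))
    p <- file.path(dir, paste0("counts_", s, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[s] <- p
    if (!is.null(schedules)) {
      write_schedule(schedules[[s]], file.path(dir, paste0("schedule_", s, ".txt")))
    }
  }
  utils::write.table(dataset$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Abundance filter for refOTUs
#'
#' Retains, independently within each subject, refOTUs with at least
#' `min_count` counts at `min_timepoints` or more time-points. This focuses
#' the analysis on taxa above the detection threshold of the sequencing
#' assay. Idempotent; an empty result is allowed.
#'
#' @param dataset A [counts_dataset()].
#' @param min_count Count threshold per time-point (default 5).
#' @param min_timepoints Minimum number of qualifying time-points (default 10).
#' @return Filtered [counts_dataset()].
#' @export
filter_refotus <- function(dataset, min_count = 5, min_timepoints = 10) {
  stopifnot(inherits(dataset, "counts_dataset"))
  counts <- lapply(dataset$counts, function(m) {
    keep <- rowSums(m >= min_count) >= min_timepoints
    m[keep, , drop = FALSE]
  })
  kept <- unique(unlist(lapply(counts, rownames)))
  taxonomy <- dataset$taxonomy[dataset$taxonomy$refotu %in% kept, , drop = FALSE]
  rownames(taxonomy) <- NULL
  out <- dataset
  out$counts <- counts
  out$taxonomy <- taxonomy
  out
}

#' Read-depth offsets
#'
#' Per-sample offsets `phi_st = log(total_st) - mean_t log(total_s.)`,
#' centred log total read counts. They enter the count model mean
#' multiplicatively, so `exp(phi)` ratios equal total-read ratios between
#' samples.
#'
#' @param dataset A [counts_dataset()].
#' @return Named list of per-subject numeric offset vectors.
#' @export
compute_read_depth_offsets <- function(dataset) {
  stopifnot(inherits(dataset, "counts_dataset"))
  lapply(dataset$totals, function(tot) {
    if (any(tot <= 0)) stop("zero or negative total reads", call. = FALSE)
    lt <- log(tot)
    lt - mean(lt)
  })
}
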