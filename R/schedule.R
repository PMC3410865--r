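#' Perturbation schedule for a two-pulse study
#'
#' A study timeline is partitioned into five contiguous half-open intervals
#' `[start, end)` delimited by two antibiotic pulses: (a) pre-antibiotic,
#' (b) first pulse, (c) first post-antibiotic interval, (d) second pulse and
#' (e) second post-antibiotic interval.
#'
#' @param breaks Numeric vector of six strictly increasing day values: the
#'   starts of intervals a--e followed by the study end day. Interval i is
#'   `[breaks[i], breaks[i+1])`; the study end itself is assigned to
#'   interval e.
#' @return An object of class `perturbation_schedule`.
#' @examples
#' sched <- perturbation_schedule(c(0, 56, 61, 238, 243, 300))
#' interval_of(sched, c(0, 58, 100, 240, 299))
#' @export
perturbation_schedule <- function(breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) != 6L || anyNA(breaks)) {
    stop("`breaks` must be six non-missing day values", call. = FALSE)
  }
  if (any(diff(breaks) <= 0)) {
    stop("schedule intervals must be contiguous, non-overlapping and ordered a < b < c < d < e",
         call. = FALSE)
  }
  structure(
    list(breaks = breaks,
         intervals = data.frame(
           interval = c("a", "b", "c", "d", "e"),
           start = breaks[1:5],
           end = breaks[2:6])),
    class = "perturbation_schedule")
}

#' Default schedule of the emulated ciprofloxacin study
#'
#' Two five-day pulses on days 56--60 and 238--242 (half-open intervals
#' `[56, 61)` and `[238, 243)`) within a 300-day study.
#'
#' @return A [perturbation_schedule()].
#' @export
default_schedule <- function() {
  perturbation_schedule(c(0, 56, 61, 238, 243, 300))
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  cat("Perturbation schedule (days):\n")
  print(x$intervals, row.names = FALSE)
  invisible(x)
}

#' Locate time-points within a schedule
#'
#' @param schedule A [perturbation_schedule()].
#' @param t Numeric vector of days.
#' @return Integer vector in 1..5 (a = 1, ..., e = 5).
#' @export
interval_of <- function(schedule, t) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  b <- schedule$breaks
  if (any(t < b[1] | t > b[6])) {
    stop("time-point outside the study range [", b[1], ", ", b[6], "]",
         call. = FALSE)
  }
  iv <- findInterval(t, b, rightmost.closed = TRUE)
  pmin(iv, 5L)
}

#' Map a subject's time-scale onto a reference schedule
#'
#' Piecewise-linear, strictly monotone map sending the five interval
#' boundaries of `schedule_s` exactly onto those of `schedule_ref`.
#' Subjects sampled on different days can thereby be compared on a common
#' time-scale.
#'
#' @param schedule_s,schedule_ref Subject and reference
#'   [perturbation_schedule()]s.
#' @param t Days on the subject scale (or reference scale when
#'   `inverse = TRUE`).
#' @param inverse Map from the reference scale back to the subject scale.
#' @return Days on the reference scale.
#' @export
map_to_common_timescale <- function(schedule_s, schedule_ref, t,
                                    inverse = FALSE) {
  stopifnot(inherits(schedule_s, "perturbation_schedule"),
            inherits(schedule_ref, "perturbation_schedule"))
  from <- schedule_s$breaks
  to <- schedule_ref$breaks
  if (inverse) {
    tmp <- from; from <- to; to <- tmp
  }
  if (any(t < from[1] | t > from[6])) {
    stop("time-point outside the study range of the source schedule",
         call. = FALSE)
  }
  stats::approx(from, to, xout = t, method = "linear", ties = "ordered")$y
}

# Parse a schedule config: one line per interval, "name = start end".
read_schedule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed schedule line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(x[[2]]), "[[:space:],]+")[[1]]))
    if (length(v) != 2L || anyNA(v)) {
      stop("schedule values must be two numbers (start end): ", x[[2]],
           call. = FALSE)
    }
    v
  })
  need <- c("a", "b", "c", "d", "e")
  if (!setequal(keys, need)) {
    stop("schedule config must define exactly intervals a, b, c, d, e",
         call. = FALSE)
  }
  m <- do.call(rbind, vals[match(need, keys)])
  if (any(abs(m[-1, 1] - m[-5, 2]) > 1e-9)) {
    stop("schedule intervals must be contiguous (end of one = start of next)",
         call. = FALSE)
  }
  perturbation_schedule(c(m[, 1], m[5, 2]))
}

write_schedule <- function(schedule, path) {
  iv <- schedule$intervals
  writeLines(sprintf("%s = %g %g", iv$interval, iv$start, iv$end), path)
  invisible(path)
}
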