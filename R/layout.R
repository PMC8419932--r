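#' Standard stepped-wedge crossover schedule
#'
#' Builds the canonical staircase treatment schedule in which every cluster
#' starts on control, sequence `s` crosses to intervention at period `s + 1`,
#' and all sequences are on intervention in the final period.  This requires
#' at least one more period than there are sequences.
#'
#' @param n_sequences Number of sequences (groups sharing a crossover time).
#' @param n_periods Number of measurement periods; must be at least
#'   `n_sequences + 1`.
#' @return An `n_sequences x n_periods` binary matrix; entry `(s, t)` is 1
#'   when sequence `s` is on intervention in period `t`.
#' @examples
#' standard_schedule(3, 4)
#' @export
standard_schedule <- function(n_sequences, n_periods) {
  stopifnot(is.numeric(n_sequences), length(n_sequences) == 1L,
            n_sequences >= 1, n_sequences == round(n_sequences),
            is.numeric(n_periods), length(n_periods) == 1L,
            n_periods == round(n_periods))
  if (n_periods < n_sequences + 1) {
    stop("invalid geometry: a standard stepped-wedge schedule needs ",
         "n_periods >= n_sequences + 1 (got ", n_sequences, " sequences, ",
         n_periods, " periods)", call. = FALSE)
  }
  sched <- outer(seq_len(n_sequences), seq_len(n_periods),
                 function(s, t) as.numeric(t > s))
  dimnames(sched) <- list(sequence = NULL, period = NULL)
  sched
}

#' Stepped-wedge trial layout
#'
#' Describes the geometry of a cross-sectional stepped-wedge design: how many
#' sequences and periods, how many clusters follow each sequence, an optional
#' second clustering level (subclusters, e.g. care providers within a
#' clinic), and how many new individuals are sampled in every
#' subcluster-period cell.
#'
#' @param n_sequences Number of treatment sequences `S`.
#' @param n_periods Number of periods `T`.
#' @param clusters_per_sequence Scalar or length-`S` vector of cluster counts
#'   per sequence (equal allocation when scalar).
#' @param subclusters Number of subclusters `J` per cluster (default 1, i.e.
#'   a single clustering level).
#' @param n_per_cell Individuals sampled in each subcluster-period cell; the
#'   design is cross-sectional, so these are new individuals every period.
#' @param schedule Optional user-supplied `S x T` binary treatment schedule;
#'   defaults to [standard_schedule()].  Rows that switch back from
#'   intervention to control are only accepted with `custom = TRUE`.
#' @param custom Set to `TRUE` to allow incomplete/custom schedules whose
#'   rows are not non-decreasing.
#' @return An object of class `swd_layout`.
#' @examples
#' swd_layout(3, 4, clusters_per_sequence = 8, n_per_cell = 100)
#' @export
swd_layout <- function(n_sequences, n_periods, clusters_per_sequence = 1,
                       subclusters = 1, n_per_cell = 1, schedule = NULL,
                       custom = FALSE) {
  stopifnot(n_sequences >= 1, n_sequences == round(n_sequences),
            n_periods >= 1, n_periods == round(n_periods),
            subclusters >= 1, subclusters == round(subclusters),
            n_per_cell >= 1, n_per_cell == round(n_per_cell))
  S <- as.integer(n_sequences); T_ <- as.integer(n_periods)
  m <- clusters_per_sequence
  if (length(m) == 1L) m <- rep_len(m, S)
  if (length(m) != S || any(m < 1) || any(m != round(m))) {
    stop("clusters_per_sequence must be a positive integer scalar or a ",
         "length-", S, " vector of positive integers", call. = FALSE)
  }
  if (is.null(schedule)) {
    schedule <- standard_schedule(S, T_)
  } else {
    schedule <- as.matrix(schedule)
    if (!all(dim(schedule) == c(S, T_))) {
      stop("schedule must be a ", S, " x ", T_, " matrix", call. = FALSE)
    }
    if (!all(schedule %in% c(0, 1))) {
      stop("schedule entries must be 0 or 1", call. = FALSE)
    }
    nondec <- all(apply(schedule, 1L, function(r) all(diff(r) >= 0)))
    if (!nondec && !custom) {
      stop("schedule rows must be non-decreasing (clusters stay on ",
           "intervention once crossed over); pass custom = TRUE for an ",
           "incomplete/custom design", call. = FALSE)
    }
  }
  if (!any(schedule == 0) || !any(schedule == 1)) {
    stop("inestimable schedule: both control (0) and intervention (1) ",
         "cells must occur somewhere in the design", call. = FALSE)
  }
  structure(
    list(n_sequences = S, n_periods = T_,
         clusters_per_sequence = as.integer(m),
         subclusters = as.integer(subclusters),
         n_per_cell = as.integer(n_per_cell),
         schedule = schedule, custom = isTRUE(custom)),
    class = "swd_layout"
  )
}

#' Expand a layout into per-cluster row tables
#'
#' Materialises the observation-level rows implied by a layout: for each
#' cluster a table of `n_periods * subclusters * n_per_cell` rows carrying
#' the period index, subcluster index, individual index, and the treatment
#' indicator from the cluster's sequence row.  Ordering is deterministic:
#' period-major, then subcluster, then individual.  Clusters within a
#' sequence are identical by construction.
#'
#' @param layout An [swd_layout()].
#' @return A list with one data frame per cluster; each has an attribute
#'   `sequence` giving the sequence the cluster follows.
#' @export
expand_layout <- function(layout) {
  stopifnot(inherits(layout, "swd_layout"))
  T_ <- layout$n_periods; J <- layout$subclusters; n <- layout$n_per_cell
  out <- list()
  cl <- 0L
  for (s in seq_len(layout$n_sequences)) {
    tab <- data.frame(
      period     = rep(seq_len(T_), each = J * n),
      subcluster = rep(rep(seq_len(J), each = n), times = T_),
      individual = rep(seq_len(n), times = T_ * J)
    )
    tab$treatment <- layout$schedule[s, tab$period]
    for (k in seq_len(layout$clusters_per_sequence[s])) {
      cl <- cl + 1L
      el <- tab
      attr(el, "sequence") <- s
      out[[cl]] <- el
    }
  }
  out
}

total_clusters <- function(layout) sum(layout$clusters_per_sequence)

#' @export
print.swd_layout <- function(x, ...) {
  cat(sprintf(
    "<swd_layout> %d sequences x %d periods, clusters/sequence: %s (%d total)\n",
    x$n_sequences, x$n_periods,
    paste(unique(x$clusters_per_sequence), collapse = "/"),
    total_clusters(x)))
  cat(sprintf("  %d subcluster(s) per cluster, %d individual(s) per cell; %s schedule\n",
              x$subclusters, x$n_per_cell,
              if (x$custom) "custom" else "standard staircase"))
  invisible(x)
}
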