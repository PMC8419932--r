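#' GLMM specification for a stepped-wedge analysis
#'
#' Collects the model side of a power calculation: the outcome family and
#' link, the fixed effects (intercept or baseline prevalence/mean,
#' categorical or linear time trend, intervention effect), and the random
#' effects as standard deviations on the link scale.
#'
#' The intercept may be given directly on the link scale (`intercept`) or
#' indirectly as the control-condition mean (`prevalence`), converted via
#' `g(prevalence)`.  With a categorical time trend, `time_effects` must hold
#' `n_periods - 1` coefficients for periods `2..T` relative to period 1.
#' With a linear trend, `time_slope` multiplies the time score of each
#' period; `time_scores` defaults to `0:(T-1)` so that the intercept remains
#' the mean of the first period, but other codings (e.g. the period index
#' `1:T`, as produced when a fitted model coded time as the period number)
#' may be supplied.
#'
#' Random-effect components are included when their standard deviation is
#' non-`NULL`: `sd_cluster` (cluster intercept), `sd_treatment` (cluster by
#' treatment interaction), `sd_time` (iid cluster by period effects, one
#' indicator column per period including the first), `sd_subcluster`
#' (subcluster intercepts).  All are uncorrelated by default; a full
#' user-supplied covariance matrix `D` (symmetric positive semidefinite,
#' with rows matching the implied random-effect columns) may be given
#' instead.
#'
#' @param family,link,dispersion,size Passed to [swd_family()].
#' @param prevalence Control-condition, reference-period mean on the
#'   response scale (mutually exclusive with `intercept`).
#' @param intercept Intercept on the link scale.
#' @param time_effects Numeric vector of categorical period effects
#'   (length `n_periods - 1`), or `NULL` when using a linear trend.
#' @param time_slope Scalar slope of a linear time trend (link scale per
#'   unit time score).
#' @param time_scores Optional numeric vector of length `n_periods` of time
#'   scores for the linear trend; default `0:(T-1)`.
#' @param effect Intervention effect on the link scale (e.g. log odds
#'   ratio), the parameter the trial is powered for.
#' @param sd_cluster,sd_treatment,sd_time,sd_subcluster Random-effect
#'   standard deviations on the link scale; `NULL` omits the component.
#' @param D Optional full random-effect covariance matrix overriding the
#'   diagonal built from the standard deviations.
#' @return An object of class `swd_model`.
#' @examples
#' swd_model("bernoulli", prevalence = 0.12,
#'           time_effects = c(0.1, 0.1, 0.1), effect = 0.2,
#'           sd_cluster = 0.05, sd_treatment = 0.05)
#' @export
swd_model <- function(family = "bernoulli", link = NULL,
                      prevalence = NULL, intercept = NULL,
                      time_effects = NULL, time_slope = NULL,
                      time_scores = NULL,
                      effect,
                      sd_cluster = NULL, sd_treatment = NULL,
                      sd_time = NULL, sd_subcluster = NULL,
                      D = NULL, dispersion = NULL, size = 1) {
  fam <- if (inherits(family, "swd_family")) family
         else swd_family(family, link, dispersion, size)
  if (is.null(intercept) == is.null(prevalence)) {
    stop("supply exactly one of `intercept` (link scale) or `prevalence` ",
         "(response scale)", call. = FALSE)
  }
  if (!is.null(prevalence)) intercept <- link_value(fam, prevalence)
  if (!is.null(time_effects) && !is.null(time_slope)) {
    stop("supply either categorical `time_effects` or a linear `time_slope`,",
         " not both", call. = FALSE)
  }
  if (missing(effect) || !is.numeric(effect) || length(effect) != 1L) {
    stop("`effect` must be a single number on the link scale", call. = FALSE)
  }
  sds <- list(cluster = sd_cluster, treatment = sd_treatment,
              time = sd_time, subcluster = sd_subcluster)
  for (nm in names(sds)) {
    v <- sds[[nm]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v < 0)) {
      stop("sd_", nm, " must be a single non-negative number", call. = FALSE)
    }
  }
  if (!is.null(D)) check_psd(D, "D")
  structure(
    list(family = fam, intercept = intercept, prevalence = prevalence,
         time_effects = time_effects, time_slope = time_slope,
         time_scores = time_scores, effect = effect, sds = sds, D = D),
    class = "swd_model"
  )
}

check_psd <- function(D, name = "D", tol = 1e-10) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop(name, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(D - t(D))) > tol * max(1, max(abs(D)))) {
    stop(name, " must be symmetric", call. = FALSE)
  }
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop(name, " must be positive semidefinite (smallest eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  }
  invisible(D)
}

# Names of the random-effect columns implied by model + layout, in canonical
# order: cluster intercept, treatment, one indicator per period, one per
# subcluster.
random_structure <- function(model, layout) {
  comp <- character(0)
  sds <- numeric(0)
  sd0 <- model$sds
  if (!is.null(sd0$cluster)) {
    comp <- c(comp, "cluster"); sds <- c(sds, sd0$cluster)
  }
  if (!is.null(sd0$treatment)) {
    comp <- c(comp, "treatment"); sds <- c(sds, sd0$treatment)
  }
  if (!is.null(sd0$time)) {
    comp <- c(comp, paste0("time", seq_len(layout$n_periods)))
    sds <- c(sds, rep(sd0$time, layout$n_periods))
  }
  if (!is.null(sd0$subcluster)) {
    if (layout$subclusters < 2L) {
      warning("sd_subcluster ignored: layout has a single subcluster level",
              call. = FALSE)
    } else {
      comp <- c(comp, paste0("sub", seq_len(layout$subclusters)))
      sds <- c(sds, rep(sd0$subcluster, layout$subclusters))
    }
  }
  list(names = comp, sds = sds)
}

# Fixed-effect coefficient vector (intervention effect last).
fixed_coef <- function(model, layout, hypothesis = "alternative") {
  T_ <- layout$n_periods
  if (!is.null(model$time_effects)) {
    if (length(model$time_effects) != T_ - 1L) {
      stop("time_effects must have length n_periods - 1 = ", T_ - 1L,
           call. = FALSE)
    }
    beta <- c(model$intercept, model$time_effects)
    names(beta) <- c("(Intercept)", paste0("period", 2:T_))
  } else if (!is.null(model$time_slope)) {
    beta <- c(model$intercept, model$time_slope)
    names(beta) <- c("(Intercept)", "time")
  } else {
    beta <- model$intercept
    names(beta) <- "(Intercept)"
  }
  bp <- if (identical(hypothesis, "null")) 0 else model$effect
  beta <- c(beta, treatment = bp)
  beta
}

#' Build the design block for one cluster
#'
#' Assembles the fixed-effect design matrix `X`, the random-effect design
#' `Z`, and the random-effect covariance `D` for a representative cluster of
#' the given sequence.  By default rows are aggregated to one per
#' subcluster-period cell with a `count` column recording how many
#' exchangeable individuals each row represents (an exact,
#' information-preserving reduction); `aggregate = FALSE` expands to one row
#' per individual.
#'
#' @param layout An [swd_layout()].
#' @param model An [swd_model()].
#' @param sequence Sequence index of the cluster.
#' @param aggregate Collapse exchangeable rows within each cell (default).
#' @return An object of class `swd_cluster_block` with elements `X`, `Z`,
#'   `D`, `count` (row multiplicities), `meta` (period, subcluster,
#'   treatment per row), `sequence`, and `replicates` (number of identical
#'   clusters in the sequence).
#' @export
build_cluster_block <- function(layout, model, sequence, aggregate = TRUE) {
  stopifnot(inherits(layout, "swd_layout"), inherits(model, "swd_model"),
            sequence >= 1, sequence <= layout$n_sequences)
  T_ <- layout$n_periods; J <- layout$subclusters
  meta <- data.frame(
    period     = rep(seq_len(T_), each = J),
    subcluster = rep(seq_len(J), times = T_)
  )
  meta$treatment <- layout$schedule[sequence, meta$period]
  count <- rep(layout$n_per_cell, nrow(meta))
  if (!aggregate) {
    idx <- rep(seq_len(nrow(meta)), each = layout$n_per_cell)
    meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
    count <- rep(1L, nrow(meta))
  }

  # Fixed design: intercept, time columns, treatment (last).
  if (!is.null(model$time_effects)) {
    if (length(model$time_effects) != T_ - 1L) {
      stop("time_effects must have length n_periods - 1 = ", T_ - 1L,
           call. = FALSE)
    }
    Tm <- matrix(0, nrow(meta), T_ - 1L)
    hit <- meta$period >= 2L
    Tm[cbind(which(hit), meta$period[hit] - 1L)] <- 1
    colnames(Tm) <- paste0("period", 2:T_)
  } else if (!is.null(model$time_slope)) {
    scores <- model$time_scores %||% (seq_len(T_) - 1)
    if (length(scores) != T_) {
      stop("time_scores must have length n_periods = ", T_, call. = FALSE)
    }
    Tm <- matrix(scores[meta$period], ncol = 1,
                 dimnames = list(NULL, "time"))
  } else {
    Tm <- matrix(0, nrow(meta), 0)
  }
  X <- cbind("(Intercept)" = 1, Tm, treatment = meta$treatment)

  # Random design in canonical component order.
  rs <- random_structure(model, layout)
  q <- length(rs$names)
  Z <- matrix(0, nrow(meta), q, dimnames = list(NULL, rs$names))
  if ("cluster" %in% rs$names) Z[, "cluster"] <- 1
  if ("treatment" %in% rs$names) Z[, "treatment"] <- meta$treatment
  tcols <- grep("^time[0-9]+$", rs$names)
  if (length(tcols)) Z[cbind(seq_len(nrow(meta)), tcols[meta$period])] <- 1
  scols <- grep("^sub[0-9]+$", rs$names)
  if (length(scols)) Z[cbind(seq_len(nrow(meta)), scols[meta$subcluster])] <- 1

  if (!is.null(model$D)) {
    D <- model$D
    if (nrow(D) != q) {
      stop("user-supplied D has dimension ", nrow(D), " but the model ",
           "implies ", q, " random-effect columns (",
           paste(rs$names, collapse = ", "), ")", call. = FALSE)
    }
  } else {
    D <- diag(rs$sds^2, q)
  }
  dimnames(D) <- list(rs$names, rs$names)

  structure(
    list(X = X, Z = Z, D = D, count = count, meta = meta,
         sequence = sequence,
         replicates = layout$clusters_per_sequence[sequence]),
    class = "swd_cluster_block"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linear predictor of a cluster block at random effects zero
#'
#' Evaluates `eta = X beta` with the random effects plugged in at their
#' prior mode of zero.  Under the null hypothesis the intervention effect is
#' set to zero while all other coefficients keep their alternative values.
#'
#' @param block An `swd_cluster_block` from [build_cluster_block()].
#' @param model The [swd_model()].
#' @param hypothesis `"alternative"` (default) or `"null"`.
#' @return Numeric vector of linear-predictor values, one per block row.
#' @export
linear_predictor <- function(block, model,
                             hypothesis = c("alternative", "null")) {
  hypothesis <- match.arg(hypothesis)
  beta <- fixed_coef_for_block(model, block, hypothesis)
  drop(block$X %*% beta)
}

fixed_coef_for_block <- function(model, block, hypothesis) {
  p <- ncol(block$X)
  if (!is.null(model$time_effects)) {
    beta <- c(model$intercept, model$time_effects)
  } else if (!is.null(model$time_slope)) {
    beta <- c(model$intercept, model$time_slope)
  } else {
    beta <- model$intercept
  }
  beta <- c(beta, if (identical(hypothesis, "null")) 0 else model$effect)
  if (length(beta) != p) {
    stop("fixed-effect specification does not match design columns (",
         length(beta), " coefficients vs ", p, " columns)", call. = FALSE)
  }
  names(beta) <- colnames(block$X)
  beta
}

#' @export
print.swd_model <- function(x, ...) {
  cat(sprintf("<swd_model> %s/%s, intercept %.4g", x$family$family,
              x$family$link, x$intercept))
  if (!is.null(x$prevalence)) cat(sprintf(" (prevalence %g)", x$prevalence))
  cat(sprintf(", effect %g\n", x$effect))
  if (!is.null(x$time_effects)) {
    cat("  categorical time effects:",
        paste(format(x$time_effects), collapse = ", "), "\n")
  } else if (!is.null(x$time_slope)) {
    cat(sprintf("  linear time slope %g\n", x$time_slope))
  }
  act <- Filter(Negate(is.null), x$sds)
  if (length(act)) {
    cat("  random-effect SDs:",
        paste(sprintf("%s = %g", names(act), unlist(act)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
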