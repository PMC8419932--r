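#' Power from the intervention-effect variances
#'
#' Evaluates the two-sided normal-approximation power
#' \deqn{\Phi\left(\frac{|\beta_p| - Z_{1-\alpha/2}\sqrt{V_0}}{\sqrt{V_a}}\right),}
#' where \eqn{V_0} and \eqn{V_a} are the variances of the estimated
#' intervention effect under the null and alternative hypotheses.
#'
#' @param beta_p Intervention effect under the alternative (link scale).
#' @param v0,va Variances of the estimator under the null and alternative.
#' @param alpha Two-sided significance level.
#' @return The power, a number in (0, 1).
#' @examples
#' power_from_variances(0.2, 0.005, 0.005, 0.05)
#' @export
power_from_variances <- function(beta_p, v0, va, alpha = 0.05) {
  if (!is.numeric(v0) || !is.numeric(va) || any(v0 <= 0) || any(va <= 0)) {
    stop("variances must be positive", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  stats::pnorm((abs(beta_p) - stats::qnorm(1 - alpha / 2) * sqrt(v0)) /
                 sqrt(va))
}

#' Bundle a layout and a model into a design
#'
#' Convenience container pairing trial geometry with the outcome model, so
#' that power functions can be called with a single object.  `coef()`
#' returns the assumed fixed effects and `vcov()` the approximate covariance
#' of their estimates.
#'
#' @param layout An [swd_layout()].
#' @param model An [swd_model()].
#' @return An object of class `swd_design`.
#' @export
swd_design <- function(layout, model) {
  stopifnot(inherits(layout, "swd_layout"), inherits(model, "swd_model"))
  structure(list(layout = layout, model = model), class = "swd_design")
}

#' @export
print.swd_design <- function(x, ...) {
  print(x$layout); print(x$model)
  invisible(x)
}

#' @export
coef.swd_design <- function(object, ...) {
  fixed_coef(object$model, object$layout)
}

#' @export
vcov.swd_design <- function(object, hypothesis = "alternative", ...) {
  v <- swd_variance(object$layout, object$model)
  if (identical(hypothesis, "null")) v$vcov_null else v$vcov_alt
}

#' Power of a stepped-wedge design
#'
#' Computes the approximate covariance of the intervention-effect estimator
#' via [swd_variance()] and plugs the null and alternative variances into
#' the normal-approximation power formula.
#'
#' @param layout An [swd_layout()] or [swd_design()].
#' @param model An [swd_model()] (omit when a design is given).
#' @param alpha Two-sided significance level.
#' @param null_variance Passed to [swd_variance()].
#' @return An object of class `swd_power`: power, effect, `v0`, `va`,
#'   `alpha`, and the design.
#' @examples
#' des <- swd_preset("sim_model1")
#' swd_power(des)
#' @export
swd_power <- function(layout, model = NULL, alpha = 0.05,
                      null_variance = c("recompute", "alternative")) {
  d <- resolve_design(layout, model)
  null_variance <- match.arg(null_variance)
  v <- swd_variance(d$layout, d$model, null_variance)
  structure(
    list(power = power_from_variances(d$model$effect, v$var_p_null,
                                      v$var_p_alt, alpha),
         beta_p = d$model$effect, v0 = v$var_p_null, va = v$var_p_alt,
         alpha = alpha, null_variance = null_variance,
         layout = d$layout, model = d$model, variance = v),
    class = "swd_power"
  )
}

#' @export
print.swd_power <- function(x, ...) {
  cat("Stepped-wedge GLMM power (Laplace approximation)\n")
  cat(sprintf("  design: %d sequences x %d periods, %d clusters, %d per cell\n",
              x$layout$n_sequences, x$layout$n_periods,
              total_clusters(x$layout),
              x$layout$n_per_cell * x$layout$subclusters))
  cat(sprintf("  effect %g, alpha %g\n", x$beta_p, x$alpha))
  cat(sprintf("  Var(beta_p): null %.6g, alternative %.6g\n", x$v0, x$va))
  cat(sprintf("  power: %.4f\n", x$power))
  invisible(x)
}

#' @export
summary.swd_power <- function(object, ...) {
  print(object)
  cat(sprintf("  information condition number: %.3g\n",
              object$variance$diagnostics$information_condition))
  invisible(object)
}

# Generic monotone integer solver: smallest k in [1, cap] with f(k) >= target.
# Exponential bracketing then integer bisection; monotonicity verified at the
# bracket endpoints.
solve_monotone_integer <- function(f, target, cap, what) {
  trace <- list()
  eval_f <- function(k) {
    p <- f(k)
    trace[[length(trace) + 1L]] <<- c(value = k, power = p)
    p
  }
  lo <- 1L
  p_lo <- eval_f(lo)
  if (p_lo >= target) {
    return(list(solution = lo, achieved = p_lo, plateau = NA_real_,
                trace = do.call(rbind, trace)))
  }
  hi <- 2L
  p_hi <- eval_f(hi)
  while (p_hi < target && hi < cap) {
    lo <- hi; p_lo <- p_hi
    hi <- min(cap, hi * 2L)
    p_hi <- eval_f(hi)
  }
  if (p_hi < target) {
    stop(swd_condition(
      "swd_unachievable",
      sprintf(paste0("power target %.3g unachievable with this random-effect",
                     " structure: power plateaus at %.4f as %s reaches the",
                     " cap of %d"), target, p_hi, what, cap),
      data = list(plateau = p_hi, cap = cap)))
  }
  if (p_hi < p_lo) {
    stop("power trace is not monotone over the bracket [", lo, ", ", hi,
         "]; refusing to bisect", call. = FALSE)
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    p_mid <- eval_f(mid)
    if (p_mid >= target) { hi <- mid; p_hi <- p_mid }
    else { lo <- mid; p_lo <- p_mid }
  }
  # minimality self-check
  stopifnot(p_hi >= target, p_lo < target)
  list(solution = hi, achieved = p_hi, plateau = NA_real_,
       trace = do.call(rbind, trace))
}

swd_condition <- function(class, message, data = list()) {
  structure(class = c(class, "error", "condition"),
            c(list(message = message, call = NULL), data))
}

#' Smallest cluster-period size reaching a power target
#'
#' Integer search over the number of individuals per subcluster-period cell.
#' Power is non-decreasing in the cell size but approaches a plateau set by
#' the random-effect structure; if the plateau lies below the target the
#' search stops at the cap with an "unachievable" error reporting the
#' plateau power.
#'
#' @param layout An [swd_layout()] or [swd_design()].
#' @param model An [swd_model()] (omit when a design is given).
#' @param target Target power.
#' @param alpha Two-sided significance level.
#' @param cap Upper bound of the search (default `1e6`).
#' @param null_variance Passed to [swd_variance()].
#' @return An object of class `swd_samplesize` with the solution, achieved
#'   power, and the search trace.
#' @export
swd_solve_n <- function(layout, model = NULL, target = 0.8, alpha = 0.05,
                        cap = 1e6, null_variance = "recompute") {
  d <- resolve_design(layout, model)
  stopifnot(target > 0, target < 1)
  f <- function(n) {
    lay <- d$layout; lay$n_per_cell <- as.integer(n)
    swd_power(lay, d$model, alpha, null_variance)$power
  }
  res <- solve_monotone_integer(f, target, as.integer(cap), "n_per_cell")
  structure(
    c(res,
      list(variable = "n_per_cell", target = target, alpha = alpha,
           layout = d$layout, model = d$model,
           per_cluster_period = res$solution * d$layout$subclusters)),
    class = "swd_samplesize"
  )
}

#' Smallest number of clusters per sequence reaching a power target
#'
#' Integer search over the (equal) number of clusters allocated to each
#' sequence; the total number of clusters is the solution times the number
#' of sequences, so totals move in multiples of the sequence count.
#'
#' @inheritParams swd_solve_n
#' @param cap Upper bound for clusters per sequence (default `1e4`).
#' @return An `swd_samplesize` object; `$total_clusters` gives the design
#'   total.
#' @export
swd_solve_clusters <- function(layout, model = NULL, target = 0.8,
                               alpha = 0.05, cap = 1e4,
                               null_variance = "recompute") {
  d <- resolve_design(layout, model)
  stopifnot(target > 0, target < 1)
  f <- function(m) {
    lay <- d$layout
    lay$clusters_per_sequence <- rep(as.integer(m), lay$n_sequences)
    swd_power(lay, d$model, alpha, null_variance)$power
  }
  res <- solve_monotone_integer(f, target, as.integer(cap),
                                "clusters_per_sequence")
  structure(
    c(res,
      list(variable = "clusters_per_sequence", target = target, alpha = alpha,
           layout = d$layout, model = d$model,
           total_clusters = res$solution * d$layout$n_sequences)),
    class = "swd_samplesize"
  )
}

#' @export
print.swd_samplesize <- function(x, ...) {
  cat("Stepped-wedge sample-size solution\n")
  cat(sprintf("  variable: %s, target power %.2f at alpha %.3g\n",
              x$variable, x$target, x$alpha))
  cat(sprintf("  solution: %d (achieved power %.4f)\n",
              x$solution, x$achieved))
  if (!is.null(x$total_clusters)) {
    cat(sprintf("  total clusters: %d over %d sequences\n",
                x$total_clusters, x$layout$n_sequences))
  }
  if (!is.null(x$per_cluster_period)) {
    cat(sprintf("  individuals per cluster-period: %d\n",
                x$per_cluster_period))
  }
  cat(sprintf("  search evaluations: %d\n", nrow(x$trace)))
  invisible(x)
}

#' Power curve over a design variable
#'
#' Evaluates the design power on a grid of values of `n_per_cell` or
#' `clusters_per_sequence`.
#'
#' @inheritParams swd_solve_n
#' @param variable `"n_per_cell"` or `"clusters_per_sequence"`.
#' @param grid Integer vector of values to evaluate.
#' @return A data frame of class `swd_power_curve` with columns `value` and
#'   `power`.
#' @export
swd_power_curve <- function(layout, model = NULL,
                            variable = c("n_per_cell",
                                         "clusters_per_sequence"),
                            grid, alpha = 0.05,
                            null_variance = "recompute") {
  d <- resolve_design(layout, model)
  variable <- match.arg(variable)
  stopifnot(is.numeric(grid), length(grid) >= 1, all(grid >= 1))
  pw <- vapply(grid, function(v) {
    lay <- d$layout
    if (variable == "n_per_cell") lay$n_per_cell <- as.integer(v)
    else lay$clusters_per_sequence <- rep(as.integer(v), lay$n_sequences)
    swd_power(lay, d$model, alpha, null_variance)$power
  }, numeric(1))
  structure(data.frame(value = grid, power = pw),
            class = c("swd_power_curve", "data.frame"),
            variable = variable, alpha = alpha)
}

#' @export
plot.swd_power_curve <- function(x, ..., target = NULL) {
  graphics::plot(x$value, x$power, type = "b", pch = 16,
                 xlab = attr(x, "variable"), ylab = "power",
                 ylim = range(c(x$power, target, 0.5, 1)), ...)
  if (!is.null(target)) graphics::abline(h = target, lty = 2)
  invisible(x)
}
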