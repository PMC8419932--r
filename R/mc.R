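#' Monte-Carlo validation of the analytic power calculation
#'
#' Reproduces the simulation comparison behind the analytic approximation:
#' repeatedly simulates data from the generating GLMM, refits the model by
#' marginal maximum likelihood, and compares the empirical variance of the
#' estimated intervention effect (and the empirical Wald power) against the
#' analytic values.
#'
#' Replicates whose fit fails to converge are excluded from the variance and
#' power tallies.  Fits whose variance estimates land on the zero boundary
#' (singular fits) are counted and reported; they are kept in the tallies by
#' default because the intervention-effect estimate from a singular fit is a
#' valid maximum-likelihood estimate, and discarding them conditions the
#' replicate sample on the variance-component estimate -- at generating
#' standard deviations near zero the boundary rate is large and the
#' conditioning visibly distorts the empirical variance.  Set
#' `exclude_boundary = TRUE` for the stricter convention.  Per-replicate
#' seeds are derived from the master seed, so any scenario is exactly
#' reproducible.
#'
#' @param layout An [swd_layout()] or [swd_design()].
#' @param model An [swd_model()] (omit when a design is given).
#' @param reps Number of replicates (default 500).
#' @param seed Master seed.
#' @param alpha Two-sided significance level for the Wald rejection rule.
#' @param hypothesis Generate data under the `"alternative"` (default) or
#'   the `"null"`.
#' @param fitter Fitting function with signature `(data, model)` returning a
#'   list with elements `coef` (treatment last), `se_treatment`,
#'   `converged`, `boundary`; defaults to [swd_fit()].
#' @param exclude_boundary Also drop boundary (singular) fits from the
#'   tallies (default `FALSE`).
#' @param min_converged Fewer usable replicates than this flags the report
#'   unreliable (default `max(2, reps %/% 2)`).
#' @return An object of class `swd_mc`: estimates and standard errors per
#'   usable replicate, empirical variance and power, analytic `v0`/`va` and
#'   power, `ratio_variance` (analytic / empirical) and `ratio_power`
#'   (analytic / empirical), and convergence/boundary counts.
#' @examples
#' \donttest{
#' des <- swd_preset("sim_model1", clusters_per_sequence = 4,
#'                   n_per_cell = 20)
#' swd_mc_validate(des, reps = 20, seed = 1)
#' }
#' @export
swd_mc_validate <- function(layout, model = NULL, reps = 500, seed = 1,
                            alpha = 0.05,
                            hypothesis = c("alternative", "null"),
                            fitter = NULL, min_converged = NULL,
                            exclude_boundary = FALSE) {
  d <- resolve_design(layout, model)
  hypothesis <- match.arg(hypothesis)
  stopifnot(reps >= 1)
  if (is.null(min_converged)) min_converged <- max(2, reps %/% 2)
  if (is.null(fitter)) fitter <- function(data, model) swd_fit(data, model)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, reps)

  est <- se <- rep(NA_real_, reps)
  conv <- bound <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- swd_simulate(d$layout, d$model, seed = rep_seeds[r],
                        hypothesis = hypothesis)
    fit <- tryCatch(fitter(dat, d$model), error = function(e) NULL)
    if (is.null(fit)) next
    conv[r] <- isTRUE(fit$converged)
    bound[r] <- isTRUE(fit$boundary)
    est[r] <- unname(fit$coef[length(fit$coef)])
    se[r] <- fit$se_treatment
  }
  use <- conv & is.finite(est) & is.finite(se)
  if (exclude_boundary) use <- use & !bound
  n_used <- sum(use)

  zcrit <- stats::qnorm(1 - alpha / 2)
  emp_var <- if (n_used >= 2) stats::var(est[use]) else NA_real_
  emp_power <- if (n_used >= 1) mean(abs(est[use]) / se[use] > zcrit)
               else NA_real_

  ana <- swd_power(d$layout, d$model, alpha)
  ana_var <- if (hypothesis == "null") ana$v0 else ana$va

  structure(
    list(estimates = est[use], ses = se[use],
         reps = reps, n_converged = sum(conv), n_boundary = sum(bound),
         n_used = n_used,
         empirical_var = emp_var, empirical_power = emp_power,
         analytic_var = ana_var, analytic_power = ana$power,
         ratio_variance = ana_var / emp_var,
         ratio_power = ana$power / emp_power,
         alpha = alpha, hypothesis = hypothesis, seed = seed,
         unreliable = n_used < min_converged),
    class = "swd_mc"
  )
}

#' @export
print.swd_mc <- function(x, ...) {
  cat("Monte-Carlo validation of the analytic approximation\n")
  cat(sprintf("  %d replicates (%s hypothesis): %d converged, %d boundary, %d used\n",
              x$reps, x$hypothesis, x$n_converged, x$n_boundary, x$n_used))
  cat(sprintf("  variance: analytic %.5g, empirical %.5g (ratio %.3f)\n",
              x$analytic_var, x$empirical_var, x$ratio_variance))
  cat(sprintf("  power:    analytic %.4f,  empirical %.4f (ratio %.3f)\n",
              x$analytic_power, x$empirical_power, x$ratio_power))
  if (x$unreliable) cat("  WARNING: too few usable replicates; unreliable\n")
  invisible(x)
}
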