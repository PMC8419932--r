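#' Simulate outcomes from the generating GLMM
#'
#' Draws one dataset from the model: for every cluster a random-effect
#' vector `b ~ Normal(0, D)` is drawn independently, the conditional mean
#' `h(X beta + Z b)` is formed, and outcomes are sampled from the stated
#' family (bernoulli, poisson, or normal with variance `dispersion`).  The
#' design is cross-sectional: every subcluster-period cell holds
#' `n_per_cell` new individuals.
#'
#' @param layout An [swd_layout()] or [swd_design()].
#' @param model An [swd_model()] (omit when a design is given).
#' @param seed Optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @param hypothesis `"alternative"` (default) or `"null"` (intervention
#'   effect set to zero).
#' @return A data frame with columns `cluster`, `sequence`, `subcluster`,
#'   `period`, `individual`, `treatment`, `y`.
#' @examples
#' d <- swd_simulate(swd_preset("sim_model1", n_per_cell = 5), seed = 1)
#' head(d)
#' @export
swd_simulate <- function(layout, model = NULL, seed = NULL,
                         hypothesis = c("alternative", "null")) {
  d <- resolve_design(layout, model)
  layout <- d$layout; model <- d$model
  hypothesis <- match.arg(hypothesis)
  if (!is.null(seed)) set.seed(seed)
  fam <- model$family
  out <- vector("list", total_clusters(layout))
  cl <- 0L
  for (s in seq_len(layout$n_sequences)) {
    block <- build_cluster_block(layout, model, s, aggregate = FALSE)
    eta_fix <- linear_predictor(block, model, hypothesis)
    L <- psd_factor(block$D)
    for (k in seq_len(layout$clusters_per_sequence[s])) {
      cl <- cl + 1L
      b <- if (ncol(L)) drop(L %*% stats::rnorm(ncol(L))) else
        numeric(nrow(block$D))
      eta <- eta_fix + if (length(b)) drop(block$Z %*% b) else 0
      mu <- fam$h(eta)
      y <- switch(fam$family,
        normal    = stats::rnorm(length(mu), mu, sqrt(fam$phi)),
        bernoulli = stats::rbinom(length(mu), 1L, mu),
        binomial  = stats::rbinom(length(mu), fam$size, mu) / fam$size,
        poisson   = stats::rpois(length(mu), mu * fam$size) / fam$size
      )
      tab <- block$meta
      tab$individual <- stats::ave(seq_len(nrow(tab)),
                                   tab$period, tab$subcluster,
                                   FUN = seq_along)
      out[[cl]] <- data.frame(cluster = cl, sequence = s,
                              subcluster = tab$subcluster,
                              period = tab$period,
                              individual = tab$individual,
                              treatment = tab$treatment, y = y)
    }
  }
  do.call(rbind, out)
}

#' @export
simulate.swd_design <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s) swd_simulate(object, seed = s, ...))
}
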