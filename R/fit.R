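#' Maximum-likelihood GLMM fit for simulated stepped-wedge data
#'
#' Internal marginal maximum-likelihood fitter used by the Monte-Carlo
#' validation harness.  Observations are first collapsed to
#' cluster-period(-subcluster) cells (a sufficient reduction for the
#' supported families), then the marginal likelihood -- integrating the
#' cluster-level random effects out of the conditional likelihood -- is
#' maximized over the fixed effects and log random-effect standard
#' deviations (plus the log residual variance for normal outcomes).
#'
#' The integral over each cluster's random effects is evaluated by adaptive
#' Gauss-Hermite quadrature when there is a single random effect per
#' cluster, and by the Laplace approximation (Newton mode-finding) for two;
#' `nAGQ = 1` degenerates to Laplace.  Structures with more than two
#' random-effect columns per cluster are not supported by the internal
#' fitter; an external fitter honouring the same contract can be plugged
#' into [swd_mc_validate()] instead.
#'
#' @param data A data frame as produced by [swd_simulate()] (columns
#'   `cluster`, `period`, `subcluster`, `treatment`, `y`).
#' @param model The generating [swd_model()]; supplies the family, the
#'   fixed-effect structure, and which random components to estimate.
#' @param nAGQ Number of adaptive quadrature nodes for one-dimensional
#'   random effects (default 9; 1 = Laplace).
#' @param start Optional named list with elements `beta`, `log_sd` (and
#'   `log_phi`) overriding the default starting values.
#' @return An object of class `swd_glmm`: `coef` (fixed effects, treatment
#'   last), `sd` (random-effect SDs), `se_treatment`, `loglik`,
#'   `converged`, `boundary`, `vcov` (fixed+variance parameters).
#' @export
swd_fit <- function(data, model, nAGQ = 9, start = NULL) {
  stopifnot(is.data.frame(data), inherits(model, "swd_model"))
  fam <- model$family
  if (!fam$family %in% c("bernoulli", "normal", "poisson")) {
    stop("internal fitter supports bernoulli, poisson, and normal outcomes",
         call. = FALSE)
  }

  cells <- fit_cells(data, model)
  q <- dim(cells$Z)[3]
  if (q > 2L) {
    stop("internal fitter supports at most 2 random-effect columns per ",
         "cluster (got ", q, "); plug an external fitter into ",
         "swd_mc_validate()", call. = FALSE)
  }
  if (q == 0L) {
    stop("no random-effect components in the model; fit with stats::glm",
         call. = FALSE)
  }
  p <- ncol(cells$Xu)
  est_phi <- fam$family == "normal"

  beta0 <- start_beta(cells, fam, start)
  lsd0 <- if (!is.null(start$log_sd)) start$log_sd else
    log(pmax(vapply(cells$sd_init, max, numeric(1)), 0.02))
  th0 <- c(beta0, lsd0)
  if (est_phi) {
    th0 <- c(th0, if (!is.null(start$log_phi)) start$log_phi else
      log(max(stats::var(data$y), 1e-4)))
  }

  negll <- function(th) {
    val <- marginal_negll(th, cells, fam, nAGQ, est_phi)
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::nlminb(th0, negll,
                       control = list(iter.max = 300, eval.max = 600,
                                      rel.tol = 1e-9))
  th <- opt$par
  k <- length(th)
  H <- num_hessian(negll, th)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  lsd <- th[(p + 1):(p + q)]
  se_tr <- if (is.finite(vc[p, p]) && vc[p, p] > 0) sqrt(vc[p, p])
           else NA_real_
  structure(
    list(coef = stats::setNames(th[1:p], colnames(cells$Xu)),
         sd = stats::setNames(exp(lsd), cells$comp),
         dispersion = if (est_phi) unname(exp(th[k])) else fam$phi,
         se_treatment = se_tr,
         loglik = -opt$objective,
         converged = opt$convergence == 0 && is.finite(se_tr) &&
           max(abs(th[1:p])) < 15,
         boundary = any(exp(lsd) < 1e-3),
         vcov = vc, optim = opt),
    class = "swd_glmm"
  )
}

#' @export
print.swd_glmm <- function(x, ...) {
  cat("<swd_glmm> marginal ML fit\n  fixed effects:\n")
  print(round(x$coef, 4))
  cat("  random-effect SDs:", paste(sprintf("%s = %.4g", names(x$sd), x$sd),
                                    collapse = ", "), "\n")
  cat(sprintf("  SE(treatment) = %.4g; converged: %s; boundary: %s\n",
              x$se_treatment, x$converged, x$boundary))
  invisible(x)
}

# Collapse data to cells and precompute per-cluster arrays.
# Returns: ysum, yss, n  (nclus x ncell matrices), Xu (ncell x p, shared
# across clusters except treatment column -> stored per cluster), Z
# (nclus x ncell x q), comp (random component names), sd_init.
fit_cells <- function(data, model) {
  if (!"subcluster" %in% names(data)) data$subcluster <- 1L
  key <- interaction(data$cluster, data$period, data$subcluster, drop = TRUE)
  agg <- data.frame(
    cluster    = as.vector(tapply(data$cluster, key, `[`, 1L)),
    period     = as.vector(tapply(data$period, key, `[`, 1L)),
    subcluster = as.vector(tapply(data$subcluster, key, `[`, 1L)),
    treatment  = as.vector(tapply(data$treatment, key, `[`, 1L)),
    ysum       = as.vector(tapply(data$y, key, sum)),
    yss        = as.vector(tapply(data$y^2, key, sum)),
    n          = as.vector(tapply(data$y, key, length))
  )
  agg <- agg[order(agg$cluster, agg$period, agg$subcluster), ]
  clus <- unique(agg$cluster)
  ncell <- nrow(agg) / length(clus)
  if (ncell != round(ncell)) {
    stop("unbalanced cell structure; the internal fitter expects the same ",
         "cells in every cluster", call. = FALSE)
  }
  T_ <- max(agg$period)

  shape <- function(v) matrix(v, nrow = length(clus), ncol = ncell,
                              byrow = TRUE)
  # columns of the fixed design per cell
  if (!is.null(model$time_effects)) {
    Tm <- matrix(0, nrow(agg), T_ - 1L)
    hit <- agg$period >= 2L
    Tm[cbind(which(hit), agg$period[hit] - 1L)] <- 1
    colnames(Tm) <- paste0("period", 2:T_)
  } else if (!is.null(model$time_slope)) {
    scores <- model$time_scores %||% (seq_len(T_) - 1)
    Tm <- matrix(scores[agg$period], ncol = 1,
                 dimnames = list(NULL, "time"))
  } else {
    Tm <- matrix(0, nrow(agg), 0)
  }
  Xall <- cbind("(Intercept)" = 1, Tm, treatment = agg$treatment)

  comp <- character(0)
  if (!is.null(model$sds$cluster)) comp <- c(comp, "cluster")
  if (!is.null(model$sds$treatment)) comp <- c(comp, "treatment")
  if (!is.null(model$sds$time)) comp <- c(comp, paste0("time", seq_len(T_)))
  if (!is.null(model$sds$subcluster) && max(agg$subcluster) > 1) {
    comp <- c(comp, paste0("sub", seq_len(max(agg$subcluster))))
  }
  q <- length(comp)
  Z <- array(0, c(length(clus), ncell, q))
  for (j in seq_len(q)) {
    zv <- switch(sub("[0-9]+$", "", comp[j]),
      cluster   = rep(1, nrow(agg)),
      treatment = agg$treatment,
      time      = as.numeric(agg$period ==
                               as.integer(sub("^time", "", comp[j]))),
      sub       = as.numeric(agg$subcluster ==
                               as.integer(sub("^sub", "", comp[j])))
    )
    Z[, , j] <- shape(zv)
  }
  sd_init <- lapply(comp, function(cn) {
    nm <- sub("[0-9]+$", "", cn)
    nm <- c(cluster = "cluster", treatment = "treatment", time = "time",
            sub = "subcluster")[[nm]]
    model$sds[[nm]]
  })

  Zk <- lapply(seq_len(q), function(k) Z[, , k])
  out <- list(ysum = shape(agg$ysum), yss = shape(agg$yss),
              n = shape(agg$n),
              Z = Z, Zk = Zk, Zksq = lapply(Zk, function(m) m^2),
              Z12 = if (q == 2L) Zk[[1L]] * Zk[[2L]],
              Xall = Xall, Xu = Xall[seq_len(ncell), , drop = FALSE],
              eta_rows = agg, comp = comp, sd_init = sd_init,
              nclus = length(clus), ncell = ncell,
              warm = new.env(parent = emptyenv()))
  out
}

start_beta <- function(cells, fam, start) {
  if (!is.null(start$beta)) return(start$beta)
  agg <- cells$eta_rows
  X <- cells$Xall
  fit <- switch(fam$family,
    bernoulli = stats::glm.fit(X, cbind(agg$ysum, agg$n - agg$ysum),
                               family = stats::binomial()),
    poisson   = stats::glm.fit(X, agg$ysum / agg$n, weights = agg$n,
                               family = stats::poisson()),
    normal    = stats::lm.wfit(X, agg$ysum / agg$n, w = agg$n)
  )
  co <- fit$coefficients
  co[!is.finite(co)] <- 0
  co
}

# Negative marginal log-likelihood.  th = (beta, log sd_1..q [, log phi]).
marginal_negll <- function(th, cells, fam, nAGQ, est_phi) {
  p <- ncol(cells$Xu)
  q <- length(cells$comp)
  beta <- th[1:p]
  sds <- exp(th[(p + 1):(p + q)])
  phi <- if (est_phi) exp(th[length(th)]) else fam$phi
  eta_fix <- matrix(drop(cells$Xall %*% beta), nrow = cells$nclus,
                    ncol = cells$ncell, byrow = TRUE)
  if (q == 1L && nAGQ > 1L) {
    ll <- ll_agq1(eta_fix, cells, fam, sds, phi, nAGQ)
  } else {
    ll <- ll_laplace(eta_fix, cells, fam, sds, phi)
  }
  -sum(ll)
}

# Conditional cell log-likelihood, residual score, and curvature for the
# supported families; all matrices nclus x ncell.
cell_terms <- function(eta, cells, fam, phi, what = "all") {
  y <- cells$ysum; n <- cells$n
  if (fam$family == "bernoulli") {
    mu <- stats::plogis(eta)
    ll <- y * eta - n * log1pexp(eta)
    r <- y - n * mu
    w <- n * mu * (1 - mu)
  } else if (fam$family == "poisson") {
    mu <- exp(eta)
    ll <- y * eta - n * mu
    r <- y - n * mu
    w <- n * mu
  } else {
    ll <- -(cells$yss - 2 * eta * y + n * eta^2) / (2 * phi) -
      n / 2 * log(2 * pi * phi)
    r <- (y - n * eta) / phi
    w <- n / phi
  }
  list(ll = ll, r = r, w = w)
}

# Newton mode-finding for the penalized objective, vectorized across
# clusters; returns the mode, the penalized objective at the mode, and the
# per-cluster negative Hessian (as columns h11, h22, h12).  Modes are
# warm-started from the previous call (cells$warm), which cuts the inner
# iterations during optimization to one or two.
find_modes <- function(eta_fix, cells, fam, sds, phi, tol = 1e-9,
                       maxit = 60) {
  q <- length(sds)
  J <- cells$nclus; C <- cells$ncell
  Z1 <- cells$Zk[[1L]]; Z1sq <- cells$Zksq[[1L]]
  if (q == 2L) { Z2 <- cells$Zk[[2L]]; Z2sq <- cells$Zksq[[2L]]
                 Z12 <- cells$Z12 }
  dinv <- 1 / sds^2
  b <- cells$warm$b
  if (is.null(b) || nrow(b) != J || ncol(b) != q) b <- matrix(0, J, q)
  obj <- function(b) {
    eta <- eta_fix + b[, 1L] * Z1
    if (q == 2L) eta <- eta + b[, 2L] * Z2
    ct <- cell_terms(eta, cells, fam, phi)
    pen <- dinv[1L] * b[, 1L]^2
    if (q == 2L) pen <- pen + dinv[2L] * b[, 2L]^2
    list(f = .rowSums(ct$ll, J, C) - 0.5 * pen, ct = ct)
  }
  cur <- obj(b)
  for (it in seq_len(maxit)) {
    g1 <- .rowSums(cur$ct$r * Z1, J, C) - b[, 1L] * dinv[1L]
    h11 <- .rowSums(cur$ct$w * Z1sq, J, C) + dinv[1L]
    if (q == 1L) {
      gmax <- max(abs(g1))
      step <- cbind(g1 / h11)
    } else {
      g2 <- .rowSums(cur$ct$r * Z2, J, C) - b[, 2L] * dinv[2L]
      h22 <- .rowSums(cur$ct$w * Z2sq, J, C) + dinv[2L]
      h12 <- .rowSums(cur$ct$w * Z12, J, C)
      det <- h11 * h22 - h12^2
      gmax <- max(abs(g1), abs(g2))
      step <- cbind((h22 * g1 - h12 * g2) / det,
                    (h11 * g2 - h12 * g1) / det)
    }
    if (gmax < tol * (1 + max(abs(cur$f)))) break
    lam <- rep(1, J)
    for (half in 1:20) {
      nxt <- obj(b + step * lam)
      worse <- nxt$f < cur$f - 1e-12
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    b <- b + step * lam
    cur <- obj(b)
  }
  cells$warm$b <- b
  h11 <- .rowSums(cur$ct$w * Z1sq, J, C) + dinv[1L]
  hess <- if (q == 1L) cbind(h11 = h11) else
    cbind(h11 = h11,
          h22 = .rowSums(cur$ct$w * Z2sq, J, C) + dinv[2L],
          h12 = .rowSums(cur$ct$w * Z12, J, C))
  list(b = b, f = cur$f, hess = hess)
}

# Per-cluster Laplace-approximate marginal log-likelihood.
ll_laplace <- function(eta_fix, cells, fam, sds, phi) {
  m <- find_modes(eta_fix, cells, fam, sds, phi)
  q <- length(sds)
  logdetD <- 2 * sum(log(sds))
  logdetH <- if (q == 1L) log(m$hess[, "h11"]) else
    log(m$hess[, "h11"] * m$hess[, "h22"] - m$hess[, "h12"]^2)
  m$f - 0.5 * logdetD - 0.5 * logdetH
}

# Adaptive Gauss-Hermite marginal log-likelihood for q = 1.
ll_agq1 <- function(eta_fix, cells, fam, sds, phi, nAGQ) {
  gh <- gh_nodes(nAGQ)
  m <- find_modes(eta_fix, cells, fam, sds, phi)
  sigma <- 1 / sqrt(m$hess[, "h11"])
  dinv <- 1 / sds[1]^2
  J <- cells$nclus
  acc <- matrix(NA_real_, J, nAGQ)
  for (i in seq_len(nAGQ)) {
    bi <- m$b[, 1] + sqrt(2) * sigma * gh$x[i]
    eta <- eta_fix + bi * cells$Zk[[1L]]
    ct <- cell_terms(eta, cells, fam, phi)
    acc[, i] <- rowSums(ct$ll) - 0.5 * bi^2 * dinv +
      gh$x[i]^2 + log(gh$w[i])
  }
  mx <- apply(acc, 1, max)
  mx + log(rowSums(exp(acc - mx))) + log(sqrt(2) * sigma) -
    0.5 * log(2 * pi * sds[1]^2)
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  pos <- x > 0
  out[pos] <- x[pos] + log1p(exp(-x[pos]))
  out[!pos] <- log1p(exp(x[!pos]))
  out
}

gh_cache <- new.env(parent = emptyenv())
gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(gh_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    gh_cache[[key]] <- list(x = gh$x, w = gh$w)
  }
  gh_cache[[key]]
}

# Central-difference Hessian of a scalar function.
num_hessian <- function(f, x, h = NULL) {
  k <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-4
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xm <- x
        xp[i] <- x[i] + h[i]; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpm <- x; xmp <- x; xmm <- x
        xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
        xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
        xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        H[i, j] <- H[j, i] <-
          (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}
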