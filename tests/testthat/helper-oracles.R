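# Independent oracles used by the tests.  These deliberately take the
# brute-force route -- explicit stacking of all clusters and dense matrix
# inversion -- so they share no code path with the package internals.

# Generalized-least-squares covariance of the fixed effects: stack the full
# individual-level X and block-diagonal V = W + Z D Z' over every cluster,
# then invert X' V^{-1} X directly.
gls_vcov_oracle <- function(layout, model, hypothesis = "alternative") {
  fam <- model$family
  Xs <- list(); Vs <- list()
  i <- 0L
  for (s in seq_len(layout$n_sequences)) {
    block <- build_cluster_block(layout, model, s, aggregate = FALSE)
    eta <- linear_predictor(block, model, hypothesis)
    mu <- fam$h(eta)
    w <- fam$phi * fam$a * fam$v(mu) * fam$gprime(mu)^2
    V <- diag(w) + block$Z %*% block$D %*% t(block$Z)
    for (k in seq_len(layout$clusters_per_sequence[s])) {
      i <- i + 1L
      Xs[[i]] <- block$X
      Vs[[i]] <- V
    }
  }
  n <- sum(vapply(Xs, nrow, integer(1)))
  p <- ncol(Xs[[1L]])
  X <- do.call(rbind, Xs)
  V <- matrix(0, n, n)
  at <- 0L
  for (k in seq_along(Vs)) {
    idx <- at + seq_len(nrow(Vs[[k]]))
    V[idx, idx] <- Vs[[k]]
    at <- at + nrow(Vs[[k]])
  }
  solve(t(X) %*% solve(V) %*% X)
}

# Fisher information of plain (no random effects) GLM evaluated at beta:
# X' diag(mu(1-mu)/phi-ish weights) X accumulated over all clusters.
glm_info_oracle <- function(layout, model, hypothesis = "alternative") {
  fam <- model$family
  info <- NULL
  for (s in seq_len(layout$n_sequences)) {
    block <- build_cluster_block(layout, model, s, aggregate = FALSE)
    eta <- linear_predictor(block, model, hypothesis)
    mu <- fam$h(eta)
    w <- 1 / (fam$phi * fam$a * fam$v(mu) * fam$gprime(mu)^2)
    contrib <- layout$clusters_per_sequence[s] *
      t(block$X) %*% (block$X * w)
    info <- if (is.null(info)) contrib else info + contrib
  }
  info
}

# Closed-form profile fit of a normal random-intercept mixed model on one
# dataset: GLS at known variance components, maximizing over them on a grid
# is avoided by direct optimization of the exact normal marginal likelihood.
lmm_ml_oracle <- function(data, formula_X) {
  X <- stats::model.matrix(formula_X, data)
  y <- data$y
  clus <- data$cluster
  negll <- function(th) {
    s2 <- exp(th[1L]); tau2 <- exp(th[2L])
    ll <- 0
    beta_acc <- matrix(0, ncol(X), ncol(X)); rhs <- numeric(ncol(X))
    for (j in unique(clus)) {
      idx <- clus == j
      Vj <- diag(s2, sum(idx)) + tau2
      Vinv <- solve(Vj)
      beta_acc <- beta_acc + t(X[idx, ]) %*% Vinv %*% X[idx, ]
      rhs <- rhs + t(X[idx, ]) %*% Vinv %*% y[idx]
    }
    beta <- solve(beta_acc, rhs)
    for (j in unique(clus)) {
      idx <- clus == j
      Vj <- diag(s2, sum(idx)) + tau2
      r <- y[idx] - X[idx, ] %*% beta
      ll <- ll - 0.5 * (determinant(Vj)$modulus +
                          t(r) %*% solve(Vj, r) +
                          sum(idx) * log(2 * pi))
    }
    -as.numeric(ll)
  }
  opt <- stats::optim(c(log(stats::var(y)), log(stats::var(y) / 10)), negll,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  s2 <- exp(opt$par[1L]); tau2 <- exp(opt$par[2L])
  beta_acc <- matrix(0, ncol(X), ncol(X)); rhs <- numeric(ncol(X))
  for (j in unique(clus)) {
    idx <- clus == j
    Vinv <- solve(diag(s2, sum(idx)) + tau2)
    beta_acc <- beta_acc + t(X[idx, ]) %*% Vinv %*% X[idx, ]
    rhs <- rhs + t(X[idx, ]) %*% Vinv %*% y[idx]
  }
  list(beta = drop(solve(beta_acc, rhs)), sigma2 = s2, tau2 = tau2)
}

rel_err <- function(a, b) {
  norm(as.matrix(a - b), "F") / max(norm(as.matrix(b), "F"),
                                    .Machine$double.eps)
}
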