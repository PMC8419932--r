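#' Working weights at random effects zero
#'
#' Diagonal entries of the working covariance `W0`,
#' \eqn{w_i = \phi\, a_i\, v(\mu_i)\, g'(\mu_i)^2} evaluated at
#' \eqn{\mu_i = h(\eta_i)} with the random effects plugged in at zero.  For
#' bernoulli/logit this is \eqn{1 / (\mu_i (1 - \mu_i))}; for
#' normal/identity it is the constant \eqn{\sigma^2}.
#'
#' @param family An [swd_family()] object or family name.
#' @param eta Linear predictor values.
#' @return Vector of working variances, one per observation.
#' @export
w0_weights <- function(family, eta) {
  fam <- as_swd_family(family)
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor: ",
         paste(utils::head(eta[!is.finite(eta)], 3L), collapse = ", "),
         call. = FALSE)
  }
  mu <- fam$h(eta)
  bad <- switch(fam$family,
    normal = rep(FALSE, length(mu)),
    bernoulli = , binomial = mu <= 0 | mu >= 1,
    poisson = mu <= 0
  )
  if (any(bad)) {
    stop("mean at the boundary of its range after inverse link; offending ",
         "eta: ", paste(utils::head(eta[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  fam$phi * fam$a * fam$v(mu) * fam$gprime(mu)^2
}

#' Working covariance of one cluster
#'
#' `V = diag(weights) + Z D Z'`, the approximate covariance of the working
#' response for a single cluster.
#'
#' @param weights Positive working variances (diagonal of `W`).
#' @param Z Random-effect design matrix (rows match `weights`).
#' @param D Random-effect covariance (PSD, columns match `Z`).
#' @return A symmetric matrix.
#' @export
cluster_V <- function(weights, Z, D) {
  n <- length(weights)
  if (nrow(Z) != n) stop("Z must have one row per weight", call. = FALSE)
  if (ncol(Z) != nrow(D)) {
    stop("Z columns must correspond 1:1 to D rows", call. = FALSE)
  }
  check_psd(D, "D")
  diag(weights, n) + Z %*% D %*% t(Z)
}

# Factor a PSD matrix as L L', dropping null directions, so that the
# Woodbury identity applies even when D is singular (zero-variance
# components).
psd_factor <- function(D, tol = 1e-12) {
  if (nrow(D) == 0L) return(matrix(0, 0, 0))
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  if (!any(keep)) return(matrix(0, nrow(D), 0))
  e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
}

#' Invert the working covariance of a cluster
#'
#' Computes `solve(diag(weights) + Z D Z')`.  The Woodbury path factors
#' `D = L L'` and inverts only the (at most `q x q`) core
#' `I + L' Z' W^{-1} Z L`, which is exact also for singular `D`; the direct
#' path forms and inverts the full matrix.  `"auto"` uses Woodbury whenever
#' the random-effect dimension is below the number of rows.
#'
#' @inheritParams cluster_V
#' @param method `"auto"`, `"direct"`, or `"woodbury"`.
#' @return The inverse of [cluster_V()], with attribute `"path"` recording
#'   the route taken.
#' @export
invert_V <- function(weights, Z, D, method = c("auto", "direct", "woodbury")) {
  method <- match.arg(method)
  if (any(weights <= 0) || any(!is.finite(weights))) {
    stop("singular working covariance: non-positive weight at row(s) ",
         paste(utils::head(which(weights <= 0 | !is.finite(weights)), 3L),
               collapse = ", "), call. = FALSE)
  }
  n <- length(weights)
  if (method == "auto") {
    method <- if (ncol(Z) < n) "woodbury" else "direct"
  }
  if (method == "direct") {
    out <- solve(cluster_V(weights, Z, D))
  } else {
    L <- psd_factor(D)
    winv <- 1 / weights
    if (ncol(L) == 0L) {
      out <- diag(winv, n)
    } else {
      U <- Z %*% L                       # n x r
      WU <- U * winv                     # W^{-1} U
      core <- diag(ncol(L)) + crossprod(U, WU)
      out <- diag(winv, n) - WU %*% solve(core, t(WU))
    }
  }
  attr(out, "path") <- method
  out
}

#' Collapse exchangeable rows of a cluster block
#'
#' Rows sharing the same subcluster-period cell have identical design rows
#' and linear predictor, so `c` such rows can be collapsed to one row whose
#' prior weight is multiplied by `c` (the working variance entry becomes
#' `w / c`).  The accumulated information `X' V^{-1} X` is unchanged; this
#' is an exact reduction, not an approximation.
#'
#' @param block An `swd_cluster_block` (typically built with
#'   `aggregate = FALSE`).
#' @return The block with one row per cell and updated `count`.
#' @export
aggregate_cluster_block <- function(block) {
  stopifnot(inherits(block, "swd_cluster_block"))
  key <- paste(block$meta$period, block$meta$subcluster, sep = ":")
  first <- !duplicated(key)
  for (cell in unique(key)) {
    rows <- which(key == cell)
    same <- function(M) all(abs(sweep(M[rows, , drop = FALSE], 2,
                                      M[rows[1L], ])) == 0)
    if (!same(block$X) || !same(block$Z)) {
      stop("refusing to aggregate: rows within cell ", cell,
           " have differing design rows", call. = FALSE)
    }
  }
  counts <- as.vector(tapply(block$count, key, sum))[match(key[first],
                                                           unique(key))]
  block$X <- block$X[first, , drop = FALSE]
  block$Z <- block$Z[first, , drop = FALSE]
  block$meta <- block$meta[first, setdiff(names(block$meta), "individual"),
                           drop = FALSE]
  rownames(block$meta) <- NULL
  block$count <- as.integer(counts)
  block
}

# Information contribution X' V^{-1} X of one block without forming the
# n x n inverse: with V = W + Z D Z', D = L L',
#   X' V^{-1} X = X' W^{-1} X - (X' W^{-1} U) M^{-1} (U' W^{-1} X),
# where U = Z L and M = I + U' W^{-1} U.
block_information <- function(block, weights) {
  w <- weights / block$count          # aggregated working variances
  winv <- 1 / w
  X <- block$X
  XtWX <- crossprod(X, X * winv)
  L <- psd_factor(block$D)
  if (ncol(L) == 0L) return(XtWX)
  U <- block$Z %*% L
  WU <- U * winv
  M <- diag(ncol(L)) + crossprod(U, WU)
  B <- crossprod(WU, X)               # r x p
  XtWX - crossprod(B, solve(M, B))
}

#' Laplace-approximation covariance of the estimated coefficients
#'
#' Accumulates the per-cluster information `X_j' V_j^{-1} X_j` over all
#' clusters (computing one representative block per sequence and scaling by
#' the number of identical clusters) and inverts it, under both the
#' alternative and the null hypothesis.  The working weights are evaluated
#' at random effects zero.  Under the null, the linear predictor (and hence
#' the weights, for non-identity links) is recomputed with the intervention
#' effect set to zero while all other coefficients and variance components
#' keep their values; set `null_variance = "alternative"` to reuse the
#' alternative-hypothesis covariance for both.
#'
#' @param layout An [swd_layout()] (or an `swd_design`, with `model` absent).
#' @param model An [swd_model()].
#' @param null_variance `"recompute"` (default) or `"alternative"`.
#' @return An object of class `swd_variance` with elements `var_p_null`,
#'   `var_p_alt`, `vcov_null`, `vcov_alt`, `coef_names`, and `diagnostics`
#'   (inversion path, block dimensions, information condition number).
#' @export
swd_variance <- function(layout, model,
                         null_variance = c("recompute", "alternative")) {
  d <- resolve_design(layout, model)
  layout <- d$layout; model <- d$model
  null_variance <- match.arg(null_variance)

  info_for <- function(hypothesis) {
    info <- NULL
    dims <- list()
    for (s in seq_len(layout$n_sequences)) {
      block <- build_cluster_block(layout, model, s)
      eta <- linear_predictor(block, model, hypothesis)
      w <- w0_weights(model$family, eta)
      contrib <- block$replicates * block_information(block, w)
      info <- if (is.null(info)) contrib else info + contrib
      dims[[s]] <- c(rows = nrow(block$X), q = ncol(block$Z),
                     replicates = block$replicates)
    }
    list(info = info, dims = dims)
  }

  alt <- info_for("alternative")
  vcov_alt <- invert_information(alt$info)
  if (null_variance == "recompute") {
    nul <- info_for("null")
    vcov_null <- invert_information(nul$info)
  } else {
    vcov_null <- vcov_alt
  }
  p <- ncol(vcov_alt)
  kappa_info <- kappa(alt$info, exact = TRUE)
  structure(
    list(var_p_null = vcov_null[p, p], var_p_alt = vcov_alt[p, p],
         vcov_null = vcov_null, vcov_alt = vcov_alt,
         coef_names = colnames(alt$info),
         null_variance = null_variance,
         diagnostics = list(
           path = "aggregated+woodbury",
           blocks = alt$dims,
           information_condition = kappa_info,
           ill_conditioned = kappa_info > 1e10
         )),
    class = "swd_variance"
  )
}

invert_information <- function(info) {
  ch <- tryCatch(chol(info), error = function(e) NULL)
  if (is.null(ch)) {
    qrd <- qr(info)
    stop("intervention effect inestimable under this design: information ",
         "matrix is singular (rank ", qrd$rank, " of ", ncol(info), ")",
         call. = FALSE)
  }
  out <- chol2inv(ch)
  dimnames(out) <- dimnames(info)
  out
}

resolve_design <- function(layout, model) {
  if (inherits(layout, "swd_design")) {
    return(list(layout = layout$layout, model = layout$model))
  }
  stopifnot(inherits(layout, "swd_layout"), inherits(model, "swd_model"))
  list(layout = layout, model = model)
}

#' @export
print.swd_variance <- function(x, ...) {
  cat("<swd_variance> Laplace-approximation covariance (random effects at 0)\n")
  cat(sprintf("  Var(beta_p) under alternative: %.6g\n", x$var_p_alt))
  cat(sprintf("  Var(beta_p) under null:        %.6g (%s)\n",
              x$var_p_null, x$null_variance))
  invisible(x)
}
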