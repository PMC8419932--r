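#' Outcome family and link registry
#'
#' Constructs the family/link specification used throughout the package: the
#' distribution of the outcome given the random effects, the link between the
#' conditional mean and the linear predictor, the variance function
#' \eqn{v(\mu)}, the dispersion \eqn{\phi}, and the prior-weight rule
#' \eqn{a_i}.  Only the canonical pairs are supported: normal/identity,
#' bernoulli/logit, poisson/log, and binomial/logit (aggregated proportions on
#' \eqn{m_i} trials).
#'
#' The working weight that enters the approximate covariance of the estimated
#' coefficients is \eqn{w_i = \phi\, a_i\, v(\mu_i)\, g'(\mu_i)^2}; see
#' [w0_weights()].
#'
#' @param family One of `"normal"` (alias `"gaussian"`), `"bernoulli"`,
#'   `"poisson"`, `"binomial"`.
#' @param link Link name; each family has exactly one supported link
#'   (identity, logit, log, logit respectively), filled in automatically.
#' @param dispersion Dispersion \eqn{\phi}: the residual variance
#'   \eqn{\sigma^2} for the normal family, fixed at 1 otherwise.
#' @param size Denominator \eqn{m_i} for binomial proportions or number of
#'   intervals for poisson counts (scalar, default 1).  Enters the prior
#'   weight \eqn{a_i = 1/m_i}.
#' @return An object of class `swd_family`: a list with elements `family`,
#'   `link`, `phi`, `size`, `a` (prior weight), and the functions
#'   `v(mu)`, `g(mu)`, `gprime(mu)`, `h(eta)`.
#' @examples
#' fam <- swd_family("bernoulli")
#' fam$v(0.5)          # 0.25
#' fam$g(0.12)         # about -2.0
#' @export
swd_family <- function(family = c("normal", "gaussian", "bernoulli",
                                  "poisson", "binomial"),
                       link = NULL, dispersion = NULL, size = 1) {
  family <- match.arg(family)
  if (family == "gaussian") family <- "normal"
  canonical <- c(normal = "identity", bernoulli = "logit",
                 poisson = "log", binomial = "logit")
  if (is.null(link)) link <- canonical[[family]]
  if (!identical(link, canonical[[family]])) {
    stop("unsupported family/link pair: ", family, "/", link,
         " (supported: ", family, "/", canonical[[family]], ")", call. = FALSE)
  }
  if (is.null(dispersion)) dispersion <- 1
  if (family != "normal" && dispersion != 1) {
    stop("dispersion is fixed at 1 for the ", family, " family", call. = FALSE)
  }
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0) {
    stop("dispersion must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(size) || length(size) != 1L || size < 1) {
    stop("size (m) must be a single number >= 1", call. = FALSE)
  }
  if (family %in% c("normal", "bernoulli") && size != 1) {
    stop("size (m) applies only to poisson/binomial outcomes", call. = FALSE)
  }
  structure(
    list(
      family = family, link = link, phi = dispersion, size = size,
      a = if (family %in% c("poisson", "binomial")) 1 / size else 1,
      v = switch(family,
        normal    = function(mu) rep_len(1, length(mu)),
        bernoulli = ,
        binomial  = function(mu) mu * (1 - mu),
        poisson   = function(mu) mu
      ),
      g = switch(link,
        identity = function(mu) mu,
        logit    = function(mu) log(mu / (1 - mu)),
        log      = function(mu) log(mu)
      ),
      gprime = switch(link,
        identity = function(mu) rep_len(1, length(mu)),
        logit    = function(mu) 1 / (mu * (1 - mu)),
        log      = function(mu) 1 / mu
      ),
      h = switch(link,
        identity = function(eta) eta,
        logit    = function(eta) stats::plogis(eta),
        log      = function(eta) exp(eta)
      )
    ),
    class = "swd_family"
  )
}

mean_domain_check <- function(fam, mu) {
  bad <- switch(fam$family,
    normal    = !is.finite(mu),
    bernoulli = ,
    binomial  = !is.finite(mu) | mu <= 0 | mu >= 1,
    poisson   = !is.finite(mu) | mu <= 0
  )
  if (any(bad)) {
    stop("mean value outside the valid range for the ", fam$family,
         " family: ", paste(utils::head(mu[bad], 3L), collapse = ", "),
         call. = FALSE)
  }
  invisible(mu)
}

#' Variance function v(mu)
#'
#' @param family An [swd_family()] object or a family name.
#' @param mu Vector of conditional means, inside the family's valid range.
#' @return `v(mu)`: 1 for normal, `mu * (1 - mu)` for bernoulli/binomial,
#'   `mu` for poisson.
#' @export
variance_function <- function(family, mu) {
  fam <- as_swd_family(family)
  mean_domain_check(fam, mu)
  fam$v(mu)
}

#' Link function, its derivative, and the inverse link
#'
#' `link_value()` returns \eqn{g(\mu)}, `link_deriv()` returns
#' \eqn{g'(\mu)}, and `inv_link()` returns \eqn{h(\eta) = g^{-1}(\eta)}.
#'
#' @param family An [swd_family()] object or a family name.
#' @param mu Conditional mean(s).
#' @param eta Linear predictor value(s).
#' @export
link_value <- function(family, mu) {
  fam <- as_swd_family(family)
  mean_domain_check(fam, mu)
  fam$g(mu)
}

#' @rdname link_value
#' @export
link_deriv <- function(family, mu) {
  fam <- as_swd_family(family)
  mean_domain_check(fam, mu)
  fam$gprime(mu)
}

#' @rdname link_value
#' @export
inv_link <- function(family, eta) {
  fam <- as_swd_family(family)
  if (any(!is.finite(eta))) stop("non-finite linear predictor", call. = FALSE)
  fam$h(eta)
}

as_swd_family <- function(x) {
  if (inherits(x, "swd_family")) x else swd_family(x)
}

#' @export
print.swd_family <- function(x, ...) {
  cat(sprintf("<swd_family> %s outcome, %s link, dispersion %g",
              x$family, x$link, x$phi))
  if (x$size != 1) cat(sprintf(", m = %g", x$size))
  cat("\n")
  invisible(x)
}
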