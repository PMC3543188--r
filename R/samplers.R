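#' Draw a variance from its flat-prior full conditional
#'
#' Under an unbounded flat prior on a variance component whose `k` effects
#' contribute a scaled sum of squares `ssq`, the full conditional is
#' inverse-gamma with shape `k/2 - 1` and scale `ssq/2`, i.e.
#' `sigma2 = ssq / chisq(k - 2)`.  Propriety requires `k >= 3`; for smaller
#' components use the proper scaled-inverse-chi-square prior via `nu`, `s2`
#' (full conditional `(ssq + nu*s2) / chisq(k + nu)`).
#'
#' @param ssq sum of squares of the effects (must be positive).
#' @param k number of effects contributing to `ssq`.
#' @param n number of draws.
#' @param nu,s2 degrees of freedom and scale of an optional proper
#'   scaled-inverse-chi-square prior; `nu = 0` (default) is the flat prior.
#' @return numeric vector of `n` positive variance draws.
#' @export
sample_variance_flat <- function(ssq, k, n = 1L, nu = 0, s2 = 0) {
  if (!is.finite(ssq) || ssq <= 0) stop("ssq must be a positive finite scalar")
  if (nu > 0) return((ssq + nu * s2) / rchisq(n, df = k + nu))
  if (k < 3) {
    stop("flat-prior variance update needs k >= 3 effects (k = ", k,
         "); configure a proper scaled-inverse-chi-square prior (nu, s2) ",
         "for this component instead")
  }
  ssq / rchisq(n, df = k - 2)
}

#' Single-site Gibbs draw for one regression coefficient
#'
#' Full conditional of a coefficient with a `N(0, prior_var)` prior given the
#' partial residual (the residual with this coefficient's contribution added
#' back): `N(m, v)` with `v = sigma_e2 / (x'x + sigma_e2 / prior_var)` and
#' `m = v * x'r / sigma_e2`.  As `prior_var -> Inf` this tends to the
#' ordinary least-squares draw (the flat-prior "fixed effect" update).
#'
#' @param x covariate column.
#' @param partial_residual residual excluding this coefficient's current
#'   contribution.
#' @param sigma_e2 residual variance.
#' @param prior_var prior variance of the coefficient; `Inf` for flat.
#' @return one draw (numeric scalar) with attributes `mean` and `var`.
#' @export
sample_effect <- function(x, partial_residual, sigma_e2, prior_var) {
  if (!is.infinite(prior_var) && prior_var <= 0) {
    stop("prior_var must be positive (or Inf for a flat prior)")
  }
  xtx <- sum(x * x)
  v <- sigma_e2 / (xtx + if (is.infinite(prior_var)) 0 else sigma_e2 / prior_var)
  m <- v * sum(x * partial_residual) / sigma_e2
  structure(rnorm(1L, m, sqrt(v)), mean = m, var = v)
}

#' Gibbs update of a mixture-inclusion indicator
#'
#' For a coefficient with the two-component normal-mixture (spike-and-slab)
#' prior `gamma*N(0, tau1sq) + (1-gamma)*N(0, tau0sq)` and
#' `gamma ~ Bern(pi)`, the full conditional of `gamma` is Bernoulli with
#' odds `pi * phi(coef; 0, tau1sq) / ((1 - pi) * phi(coef; 0, tau0sq))`,
#' computed in log space for numerical stability.
#'
#' @param coef current coefficient value.
#' @param tau1sq,tau0sq slab ("large") and spike ("small") variances;
#'   `tau1sq > tau0sq` required.
#' @param pi prior inclusion probability, in (0, 1]; 1 collapses the prior
#'   to the slab alone.
#' @return 0/1 draw with attribute `prob` (the conditional P(gamma = 1)).
#' @export
update_mixture_indicator <- function(coef, tau1sq, tau0sq, pi) {
  if (!is.finite(coef)) stop("coef must be finite")
  stopifnot(tau1sq > tau0sq, pi > 0, pi <= 1)
  lo <- log(pi) - log1p(-pi) +
    dnorm(coef, 0, sqrt(tau1sq), log = TRUE) -
    dnorm(coef, 0, sqrt(tau0sq), log = TRUE)
  p1 <- 1 / (1 + exp(-lo))
  structure(as.integer(runif(1L) < p1), prob = p1)
}
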