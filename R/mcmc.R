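#' Uniform prior bounds for the spatial decay parameter
#'
#' The decay rate of the exponential correlation gets a Uniform prior whose
#' bounds make the correlation equal `rho` at the maximum and minimum
#' observed inter-site distances: `theta_lo = -log(rho)/d_max`,
#' `theta_hi = -log(rho)/d_min`.
#'
#' @param d_min,d_max minimum and maximum pairwise distances (m).
#' @param rho target correlation at those distances (default 0.05).
#' @return Named numeric vector `c(theta_lo, theta_hi)`.
#' @export
theta_prior_bounds <- function(d_min, d_max, rho = 0.05) {
  if (!(d_min > 0 && d_max > d_min)) {
    stop("need 0 < d_min < d_max")
  }
  if (!(rho > 0 && rho < 1)) stop("need 0 < rho < 1")
  c(theta_lo = -log(rho) / d_max, theta_hi = -log(rho) / d_min)
}

#' Exponential-decay spatial correlation matrix
#'
#' `Phi_ij = exp(-(theta * d_ij)^delta)`; `delta = 1` gives the standard
#' exponential model, which is positive definite for any point layout.
#'
#' @param d distance matrix (a `distance_matrix` object or plain matrix).
#' @param theta decay rate per metre (> 0).
#' @param delta smoothing exponent (default 1).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
exp_correlation <- function(d, theta, delta = 1) {
  if (inherits(d, "distance_matrix")) d <- d$d
  stopifnot(theta > 0, delta > 0)
  exp(-(theta * d)^delta)
}

#' Prior specification for the flux models
#'
#' Diffuse Normal(0, 1e6) priors on all regression coefficients; uniform
#' priors on the standard deviations: residual `sigma ~ U(0, sigma_max)`
#' (default 5), ICAR conditional SD `sigma_u ~ U(0, 10)`, Gaussian-process
#' SD `sigma_s ~ U(0, 10)`; decay `theta ~ U(theta_lo, theta_hi)` from
#' [theta_prior_bounds()].
#'
#' @param beta_var prior variance of each coefficient (default 1e6).
#' @param sigma_max upper bound of the residual-SD prior (default 5).
#' @param sigma_u_max upper bound of the ICAR conditional SD (default 10).
#' @param sigma_s_max upper bound of the GP SD (default 10).
#' @param theta_bounds length-2 vector `(theta_lo, theta_hi)`; required for
#'   the geostatistical model.
#' @return A list of class `flux_priors`.
#' @export
flux_priors <- function(beta_var = 1e6, sigma_max = 5, sigma_u_max = 10,
                        sigma_s_max = 10, theta_bounds = NULL) {
  if (!is.null(theta_bounds)) {
    stopifnot(length(theta_bounds) == 2, theta_bounds[1] > 0,
              theta_bounds[1] < theta_bounds[2])
  }
  structure(list(beta_var = beta_var, sigma_max = sigma_max,
                 sigma_u_max = sigma_u_max, sigma_s_max = sigma_s_max,
                 theta_bounds = theta_bounds),
            class = "flux_priors")
}

#' MCMC run configuration
#'
#' @param n_iter total iterations (default 150000, the full production run).
#' @param burn_in discarded initial iterations (default 50000).
#' @param thin keep every `thin`-th post-burn-in draw (default 10).
#' @param seed RNG seed for the chain.
#' @param theta_scale initial random-walk SD for the decay parameter.
#' @param adapt_window iterations between proposal-scale adaptations during
#'   burn-in (adaptation is frozen afterwards to preserve detailed balance).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 150000L, burn_in = 50000L, thin = 10L,
                        seed = 1L, theta_scale = 0.5, adapt_window = 50L) {
  stopifnot(burn_in < n_iter, thin >= 1, theta_scale > 0, adapt_window >= 10)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 theta_scale = theta_scale,
                 adapt_window = as.integer(adapt_window)),
            class = "mcmc_config")
}

# Slice sampler for a scalar with bounded support (lo, hi): shrinkage from
# the full support interval, valid because the support is the initial
# interval.  logf need not be normalised.
slice_bounded <- function(x0, logf, lo, hi, max_steps = 100L) {
  ly <- logf(x0) - stats::rexp(1)
  l <- lo; r <- hi
  for (k in seq_len(max_steps)) {
    x1 <- stats::runif(1, l, r)
    if (logf(x1) >= ly) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
    if (r - l < 1e-300) break
  }
  x0
}

#' Gaussian deviance of a parameter state
#'
#' `D = -2 sum log Normal(y_ir | mu_ir, sigma2)` with `mu` including the
#' site spatial effect when the model has one (the deviance is conditional
#' on the latent effects, the random-effects focus conventional for DIC in
#' these hierarchical models).
#'
#' @param y observed log-flux vector (or matrix).
#' @param mu fitted means, same shape as `y`.
#' @param sigma2 residual variance.
#' @return Scalar deviance.
#' @export
gaussian_deviance <- function(y, mu, sigma2) {
  -2 * sum(stats::dnorm(as.vector(y), as.vector(mu), sqrt(sigma2),
                        log = TRUE))
}

# Full conditional of beta given the partial residual target t = y - effect
# and sigma2: Normal with precision X'X/sigma2 + I/beta_var.  Returns the
# mean and a draw. Exposed for closed-form conditional tests.
beta_full_conditional <- function(xtx, xty_fun, target, sigma2, beta_var,
                                  draw = TRUE) {
  p <- ncol(xtx)
  prec <- xtx / sigma2 + diag(1 / beta_var, p)
  ch <- chol(prec)
  b <- xty_fun(target) / sigma2
  mean <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  if (!draw) return(list(mean = drop(mean)))
  beta <- mean + backsolve(ch, stats::rnorm(p))
  list(mean = drop(mean), draw = drop(beta))
}

# Full conditional of the GP site effects s: precision
# Phi^{-1}/sigma_s2 + (M/sigma2) I, linear term r_site/sigma2 where r_site
# are per-site residual sums.  Exposed for conjugate-normal oracle tests.
gp_effect_conditional <- function(phi_inv, sigma_s2, m, sigma2, r_site,
                                  draw = TRUE) {
  q <- length(r_site)
  prec <- phi_inv / sigma_s2 + diag(m / sigma2, q)
  ch <- chol(prec)
  mean <- backsolve(ch, backsolve(ch, r_site / sigma2, transpose = TRUE))
  if (!draw) return(list(mean = drop(mean)))
  s <- mean + backsolve(ch, stats::rnorm(q))
  list(mean = drop(mean), draw = drop(s))
}

# Single-site ICAR full conditional for u_i: prior mean is the weighted
# neighbour average with precision w_i+/sigma_u2, blended with a Gaussian
# data term of precision `data_prec` and mean `data_mean`. With binary
# weights and no data term the mean reduces to the arithmetic neighbour
# mean.
icar_site_conditional <- function(i, u, w, sigma_u2, data_prec = 0,
                                  data_mean = 0) {
  wi <- sum(w[i, ])
  prior_mean <- sum(w[i, ] * u) / wi
  prior_prec <- wi / sigma_u2
  prec <- prior_prec + data_prec
  list(mean = (prior_prec * prior_mean + data_prec * data_mean) / prec,
       var = 1 / prec)
}

# Greedy graph colouring of the adjacency matrix: sites in one colour class
# are mutually non-adjacent, so their single-site Gibbs updates can be
# executed together without changing the conditionals.
colour_classes <- function(w) {
  q <- nrow(w)
  colour <- integer(q)
  for (i in order(-rowSums(w))) {
    used <- colour[which(w[i, ] == 1)]
    colour[i] <- min(setdiff(seq_len(q), used))
  }
  split(seq_len(q), colour)
}
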