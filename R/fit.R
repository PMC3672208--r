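# Shared fitting scaffold: design matrix, response, per-site bookkeeping,
# and the exact-singularity guard.  The sand+silt+clay+intercept identity
# (texture sums to ~100) is tolerated — the ridge-like Normal prior keeps
# the posterior proper, mirroring how vague-prior Bayesian fits handle it —
# but any *other* exact linear dependence is an error.
prepare_fit <- function(data, priors) {
  x <- model_matrix(data)
  y <- response_vector(data)
  p <- ncol(x)
  qr_full <- qr(x)
  if (qr_full$rank < p) {
    defect <- p - qr_full$rank
    tex <- c("sand", "silt", "clay")
    rank_wo <- qr(x[, setdiff(colnames(x), "clay"), drop = FALSE])$rank
    texture_identity <- defect == 1L && rank_wo == p - 1L
    if (!texture_identity) {
      bad <- colnames(x)[qr_full$pivot[(qr_full$rank + 1L):p]]
      stop("design matrix is exactly singular; collinear column(s): ",
           paste(bad, collapse = ", "))
    }
  }
  list(x = x, y = y, n = length(y), p = p, q = data$Q, m = data$M,
       xtx = crossprod(x),
       xty_fun = function(t) drop(crossprod(x, t)),
       site_of = site_index(data))
}

# per-site residual sums for balanced replicates (rows ordered site-major)
site_resid_sums <- function(resid, m, q) {
  .colSums(matrix(resid, nrow = m, ncol = q), m, q)
}

new_posterior_samples <- function(model, beta, sigma2, deviance, config,
                                  priors, q, m, effect = NULL,
                                  sigma_s2 = NULL, theta = NULL,
                                  sigma_u2 = NULL, accept_theta = NA_real_) {
  structure(list(model = model, beta = beta, sigma2 = sigma2,
                 effect = effect, sigma_s2 = sigma_s2, theta = theta,
                 sigma_u2 = sigma_u2, deviance = deviance,
                 accept_theta = accept_theta, config = config,
                 priors = priors, Q = q, M = m,
                 n_kept = length(sigma2)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %s model, %d retained draws\n",
              x$model, x$n_kept))
  cat(sprintf("  mean deviance %.2f, mean sigma2 %.3f\n",
              mean(x$deviance), mean(x$sigma2)))
  if (!is.na(x$accept_theta)) {
    cat(sprintf("  theta acceptance rate %.2f\n", x$accept_theta))
  }
  invisible(x)
}

keep_index <- function(config) {
  iters <- seq_len(config$n_iter)
  kept <- iters > config$burn_in &
    (iters - config$burn_in) %% config$thin == 0
  which(kept)
}

#' Fit the independent-error Bayesian regression
#'
#' Gibbs sampler for the log-flux regression with iid Normal residuals:
#' coefficients from their multivariate-Normal full conditional, residual
#' SD by slice sampling within its Uniform(0, 5) prior. The per-iteration
#' deviance is recorded for DIC computation.
#'
#' @param data a `chamber_dataset`.
#' @param priors a [flux_priors()] object.
#' @param config an [mcmc_config()].
#' @return A `posterior_samples` object (model tag `"independent"`).
#' @export
fit_independent <- function(data, priors = flux_priors(),
                            config = mcmc_config()) {
  f <- prepare_fit(data, priors)
  set.seed(config$seed)
  keep <- keep_index(config)
  n_keep <- length(keep)
  beta_out <- matrix(NA_real_, n_keep, f$p,
                     dimnames = list(NULL, colnames(f$x)))
  sigma2_out <- dev_out <- numeric(n_keep)

  sigma <- min(max(stats::sd(f$y), 0.05), 0.9 * priors$sigma_max)
  k <- 0L
  for (iter in seq_len(config$n_iter)) {
    bc <- beta_full_conditional(f$xtx, f$xty_fun, f$y, sigma^2,
                                priors$beta_var)
    beta <- bc$draw
    e <- f$y - drop(f$x %*% beta)
    sse <- sum(e * e)
    sigma <- slice_bounded(sigma, function(s) {
      -f$n * log(s) - sse / (2 * s * s)
    }, 1e-12, priors$sigma_max)
    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      beta_out[k, ] <- beta
      sigma2_out[k] <- sigma^2
      dev_out[k] <- f$n * log(2 * pi * sigma^2) + sse / sigma^2
    }
  }
  new_posterior_samples("independent", beta_out, sigma2_out, dev_out,
                        config, priors, f$q, f$m)
}

#' Fit the geostatistical (exponential Gaussian-process) model
#'
#' Blocked Gibbs/Metropolis sampler: coefficients and site effects from
#' Gaussian full conditionals; residual SD and process SD by slice sampling
#' within their uniform priors; the decay rate by adaptive random-walk
#' Metropolis on its Uniform support (proposal scale tuned toward 20-50%
#' acceptance during burn-in only, then frozen).
#'
#' @param data a `chamber_dataset`.
#' @param dist a `distance_matrix` from [pairwise_distances()].
#' @param priors a [flux_priors()]; if its `theta_bounds` is `NULL` the
#'   bounds are derived from `dist` via [theta_prior_bounds()].
#' @param config an [mcmc_config()].
#' @return A `posterior_samples` object (model tag `"exp"`); `effect` holds
#'   the Gaussian-process site effects.
#' @export
fit_exp_geostat <- function(data, dist, priors = flux_priors(),
                            config = mcmc_config()) {
  if (is.null(priors$theta_bounds)) {
    priors$theta_bounds <- theta_prior_bounds(dist$d_min, dist$d_max)
  }
  f <- prepare_fit(data, priors)
  d <- dist$d
  set.seed(config$seed)
  keep <- keep_index(config)
  n_keep <- length(keep)
  beta_out <- matrix(NA_real_, n_keep, f$p,
                     dimnames = list(NULL, colnames(f$x)))
  s_out <- matrix(NA_real_, n_keep, f$q)
  sigma2_out <- sigma_s2_out <- theta_out <- dev_out <- numeric(n_keep)

  lo <- priors$theta_bounds[1L]; hi <- priors$theta_bounds[2L]
  theta <- (lo + hi) / 2
  phi_state <- function(th) {
    ch <- chol_with_jitter(exp_correlation(d, th))
    list(theta = th, chol = ch$chol,
         inv = chol2inv(ch$chol),
         logdet = 2 * sum(log(diag(ch$chol))))
  }
  st <- phi_state(theta)
  sigma <- min(max(stats::sd(f$y), 0.05), 0.9 * priors$sigma_max)
  sigma_s <- min(1, 0.9 * priors$sigma_s_max)
  s <- rep(0, f$q)
  scale <- config$theta_scale
  acc <- 0L; acc_win <- 0L; n_post <- 0L
  k <- 0L

  for (iter in seq_len(config$n_iter)) {
    # beta | s, sigma
    target <- f$y - s[f$site_of]
    beta <- beta_full_conditional(f$xtx, f$xty_fun, target, sigma^2,
                                  priors$beta_var)$draw
    mu_fix <- drop(f$x %*% beta)
    r_site <- site_resid_sums(f$y - mu_fix, f$m, f$q)
    # s | beta, sigma, sigma_s, theta
    s <- gp_effect_conditional(st$inv, sigma_s^2, f$m, sigma^2, r_site)$draw
    quad <- drop(crossprod(s, st$inv %*% s))
    # sigma_s | s, theta
    sigma_s <- slice_bounded(sigma_s, function(g) {
      -f$q * log(g) - quad / (2 * g * g)
    }, 1e-12, priors$sigma_s_max)
    # theta | s, sigma_s : random-walk Metropolis on (lo, hi)
    th_p <- theta + scale * stats::rnorm(1)
    if (th_p > lo && th_p < hi) {
      st_p <- phi_state(th_p)
      quad_p <- drop(crossprod(s, st_p$inv %*% s))
      logr <- -0.5 * (st_p$logdet - st$logdet) -
        (quad_p - quad) / (2 * sigma_s^2)
      if (log(stats::runif(1)) < logr) {
        theta <- th_p; st <- st_p; quad <- quad_p
        acc <- acc + 1L; acc_win <- acc_win + 1L
      }
    }
    if (iter <= config$burn_in && iter %% config$adapt_window == 0L) {
      rate <- acc_win / config$adapt_window
      scale <- min(max(scale * exp(2 * (rate - 0.35)), 1e-4), hi - lo)
      acc_win <- 0L
    }
    if (iter > config$burn_in) n_post <- n_post + 1L
    # sigma | beta, s
    e <- f$y - mu_fix - s[f$site_of]
    sse <- sum(e * e)
    sigma <- slice_bounded(sigma, function(g) {
      -f$n * log(g) - sse / (2 * g * g)
    }, 1e-12, priors$sigma_max)

    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      beta_out[k, ] <- beta
      s_out[k, ] <- s
      sigma2_out[k] <- sigma^2
      sigma_s2_out[k] <- sigma_s^2
      theta_out[k] <- theta
      dev_out[k] <- f$n * log(2 * pi * sigma^2) + sse / sigma^2
    }
  }
  new_posterior_samples("exp", beta_out, sigma2_out, dev_out, config,
                        priors, f$q, f$m, effect = s_out,
                        sigma_s2 = sigma_s2_out, theta = theta_out,
                        accept_theta = acc / config$n_iter)
}

# breadth-first connectivity check on a binary adjacency matrix
is_connected_graph <- function(w) {
  q <- nrow(w)
  seen <- logical(q); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- which(colSums(w[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Fit the intrinsic CAR (ICAR) spatial model
#'
#' Gibbs sampler with single-site updates of the ICAR effects (each
#' conditional blends the neighbour-average prior with the site's data
#' likelihood; updates are executed colour-class-wise), a sum-to-zero
#' recentring of the effects after every sweep, and slice updates for the
#' residual and conditional SDs within their Uniform(0,5)/Uniform(0,10)
#' priors. The intercept is retained; the sum-to-zero constraint carries
#' identifiability.
#'
#' @param data a `chamber_dataset`.
#' @param weights `spatial_weights` from [thiessen_adjacency()]; must form
#'   a single connected component.
#' @param priors a [flux_priors()].
#' @param config an [mcmc_config()].
#' @return A `posterior_samples` object (model tag `"icar"`); `effect`
#'   holds the ICAR site effects.
#' @export
fit_icar <- function(data, weights, priors = flux_priors(),
                     config = mcmc_config()) {
  w <- weights$w
  if (!is_connected_graph(w)) {
    stop("adjacency graph is disconnected; the intrinsic CAR prior is ",
         "undefined per component without extra constraints")
  }
  f <- prepare_fit(data, priors)
  if (nrow(w) != f$q) stop("weights do not match the dataset's sites")
  set.seed(config$seed)
  keep <- keep_index(config)
  n_keep <- length(keep)
  beta_out <- matrix(NA_real_, n_keep, f$p,
                     dimnames = list(NULL, colnames(f$x)))
  u_out <- matrix(NA_real_, n_keep, f$q)
  sigma2_out <- sigma_u2_out <- dev_out <- numeric(n_keep)

  rs <- rowSums(w)
  classes <- colour_classes(w)
  sigma <- min(max(stats::sd(f$y), 0.05), 0.9 * priors$sigma_max)
  sigma_u <- min(1, 0.9 * priors$sigma_u_max)
  u <- rep(0, f$q)
  k <- 0L

  for (iter in seq_len(config$n_iter)) {
    target <- f$y - u[f$site_of]
    beta <- beta_full_conditional(f$xtx, f$xty_fun, target, sigma^2,
                                  priors$beta_var)$draw
    mu_fix <- drop(f$x %*% beta)
    r_site <- site_resid_sums(f$y - mu_fix, f$m, f$q)
    # single-site ICAR conditionals, batched by colour class
    data_prec <- f$m / sigma^2
    for (cls in classes) {
      wu <- drop(w[cls, , drop = FALSE] %*% u)
      prec <- rs[cls] / sigma_u^2 + data_prec
      mean_c <- (wu / sigma_u^2 + r_site[cls] / sigma^2) / prec
      u[cls] <- stats::rnorm(length(cls), mean_c, sqrt(1 / prec))
    }
    u <- u - mean(u)
    quad <- sum(rs * u * u) - drop(crossprod(u, w %*% u))
    sigma_u <- slice_bounded(sigma_u, function(g) {
      -(f$q - 1) * log(g) - quad / (2 * g * g)
    }, 1e-12, priors$sigma_u_max)
    e <- f$y - mu_fix - u[f$site_of]
    sse <- sum(e * e)
    sigma <- slice_bounded(sigma, function(g) {
      -f$n * log(g) - sse / (2 * g * g)
    }, 1e-12, priors$sigma_max)

    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      beta_out[k, ] <- beta
      u_out[k, ] <- u
      sigma2_out[k] <- sigma^2
      sigma_u2_out[k] <- sigma_u^2
      dev_out[k] <- f$n * log(2 * pi * sigma^2) + sse / sigma^2
    }
  }
  new_posterior_samples("icar", beta_out, sigma2_out, dev_out, config,
                        priors, f$q, f$m, effect = u_out,
                        sigma_u2 = sigma_u2_out)
}

#' Persist posterior samples as a columnar CSV
#'
#' One row per retained draw; columns are the coefficients, variances,
#' structure-specific parameters, site effects and the deviance trace.
#'
#' @param samples a `posterior_samples` object.
#' @param path output CSV path.
#' @export
write_samples_csv <- function(samples, path) {
  df <- as.data.frame(samples$beta)
  names(df) <- paste0("beta.", c("intercept", COVARIATE_NAMES))
  df$sigma2 <- samples$sigma2
  if (!is.null(samples$theta)) df$theta <- samples$theta
  if (!is.null(samples$sigma_s2)) df$sigma_s2 <- samples$sigma_s2
  if (!is.null(samples$sigma_u2)) df$sigma_u2 <- samples$sigma_u2
  if (!is.null(samples$effect)) {
    eff <- as.data.frame(samples$effect)
    names(eff) <- paste0(if (samples$model == "icar") "u." else "s.",
                         seq_len(ncol(eff)))
    df <- cbind(df, eff)
  }
  df$deviance <- samples$deviance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
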