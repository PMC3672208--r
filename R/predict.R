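#' Posterior predictive summaries per site and observation
#'
#' For every retained draw, builds the fitted mean `mu_ir` (including the
#' site spatial effect when present) and a predictive replicate
#' `mu_ir + Normal(0, sigma2)`. Observation-level intervals use the
#' per-(site, replicate) predictive draws; site-level summaries aggregate
#' the replicates of each site within each draw.
#'
#' @param samples a `posterior_samples` object.
#' @param data the `chamber_dataset` the model was fitted to.
#' @param seed RNG seed for the predictive noise.
#' @return A list of class `site_prediction`: `site` (per-site predictive
#'   mean/median/2.5%/97.5% of log-flux plus posterior mean/SD of the
#'   spatial effect), `obs` (per-observation predictive mean and 95%
#'   bounds alongside the observed log-flux), `site_draws` (draws x Q
#'   matrix of site-level predictive draws), `model`.
#' @export
posterior_predict <- function(samples, data, seed = 1L) {
  set.seed(derive_seed(seed, paste0("predict-", samples$model)))
  x <- model_matrix(data)
  y <- response_vector(data)
  site_of <- site_index(data)
  q <- data$Q; m <- data$M
  t_draws <- samples$n_kept
  n <- length(y)

  mu <- samples$beta %*% t(x)                       # T x N fitted means
  if (!is.null(samples$effect)) {
    mu <- mu + samples$effect[, site_of, drop = FALSE]
  }
  noise <- matrix(stats::rnorm(t_draws * n), t_draws, n) *
    sqrt(samples$sigma2)
  yrep <- mu + noise

  obs_q <- apply(yrep, 2L, stats::quantile, probs = c(0.025, 0.975))
  obs <- data.frame(
    site_id = data$coords$site_id[site_of],
    replicate = rep(as.integer(colnames(data$y)), times = q),
    observed = y,
    pred_mean = colMeans(yrep),
    lower = obs_q[1L, ],
    upper = obs_q[2L, ]
  )

  # site-level: average the M replicate draws within each posterior draw
  site_draws <- matrix(NA_real_, t_draws, q)
  for (i in seq_len(q)) {
    cols <- which(site_of == i)
    site_draws[, i] <- rowMeans(yrep[, cols, drop = FALSE])
  }
  sq <- apply(site_draws, 2L, stats::quantile,
              probs = c(0.025, 0.5, 0.975))
  eff_mean <- if (is.null(samples$effect)) rep(0, q) else {
    colMeans(samples$effect)
  }
  eff_sd <- if (is.null(samples$effect)) rep(0, q) else {
    apply(samples$effect, 2L, stats::sd)
  }
  site <- data.frame(site_id = data$coords$site_id,
                     mean = colMeans(site_draws),
                     lower = sq[1L, ], median = sq[2L, ], upper = sq[3L, ],
                     effect_mean = eff_mean, effect_sd = eff_sd)
  structure(list(site = site, obs = obs, site_draws = site_draws,
                 model = samples$model),
            class = "site_prediction")
}

#' Fraction of observations outside their 95% predictive intervals
#'
#' @param observed numeric vector of observed log-fluxes, or `NULL` to use
#'   the observations stored in `predictions$obs`.
#' @param predictions a `site_prediction` object, or a data frame with
#'   `lower` and `upper` columns aligned with `observed`.
#' @return Fraction of observations strictly outside `[lower, upper]`.
#' @export
coverage_check <- function(observed, predictions) {
  tab <- if (inherits(predictions, "site_prediction")) {
    predictions$obs
  } else predictions
  if (is.null(observed)) observed <- tab$observed
  if (length(observed) != nrow(tab)) {
    stop("observed values and predictions have different lengths")
  }
  mean(observed < tab$lower | observed > tab$upper)
}

#' Sum of squared residuals against posterior predictive means
#'
#' @param observed numeric vector of observed log-fluxes, or `NULL` to use
#'   the observations stored in the prediction object.
#' @param predictions a `site_prediction` object or a numeric vector of
#'   predictive means aligned with `observed`.
#' @return `sum((observed - predicted)^2)`.
#' @export
sum_squared_residuals <- function(observed, predictions) {
  pred <- if (inherits(predictions, "site_prediction")) {
    if (is.null(observed)) observed <- predictions$obs$observed
    predictions$obs$pred_mean
  } else predictions
  if (length(observed) != length(pred)) {
    stop("observed values and predictions have different lengths")
  }
  sum((observed - pred)^2)
}
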