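#' Deviance information criterion from posterior samples
#'
#' `Dbar` is the posterior mean of the deviance trace; `D_at_mean` is the
#' deviance re-evaluated at the posterior means of every parameter entering
#' the likelihood (coefficients, site effects, residual variance);
#' `pD = Dbar - D_at_mean` is the effective number of parameters and
#' `DIC = Dbar + pD`. Smaller DIC indicates better fit after accounting
#' for model complexity. The deviance is conditional on the latent site
#' effects throughout.
#'
#' @param samples a `posterior_samples` object with a deviance trace.
#' @param data the `chamber_dataset` the model was fitted to.
#' @return A list of class `dic_result`: `model`, `Dbar`, `D_at_mean`,
#'   `pD`, `DIC`.
#' @export
compute_dic <- function(samples, data) {
  dev <- samples$deviance
  if (is.null(dev) || !length(dev)) stop("no deviance trace in samples")
  bad <- which(!is.finite(dev))
  if (length(bad)) {
    stop("non-finite deviance at retained iteration ", bad[1L])
  }
  dbar <- mean(dev)
  x <- model_matrix(data)
  y <- response_vector(data)
  beta_bar <- colMeans(samples$beta)
  mu <- drop(x %*% beta_bar)
  if (!is.null(samples$effect)) {
    mu <- mu + colMeans(samples$effect)[site_index(data)]
  }
  d_hat <- gaussian_deviance(y, mu, mean(samples$sigma2))
  pd <- dbar - d_hat
  structure(list(model = samples$model, Dbar = dbar, D_at_mean = d_hat,
                 pD = pd, DIC = dbar + pd),
            class = "dic_result")
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("%s model: Dbar = %.2f, pD = %.2f, DIC = %.2f\n",
              x$model, x$Dbar, x$pD, x$DIC))
  invisible(x)
}

#' DIC-weighted posterior model probabilities
#'
#' Information-criterion approximation to the posterior model probability:
#' `p(M_l | D) = p(M_l) exp(-DIC_l / 2) / sum_m p(M_m) exp(-DIC_m / 2)`,
#' computed in log space with max-subtraction so that DIC values of
#' several hundred do not underflow.
#'
#' @param dic numeric vector of DIC values, or a list of `dic_result`s.
#' @param prior_probs prior model probabilities (default equal); must sum
#'   to 1.
#' @return Named numeric vector of posterior model probabilities.
#' @export
bma_weights <- function(dic, prior_probs = NULL) {
  if (is.list(dic) && all(vapply(dic, inherits, TRUE, "dic_result"))) {
    nms <- vapply(dic, `[[`, "", "model")
    dic <- vapply(dic, `[[`, 0, "DIC")
    names(dic) <- nms
  }
  l <- length(dic)
  if (l < 2L) stop("need at least 2 models to average")
  if (is.null(prior_probs)) prior_probs <- rep(1 / l, l)
  if (abs(sum(prior_probs) - 1) > 1e-8) stop("priors must sum to 1")
  logw <- -dic / 2 + log(prior_probs)
  logw <- logw - max(logw)
  w <- exp(logw)
  w <- w / sum(w)
  names(w) <- names(dic)
  w
}

#' Combine per-model posterior predictions by model averaging
#'
#' The averaged posterior predictive is the mixture of the per-model
#' predictive distributions with the BMA weights: draws are resampled from
#' each model in proportion to its weight (largest-remainder allocation of
#' the draw budget, so a weight of exactly 1 reproduces that model's draws
#' unchanged). The mixture mean equals the weight-average of the per-model
#' means and is reported analytically.
#'
#' @param predictions list of `site_prediction` objects (one per model) on
#'   identical site sets.
#' @param weights model weights from [bma_weights()] (same order).
#' @param n_draws mixture draw budget (default: smallest per-model count).
#' @param seed RNG seed for the resampling.
#' @return A list of class `bma_result`: `weights`, `site` (per-site
#'   mixture mean/variance/quantiles), `site_draws`, `effect` (averaged
#'   spatial-effect summaries), `prior_probs`.
#' @export
bma_combine <- function(predictions, weights, n_draws = NULL, seed = 1L,
                        prior_probs = NULL) {
  l <- length(predictions)
  stopifnot(l == length(weights), abs(sum(weights) - 1) < 1e-8)
  sites <- predictions[[1L]]$site$site_id
  for (p in predictions) {
    if (!identical(p$site$site_id, sites)) {
      stop("predictions have misaligned site sets")
    }
  }
  q <- length(sites)
  if (is.null(n_draws)) {
    n_draws <- min(vapply(predictions, function(p) nrow(p$site_draws), 0L))
  }
  # largest-remainder allocation of the draw budget
  raw <- weights * n_draws
  n_l <- floor(raw)
  rem <- n_draws - sum(n_l)
  if (rem > 0) {
    ord <- order(raw - n_l, decreasing = TRUE)
    n_l[ord[seq_len(rem)]] <- n_l[ord[seq_len(rem)]] + 1L
  }
  set.seed(derive_seed(seed, "bma-mixture"))
  draws <- do.call(rbind, lapply(seq_len(l), function(i) {
    di <- predictions[[i]]$site_draws
    if (n_l[i] == 0L) return(NULL)
    rows <- if (n_l[i] == nrow(di)) seq_len(nrow(di)) else {
      sample.int(nrow(di), n_l[i], replace = TRUE)
    }
    di[rows, , drop = FALSE]
  }))
  # analytic mixture moments (law of total variance over models)
  means <- vapply(predictions, function(p) p$site$mean, numeric(q))
  vars <- vapply(predictions, function(p) {
    apply(p$site_draws, 2L, stats::var)
  }, numeric(q))
  mix_mean <- drop(means %*% weights)
  mix_var <- drop((vars + means^2) %*% weights) - mix_mean^2
  qs <- apply(draws, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975))
  site <- data.frame(site_id = sites, mean = mix_mean, var = mix_var,
                     lower = qs[1L, ], median = qs[2L, ], upper = qs[3L, ])
  eff_means <- vapply(predictions, function(p) p$site$effect_mean,
                      numeric(q))
  effect <- data.frame(site_id = sites,
                       effect_mean = drop(eff_means %*% weights))
  structure(list(weights = weights,
                 prior_probs = if (is.null(prior_probs)) {
                   rep(1 / l, l)
                 } else prior_probs,
                 site = site, site_draws = draws, effect = effect,
                 n_per_model = n_l),
            class = "bma_result")
}

#' Write the model-comparison table
#'
#' @param dics list of `dic_result` objects.
#' @param weights matching [bma_weights()] vector.
#' @param path output CSV path.
#' @param prior_probs prior model probabilities (default equal).
#' @export
write_dic_table <- function(dics, weights, path, prior_probs = NULL) {
  l <- length(dics)
  if (is.null(prior_probs)) prior_probs <- rep(1 / l, l)
  tab <- data.frame(
    model = vapply(dics, `[[`, "", "model"),
    Dbar = vapply(dics, `[[`, 0, "Dbar"),
    pD = vapply(dics, `[[`, 0, "pD"),
    DIC = vapply(dics, `[[`, 0, "DIC"),
    prior = prior_probs,
    posterior_prob = as.numeric(weights)
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
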