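# Deterministic stream splitting: every stage of a simulation draws from a
# sub-seed derived from the master seed and a stage label, so stages can be
# re-run independently yet the whole run is reproducible from one integer.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483647)
}

#' Reference covariate moments for the emulated pasture study
#'
#' Mean, SD and observed range of the seven soil covariates (and flux) in a
#' replicated subtropical pasture chamber study: gravimetric moisture (%),
#' soil temperature (deg C), NO3- (kg N/ha), pH, and sand/silt/clay (%).
#'
#' @return Data frame with columns `variable`, `mean`, `sd`, `min`, `max`.
#' @export
table1_moments <- function() {
  data.frame(
    variable = c("moisture", "temperature", "no3", "ph", "sand", "silt",
                 "clay"),
    mean = c(35.57, 22.16, 18.98, 5.47, 37.25, 44.34, 18.4),
    sd   = c(9.27, 3.07, 14.1, 0.29, 7.74, 7.2, 3.07),
    min  = c(12.37, 14.8, 0.0, 5.2, 22.75, 34.44, 9.65),
    max  = c(70, 27.3, 90.34, 6.4, 50.89, 60.94, 23.34)
  )
}

#' Study-design configuration for the synthetic generator
#'
#' Defaults emulate the field design the models target: 17 chambers in a
#' ~272 m^2 square field (16.5 m x 16.5 m) sampled at 13 monthly replicates,
#' with chamber separations of at least 0.75 m and covariates matching
#' [table1_moments()].
#'
#' @param n_sites number of chambers Q (default 17).
#' @param n_replicates number of monthly replicates M (default 13).
#' @param field_width,field_height field dimensions in metres
#'   (default 16.5 x 16.5, area approx. 272 m^2).
#' @param min_separation minimum pairwise chamber distance in metres
#'   (default 0.75).
#' @param moments covariate moment table, defaults to [table1_moments()].
#' @param seed master RNG seed.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_sites = 17, n_replicates = 13,
                          field_width = 16.5, field_height = 16.5,
                          min_separation = 0.75,
                          moments = table1_moments(), seed = 1L) {
  stopifnot(n_sites >= 2, n_replicates >= 1, field_width > 0,
            field_height > 0, min_separation >= 0)
  # a packing feasibility sanity check: disks of radius min_sep/2 must fit
  if (n_sites * pi * (min_separation / 2)^2 > field_width * field_height) {
    stop("min_separation not achievable for this many sites in the field")
  }
  tex <- moments$mean[moments$variable %in% c("sand", "silt", "clay")]
  if (abs(sum(tex) - 100) > 1) {
    stop("texture means must sum to approximately 100%")
  }
  structure(list(n_sites = as.integer(n_sites),
                 n_replicates = as.integer(n_replicates),
                 field_width = field_width, field_height = field_height,
                 min_separation = min_separation, moments = moments,
                 seed = as.integer(seed)),
            class = "design_config")
}

#' Generate a random chamber layout
#'
#' Places `n_sites` points uniformly in the field rectangle, rejection
#' sampling each point until all pairwise distances are at least
#' `min_separation`. Deterministic given the seed.
#'
#' @param config a [design_config()].
#' @param seed optional override of `config$seed`.
#' @param max_tries attempts per site before giving up (default 2000).
#' @return A [site_coordinates()] object.
#' @export
generate_layout <- function(config = design_config(), seed = NULL,
                            max_tries = 2000L) {
  if (is.null(seed)) seed <- config$seed
  set.seed(derive_seed(seed, "layout"))
  q <- config$n_sites
  xs <- numeric(q); ys <- numeric(q)
  for (i in seq_len(q)) {
    placed <- FALSE
    for (tries in seq_len(max_tries)) {
      px <- stats::runif(1, 0, config$field_width)
      py <- stats::runif(1, 0, config$field_height)
      if (i == 1L ||
          min(sqrt((xs[seq_len(i - 1L)] - px)^2 +
                   (ys[seq_len(i - 1L)] - py)^2)) >=
            config$min_separation) {
        xs[i] <- px; ys[i] <- py; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place site ", i, " after ", max_tries,
           " attempts; enlarge the field or reduce n_sites/min_separation")
    }
  }
  site_coordinates(seq_len(q), xs, ys)
}

# Clip to the observed range, preserving vector shape.
clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate covariate values matching the study's summary moments
#'
#' Site-static covariates (pH and the sand/silt/clay texture triplet) are
#' drawn once per site; replicate-varying covariates (moisture, temperature,
#' NO3-) are drawn per site x replicate. Moisture and temperature share a
#' smooth sinusoidal seasonal signal across the monthly replicates
#' (variance split: 50% seasonal, 25% site, 25% residual); NO3- is drawn
#' from a Gamma distribution matching the target mean/SD (right-skewed,
#' non-negative). All values are clipped to the observed min-max ranges and
#' texture triplets are renormalised to sum to 100.
#'
#' @param coords a [site_coordinates()] layout.
#' @param config a [design_config()].
#' @param seed optional override of `config$seed`.
#' @return Long data frame: `site_id`, `replicate`, then the 7 covariates.
#' @export
generate_covariates <- function(coords, config = design_config(),
                                seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  set.seed(derive_seed(seed, "covariates"))
  coords <- as_site_coordinates(coords)
  q <- nrow(coords); m <- config$n_replicates
  mom <- config$moments
  g <- function(v, f) mom[[f]][mom$variable == v]

  # shared standardized seasonal driver over monthly replicates
  raw <- sin(2 * pi * (seq_len(m) - 1) / 12 - pi / 2)
  seas <- if (m > 1 && stats::sd(raw) > 0) {
    (raw - mean(raw)) / stats::sd(raw)
  } else rep(0, m)

  seasonal_cov <- function(v) {
    mu <- g(v, "mean"); sdev <- g(v, "sd")
    site_z <- stats::rnorm(q)
    e <- matrix(stats::rnorm(q * m), q, m)
    vals <- mu + sdev * (sqrt(0.5) * matrix(seas, q, m, byrow = TRUE) +
                           sqrt(0.25) * site_z +
                           sqrt(0.25) * e)
    clip_range(vals, g(v, "min"), g(v, "max"))
  }
  moisture <- seasonal_cov("moisture")
  temperature <- seasonal_cov("temperature")

  no3 <- {
    mu <- g("no3", "mean"); sdev <- g("no3", "sd")
    vals <- if (sdev > 0) {
      shape <- (mu / sdev)^2
      matrix(stats::rgamma(q * m, shape = shape, rate = mu / sdev^2), q, m)
    } else matrix(mu, q, m)
    clip_range(vals, g("no3", "min"), g("no3", "max"))
  }

  static_cov <- function(v) {
    mu <- g(v, "mean"); sdev <- g(v, "sd")
    clip_range(mu + sdev * stats::rnorm(q), g(v, "min"), g(v, "max"))
  }
  ph <- static_cov("ph")
  sand <- static_cov("sand"); silt <- static_cov("silt")
  clay <- static_cov("clay")
  tex_sd <- c(g("sand", "sd"), g("silt", "sd"), g("clay", "sd"))
  if (any(tex_sd > 0)) {
    tot <- sand + silt + clay
    sand <- 100 * sand / tot; silt <- 100 * silt / tot
    clay <- 100 * clay / tot
  }

  data.frame(
    site_id = rep(coords$site_id, each = m),
    replicate = rep(seq_len(m), times = q),
    moisture = as.vector(t(moisture)),
    temperature = as.vector(t(temperature)),
    no3 = as.vector(t(no3)),
    ph = rep(ph, each = m),
    sand = rep(sand, each = m),
    silt = rep(silt, each = m),
    clay = rep(clay, each = m)
  )
}

#' Generative parameters for synthetic fluxes
#'
#' Defaults are realistic posterior-scale values for a pasture flux
#' regression on the log scale: regression coefficients for the 7 covariates
#' plus intercept, residual variance, and the structure-specific spatial
#' parameters (Gaussian-process variance `sigma_s2` and decay `theta` for
#' the geostatistical structure; conditional variance `sigma_u2` for the
#' ICAR structure). The spatial smoothing exponent `delta` is fixed at 1.
#'
#' @param structure one of `"independent"`, `"exp"`, `"icar"`.
#' @param beta named length-8 coefficient vector (intercept first).
#' @param sigma2 residual variance on the log scale.
#' @param sigma_s2,theta Gaussian-process variance and decay rate (1/m);
#'   used when `structure = "exp"`.
#' @param sigma_u2 ICAR conditional variance; used when `structure = "icar"`.
#' @return A list of class `generative_params`.
#' @export
generative_params <- function(structure = c("independent", "exp", "icar"),
                              beta = c(-5.84, 0.039, 0.15, -0.006, 0.21,
                                       0.023, 0.033, 0.004),
                              sigma2 = NULL, sigma_s2 = 0.76, theta = 1.0,
                              sigma_u2 = 1.78) {
  structure <- match.arg(structure)
  if (is.null(sigma2)) {
    sigma2 <- if (structure == "independent") 2.0 else 1.59
  }
  stopifnot(length(beta) == 8, sigma2 > 0, sigma_s2 >= 0, theta > 0,
            sigma_u2 > 0)
  names(beta) <- c("(Intercept)", COVARIATE_NAMES)
  out <- list(structure = structure, beta = beta, sigma2 = sigma2,
              delta = 1)
  if (structure == "exp") {
    out$sigma_s2 <- sigma_s2; out$theta <- theta
  }
  if (structure == "icar") out$sigma_u2 <- sigma_u2
  class(out) <- "generative_params"
  out
}

# Joint draw from the sum-to-zero-constrained ICAR distribution via the
# eigen-decomposition of the graph Laplacian D - W (the improper intrinsic
# prior is only samplable on the subspace orthogonal to the constant).
ricar <- function(w, sigma_u2) {
  lap <- diag(rowSums(w)) - w
  e <- eigen(lap, symmetric = TRUE)
  pos <- e$values > 1e-8 * max(e$values)
  z <- stats::rnorm(sum(pos))
  u <- e$vectors[, pos, drop = FALSE] %*%
    (z * sqrt(sigma_u2 / e$values[pos]))
  drop(u - mean(u))   # exact sum-to-zero despite floating-point residue
}

#' Simulate chamber fluxes from a chosen spatial structure
#'
#' Log-fluxes follow the regression `beta0 + X beta + effect_i + eps_ir`
#' with iid Normal residuals; the site effect is 0 (independent), a draw
#' from a zero-mean Gaussian process with correlation `exp(-theta d_ij)`
#' (exp), or a sum-to-zero ICAR draw on the supplied neighbourhood weights
#' (icar). Natural-scale fluxes are `exp(logflux) - back_shift`, floored at
#' zero, so a positive `back_shift` exercises the zero-flux handling path.
#'
#' @param coords site layout.
#' @param covariates long covariate table from [generate_covariates()].
#' @param params a [generative_params()] object.
#' @param weights `spatial_weights`; required when `params$structure` is
#'   `"icar"`.
#' @param seed RNG seed.
#' @param back_shift additive back-shift on the natural scale (default 0).
#' @return A `chamber_dataset`; the true site effects and parameters are
#'   attached as attribute `"truth"`.
#' @export
simulate_fluxes <- function(coords, covariates, params, weights = NULL,
                            seed = 1L, back_shift = 0) {
  coords <- as_site_coordinates(coords)
  set.seed(derive_seed(seed, paste0("fluxes-", params$structure)))
  q <- nrow(coords)
  m <- length(unique(covariates$replicate))
  cov_tab <- covariates[order(match(covariates$site_id, coords$site_id),
                              covariates$replicate), ]
  x <- as.matrix(cov_tab[, COVARIATE_NAMES])
  eta <- params$beta[1L] + drop(x %*% params$beta[-1L])

  effect <- rep(0, q)
  if (params$structure == "exp" && params$sigma_s2 > 0) {
    d <- pairwise_distances(coords)$d
    sig <- params$sigma_s2 * exp(-(params$theta * d)^params$delta)
    ch <- chol_with_jitter(sig)
    effect <- drop(crossprod(ch$chol, stats::rnorm(q)))
  } else if (params$structure == "icar") {
    if (is.null(weights)) stop("icar structure requires 'weights'")
    effect <- ricar(weights$w, params$sigma_u2)
  }

  site_of <- rep(seq_len(q), each = m)
  z <- eta + effect[site_of] + stats::rnorm(q * m, 0, sqrt(params$sigma2))
  flux <- pmax(exp(z) - back_shift, 0)
  tab <- cbind(cov_tab[, c("site_id", "replicate")], n2o_flux = flux,
               cov_tab[, COVARIATE_NAMES])
  data <- chamber_dataset(tab, coords)
  attr(data, "truth") <- list(params = params, effect = effect,
                              log_flux = z, seed = seed,
                              back_shift = back_shift)
  data
}

# Cholesky with escalating diagonal jitter; returns the factor and the
# jitter actually applied (0 when the matrix was already PD).
chol_with_jitter <- function(sigma, max_tries = 6L, jitter0 = 1e-8) {
  jit <- 0
  for (k in 0:max_tries) {
    ch <- tryCatch(chol(sigma + diag(jit, nrow(sigma))),
                   error = function(e) NULL)
    if (!is.null(ch)) return(list(chol = ch, jitter = jit))
    jit <- if (jit == 0) jitter0 * mean(diag(sigma)) else jit * 10
  }
  stop("correlation matrix not positive definite even after jitter")
}

#' Simulate a complete replicated chamber study
#'
#' Orchestrates layout, covariates, Thiessen weights and flux generation
#' from one master seed (every stage uses a documented derived sub-seed).
#'
#' @param config a [design_config()].
#' @param params a [generative_params()].
#' @param seed optional override of `config$seed`.
#' @param back_shift passed to [simulate_fluxes()].
#' @return A list of class `chamber_simulation`: `data`
#'   (`chamber_dataset`), `coords`, `dist`, `weights`, `params`, `config`,
#'   `seed`.
#' @export
simulate_chamber_study <- function(config = design_config(),
                                   params = generative_params("exp"),
                                   seed = NULL, back_shift = 0) {
  if (is.null(seed)) seed <- config$seed
  coords <- generate_layout(config, seed = seed)
  covs <- generate_covariates(coords, config, seed = seed)
  weights <- thiessen_adjacency(coords)
  data <- simulate_fluxes(coords, covs, params, weights = weights,
                          seed = seed, back_shift = back_shift)
  structure(list(data = data, coords = coords,
                 dist = pairwise_distances(coords), weights = weights,
                 params = params, config = config, seed = seed),
            class = "chamber_simulation")
}
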