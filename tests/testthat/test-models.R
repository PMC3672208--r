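test_that("decay-parameter prior bounds follow the closed form", {
  b <- theta_prior_bounds(0.75, 25.35, 0.05)
  expect_equal(unname(b[1]), -log(0.05) / 25.35, tolerance = 1e-12)
  expect_equal(unname(b[2]), -log(0.05) / 0.75, tolerance = 1e-12)
  b2 <- theta_prior_bounds(1, exp(1), rho = exp(-1))
  expect_equal(unname(b2), c(exp(-1), 1), tolerance = 1e-12)
  # bounds shrink to zero as the target correlation approaches 1
  b3 <- theta_prior_bounds(0.75, 25.35, rho = 1 - 1e-12)
  expect_lt(b3[2], 1e-10)
  expect_error(theta_prior_bounds(5, 2), "d_min < d_max")
  expect_error(theta_prior_bounds(1, 2, rho = 1.5), "rho")
})

test_that("exponential correlation has the defining properties", {
  co <- random_layout(7, seed = 3)
  d <- pairwise_distances(co)
  phi <- exp_correlation(d, theta = 0.4)
  expect_equal(diag(phi), rep(1, 7), ignore_attr = TRUE)
  expect_true(isSymmetric(phi))
  expect_true(all(phi > 0 & phi <= 1))
  expect_true(all(eigen(phi, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # theta d = log 2 halves the correlation
  expect_equal(exp_correlation(matrix(c(0, 2, 2, 0), 2), log(2) / 2)[1, 2],
               0.5)
  # at the prior bound the correlation at d_max is exactly rho
  b <- theta_prior_bounds(0.75, 25.35, 0.05)
  expect_equal(exp(-(b[1] * 25.35)), 0.05, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("Gaussian full conditionals match closed-form oracles", {
  data <- full_rank_dataset(q = 8, m = 4, seed = 2)
  x <- n2ospatial:::model_matrix(data)
  y <- n2ospatial:::response_vector(data)
  xtx <- crossprod(x)
  set.seed(33)
  for (rep in 1:5) {
    sigma2 <- runif(1, 0.5, 3)
    # beta conditional: ridge/GLS closed form
    bc <- n2ospatial:::beta_full_conditional(
      xtx, function(t) drop(crossprod(x, t)), y, sigma2, 1e6,
      draw = FALSE)
    oracle <- solve(xtx / sigma2 + diag(1e-6, ncol(x)),
                    crossprod(x, y) / sigma2)
    expect_equal(bc$mean, drop(oracle), tolerance = 1e-10,
                 ignore_attr = TRUE)

    # GP site-effect conditional: precision-weighted Gaussian
    q <- data$Q
    phi <- exp_correlation(pairwise_distances(data$coords), runif(1, 0.2, 2))
    phi_inv <- solve(phi)
    sigma_s2 <- runif(1, 0.3, 2)
    r_site <- rnorm(q)
    gc <- n2ospatial:::gp_effect_conditional(phi_inv, sigma_s2, data$M,
                                             sigma2, r_site, draw = FALSE)
    a <- phi_inv / sigma_s2 + diag(data$M / sigma2, q)
    expect_equal(gc$mean, drop(solve(a, r_site / sigma2)),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("ICAR conditional mean is the neighbour average (prior only)", {
  g <- expand.grid(x = 0:3, y = 0:3)
  w <- thiessen_adjacency(site_coordinates(1:16, g$x, g$y))$w
  set.seed(5)
  u <- rnorm(16)
  for (i in c(1, 6, 11, 16)) {
    cond <- n2ospatial:::icar_site_conditional(i, u, w, sigma_u2 = 2)
    nb <- which(w[i, ] == 1)
    expect_equal(cond$mean, mean(u[nb]), tolerance = 1e-12)
    expect_equal(cond$var, 2 / length(nb), tolerance = 1e-12)
  }
  # with a data term the conditional is the precision-weighted blend
  cond <- n2ospatial:::icar_site_conditional(3, u, w, sigma_u2 = 1.5,
                                             data_prec = 4, data_mean = 2)
  nb <- which(w[3, ] == 1)
  pp <- length(nb) / 1.5
  expect_equal(cond$mean, (pp * mean(u[nb]) + 4 * 2) / (pp + 4),
               tolerance = 1e-12)
})

test_that("deviance matches its closed forms and a brute-force oracle", {
  expect_equal(gaussian_deviance(1.3, 1.3, 1 / (2 * pi)), 0,
               tolerance = 1e-12)
  y <- rnorm(40)
  expect_equal(gaussian_deviance(y, y, 1), 40 * log(2 * pi),
               tolerance = 1e-10)
  set.seed(9)
  mu <- rnorm(40); s2 <- 1.7
  oracle <- -2 * sum(log(1 / sqrt(2 * pi * s2) *
                           exp(-(y - mu)^2 / (2 * s2))))
  expect_equal(gaussian_deviance(y, mu, s2), oracle, tolerance = 1e-10)
})

test_that("the independent fit recovers known coefficients", {
  data <- full_rank_dataset(q = 15, m = 8, seed = 3, sigma = 0.7)
  beta_true <- attr(data, "beta_true")
  fit <- fit_independent(data, config = quick_mcmc(seed = 21))
  post_mean <- colMeans(fit$beta)
  post_sd <- apply(fit$beta, 2, sd)
  expect_true(all(abs(post_mean - beta_true) < 4 * post_sd))
  expect_true(all(fit$sigma2 > 0 & sqrt(fit$sigma2) < 5))
})

test_that("a constant response pins the intercept", {
  co <- site_coordinates(1:4, c(0, 5, 5, 0), c(0, 0, 5, 5))
  tab <- expand.grid(replicate = 1:4, site_id = 1:4)
  tab$n2o_flux <- exp(2)    # constant log-flux of 2
  set.seed(8)
  for (v in c("moisture", "temperature", "no3", "ph", "sand", "silt",
              "clay")) {
    tab[[v]] <- rnorm(nrow(tab), 0, 1e-4)   # effectively no covariates
  }
  data <- chamber_dataset(tab[, c("site_id", "replicate", "n2o_flux",
                                  "moisture", "temperature", "no3", "ph",
                                  "sand", "silt", "clay")], co)
  fit <- fit_independent(data, config = quick_mcmc(seed = 2))
  expect_equal(mean(fit$beta[, 1]), 2, tolerance = 0.05)
})

test_that("an exactly singular non-texture design is rejected", {
  data <- full_rank_dataset(q = 8, m = 4, seed = 4)
  data$xarr[, , "temperature"] <- data$xarr[, , "moisture"]  # duplicate
  expect_error(fit_independent(data, config = quick_mcmc()),
               "collinear")
})

test_that("spatial fits are reproducible and respect prior supports", {
  sim <- quick_sim("exp", seed = 14)
  cfg <- quick_mcmc(seed = 5, n_iter = 1500, burn_in = 500)
  f1 <- fit_exp_geostat(sim$data, sim$dist, config = cfg)
  f2 <- fit_exp_geostat(sim$data, sim$dist, config = cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$theta, f2$theta)
  b <- theta_prior_bounds(sim$dist$d_min, sim$dist$d_max)
  expect_true(all(f1$theta > b[1] & f1$theta < b[2]))
  expect_true(all(sqrt(f1$sigma2) < 5))
  expect_true(all(sqrt(f1$sigma_s2) < 10))

  f3 <- fit_icar(sim$data, sim$weights, config = cfg)
  expect_true(all(sqrt(f3$sigma_u2) < 10))
  expect_lt(max(abs(rowSums(f3$effect))), 1e-8)
})

test_that("the ICAR fit requires a connected neighbourhood graph", {
  sim <- quick_sim("icar", seed = 2)
  w <- sim$weights
  w$w[, 1] <- 0; w$w[1, ] <- 0          # isolate site 1
  expect_error(fit_icar(sim$data, w, config = quick_mcmc()),
               "disconnected")
})

test_that("ICAR variance is recovered within an order of magnitude", {
  g <- expand.grid(x = 0:3, y = 0:3)
  co <- site_coordinates(1:16, g$x * 4, g$y * 4)
  w <- thiessen_adjacency(co)
  cfg <- design_config(n_sites = 16, field_width = 12, field_height = 12,
                       seed = 31)
  cv <- generate_covariates(co, cfg)
  hits <- 0
  for (s in 1:5) {
    data <- simulate_fluxes(co, cv, generative_params("icar",
                                                      sigma_u2 = 1.78),
                            weights = w, seed = s)
    fit <- fit_icar(data, w, config = quick_mcmc(seed = s,
                                                 n_iter = 4000,
                                                 burn_in = 1000))
    med <- stats::median(fit$sigma_u2)
    if (med > 1.78 / 4 && med < 1.78 * 4) hits <- hits + 1
  }
  expect_gte(hits, 4)    # weakly identified at Q = 16; order of magnitude
})

test_that("convergence diagnostics behave on known chains", {
  set.seed(77)
  iid <- matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "z"))
  rep_iid <- convergence_report(iid)
  expect_lt(abs(rep_iid$acf_lag1), 0.05)
  expect_gt(rep_iid$ess, 5000)

  ar1 <- numeric(1e4)
  for (t in 2:1e4) ar1[t] <- 0.9 * ar1[t - 1] + rnorm(1)
  rep_ar <- convergence_report(matrix(ar1, ncol = 1,
                                      dimnames = list(NULL, "ar")))
  expect_equal(rep_ar$acf_lag1, 0.9, tolerance = 0.03 / 0.9)
  expect_lt(rep_ar$ess, 2000)

  const <- matrix(1, 500, 1, dimnames = list(NULL, "c"))
  rep_c <- convergence_report(const)
  expect_true(rep_c$degenerate)
  expect_true(is.na(rep_c$ess))
})

test_that("samples survive a CSV round trip", {
  sim <- quick_sim("exp", seed = 18)
  fit <- fit_exp_geostat(sim$data, sim$dist,
                         config = quick_mcmc(seed = 3, n_iter = 1500,
                                             burn_in = 500))
  f <- tempfile(fileext = ".csv")
  write_samples_csv(fit, f)
  back <- read_samples_csv(f, "exp", sim$data)
  expect_equal(unname(back$beta), unname(fit$beta), tolerance = 1e-12)
  expect_equal(back$deviance, fit$deviance, tolerance = 1e-12)
  expect_equal(unname(back$effect), unname(fit$effect), tolerance = 1e-12)
})
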