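test_that("DIC components follow their definitions", {
  sim <- quick_sim("independent", seed = 1)
  fit <- fit_independent(sim$data, config = quick_mcmc(seed = 1,
                                                       n_iter = 1500,
                                                       burn_in = 500))
  dic <- compute_dic(fit, sim$data)
  expect_equal(dic$DIC, dic$Dbar + dic$pD, tolerance = 1e-12)
  expect_equal(dic$pD, dic$Dbar - dic$D_at_mean, tolerance = 1e-12)
  expect_equal(dic$Dbar, mean(fit$deviance), tolerance = 1e-12)

  # degenerate and two-point arithmetic cases on a synthetic trace
  fake <- fit
  fake$deviance <- rep(10, fit$n_kept)
  fake$beta <- matrix(colMeans(fit$beta), fit$n_kept, ncol(fit$beta),
                      byrow = TRUE, dimnames = dimnames(fit$beta))
  fake$sigma2 <- rep(mean(fit$sigma2), fit$n_kept)
  dic_c <- compute_dic(fake, sim$data)
  expect_equal(dic_c$Dbar, 10)
  # constant chain: deviance at the posterior mean equals the trace value
  y <- n2ospatial:::response_vector(sim$data)
  x <- n2ospatial:::model_matrix(sim$data)
  d0 <- gaussian_deviance(y, drop(x %*% colMeans(fit$beta)),
                          mean(fit$sigma2))
  expect_equal(dic_c$pD, 10 - d0, tolerance = 1e-10)

  bad <- fit
  bad$deviance[7] <- NaN
  expect_error(compute_dic(bad, sim$data), "iteration 7")
})

test_that("deviance trace arithmetic matches the worked example", {
  # Dbar of {10, 14} is 12; with deviance 11 at the mean, pD = 1, DIC = 13
  dbar <- mean(c(10, 14))
  pd <- dbar - 11
  expect_equal(dbar, 12)
  expect_equal(pd, 1)
  expect_equal(dbar + pd, 13)
})

test_that("pD approximates the free mean-parameter count", {
  data <- full_rank_dataset(q = 17, m = 13, seed = 6, sigma = 1)
  fit <- fit_independent(data, config = quick_mcmc(seed = 4,
                                                   n_iter = 6000,
                                                   burn_in = 1000))
  dic <- compute_dic(fit, data)
  # 8 mean parameters (+ ~0.5 for the variance)
  expect_equal(dic$pD, 8, tolerance = 0.15 * 8 / 8)
})

test_that("DIC agrees with an independent re-evaluation off the CSV", {
  sim <- quick_sim("icar", seed = 8)
  fit <- fit_icar(sim$data, sim$weights,
                  config = quick_mcmc(seed = 2, n_iter = 1500,
                                      burn_in = 500))
  dic <- compute_dic(fit, sim$data)
  f <- tempfile(fileext = ".csv")
  write_samples_csv(fit, f)
  # oracle: recompute every ingredient from the persisted draws
  df <- utils::read.csv(f)
  x <- n2ospatial:::model_matrix(sim$data)
  y <- n2ospatial:::response_vector(sim$data)
  beta_bar <- colMeans(as.matrix(df[grep("^beta", names(df))]))
  u_bar <- colMeans(as.matrix(df[grep("^u\\.", names(df))]))
  mu <- drop(x %*% beta_bar) + u_bar[n2ospatial:::site_index(sim$data)]
  dbar_oracle <- mean(df$deviance)
  dhat_oracle <- -2 * sum(dnorm(y, mu, sqrt(mean(df$sigma2)), log = TRUE))
  expect_equal(dic$Dbar, dbar_oracle, tolerance = 1e-10)
  expect_equal(dic$DIC, 2 * dbar_oracle - dhat_oracle, tolerance = 1e-8)
})

test_that("BMA weights follow the normalised exp(-DIC/2) form", {
  w <- bma_weights(c(745.75, 746.1, 786.69))
  direct <- exp(-c(745.75, 746.1, 786.69) / 2 + 745.75 / 2)
  expect_equal(unname(w), direct / sum(direct), tolerance = 1e-12)
  expect_equal(unname(bma_weights(c(5, 5, 5))), rep(1 / 3, 3))
  expect_error(bma_weights(c(1, 2), prior_probs = c(0.6, 0.6)), "sum to 1")
})

test_that("weights are normalised and shift invariant for random DICs", {
  set.seed(123)
  for (rep in 1:50) {
    l <- sample(2:6, 1)
    dic <- runif(l, 100, 2000)
    pri <- runif(l); pri <- pri / sum(pri)
    w <- bma_weights(dic, pri)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0 & w <= 1))
    shift <- runif(1, -500, 500)
    expect_equal(unname(bma_weights(dic + shift, pri)), unname(w),
                 tolerance = 1e-9)
    # permutation equivariance
    perm <- sample(l)
    expect_equal(unname(bma_weights(dic[perm], pri[perm])),
                 unname(w)[perm], tolerance = 1e-12)
  }
})

make_fake_prediction <- function(means, n_draws = 400, sd = 0.3,
                                 seed = 1, effect = NULL) {
  set.seed(seed)
  q <- length(means)
  draws <- matrix(rnorm(n_draws * q, rep(means, each = n_draws), sd),
                  n_draws, q)
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.5, 0.975))
  structure(list(
    site = data.frame(site_id = seq_len(q), mean = colMeans(draws),
                      lower = qs[1, ], median = qs[2, ], upper = qs[3, ],
                      effect_mean = effect %||% rep(0, q),
                      effect_sd = rep(0, q)),
    site_draws = draws, model = "fake"), class = "site_prediction")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("model averaging mixes predictive draws correctly", {
  p1 <- make_fake_prediction(rep(1, 4), seed = 1)
  p2 <- make_fake_prediction(rep(3, 4), seed = 2)

  # degenerate mixture reproduces the single model
  b1 <- bma_combine(list(p1, p2), c(1, 0))
  expect_equal(b1$site$mean, p1$site$mean, tolerance = 1e-12)
  expect_equal(b1$site_draws, p1$site_draws)

  # equal weights average the means exactly
  b <- bma_combine(list(p1, p2), c(0.5, 0.5))
  expect_equal(b$site$mean, (p1$site$mean + p2$site$mean) / 2,
               tolerance = 1e-12)

  # law of total variance: mixture variance >= weighted within variance
  w <- c(0.3, 0.7)
  bm <- bma_combine(list(p1, p2), w)
  within <- w[1] * apply(p1$site_draws, 2, var) +
    w[2] * apply(p2$site_draws, 2, var)
  expect_true(all(bm$site$var >= within - 1e-9))
  # between-model spread present: mixture var far exceeds within var
  expect_true(all(bm$site$var > within + 0.5))

  p3 <- make_fake_prediction(rep(1, 5), seed = 3)
  expect_error(bma_combine(list(p1, p3), c(0.5, 0.5)), "misaligned")
})
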