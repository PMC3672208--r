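test_that("layout generation is deterministic and honours separation", {
  cfg <- design_config(n_sites = 2, field_width = 100, field_height = 100,
                       seed = 7)
  a <- generate_layout(cfg)
  b <- generate_layout(cfg)
  expect_identical(a, b)
  expect_gte(pairwise_distances(a)$d_min, 0.75)

  co <- generate_layout(design_config(seed = 3))
  expect_equal(nrow(co), 17)
  expect_gte(pairwise_distances(co)$d_min, 0.75)
})

test_that("layout spans distances comparable to the emulated field", {
  dmax <- vapply(1:30, function(s) {
    pairwise_distances(generate_layout(design_config(seed = s)))$d_max
  }, 0)
  # field diagonal is 23.3 m; random layouts should approach it
  expect_true(all(dmax <= 23.4))
  expect_gt(stats::median(dmax), 15)
})

test_that("infeasible layouts error with advice", {
  # geometric impossibility caught at configuration time
  expect_error(design_config(n_sites = 10, field_width = 2,
                             field_height = 2, min_separation = 0.75),
               "not achievable")
  # a tight-but-legal config exhausts the placement attempts
  cfg <- design_config(n_sites = 10, field_width = 2.6,
                       field_height = 2.6, min_separation = 0.75,
                       seed = 1)
  expect_error(generate_layout(cfg, max_tries = 8), "enlarge the field")
})

test_that("covariates reproduce the target moments and constraints", {
  cfg <- design_config(n_sites = 60, n_replicates = 13, field_width = 50,
                       field_height = 50, seed = 11)
  co <- generate_layout(cfg)
  cv <- generate_covariates(co, cfg)
  expect_equal(mean(cv$moisture), 35.57, tolerance = 0.5 / 35.57)
  expect_equal(sd(cv$moisture), 9.27, tolerance = 0.5 / 9.27)
  expect_equal(mean(cv$temperature), 22.16, tolerance = 0.5 / 22.16)
  # texture sums to 100 per site after renormalisation
  expect_equal(cv$sand + cv$silt + cv$clay, rep(100, nrow(cv)),
               tolerance = 1e-9)
  expect_true(all(cv$ph >= 5.2 & cv$ph <= 6.4))
  expect_true(all(cv$no3 >= 0 & cv$no3 <= 90.34))
  # site-static covariates constant within site
  per_site <- tapply(cv$ph, cv$site_id, function(x) diff(range(x)))
  expect_true(all(per_site == 0))
})

test_that("zero-SD moments give exactly the mean for every covariate", {
  mom <- table1_moments()
  mom$sd <- 0
  cfg <- design_config(n_sites = 5, n_replicates = 3, moments = mom,
                       seed = 2)
  cv <- generate_covariates(generate_layout(cfg), cfg)
  for (v in mom$variable) {
    expect_equal(unique(cv[[v]]), mom$mean[mom$variable == v],
                 label = v)
  }
})

test_that("simulated GP effects follow the exponential covariance", {
  co <- random_layout(8, seed = 5)
  d <- pairwise_distances(co)$d
  theta <- 0.3; sigma_s2 <- 1.5
  ch <- chol(sigma_s2 * exp_correlation(d, theta))
  set.seed(10)
  draws <- matrix(rnorm(2000 * 8), 2000, 8) %*% ch
  emp <- cov(draws)
  expect_equal(unname(emp), unname(sigma_s2 * exp_correlation(d, theta)),
               tolerance = 0.12)
})

test_that("a huge decay rate decorrelates the most distant sites", {
  co <- random_layout(6, seed = 8)
  d <- pairwise_distances(co)
  phi <- exp_correlation(d, theta = 1e6)
  far <- which(d$d == d$d_max, arr.ind = TRUE)[1, ]
  expect_lt(phi[far[1], far[2]], 1e-12)
  set.seed(4)
  ch <- chol_def <- n2ospatial:::chol_with_jitter(phi)$chol
  draws <- matrix(rnorm(1000 * 6), 1000, 6) %*% ch
  expect_lt(abs(cor(draws[, far[1]], draws[, far[2]])), 0.1)
})

test_that("zero GP variance reduces the exp structure to independence", {
  co <- random_layout(5, seed = 6, width = 20, height = 20)
  cfg <- design_config(n_sites = 5, n_replicates = 3, field_width = 20,
                       field_height = 20, seed = 6)
  cv <- generate_covariates(co, cfg)
  sim <- simulate_fluxes(co, cv, generative_params("exp", sigma_s2 = 0),
                         seed = 3)
  expect_equal(attr(sim, "truth")$effect, rep(0, 5))
  # site-mean variance matches the independent structure across seeds
  var_site_means <- function(structure, seeds) {
    vapply(seeds, function(s) {
      si <- simulate_fluxes(co, cv, generative_params(
        structure, sigma_s2 = 0, sigma2 = 1.59), seed = s)
      var(rowMeans(si$y))
    }, 0)
  }
  v_exp <- var_site_means("exp", 1:100)
  v_ind <- var_site_means("independent", 1:100)
  expect_equal(mean(v_exp), mean(v_ind), tolerance = 0.25)
})

test_that("ICAR draws sum to zero and fluxes are reproducible", {
  sim <- quick_sim("icar", seed = 4)
  expect_lt(abs(sum(attr(sim$data, "truth")$effect)), 1e-12)

  f1 <- tempfile(); f2 <- tempfile()
  write_chamber_csv(quick_sim("exp", seed = 9), f1)
  write_chamber_csv(quick_sim("exp", seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
})

test_that("log fluxes are Gaussian given the parameters", {
  sim <- quick_sim("independent", seed = 12)
  pvals <- apply(sim$data$y, 1, function(r) stats::shapiro.test(r)$p.value)
  # per-site normality rejected at most occasionally at the 5% level
  expect_lt(mean(pvals < 0.05), 0.3)
})

test_that("a back-shift produces zero fluxes handled by the log shift", {
  co <- random_layout(5, seed = 1, width = 20, height = 20)
  cfg <- design_config(n_sites = 5, n_replicates = 6, field_width = 20,
                       field_height = 20, seed = 1)
  cv <- generate_covariates(co, cfg)
  sim <- simulate_fluxes(co, cv, generative_params("independent"),
                         seed = 2, back_shift = 20)
  expect_true(any(sim$flux == 0))
  expect_equal(sim$shift, min(sim$flux[sim$flux > 0]) / 2)
  expect_true(all(is.finite(sim$y)))
})
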