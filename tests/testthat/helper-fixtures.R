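# Shared fixtures and independent oracles used across the suite.

# Brute-force Thiessen adjacency oracle: two sites are neighbours iff a
# positive-length stretch of their perpendicular bisector, inside the
# boundary rectangle, is closer to these two sites than to any other.
# Implemented by dense sampling along each bisector — entirely independent
# of the package's half-plane polygon construction.
oracle_adjacency <- function(coords, boundary, n_samp = 8001L,
                             min_len = 1e-6) {
  q <- nrow(coords)
  p <- cbind(coords$x, coords$y)
  xmin <- boundary[["xmin"]]; xmax <- boundary[["xmax"]]
  ymin <- boundary[["ymin"]]; ymax <- boundary[["ymax"]]
  half_diag <- sqrt((xmax - xmin)^2 + (ymax - ymin)^2)
  w <- matrix(0, q, q)
  for (i in seq_len(q - 1L)) {
    for (j in (i + 1L):q) {
      mid <- (p[i, ] + p[j, ]) / 2
      v <- p[j, ] - p[i, ]
      t_hat <- c(-v[2L], v[1L]) / sqrt(sum(v^2))
      tt <- seq(-half_diag, half_diag, length.out = n_samp)
      step <- tt[2L] - tt[1L]
      px <- mid[1L] + tt * t_hat[1L]
      py <- mid[2L] + tt * t_hat[2L]
      inside <- px >= xmin & px <= xmax & py >= ymin & py <= ymax
      di <- sqrt((px - p[i, 1L])^2 + (py - p[i, 2L])^2)
      nearest <- rep(TRUE, n_samp)
      for (k in seq_len(q)) {
        if (k == i || k == j) next
        dk <- sqrt((px - p[k, 1L])^2 + (py - p[k, 2L])^2)
        nearest <- nearest & (dk > di)
      }
      ok <- inside & nearest
      r <- rle(ok)
      run <- if (any(r$values)) max(r$lengths[r$values]) else 0L
      if (run * step >= min_len) {
        w[i, j] <- 1
        w[j, i] <- 1
      }
    }
  }
  w
}

# Small random layout in a unit-ish field with a guaranteed separation.
random_layout <- function(q, seed, width = 10, height = 10,
                          min_sep = 0.4) {
  generate_layout(design_config(n_sites = q, field_width = width,
                                field_height = height,
                                min_separation = min_sep, seed = seed))
}

# Small simulated study for fast fitting tests.
quick_sim <- function(structure = "exp", seed = 1, ...) {
  simulate_chamber_study(design_config(seed = seed),
                         generative_params(structure, ...),
                         seed = seed)
}

# Short test chains (full-length defaults are production scale).
quick_mcmc <- function(seed = 1, n_iter = 3000, burn_in = 1000,
                       thin = 5) {
  mcmc_config(n_iter = n_iter, burn_in = burn_in, thin = thin,
              seed = seed)
}

# Manually constructed chamber dataset with well-conditioned covariates
# (texture NOT renormalised, so the design matrix is full rank).
full_rank_dataset <- function(q = 10, m = 6, seed = 1, sigma = 1,
                              beta = NULL) {
  set.seed(seed)
  coords <- site_coordinates(seq_len(q), runif(q, 0, 20), runif(q, 0, 20))
  tab <- expand.grid(replicate = seq_len(m), site_id = seq_len(q))
  n <- nrow(tab)
  covs <- matrix(rnorm(n * 7), n, 7)
  colnames(covs) <- c("moisture", "temperature", "no3", "ph", "sand",
                      "silt", "clay")
  if (is.null(beta)) beta <- c(1, 0.5, -0.3, 0.2, 0, 0.1, -0.1, 0.05)
  eta <- beta[1] + drop(covs %*% beta[-1])
  flux <- exp(eta + rnorm(n, 0, sigma))
  tab <- cbind(tab[, c("site_id", "replicate")], n2o_flux = flux,
               as.data.frame(covs))
  structure_out <- chamber_dataset(tab, coords)
  attr(structure_out, "beta_true") <- beta
  structure_out
}
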