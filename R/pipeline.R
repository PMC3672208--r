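#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow: input data (or the
#' synthetic design used to simulate it), which models to fit, MCMC
#' settings, prediction grid resolution, and the master seed from which
#' all stage seeds are derived.
#'
#' @param out_dir output directory (created if needed).
#' @param input_csv chamber CSV to analyse; `NULL` means the `simulate`
#'   stage must run first (its output is used).
#' @param models subset of `c("independent", "exp", "icar")`.
#' @param design a [design_config()] for the simulate stage.
#' @param params a [generative_params()] for the simulate stage.
#' @param mcmc an [mcmc_config()].
#' @param grid_res kriging grid resolution in metres (default 0.5).
#' @param seed master seed; stage seeds are derived from it.
#' @param quiet suppress progress messages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_csv = NULL,
                            models = c("independent", "exp", "icar"),
                            design = design_config(),
                            params = generative_params("exp"),
                            mcmc = mcmc_config(), grid_res = 0.5,
                            seed = 1L, quiet = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  structure(list(out_dir = out_dir, input_csv = input_csv,
                 models = models, design = design, params = params,
                 mcmc = mcmc, grid_res = grid_res,
                 seed = as.integer(seed), quiet = quiet),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `design`, `params` and `mcmc` may be nested maps passed to their
#' constructors.
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  args <- list(
    out_dir = raw$out_dir %||% ".",
    input_csv = raw$input_csv,
    models = raw$models %||% c("independent", "exp", "icar"),
    design = do.call(design_config, raw$design %||% list()),
    params = do.call(generative_params, raw$params %||% list()),
    mcmc = do.call(mcmc_config, raw$mcmc %||% list()),
    grid_res = raw$grid_res %||% 0.5,
    seed = raw$seed %||% 1L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(config) {
  logfile <- file.path(config$out_dir, "run.log")
  function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    if (!config$quiet) message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
}

require_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s' needs missing file %s (run earlier stages)",
                 stage, path), call. = FALSE)
  }
  path
}

#' Run the analysis pipeline
#'
#' Stages: `simulate` (write a synthetic chamber CSV plus the true
#' parameters), `fit` (Thiessen adjacency, distance matrix, one MCMC fit
#' per requested model; samples and run metadata written per model),
#' `compare` (DIC table and BMA weights), `predict` (site predictions,
#' coverage and SSR diagnostics, convergence report, BMA combination, and
#' kriged surfaces of predicted log-flux and spatial variation). `all`
#' runs everything in order. Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages, or `"all"`.
#' @return (invisibly) a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(config, stages = "all") {
  if (identical(stages, "all")) {
    stages <- c("simulate", "fit", "compare", "predict")
    if (!is.null(config$input_csv)) stages <- setdiff(stages, "simulate")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- pipeline_log(config)
  out <- list()
  for (stage in stages) {
    log("stage '%s' starting (seed %d)", stage, config$seed)
    out <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, out, log),
             fit = stage_fit(config, out, log),
             compare = stage_compare(config, out, log),
             predict = stage_predict(config, out, log),
             stop("unknown stage: ", stage)),
      error = function(e) {
        stop(sprintf("pipeline stage '%s' failed: %s", stage,
                     conditionMessage(e)), call. = FALSE)
      })
    log("stage '%s' done", stage)
  }
  invisible(out)
}

stage_simulate <- function(config, out, log) {
  sim <- simulate_chamber_study(config$design, config$params,
                                seed = config$seed)
  csv <- file.path(config$out_dir, "chamber.csv")
  write_chamber_csv(sim, csv)
  write_true_params(sim, file.path(config$out_dir, "true_params.yaml"))
  log("simulated %d sites x %d replicates (%s structure) -> %s",
      sim$data$Q, sim$data$M, config$params$structure, csv)
  out$sim <- sim
  out$data <- sim$data
  out
}

pipeline_data <- function(config, out, stage) {
  if (!is.null(out$data)) return(out$data)
  csv <- config$input_csv %||% file.path(config$out_dir, "chamber.csv")
  read_chamber_csv(require_file(csv, stage), quiet = config$quiet)
}

stage_fit <- function(config, out, log) {
  data <- pipeline_data(config, out, "fit")
  dist <- pairwise_distances(data$coords)
  weights <- thiessen_adjacency(data$coords)
  write_adjacency(weights, file.path(config$out_dir, "adjacency.txt"))
  write_distance_csv(dist, file.path(config$out_dir, "distances.csv"))
  fits <- list()
  for (model in config$models) {
    cfg <- config$mcmc
    cfg$seed <- derive_seed(config$seed, paste0("fit-", model))
    fit <- switch(model,
                  independent = fit_independent(data, config = cfg),
                  exp = fit_exp_geostat(data, dist, config = cfg),
                  icar = fit_icar(data, weights, config = cfg))
    write_samples_csv(fit, file.path(config$out_dir,
                                     paste0("samples_", model, ".csv")))
    meta <- list(model = model, seed = cfg$seed, n_iter = cfg$n_iter,
                 burn_in = cfg$burn_in, thin = cfg$thin,
                 n_kept = fit$n_kept, Q = fit$Q, M = fit$M,
                 accept_theta = fit$accept_theta,
                 mean_deviance = mean(fit$deviance))
    yaml::write_yaml(meta, file.path(config$out_dir,
                                     paste0("meta_", model, ".yaml")))
    log("fitted %s model: %d kept draws, mean deviance %.1f", model,
        fit$n_kept, mean(fit$deviance))
    fits[[model]] <- fit
  }
  out$data <- data
  out$dist <- dist
  out$weights <- weights
  out$fits <- fits
  out
}

stage_compare <- function(config, out, log) {
  data <- pipeline_data(config, out, "compare")
  if (is.null(out$fits)) {
    out$fits <- lapply(stats::setNames(config$models, config$models),
                       function(model) {
      read_samples_csv(require_file(
        file.path(config$out_dir, paste0("samples_", model, ".csv")),
        "compare"), model, data)
    })
  }
  dics <- lapply(out$fits, compute_dic, data = data)
  weights <- bma_weights(dics)
  tab <- write_dic_table(dics, weights,
                         file.path(config$out_dir, "dic_bma.csv"))
  log("DIC: %s; BMA weights: %s",
      paste(sprintf("%s=%.1f", tab$model, tab$DIC), collapse = ", "),
      paste(sprintf("%s=%.3f", tab$model, tab$posterior_prob),
            collapse = ", "))
  out$data <- data
  out$dics <- dics
  out$bma_weights <- weights
  out
}

stage_predict <- function(config, out, log) {
  if (is.null(out$dics)) out <- stage_compare(config, out, log)
  data <- out$data
  preds <- lapply(out$fits, posterior_predict, data = data,
                  seed = config$seed)
  diag_tab <- data.frame(
    model = names(preds),
    frac_outside_95 = vapply(preds, function(p) {
      coverage_check(NULL, p)
    }, 0),
    ssr = vapply(preds, function(p) sum_squared_residuals(NULL, p), 0)
  )
  utils::write.csv(diag_tab, file.path(config$out_dir, "fit_checks.csv"),
                   row.names = FALSE)
  for (model in names(preds)) {
    utils::write.csv(preds[[model]]$site,
                     file.path(config$out_dir,
                               paste0("site_pred_", model, ".csv")),
                     row.names = FALSE)
    conv <- convergence_report(out$fits[[model]])
    utils::write.csv(conv,
                     file.path(config$out_dir,
                               paste0("convergence_", model, ".csv")),
                     row.names = FALSE)
  }
  bma <- bma_combine(unname(preds), as.numeric(out$bma_weights),
                     seed = config$seed)
  utils::write.csv(bma$site, file.path(config$out_dir, "site_pred_bma.csv"),
                   row.names = FALSE)
  boundary <- default_boundary(data$coords)
  surfaces <- list()
  for (model in names(preds)) {
    surfaces[[model]] <- krige_prediction(preds[[model]], data$coords,
                                          boundary, config$grid_res)
    write_surface_csv(surfaces[[model]],
                      file.path(config$out_dir,
                                paste0("surface_", model, ".csv")))
  }
  bma_pred_for_krige <- list(site = data.frame(
    site_id = bma$site$site_id, mean = bma$site$mean,
    effect_mean = bma$effect$effect_mean))
  surfaces$bma <- krige_prediction(bma_pred_for_krige, data$coords,
                                   boundary, config$grid_res)
  write_surface_csv(surfaces$bma,
                    file.path(config$out_dir, "surface_bma.csv"))
  write_ascii_grid(surfaces$bma,
                   file.path(config$out_dir, "surface_bma.asc"))
  spatial_models <- intersect(names(preds), c("exp", "icar"))
  for (model in spatial_models) {
    sv <- krige_prediction(preds[[model]], data$coords, boundary,
                           config$grid_res, what = "effect")
    write_surface_csv(sv, file.path(config$out_dir,
                                    paste0("variation_", model, ".csv")))
  }
  log("coverage check: %s",
      paste(sprintf("%s %.1f%% outside", diag_tab$model,
                    100 * diag_tab$frac_outside_95), collapse = "; "))
  out$predictions <- preds
  out$bma <- bma
  out$surfaces <- surfaces
  out$fit_checks <- diag_tab
  out
}

#' Read persisted posterior samples back from CSV
#'
#' Reconstructs a `posterior_samples` object from [write_samples_csv()]
#' output (an independent re-evaluation path used both by the `compare`
#' stage and by DIC cross-checks).
#'
#' @param path samples CSV path.
#' @param model model tag (`"independent"`, `"exp"`, `"icar"`).
#' @param data the matching `chamber_dataset` (for dimensions).
#' @return A `posterior_samples` object.
#' @export
read_samples_csv <- function(path, model, data) {
  df <- utils::read.csv(path)
  beta_cols <- grep("^beta\\.", names(df))
  beta <- as.matrix(df[, beta_cols])
  colnames(beta) <- c("(Intercept)", COVARIATE_NAMES)
  eff_cols <- grep("^[su]\\.", names(df))
  effect <- if (length(eff_cols)) as.matrix(df[, eff_cols]) else NULL
  new_posterior_samples(model, beta, df$sigma2, df$deviance,
                        config = NULL, priors = NULL,
                        q = data$Q, m = data$M, effect = effect,
                        sigma_s2 = df$sigma_s2, theta = df$theta,
                        sigma_u2 = df$sigma_u2)
}
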