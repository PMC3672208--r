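CHAMBER_CSV_COLUMNS <- c("site_id", "x_m", "y_m", "replicate", "n2o_flux",
                         COVARIATE_NAMES)

#' Read a chamber flux CSV
#'
#' Expects one row per site x replicate with the header
#' `site_id,x_m,y_m,replicate,n2o_flux,moisture,temperature,no3,ph,sand,silt,clay`.
#' Validates completeness (every site carries the same replicates and fixed
#' coordinates), rejects negative fluxes, and applies the log transform
#' with the zero-shift rule (see [chamber_dataset()]). A short validation
#' report is emitted as a message.
#'
#' @param path CSV file path.
#' @param quiet suppress the validation report (default `FALSE`).
#' @return A `chamber_dataset`.
#' @export
read_chamber_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path)
  missing_cols <- setdiff(CHAMBER_CSV_COLUMNS, names(tab))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(tab$n2o_flux < 0, na.rm = TRUE)) {
    stop("negative fluxes present in ", path)
  }
  n_missing <- sum(!stats::complete.cases(tab[, CHAMBER_CSV_COLUMNS]))
  if (n_missing > 0) {
    stop(n_missing, " row(s) with missing values in ", path)
  }
  site_rows <- unique(tab[, c("site_id", "x_m", "y_m")])
  if (anyDuplicated(site_rows$site_id)) {
    stop("site ", site_rows$site_id[duplicated(site_rows$site_id)][1L],
         " has inconsistent coordinates across rows")
  }
  coords <- site_coordinates(site_rows$site_id, site_rows$x_m,
                             site_rows$y_m)
  data <- chamber_dataset(tab, coords)
  if (!quiet) {
    message(sprintf(
      "read %d sites x %d replicates from %s (log shift c = %g)",
      data$Q, data$M, path, data$shift))
  }
  data
}

#' Write a chamber dataset (or simulation) as the standard CSV
#'
#' @param data a `chamber_dataset` or `chamber_simulation`.
#' @param path output CSV path.
#' @export
write_chamber_csv <- function(data, path) {
  if (inherits(data, "chamber_simulation")) data <- data$data
  tab <- as_long_table(data)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write the true generative parameters of a simulation
#'
#' Sidecar YAML used by parameter-recovery checks.
#'
#' @param sim a `chamber_simulation`.
#' @param path output path.
#' @export
write_true_params <- function(sim, path) {
  truth <- attr(sim$data, "truth")
  p <- truth$params
  out <- list(structure = p$structure, beta = as.list(p$beta),
              sigma2 = p$sigma2, seed = sim$seed)
  if (!is.null(p$sigma_s2)) {
    out$sigma_s2 <- p$sigma_s2
    out$theta <- p$theta
  }
  if (!is.null(p$sigma_u2)) out$sigma_u2 <- p$sigma_u2
  out$effect <- as.numeric(truth$effect)
  yaml::write_yaml(out, path)
  invisible(path)
}
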