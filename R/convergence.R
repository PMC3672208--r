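# Effective sample size from the empirical autocorrelation function,
# truncated at the first non-positive lag (a simple initial-sequence rule).
ess_from_chain <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1L] - 1L)]
  n / (1 + 2 * sum(rho))
}

#' MCMC convergence diagnostics
#'
#' Per-parameter lag autocorrelations, effective sample size, and a
#' split-chain stationarity z-statistic (difference of the two half-chain
#' means scaled by their ESS-adjusted standard errors). Chains with zero
#' variance are flagged degenerate and get an undefined (NA) ESS.
#'
#' @param samples a `posterior_samples` object, or a numeric matrix with
#'   one column per parameter.
#' @param lags lags at which to report autocorrelation (default 1, 5, 10).
#' @return Data frame with one row per parameter: `parameter`, `mean`,
#'   `sd`, `acf_lag*`, `ess`, `split_z`, `degenerate`.
#' @export
convergence_report <- function(samples, lags = c(1L, 5L, 10L)) {
  mat <- if (is.matrix(samples)) {
    samples
  } else if (inherits(samples, "posterior_samples")) {
    m <- cbind(samples$beta, sigma2 = samples$sigma2)
    if (!is.null(samples$theta)) m <- cbind(m, theta = samples$theta)
    if (!is.null(samples$sigma_s2)) {
      m <- cbind(m, sigma_s2 = samples$sigma_s2)
    }
    if (!is.null(samples$sigma_u2)) {
      m <- cbind(m, sigma_u2 = samples$sigma_u2)
    }
    m
  } else {
    as.matrix(samples)
  }
  if (nrow(mat) < 100L) stop("need at least 100 retained draws")
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("param", seq_len(ncol(mat)))
  }
  out <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    n <- length(x)
    degenerate <- stats::sd(x) == 0
    ac <- rep(NA_real_, length(lags))
    split_z <- NA_real_
    ess <- NA_real_
    if (!degenerate) {
      full <- stats::acf(x, lag.max = max(lags), plot = FALSE)$acf
      ac <- full[lags + 1L]
      ess <- ess_from_chain(x)
      h <- n %/% 2L
      a <- x[seq_len(h)]; b <- x[(n - h + 1L):n]
      se2 <- stats::var(a) / max(ess_from_chain(a), 1) +
        stats::var(b) / max(ess_from_chain(b), 1)
      split_z <- (mean(a) - mean(b)) / sqrt(se2)
    }
    row <- data.frame(parameter = colnames(mat)[j], mean = mean(x),
                      sd = stats::sd(x), ess = ess, split_z = split_z,
                      degenerate = degenerate)
    for (i in seq_along(lags)) row[[paste0("acf_lag", lags[i])]] <- ac[i]
    row
  })
  do.call(rbind, out)
}

#' Trace and autocorrelation plots for a fitted chain
#'
#' @param samples a `posterior_samples` object.
#' @param parameters character vector of parameter names to plot (default:
#'   the first coefficient, `sigma2`, and the structure parameter if any).
#' @param file optional PNG path; `NULL` plots to the active device.
#' @export
plot_traces <- function(samples, parameters = NULL, file = NULL) {
  rep_tab <- convergence_report(samples)
  mat <- cbind(samples$beta, sigma2 = samples$sigma2)
  if (!is.null(samples$theta)) mat <- cbind(mat, theta = samples$theta)
  if (!is.null(samples$sigma_s2)) {
    mat <- cbind(mat, sigma_s2 = samples$sigma_s2)
  }
  if (!is.null(samples$sigma_u2)) {
    mat <- cbind(mat, sigma_u2 = samples$sigma_u2)
  }
  if (is.null(parameters)) {
    parameters <- intersect(c(colnames(samples$beta)[2L], "sigma2",
                              "theta", "sigma_s2", "sigma_u2"),
                            colnames(mat))
  }
  if (!is.null(file)) grDevices::png(file, width = 900, height = 300 *
                                       length(parameters))
  op <- graphics::par(mfrow = c(length(parameters), 2L),
                      mar = c(3, 3, 2, 1))
  on.exit({
    graphics::par(op)
    if (!is.null(file)) grDevices::dev.off()
  })
  for (p in parameters) {
    graphics::plot(mat[, p], type = "l", main = paste("trace:", p),
                   xlab = "", ylab = "")
    stats::acf(mat[, p], main = paste("acf:", p))
  }
  invisible(rep_tab)
}
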