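# Canonical covariate order used throughout: the K = 7 soil drivers of the
# flux regression.
COVARIATE_NAMES <- c("moisture", "temperature", "no3", "ph", "sand", "silt",
                     "clay")

#' Replicated chamber flux dataset
#'
#' Validates a long-format table of replicated chamber measurements and
#' packs it into the matrix/array layout the samplers use: a Q x M log-flux
#' matrix `y`, the natural-scale fluxes, and a Q x M x 7 covariate array in
#' canonical order (moisture, temperature, NO3-, pH, sand, silt, clay).
#'
#' Fluxes are log-transformed; when zero fluxes are present, `log(flux + c)`
#' is used with `c` equal to half the smallest positive flux (recorded in
#' the `shift` field), unless an explicit `shift` is supplied.
#'
#' @param table data frame with columns `site_id`, `replicate`, `n2o_flux`
#'   and the seven covariates.
#' @param coords a [site_coordinates()] object covering every `site_id`.
#' @param shift optional log-shift constant; `NULL` applies the zero-flux
#'   rule automatically.
#' @return An object of class `chamber_dataset` with fields `y`, `flux`,
#'   `xarr`, `coords`, `shift`, `Q`, `M`, `K`.
#' @export
chamber_dataset <- function(table, coords, shift = NULL) {
  coords <- as_site_coordinates(coords)
  needed <- c("site_id", "replicate", "n2o_flux", COVARIATE_NAMES)
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(table$n2o_flux))) stop("non-finite fluxes present")
  if (any(table$n2o_flux < 0)) stop("negative fluxes present")
  sites <- coords$site_id
  reps <- sort(unique(table$replicate))
  q <- length(sites); m <- length(reps)
  if (!setequal(unique(table$site_id), sites)) {
    stop("site ids in the table do not match the coordinates")
  }
  tab <- table[order(match(table$site_id, sites), table$replicate), ]
  if (nrow(tab) != q * m ||
      !all(tab$replicate == rep(reps, times = q))) {
    stop("non-rectangular layout: every site needs the same replicates")
  }
  flux <- matrix(tab$n2o_flux, nrow = q, ncol = m, byrow = TRUE,
                 dimnames = list(sites, reps))
  if (is.null(shift)) {
    shift <- if (any(flux == 0)) min(flux[flux > 0]) / 2 else 0
  }
  y <- log(flux + shift)
  xarr <- array(NA_real_, dim = c(q, m, length(COVARIATE_NAMES)),
                dimnames = list(sites, reps, COVARIATE_NAMES))
  for (k in seq_along(COVARIATE_NAMES)) {
    xarr[, , k] <- matrix(tab[[COVARIATE_NAMES[k]]], nrow = q, ncol = m,
                          byrow = TRUE)
  }
  if (q * m < length(COVARIATE_NAMES) + 2L) {
    stop("too few observations for a ", length(COVARIATE_NAMES) + 1L,
         "-parameter regression")
  }
  structure(list(y = y, flux = flux, xarr = xarr, coords = coords,
                 shift = shift, Q = q, M = m,
                 K = length(COVARIATE_NAMES)),
            class = "chamber_dataset")
}

#' @export
print.chamber_dataset <- function(x, ...) {
  cat(sprintf(
    "chamber_dataset: %d sites x %d replicates, %d covariates\n",
    x$Q, x$M, x$K))
  cat(sprintf("  log shift constant: %g\n", x$shift))
  cat(sprintf("  log-flux range: [%.3f, %.3f]\n", min(x$y), max(x$y)))
  invisible(x)
}

# N x (K+1) design matrix (intercept first), rows site-major:
# n = (i-1)*M + r.  Companion vectors: site index and response.
model_matrix <- function(data) {
  q <- data$Q; m <- data$M; k <- data$K
  x <- matrix(NA_real_, nrow = q * m, ncol = k)
  for (j in seq_len(k)) x[, j] <- as.vector(t(data$xarr[, , j]))
  x <- cbind(`(Intercept)` = 1, x)
  colnames(x) <- c("(Intercept)", COVARIATE_NAMES)
  x
}

response_vector <- function(data) as.vector(t(data$y))

site_index <- function(data) rep(seq_len(data$Q), each = data$M)

# Long-format view of a chamber_dataset (inverse of the constructor).
as_long_table <- function(data) {
  q <- data$Q; m <- data$M
  tab <- data.frame(
    site_id = rep(data$coords$site_id, each = m),
    x_m = rep(data$coords$x, each = m),
    y_m = rep(data$coords$y, each = m),
    replicate = rep(as.integer(colnames(data$y)), times = q),
    n2o_flux = as.vector(t(data$flux))
  )
  for (k in COVARIATE_NAMES) {
    tab[[k]] <- as.vector(t(data$xarr[, , k]))
  }
  tab
}
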