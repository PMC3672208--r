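# Exponential semivariogram with practical range `range` (the lag at which
# ~95% of the sill is reached): gamma(h) = nugget + psill (1 - exp(-3h/a)).
variogram_value <- function(h, nugget, psill, range) {
  ifelse(h <= 0, 0, nugget + psill * (1 - exp(-3 * h / range)))
}

#' Fit an exponential variogram to site values
#'
#' Binned method-of-moments empirical semivariogram, fitted by weighted
#' least squares (weights = pair counts per bin) with an exponential model
#' `gamma(h) = nugget + psill (1 - exp(-3 h / range))`, so `range` is the
#' practical range. When the fitted range collapses onto its lower bound
#' (no spatial structure resolvable below the first lag), the model is
#' folded into a pure-nugget fit; a constant field returns a degenerate
#' pure-nugget model with zero sill.
#'
#' @param site_values numeric vector of site-level values.
#' @param coords matching [site_coordinates()].
#' @param n_bins number of distance bins (default 8).
#' @param max_lag largest lag used (default 2/3 of the maximum distance).
#' @return A list of class `variogram_model`: `nugget`, `psill`,
#'   `sill = nugget + psill`, `range`, `degenerate`, `empirical` (binned
#'   lag/semivariance/count table).
#' @export
fit_variogram <- function(site_values, coords, n_bins = 8L,
                          max_lag = NULL) {
  coords <- as_site_coordinates(coords)
  z <- as.numeric(site_values)
  if (length(z) != nrow(coords)) stop("site_values do not match coords")
  if (length(z) < 5L) stop("need at least 5 sites to fit a variogram")
  d <- pairwise_distances(coords)$d
  ut <- upper.tri(d)
  h <- d[ut]
  gam <- 0.5 * (outer(z, z, `-`)^2)[ut]
  if (is.null(max_lag)) max_lag <- max(h) * 2 / 3
  use <- h <= max_lag
  breaks <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(h[use], breaks, include.lowest = TRUE)
  emp <- data.frame(
    lag = tapply(h[use], bin, mean),
    gamma = tapply(gam[use], bin, mean),
    n = as.integer(table(bin))
  )
  emp <- emp[emp$n > 0L & is.finite(emp$gamma), ]

  vz <- stats::var(z)
  if (vz < 1e-12) {
    return(structure(list(nugget = 0, psill = 0, sill = 0,
                          range = max(h) / 3, degenerate = TRUE,
                          empirical = emp),
                     class = "variogram_model"))
  }
  range_lo <- max(min(emp$lag), max(h) / 50)
  obj <- function(par) {
    fit <- variogram_value(emp$lag, par[1L], par[2L], par[3L])
    sum(emp$n * (emp$gamma - fit)^2)
  }
  best <- NULL
  for (start_range in c(max(h) / 6, max(h) / 3, max(h))) {
    o <- stats::optim(c(0.1 * vz, 0.9 * vz, start_range), obj,
                      method = "L-BFGS-B",
                      lower = c(0, 1e-10, range_lo),
                      upper = c(5 * vz, 10 * vz, 2 * max(h)))
    if (is.null(best) || o$value < best$value) best <- o
  }
  par <- best$par
  nugget <- par[1L]; psill <- par[2L]; range <- par[3L]
  if (range <= 1.05 * range_lo) {
    # structure below the first resolvable lag: pure nugget
    nugget <- nugget + psill
    psill <- 1e-10
  }
  structure(list(nugget = nugget, psill = psill, sill = nugget + psill,
                 range = range, degenerate = FALSE, empirical = emp),
            class = "variogram_model")
}

#' Regular prediction grid over a rectangle
#'
#' @param boundary a [field_rectangle()] (or anything with xmin/xmax/
#'   ymin/ymax entries).
#' @param resolution node spacing in metres (default 0.5).
#' @return Data frame of `x`, `y` node coordinates.
#' @export
make_grid <- function(boundary, resolution = 0.5) {
  stopifnot(resolution > 0)
  xs <- seq(boundary[["xmin"]], boundary[["xmax"]], by = resolution)
  ys <- seq(boundary[["ymin"]], boundary[["ymax"]], by = resolution)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Ordinary kriging of site values onto a grid
#'
#' Solves the standard ordinary-kriging system (semivariogram form with the
#' unbiasedness constraint `sum(lambda) = 1`) at every grid node, returning
#' the kriged value and kriging variance. With a zero nugget the surface
#' honours the data exactly at nodes coinciding with sites.
#'
#' @param site_values numeric vector of site-level values.
#' @param coords matching [site_coordinates()].
#' @param grid data frame of `x`, `y` nodes from [make_grid()].
#' @param variogram a `variogram_model` from [fit_variogram()].
#' @return A list of class `prediction_surface`: `grid` (data frame with
#'   `x`, `y`, `value`, `variance`), `variogram`, `max_weight_error`
#'   (largest deviation of any node's weight sum from 1).
#' @export
krige <- function(site_values, coords, grid, variogram) {
  coords <- as_site_coordinates(coords)
  z <- as.numeric(site_values)
  q <- nrow(coords)
  stopifnot(length(z) == q)
  p <- cbind(coords$x, coords$y)
  gmat <- if (q > 1L) {
    variogram_value(as.matrix(stats::dist(p)), variogram$nugget,
                    variogram$psill, variogram$range)
  } else matrix(0, 1L, 1L)
  diag(gmat) <- 0
  a <- rbind(cbind(gmat, 1), c(rep(1, q), 0))

  dx <- outer(grid$x, coords$x, `-`)
  dy <- outer(grid$y, coords$y, `-`)
  h0 <- sqrt(dx * dx + dy * dy)
  g0 <- variogram_value(h0, variogram$nugget, variogram$psill,
                        variogram$range)
  g0[h0 == 0] <- 0
  rhs <- rbind(t(g0), 1)

  sol <- tryCatch(solve(a, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    a[seq_len(q), seq_len(q)] <- a[seq_len(q), seq_len(q)] +
      diag(1e-10, q)
    sol <- solve(a, rhs)   # errors if still singular
  }
  lambda <- sol[seq_len(q), , drop = FALSE]
  mu <- sol[q + 1L, ]
  wsum_err <- max(abs(colSums(lambda) - 1))
  if (wsum_err > 1e-6) {
    stop("kriging weights failed the unbiasedness constraint")
  }
  value <- drop(crossprod(lambda, z))
  variance <- pmax(colSums(lambda * t(g0)) + mu, 0)
  structure(list(grid = data.frame(x = grid$x, y = grid$y, value = value,
                                   variance = variance),
                 variogram = variogram, max_weight_error = wsum_err),
            class = "prediction_surface")
}

#' Krige site-level posterior predictions over the field
#'
#' Convenience wrapper: fits the variogram to the site-level posterior
#' summaries and interpolates them (and optionally the posterior-mean
#' spatial effects) on a regular grid, matching the study workflow of
#' interpolating model predictions rather than raw data.
#'
#' @param prediction a `site_prediction` or `bma_result`.
#' @param coords the site layout.
#' @param boundary clipping rectangle (default: coordinate bounding box
#'   expanded 10%).
#' @param resolution grid spacing in metres (default 0.5).
#' @param what `"mean"` (site posterior predictive mean log-flux) or
#'   `"effect"` (posterior mean spatial effect).
#' @return A `prediction_surface`.
#' @export
krige_prediction <- function(prediction, coords, boundary = NULL,
                             resolution = 0.5,
                             what = c("mean", "effect")) {
  what <- match.arg(what)
  coords <- as_site_coordinates(coords)
  if (is.null(boundary)) boundary <- default_boundary(coords)
  values <- if (what == "mean") {
    prediction$site$mean
  } else if (!is.null(prediction$site$effect_mean)) {
    prediction$site$effect_mean
  } else {
    prediction$effect$effect_mean
  }
  vg <- fit_variogram(values, coords)
  krige(values, coords, make_grid(boundary, resolution), vg)
}

#' Write a surface as x,y,value,variance CSV
#'
#' @param surface a `prediction_surface`.
#' @param path output path.
#' @export
write_surface_csv <- function(surface, path) {
  utils::write.csv(surface$grid, path, row.names = FALSE)
  invisible(path)
}

#' Write a surface as an ESRI-ASCII-style grid
#'
#' Nodes must form a regular grid (as produced by [make_grid()]).
#'
#' @param surface a `prediction_surface`.
#' @param path output path.
#' @param field `"value"` or `"variance"`.
#' @export
write_ascii_grid <- function(surface, path, field = "value") {
  g <- surface$grid
  xs <- sort(unique(g$x)); ys <- sort(unique(g$y))
  cell <- if (length(xs) > 1L) xs[2L] - xs[1L] else 1
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(g$y, ys), match(g$x, xs))] <- g[[field]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", length(xs)),
    sprintf("nrows %d", length(ys)),
    sprintf("xllcorner %g", min(xs) - cell / 2),
    sprintf("yllcorner %g", min(ys) - cell / 2),
    sprintf("cellsize %g", cell),
    "NODATA_value -9999"
  ), con)
  for (r in rev(seq_along(ys))) {
    writeLines(paste(formatC(m[r, ], format = "g", digits = 8),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @export
plot.prediction_surface <- function(x, field = "value", ...) {
  g <- x$grid
  xs <- sort(unique(g$x)); ys <- sort(unique(g$y))
  m <- matrix(NA_real_, length(xs), length(ys))
  m[cbind(match(g$x, xs), match(g$y, ys))] <- g[[field]]
  graphics::image(xs, ys, m, xlab = "x (m)", ylab = "y (m)",
                  main = paste("kriged", field), ...)
  invisible(x)
}
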