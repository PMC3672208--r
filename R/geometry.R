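#' Site coordinates for a chamber layout
#'
#' Builds and validates a set of point-referenced chamber locations in a
#' planar field frame (metres, origin at a field corner).
#'
#' @param site_id integer vector of unique site labels.
#' @param x,y numeric vectors of planar coordinates in metres.
#' @return A data frame of class `site_coordinates` with columns
#'   `site_id`, `x`, `y`.
#' @export
site_coordinates <- function(site_id, x, y) {
  stopifnot(length(site_id) == length(x), length(x) == length(y))
  if (length(x) < 2L) stop("at least 2 sites are required")
  if (anyDuplicated(site_id)) stop("site_id values must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("coordinates must be finite")
  }
  coords <- data.frame(site_id = as.integer(site_id), x = as.numeric(x),
                       y = as.numeric(y))
  dup <- duplicated(coords[, c("x", "y")])
  if (any(dup)) {
    i <- which(dup)[1L]
    j <- which(coords$x == coords$x[i] & coords$y == coords$y[i])[1L]
    stop(sprintf("sites %d and %d have coincident coordinates (%.3f, %.3f)",
                 coords$site_id[j], coords$site_id[i], coords$x[i],
                 coords$y[i]))
  }
  class(coords) <- c("site_coordinates", "data.frame")
  coords
}

#' Pairwise Euclidean distance matrix between sites
#'
#' @param coords a [site_coordinates()] object (or data frame with `x`, `y`).
#' @return A list of class `distance_matrix`: `d` (Q x Q symmetric matrix,
#'   metres), `d_min` and `d_max` over distinct pairs. `d_min`/`d_max` feed
#'   the decay-parameter prior bounds of the geostatistical model.
#' @export
pairwise_distances <- function(coords) {
  coords <- as_site_coordinates(coords)
  p <- cbind(coords$x, coords$y)
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(coords$site_id, coords$site_id)
  off <- d[upper.tri(d)]
  if (any(off <= 0)) {
    idx <- which(upper.tri(d) & d <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("sites %s and %s are coincident (zero distance)",
                 rownames(d)[idx[1L]], colnames(d)[idx[2L]]))
  }
  structure(list(d = d, d_min = min(off), d_max = max(off)),
            class = "distance_matrix")
}

as_site_coordinates <- function(coords) {
  if (inherits(coords, "site_coordinates")) return(coords)
  if (is.data.frame(coords) && all(c("x", "y") %in% names(coords))) {
    id <- if ("site_id" %in% names(coords)) coords$site_id
          else seq_len(nrow(coords))
    return(site_coordinates(id, coords$x, coords$y))
  }
  if (is.matrix(coords) && ncol(coords) == 2L) {
    return(site_coordinates(seq_len(nrow(coords)), coords[, 1L],
                            coords[, 2L]))
  }
  stop("cannot interpret 'coords' as site coordinates")
}

#' Rectangle helper for clipping Thiessen polygons
#'
#' @param xmin,xmax,ymin,ymax rectangle limits in metres.
#' @return A named numeric vector of class `field_rectangle`.
#' @export
field_rectangle <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmin < xmax, ymin < ymax)
  structure(c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "field_rectangle")
}

default_boundary <- function(coords, margin = 0.1) {
  rx <- range(coords$x); ry <- range(coords$y)
  mx <- max(diff(rx), 1e-6) * margin
  my <- max(diff(ry), 1e-6) * margin
  field_rectangle(rx[1L] - mx, rx[2L] + mx, ry[1L] - my, ry[2L] + my)
}

rect_polygon <- function(b) {
  cbind(x = c(b[["xmin"]], b[["xmax"]], b[["xmax"]], b[["xmin"]]),
        y = c(b[["ymin"]], b[["ymin"]], b[["ymax"]], b[["ymax"]]))
}

# Sutherland-Hodgman clip of polygon `poly` (n x 2) by the half-plane
# { p : (p - m) . n >= 0 }.
clip_halfplane <- function(poly, m, n) {
  if (nrow(poly) == 0L) return(poly)
  s <- (poly[, 1L] - m[1L]) * n[1L] + (poly[, 2L] - m[2L]) * n[2L]
  k <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    pi <- poly[i, ]; pj <- poly[j, ]
    si <- s[i]; sj <- s[j]
    if (si >= 0) out <- rbind(out, pi)
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      t <- si / (si - sj)
      out <- rbind(out, pi + t * (pj - pi))
    }
  }
  out
}

# Voronoi cell of site i clipped to the boundary rectangle: successive
# half-plane clips against the bisector with every other site.
voronoi_cell <- function(coords, i, boundary) {
  poly <- rect_polygon(boundary)
  pi <- c(coords$x[i], coords$y[i])
  for (j in seq_len(nrow(coords))) {
    if (j == i) next
    pj <- c(coords$x[j], coords$y[j])
    m <- (pi + pj) / 2
    n <- pi - pj                      # keep side closer to i
    poly <- clip_halfplane(poly, m, n)
    if (nrow(poly) < 3L) break
  }
  poly
}

# Total length of the edges of `poly` lying on the bisector line of (pi, pj).
shared_edge_length <- function(poly, pi, pj, tol = 1e-7) {
  if (nrow(poly) < 2L) return(0)
  m <- (pi + pj) / 2
  n <- (pi - pj)
  n <- n / sqrt(sum(n^2))
  s <- abs((poly[, 1L] - m[1L]) * n[1L] + (poly[, 2L] - m[2L]) * n[2L])
  on_line <- s < tol
  len <- 0
  k <- nrow(poly)
  for (a in seq_len(k)) {
    b <- if (a == k) 1L else a + 1L
    if (on_line[a] && on_line[b]) {
      len <- len + sqrt(sum((poly[a, ] - poly[b, ])^2))
    }
  }
  len
}

is_collinear <- function(coords, tol = 1e-9) {
  p <- cbind(coords$x, coords$y)
  if (nrow(p) < 3L) return(TRUE)
  p0 <- p[1L, ]
  v <- sweep(p[-1L, , drop = FALSE], 2L, p0)
  # largest cross product magnitude relative to the layout scale
  ref <- v[which.max(rowSums(v^2)), ]
  scale <- max(sqrt(rowSums(v^2)))
  if (scale == 0) return(TRUE)
  cross <- abs(v[, 1L] * ref[2L] - v[, 2L] * ref[1L]) / scale^2
  all(cross < tol)
}

#' First-order Thiessen-polygon adjacency
#'
#' Converts point-referenced sites to areal neighbourhoods: each site's
#' Thiessen (Voronoi) polygon is constructed inside a clipping rectangle,
#' and two sites are neighbours (`w_ij = 1`) exactly when their clipped
#' polygons share a boundary edge of strictly positive length. Cells that
#' touch only at a point (the four-corner degeneracy) are not neighbours.
#'
#' @param coords a [site_coordinates()] object.
#' @param boundary a [field_rectangle()] containing all sites, or `NULL` to
#'   use the coordinate bounding box expanded by `margin` on each side.
#' @param margin fractional expansion of the bounding box when `boundary`
#'   is `NULL` (default 0.1).
#' @param edge_tol minimum shared-edge length (metres) to count as a
#'   boundary (default 1e-9; breaks point-contact ties deterministically).
#' @return A list of class `spatial_weights`: `w` (Q x Q symmetric 0/1
#'   matrix, zero diagonal), `row_sums` (neighbour counts `w_i+`),
#'   `boundary` (the clipping rectangle used).
#' @export
thiessen_adjacency <- function(coords, boundary = NULL, margin = 0.1,
                               edge_tol = 1e-9) {
  coords <- as_site_coordinates(coords)
  q <- nrow(coords)
  if (is.null(boundary)) boundary <- default_boundary(coords, margin)
  if (!inherits(boundary, "field_rectangle")) {
    boundary <- do.call(field_rectangle, as.list(unname(boundary[
      c("xmin", "xmax", "ymin", "ymax")])))
  }
  outside <- coords$x < boundary[["xmin"]] | coords$x > boundary[["xmax"]] |
    coords$y < boundary[["ymin"]] | coords$y > boundary[["ymax"]]
  if (any(outside)) {
    stop(sprintf("site %d lies outside the clipping boundary",
                 coords$site_id[which(outside)[1L]]))
  }
  w <- matrix(0, q, q, dimnames = list(coords$site_id, coords$site_id))
  if (is_collinear(coords)) {
    warning("all sites are collinear; using 1-D chain adjacency")
    # order along the dominant direction of the layout
    dx <- coords$x - mean(coords$x); dy <- coords$y - mean(coords$y)
    dir <- if (stats::var(dx) >= stats::var(dy)) dx else dy
    ord <- order(dir)
    for (k in seq_len(q - 1L)) {
      w[ord[k], ord[k + 1L]] <- 1
      w[ord[k + 1L], ord[k]] <- 1
    }
  } else {
    cells <- lapply(seq_len(q), function(i) voronoi_cell(coords, i, boundary))
    p <- cbind(coords$x, coords$y)
    for (i in seq_len(q - 1L)) {
      for (j in (i + 1L):q) {
        len <- shared_edge_length(cells[[i]], p[i, ], p[j, ])
        if (len > edge_tol) {
          w[i, j] <- 1
          w[j, i] <- 1
        }
      }
    }
  }
  rs <- rowSums(w)
  if (any(rs == 0)) {
    stop(sprintf("site %d has no Thiessen neighbours",
                 coords$site_id[which(rs == 0)[1L]]))
  }
  structure(list(w = w, row_sums = rs, boundary = boundary),
            class = "spatial_weights")
}

#' Write adjacency as an edge list
#'
#' One `site_i,site_j` line per undirected edge with `site_i < site_j`.
#'
#' @param weights a `spatial_weights` object.
#' @param path output file path.
#' @export
write_adjacency <- function(weights, path) {
  w <- weights$w
  ids <- as.integer(rownames(w))
  idx <- which(upper.tri(w) & w == 1, arr.ind = TRUE)
  lines <- sprintf("%d,%d", ids[idx[, 1L]], ids[idx[, 2L]])
  writeLines(lines[order(idx[, 1L], idx[, 2L])], path)
  invisible(path)
}

#' Write a distance matrix as CSV
#'
#' @param dist a `distance_matrix` object.
#' @param path output file path.
#' @export
write_distance_csv <- function(dist, path) {
  utils::write.csv(as.data.frame(dist$d), path, row.names = TRUE)
  invisible(path)
}
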