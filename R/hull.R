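# Convex-hull primitives for small point sets (<= a few dozen points in
# low dimension), used by the functional-richness and functional-divergence
# indices. Facets are enumerated by brute force: every d-subset spanning a
# hyperplane with all remaining points on one side is a (part of a) facet.
# This is exact and fast at the problem sizes of trait spaces (n <= 16,
# d <= 5); 1-D and 2-D inputs take closed-form fast paths.

# simplex volume spanned by rows of x (d+1 points in d dims)
.simplex_volume <- function(x) {
  d <- ncol(x)
  abs(det(x[-1L, , drop = FALSE] - matrix(x[1L, ], d, d, byrow = TRUE))) /
    factorial(d)
}

# polygon area from vertices in hull order (shoelace)
.polygon_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1L)
  abs(sum(v[, 1L] * v[i2, 2L] - v[i2, 1L] * v[, 2L])) / 2
}

# facets of the convex hull as a list of point-index vectors (d >= 3)
.hull_facets <- function(x, tol) {
  n <- nrow(x)
  d <- ncol(x)
  combs <- utils::combn(n, d)
  seen <- character(0)
  facets <- list()
  for (k in seq_len(ncol(combs))) {
    idx <- combs[, k]
    pts <- x[idx, , drop = FALSE]
    diffs <- pts[-1L, , drop = FALSE] - matrix(pts[1L, ], d - 1L, d, byrow = TRUE)
    qrd <- qr(t(diffs))
    if (qrd$rank < d - 1L) next  # degenerate subset
    normal <- qr.Q(qrd, complete = TRUE)[, d, drop = TRUE]
    s <- (x - matrix(pts[1L, ], n, d, byrow = TRUE)) %*% normal
    if (all(s >= -tol) || all(s <= tol)) {
      on_plane <- which(abs(s) <= tol)
      key <- paste(sort(on_plane), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        facets[[length(facets) + 1L]] <- sort(on_plane)
      }
    }
  }
  facets
}

#' Convex-hull volume of a point set
#'
#' Exact hull volume for small point sets in arbitrary (low) dimension:
#' range length in 1-D, shoelace polygon area in 2-D, and brute-force facet
#' enumeration with recursive facet triangulation in higher dimensions.
#' Point sets that do not span the full dimension have volume 0.
#'
#' @param x Numeric matrix, one point per row.
#' @return The d-dimensional hull volume (a length, area, volume, ...).
#' @examples
#' convhull_volume(rbind(c(0, 0), c(1, 0), c(0, 1)))  # 0.5
#' @export
convhull_volume <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (n < d + 1L) return(0)
  if (d == 1L) return(diff(range(x[, 1L])))
  if (d == 2L) {
    v <- grDevices::chull(x[, 1L], x[, 2L])
    if (length(v) < 3L) return(0)
    return(.polygon_area(x[v, , drop = FALSE]))
  }
  scale <- max(1, max(abs(x)))
  tol <- 1e-9 * scale
  if (qr(sweep(x, 2L, colMeans(x)))$rank < d) return(0)
  facets <- .hull_facets(x, tol)
  o <- colMeans(x)
  vol <- 0
  for (f in facets) {
    pts <- x[f, , drop = FALSE]
    diffs <- pts[-1L, , drop = FALSE] -
      matrix(pts[1L, ], nrow(pts) - 1L, d, byrow = TRUE)
    qrd <- qr(t(diffs))
    basis <- qr.Q(qrd, complete = TRUE)
    normal <- basis[, d]
    h <- abs(sum((o - pts[1L, ]) * normal))
    proj <- (pts - matrix(pts[1L, ], nrow(pts), d, byrow = TRUE)) %*%
      basis[, seq_len(d - 1L), drop = FALSE]
    vol <- vol + convhull_volume(proj) * h / d
  }
  vol
}

#' Convex-hull vertices of a point set
#'
#' @param x Numeric matrix, one point per row.
#' @return Integer row indices of the points that are hull vertices (for a
#'   degenerate set that does not span its dimension, the extreme points
#'   along the spanned subspace are still returned via recursion on the
#'   reduced coordinates).
#' @export
convhull_vertices <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  d <- ncol(x)
  if (n <= d + 1L) return(seq_len(n))
  if (d == 1L) return(sort(unique(c(which.min(x[, 1L]), which.max(x[, 1L])))))
  if (d == 2L) return(sort(grDevices::chull(x[, 1L], x[, 2L])))
  centred <- sweep(x, 2L, colMeans(x))
  qrd <- qr(centred)
  if (qrd$rank < d) {
    # project onto the spanned subspace and recurse
    basis <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
    return(convhull_vertices(centred %*% basis))
  }
  scale <- max(1, max(abs(x)))
  facets <- .hull_facets(x, 1e-9 * scale)
  sort(unique(unlist(facets)))
}
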