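#' Gower distances among species from a trait table
#'
#' Classical Gower dissimilarity for quantitative traits: for each pair of
#' species, the absolute trait differences are divided by the trait's
#' range over the pool and averaged over traits, giving distances in
#' \[0, 1\].
#'
#' @param traits A data frame with a `species` column plus numeric trait
#'   columns, or a numeric matrix with species as rownames.
#' @return A symmetric distance matrix with zero diagonal and species
#'   names as dimnames.
#' @examples
#' tr <- data.frame(species = c("a", "b", "c"), x = c(0, 1, 2), y = c(0, 0, 4))
#' gower_distances(tr)
#' @export
gower_distances <- function(traits) {
  m <- .trait_matrix(traits)
  rng <- apply(m, 2L, function(x) diff(range(x)))
  if (any(rng <= 0)) {
    stop("trait(s) with zero range across the pool: ",
         paste(colnames(m)[rng <= 0], collapse = ", "), call. = FALSE)
  }
  scaled <- sweep(m, 2L, rng, "/")
  d <- as.matrix(stats::dist(scaled, method = "manhattan")) / ncol(m)
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

.trait_matrix <- function(traits) {
  if (is.data.frame(traits) && "species" %in% names(traits)) {
    m <- as.matrix(traits[, setdiff(names(traits), "species"), drop = FALSE])
    rownames(m) <- traits$species
  } else {
    m <- as.matrix(traits)
  }
  if (!is.numeric(m)) stop("traits must be numeric", call. = FALSE)
  if (any(!is.finite(m))) stop("traits contain missing values", call. = FALSE)
  m
}

#' Embed a distance matrix by principal coordinates analysis
#'
#' Metric embedding of species distances into Euclidean coordinates via
#' eigendecomposition of the doubly centred squared-distance matrix
#' (delegated to [ape::pcoa()]). When negative eigenvalues occur (the
#' distance is not Euclidean-embeddable), the requested correction is
#' applied; with the default Cailliez correction the corrected distances
#' are exactly reproduced by the retained coordinates. Axes with
#' eigenvalue below `1e-9` times the largest are dropped.
#'
#' @param distances A symmetric distance matrix or `dist` object.
#' @param correction One of `"cailliez"` (default), `"lingoes"`, `"none"`.
#' @return An object of class `functional_space`: a list with `coords`
#'   (species x axes matrix), `eig` (retained eigenvalues), `correction`
#'   (the tag actually applied: corrections only activate when negative
#'   eigenvalues occur), and `distances` (the input matrix).
#' @export
pcoa_embed <- function(distances, correction = c("cailliez", "lingoes", "none")) {
  correction <- match.arg(correction)
  d <- as.matrix(distances)
  stopifnot(nrow(d) == ncol(d), isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(abs(diag(d)) < 1e-12))
  if (nrow(d) == 2L) {
    # trivial one-axis embedding; below ape::pcoa's minimum size
    coords <- matrix(c(-d[1L, 2L] / 2, d[1L, 2L] / 2), ncol = 1L,
                     dimnames = list(rownames(d), "Axis.1"))
    return(structure(list(coords = coords, eig = d[1L, 2L]^2 / 2,
                          correction = "none", distances = d),
                     class = "functional_space"))
  }
  fit <- ape::pcoa(stats::as.dist(d), correction = if (correction == "none")
    "none" else correction)
  corrected <- !is.null(fit$vectors.cor)
  coords <- if (corrected) fit$vectors.cor else fit$vectors
  eig <- if (corrected) fit$values$Corr_eig else fit$values$Eigenvalues
  eig <- eig[seq_len(ncol(coords))]
  keep <- which(eig > 1e-9 * max(eig))
  coords <- coords[, keep, drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis.", seq_along(keep))
  structure(list(coords = coords, eig = eig[keep],
                 correction = if (corrected) correction else "none",
                 distances = d),
            class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat(sprintf("<functional_space: %d species, %d axes, correction: %s>\n",
              nrow(x$coords), ncol(x$coords), x$correction))
  invisible(x)
}

.space_coords <- function(space) {
  if (inherits(space, "functional_space")) space$coords else as.matrix(space)
}

# align an abundance vector to coordinate rownames; abundances may be a
# named vector or in rowname order
.align_abund <- function(abund, coords) {
  if (!is.null(names(abund))) {
    missing <- setdiff(names(abund)[abund > 0], rownames(coords))
    if (length(missing) > 0)
      stop("species missing from the functional space: ",
           paste(missing, collapse = ", "), call. = FALSE)
    full <- stats::setNames(numeric(nrow(coords)), rownames(coords))
    full[names(abund)] <- abund
    full
  } else {
    stopifnot(length(abund) == nrow(coords))
    stats::setNames(as.numeric(abund), rownames(coords))
  }
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean distance of species to the abundance-weighted
#' centroid of the community in the ordination space. Defined for any
#' community with positive total abundance; 0 for a monoculture.
#'
#' @param space A `functional_space` from [pcoa_embed()], or a coordinate
#'   matrix (species x axes).
#' @param abundances Nonnegative abundances, named by species or in
#'   coordinate row order.
#' @return FDis (>= 0).
#' @export
functional_dispersion <- function(space, abundances) {
  coords <- .space_coords(space)
  a <- .align_abund(abundances, coords)
  if (any(a < 0)) stop("abundances must be nonnegative", call. = FALSE)
  if (sum(a) <= 0)
    stop("functional dispersion is undefined for an all-zero community",
         call. = FALSE)
  p <- a / sum(a)
  centroid <- colSums(coords * p)
  dev <- sweep(coords, 2L, centroid)
  sum(p * sqrt(rowSums(dev^2)))
}

#' Functional richness (FRic)
#'
#' Convex-hull volume of the community's species in the first `axes`
#' ordination axes, standardized by the hull volume of the whole pool on
#' the same axes (so FRic is a fraction in \[0, 1\] and equals 1 when the
#' full pool is present). The community must contain more species than
#' axes; otherwise `NA` is returned.
#'
#' @inheritParams functional_dispersion
#' @param present_species Character vector of species present, or a
#'   logical/abundance vector convertible to one.
#' @param axes Number of leading ordination axes to use; default is all
#'   retained axes, capped at (number of present species - 1).
#' @return FRic in \[0, 1\], or `NA_real_` when undefined.
#' @export
functional_richness <- function(space, present_species, axes = NULL) {
  coords <- .space_coords(space)
  present <- .as_present(present_species, coords)
  s <- length(present)
  if (is.null(axes)) axes <- min(ncol(coords), s - 1L)
  if (s < 3L || s <= axes || axes < 1L) return(NA_real_)
  use <- coords[, seq_len(axes), drop = FALSE]
  vol_pool <- convhull_volume(use)
  if (vol_pool <= 0)
    stop("pool hull volume is zero on the chosen axes", call. = FALSE)
  convhull_volume(use[present, , drop = FALSE]) / vol_pool
}

.as_present <- function(present_species, coords) {
  if (is.character(present_species)) {
    missing <- setdiff(present_species, rownames(coords))
    if (length(missing) > 0)
      stop("species missing from the functional space: ",
           paste(missing, collapse = ", "), call. = FALSE)
    present_species
  } else if (is.logical(present_species)) {
    rownames(coords)[present_species]
  } else {
    rownames(coords)[present_species > 0]
  }
}

# minimum spanning tree over rows of coords (Euclidean), Prim's algorithm;
# ties in edge weight are broken by species-name lexicographic order so
# the tree (hence FEve) is deterministic
.mst_edges <- function(coords) {
  n <- nrow(coords)
  labels <- rownames(coords)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dm <- as.matrix(stats::dist(coords))
  ord <- order(labels)
  in_tree <- rep(FALSE, n)
  in_tree[ord[1L]] <- TRUE
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_len(n - 1L)) {
    best <- NULL
    best_w <- Inf
    for (i in which(in_tree)) {
      for (j in which(!in_tree)) {
        w <- dm[i, j]
        better <- w < best_w - 1e-12 ||
          (abs(w - best_w) <= 1e-12 && !is.null(best) &&
           (labels[j] < labels[best[2L]] ||
            (labels[j] == labels[best[2L]] && labels[i] < labels[best[1L]])))
        if (is.null(best) || better) {
          best <- c(i, j)
          best_w <- w
        }
      }
    }
    edges[k, ] <- best
    in_tree[best[2L]] <- TRUE
  }
  edges
}

#' Functional evenness (FEve)
#'
#' Villeger's minimum-spanning-tree index: the regularity of branch
#' lengths of the MST linking all present species in the ordination space,
#' weighted by abundances. For each branch l linking species i and j, the
#' partial weighted evenness is `EW_l = dist(i, j) / (p_i + p_j)`; with
#' `PEW_l = EW_l / sum(EW)` and S species,
#' `FEve = (sum(min(PEW_l, 1/(S-1))) - 1/(S-1)) / (1 - 1/(S-1))`.
#' Requires at least three species; otherwise `NA`.
#'
#' @inheritParams functional_dispersion
#' @return FEve in \[0, 1\], or `NA_real_` when undefined.
#' @export
functional_evenness <- function(space, abundances) {
  coords <- .space_coords(space)
  a <- .align_abund(abundances, coords)
  present <- names(a)[a > 0]
  s <- length(present)
  if (s < 3L) return(NA_real_)
  sub <- coords[present, , drop = FALSE]
  p <- a[present] / sum(a[present])
  edges <- .mst_edges(sub)
  dm <- as.matrix(stats::dist(sub))
  ew <- dm[edges] / (p[edges[, 1L]] + p[edges[, 2L]])
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1L)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence (FDiv)
#'
#' Villeger's index of how abundance is distributed relative to the centre
#' of gravity of the convex-hull vertices: with `dG_i` the distance of
#' species i to that centre, `mean_dG` the unweighted mean over all
#' present species, `dd = sum(p_i * (dG_i - mean_dG))` and
#' `dabs = sum(p_i * |dG_i - mean_dG|)`,
#' `FDiv = (dd + mean_dG) / (dabs + mean_dG)`. Requires at least three
#' species; otherwise `NA`.
#'
#' @inheritParams functional_dispersion
#' @param axes Number of leading axes used for the hull (default: all
#'   retained axes, capped at number of present species - 1).
#' @return FDiv in \[0, 1\], or `NA_real_` when undefined.
#' @export
functional_divergence <- function(space, abundances, axes = NULL) {
  coords <- .space_coords(space)
  a <- .align_abund(abundances, coords)
  present <- names(a)[a > 0]
  s <- length(present)
  if (s < 3L) return(NA_real_)
  if (is.null(axes)) axes <- min(ncol(coords), s - 1L)
  sub <- coords[present, seq_len(axes), drop = FALSE]
  p <- a[present] / sum(a[present])
  verts <- convhull_vertices(sub)
  gravity <- colMeans(sub[verts, , drop = FALSE])
  dG <- sqrt(rowSums(sweep(sub, 2L, gravity)^2))
  mean_dG <- mean(dG)
  dd <- sum(p * (dG - mean_dG))
  dabs <- sum(p * abs(dG - mean_dG))
  (dd + mean_dG) / (dabs + mean_dG)
}

#' Per-plot functional-diversity table
#'
#' Builds the functional trait space (Gower distances, PCoA with the
#' chosen correction) once for the pool and applies the four indices to
#' every plot of a cover table, weighting by relative covers. Plots where
#' every sown species went extinct receive 0 for all indices; plots with
#' fewer than three species receive `NA` for FRic, FEve and FDiv (FDis is
#' defined for any non-empty community and is 0 for monocultures).
#' Following the convention of distance-based FD software, the number of
#' hull axes is reduced to (minimum richness among plots with >= 3
#' species - 1) when needed, so FRic/FDiv are computed in the same space
#' for every plot.
#'
#' @param covers Data frame with `plot_id` plus one cover column per
#'   species.
#' @param traits Trait table (see [gower_distances()]) covering every
#'   species that has positive cover anywhere.
#' @param correction Passed to [pcoa_embed()].
#' @param detect_threshold Covers above this value count as present.
#' @param max_axes Upper bound on the number of ordination axes used for
#'   the convex-hull indices (FRic, FDiv); hull quality degrades and cost
#'   explodes in high dimension, so trait spaces are conventionally
#'   reduced to a few leading axes.
#' @return A data frame with columns `plot_id`, `FRic`, `FEve`, `FDiv`,
#'   `FDis`.
#' @export
community_fd <- function(covers, traits, correction = "cailliez",
                         detect_threshold = 0, max_axes = 5L) {
  stopifnot("plot_id" %in% names(covers))
  sp_cols <- setdiff(names(covers), "plot_id")
  tm <- .trait_matrix(traits)
  missing <- setdiff(sp_cols, rownames(tm))
  if (length(missing) > 0)
    stop("species in covers absent from traits: ",
         paste(missing, collapse = ", "), call. = FALSE)
  space <- pcoa_embed(gower_distances(tm[sp_cols, , drop = FALSE]),
                      correction = correction)
  mat <- as.matrix(covers[, sp_cols, drop = FALSE])
  rich <- rowSums(mat > detect_threshold)
  rich3 <- rich[rich >= 3L]
  hull_axes <- if (length(rich3) > 0)
    min(ncol(space$coords), min(rich3) - 1L, max_axes) else 1L
  out <- data.frame(plot_id = covers$plot_id, FRic = NA_real_,
                    FEve = NA_real_, FDiv = NA_real_, FDis = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    a <- mat[i, ]
    a[a <= detect_threshold] <- 0
    if (sum(a) <= 0) {  # all sown species extinct
      out[i, c("FRic", "FEve", "FDiv", "FDis")] <- 0
      next
    }
    out$FDis[i] <- functional_dispersion(space, a)
    if (rich[i] >= 3L) {
      out$FRic[i] <- functional_richness(space, names(a)[a > 0],
                                         axes = hull_axes)
      out$FEve[i] <- functional_evenness(space, a)
      out$FDiv[i] <- functional_divergence(space, a, axes = hull_axes)
    }
  }
  out
}
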