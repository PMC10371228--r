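#' Density of CD8+ T cells in interaction with fibrocytes
#'
#' A C point is "interacting" when at least one F point lies within `radius`
#' micrometres (Euclidean, centre-to-centre).  This is the point-process
#' counterpart of dilating each segmented CD8 particle by the given distance
#' and intersecting with the fibrocyte mask; the default radius 3.6 um is the
#' 8-pixel dilation, the radius of a mean ideal round cell in the original
#' image analysis.
#'
#' @param pattern a [point_pattern()].
#' @param radius interaction radius, micrometres (>= 0; at 0 only exact
#'   coincidences count).
#' @return list with `density` (interacting C per mm^2), `n_interacting`,
#'   and `interacting` (logical over the C points, in pattern order).
#' @export
interacting_density <- function(pattern, radius = 3.6) {
  if (radius < 0) stop("radius must be >= 0")
  ci <- pattern$type == "C"
  fi <- pattern$type == "F"
  if (!any(ci) || !any(fi)) {
    return(list(density = 0, n_interacting = 0L,
                interacting = logical(sum(ci))))
  }
  d2 <- .cross_dist2(pattern$x[ci], pattern$y[ci],
                     pattern$x[fi], pattern$y[fi])
  hit <- apply(d2, 1, min) <= radius^2
  list(density = sum(hit) / pattern$area_mm2,
       n_interacting = sum(hit), interacting = hit)
}

# squared distance matrix between two point sets
.cross_dist2 <- function(x1, y1, x2, y2) {
  outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
}

#' Convert a pixel dilation to micrometres
#'
#' Image dilations are specified in pixels; the pixel pitch is anchored by a
#' reference correspondence (by default 4 px = 1.8 um, so 8 px = 3.6 um,
#' 10 px = 4.5 um, 15 px = 6.75 um).
#'
#' @param dilation_px dilation in pixels.
#' @param reference length-2 vector `c(px, um)` fixing the scale.
#' @return dilation in micrometres.
#' @examples
#' dilation_px_to_um(8)   # 3.6
#' @export
dilation_px_to_um <- function(dilation_px, reference = c(px = 4, um = 1.8)) {
  if (reference[1] <= 0) stop("reference pixel count must be > 0")
  unname(dilation_px * reference[2] / reference[1])
}

#' Minimal-distance statistics between cell types
#'
#' For every point of `from_type`, the Euclidean distance to its nearest
#' `to_type` point; returns the mean minimal distance and a binned frequency
#' distribution (default 7 um bins: [0,7), [7,14), ...).  In same-type mode
#' the point itself is excluded.
#'
#' @param pattern a [point_pattern()].
#' @param from_type,to_type `"C"` or `"F"` (may be equal).
#' @param bin_width histogram bin width, micrometres.
#' @return list with `mean` (mean minimal distance, `NA` when undefined),
#'   `distances`, `counts` (per bin), `breaks`, and `n_from`.  When either
#'   type is absent the result is the explicit empty signal
#'   (`n_from = 0` or `mean = NA`), not an error.
#' @export
min_distance_stats <- function(pattern, from_type = "F", to_type = "C",
                               bin_width = 7) {
  fi <- which(pattern$type == from_type)
  ti <- which(pattern$type == to_type)
  if (length(fi) == 0 || length(ti) == 0 ||
      (from_type == to_type && length(ti) < 2)) {
    return(list(mean = NA_real_, distances = numeric(0),
                counts = integer(0), breaks = numeric(0),
                n_from = length(fi)))
  }
  d2 <- .cross_dist2(pattern$x[fi], pattern$y[fi],
                     pattern$x[ti], pattern$y[ti])
  if (from_type == to_type) {
    d2[cbind(seq_along(fi), match(fi, ti))] <- Inf  # no zero self-match
  }
  dmin <- sqrt(apply(d2, 1, min))
  nb <- max(1, ceiling((max(dmin) + 1e-9) / bin_width))
  breaks <- seq(0, nb * bin_width, by = bin_width)
  counts <- as.integer(table(cut(dmin, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  list(mean = mean(dmin), distances = dmin, counts = counts,
       breaks = breaks, n_from = length(fi))
}

#' Delaunay edges of a point set
#'
#' Unique edges of the Delaunay triangulation (Bowyer-Watson).  With fewer
#' than 3 points, or a degenerate (collinear) configuration, falls back to
#' the complete graph of pairwise edges, flagged by the `degenerate`
#' attribute.
#'
#' @param x,y coordinates.
#' @return 2-column matrix of point indices (each edge once, i < j), with
#'   attributes `triangles` (m x 3 index matrix) and `degenerate`.
#' @export
delaunay_edges <- function(x, y) {
  n <- length(x)
  degenerate <- FALSE
  tri <- matrix(integer(0), 0, 3)
  if (n >= 3) {
    tri <- cpp_delaunay(as.numeric(x), as.numeric(y))
    if (nrow(tri) == 0) degenerate <- TRUE
  } else {
    degenerate <- TRUE
  }
  if (degenerate) {
    if (n < 2) {
      e <- matrix(integer(0), 0, 2)
    } else {
      cmb <- utils::combn(n, 2)
      e <- cbind(cmb[1, ], cmb[2, ])
    }
  } else {
    e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
    e <- t(apply(e, 1, sort))
    e <- unique(e)
  }
  colnames(e) <- c("from", "to")
  attr(e, "triangles") <- tri
  attr(e, "degenerate") <- degenerate
  e
}

#' Distance-thresholded Delaunay cluster detection
#'
#' Reimplementation of the triangulation-based cluster analysis used on
#' segmented tissue images: all centroids (both cell types pooled) are
#' connected by a Delaunay triangulation; triangles touching the ROI boundary
#' are removed (operationalised as: any triangle with an edge whose midpoint
#' lies outside the ROI or within `edge_tol` of its boundary); the remaining
#' edges are kept only when strictly shorter than `threshold`; connected
#' components with at least `min_cluster_size` members are the clusters,
#' classified by composition (CD8-only, Fib-only, mixed).
#'
#' @param pattern a [point_pattern()].
#' @param threshold edge-length threshold, micrometres (default 40, the mean
#'   minimal fibrocyte-to-CD8 distance scale; comparison is strict `<`).
#' @param min_cluster_size minimum member count for a component to be
#'   reported (default 2: singletons are not groups).
#' @param edge_tol boundary tolerance for the ROI-edge triangle removal, um.
#' @return object of class `cluster_report`: `clusters` data.frame
#'   (cluster_id, kind, n_C, n_F, size), `members` (list of point-index
#'   vectors), `densities` (clusters per mm^2 by kind), `mean_cells` (mean
#'   members per cluster by kind), `degenerate` flag.
#' @export
delaunay_threshold_clusters <- function(pattern, threshold = 40,
                                        min_cluster_size = 2, edge_tol = 1e-6) {
  if (threshold <= 0) stop("threshold must be > 0")
  n <- length(pattern$x)
  e <- delaunay_edges(pattern$x, pattern$y)
  degenerate <- attr(e, "degenerate")
  tri <- attr(e, "triangles")

  if (!degenerate && !is.null(pattern$roi)) {
    # drop whole triangles that touch the ROI boundary, then recollect edges
    mx <- (pattern$x[tri[, 1]] + pattern$x[tri[, 2]]) / 2
    my <- (pattern$y[tri[, 1]] + pattern$y[tri[, 2]]) / 2
    keep12 <- roi_contains(pattern$roi, mx, my, tol = edge_tol)
    mx <- (pattern$x[tri[, 2]] + pattern$x[tri[, 3]]) / 2
    my <- (pattern$y[tri[, 2]] + pattern$y[tri[, 3]]) / 2
    keep23 <- roi_contains(pattern$roi, mx, my, tol = edge_tol)
    mx <- (pattern$x[tri[, 1]] + pattern$x[tri[, 3]]) / 2
    my <- (pattern$y[tri[, 1]] + pattern$y[tri[, 3]]) / 2
    keep13 <- roi_contains(pattern$roi, mx, my, tol = edge_tol)
    tri <- tri[keep12 & keep23 & keep13, , drop = FALSE]
    e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
    if (nrow(e) > 0) {
      e <- t(apply(e, 1, sort))
      e <- unique(e)
    }
  }

  if (nrow(e) > 0) {
    len <- sqrt((pattern$x[e[, 1]] - pattern$x[e[, 2]])^2 +
                (pattern$y[e[, 1]] - pattern$y[e[, 2]])^2)
    e <- e[len < threshold, , drop = FALSE]   # strict
  }

  comp <- .components(n, e)
  sizes <- tabulate(comp, nbins = max(comp, 0))
  ids <- which(sizes >= min_cluster_size)

  members <- lapply(ids, function(k) which(comp == k))
  n_C <- vapply(members, function(m) sum(pattern$type[m] == "C"), 0L)
  n_F <- vapply(members, function(m) sum(pattern$type[m] == "F"), 0L)
  kind <- ifelse(n_C > 0 & n_F > 0, "mixed",
                 ifelse(n_C > 0, "CD8-only", "Fib-only"))
  clusters <- data.frame(cluster_id = seq_along(ids), kind = kind,
                         n_C = n_C, n_F = n_F, size = n_C + n_F)

  kinds <- c("CD8-only", "Fib-only", "mixed")
  densities <- vapply(kinds, function(k) sum(kind == k) / pattern$area_mm2, 0)
  mean_cells <- vapply(kinds, function(k) {
    if (any(kind == k)) mean(clusters$size[kind == k]) else NA_real_
  }, 0)

  structure(list(clusters = clusters, members = members,
                 densities = densities, mean_cells = mean_cells,
                 area_mm2 = pattern$area_mm2, threshold = threshold,
                 min_cluster_size = min_cluster_size,
                 degenerate = degenerate),
            class = "cluster_report")
}

# connected components via union-find
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Delaunay-threshold cluster report (", nrow(x$clusters), " clusters, ",
      "threshold ", x$threshold, " um, min size ", x$min_cluster_size, ")\n",
      sep = "")
  for (k in names(x$densities)) {
    cat(sprintf("  %-9s %3d clusters  (%.1f /mm^2, mean %.1f cells)\n", k,
                sum(x$clusters$kind == k), x$densities[[k]],
                x$mean_cells[[k]]))
  }
  if (x$degenerate) cat("  [degenerate triangulation: pairwise-edge fallback]\n")
  invisible(x)
}

#' Write a cluster report to CSV
#'
#' @param report a `cluster_report`.
#' @param path file path.
#' @export
write_cluster_csv <- function(report, path) {
  utils::write.csv(report$clusters, path, row.names = FALSE)
  invisible(path)
}

#' Random-placement null model for mixed-cluster density
#'
#' Places `round(density x area)` points of each type uniformly at random in
#' the ROI (complete spatial randomness), applies the same Delaunay-threshold
#' cluster detection, and records the density of mixed clusters; repeated
#' over replicates.  This is the reference against which the spatial
#' organisation of simulated or observed patterns is judged.
#'
#' @param rhoC,rhoF densities, cells/mm^2.
#' @param roi region of interest (e.g. the crown domain's `$roi`).
#' @param threshold,min_cluster_size passed to
#'   [delaunay_threshold_clusters()].
#' @param replicates number of random placements (>= 2).
#' @return list with `median`, `ci` (2.5 and 97.5 percentiles across
#'   replicates), and `values` (mixed-cluster densities per replicate,
#'   per mm^2).
#' @export
random_null_mixed_density <- function(rhoC, rhoF, roi, threshold = 40,
                                      replicates = 100, min_cluster_size = 2) {
  if (replicates < 2) stop("replicates must be >= 2")
  area <- roi$area_um2 / 1e6
  nC <- round(rhoC * area)
  nF <- round(rhoF * area)
  vals <- vapply(seq_len(replicates), function(r) {
    pc <- roi_runif(roi, nC)
    pf <- roi_runif(roi, nF)
    pat <- point_pattern(rep(c("C", "F"), c(nC, nF)),
                         c(pc[, 1], pf[, 1]), c(pc[, 2], pf[, 2]),
                         roi = roi, check = FALSE)
    rep_ <- delaunay_threshold_clusters(pat, threshold, min_cluster_size)
    rep_$densities[["mixed"]]
  }, 0)
  list(median = stats::median(vals),
       ci = stats::quantile(vals, c(0.025, 0.975)),
       values = vals)
}
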