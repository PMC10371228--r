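#' Build the annular ("crown") lattice domain
#'
#' Rasterizes an annulus on a square lattice so that the number of sites
#' matches `target_site_count` exactly.  Sites are indexed by integer `(i, j)`
#' with the annulus centre at the origin; the centre of site `(i, j)` is at
#' `((i + 0.5) * site_length, (j + 0.5) * site_length)` in micrometres.  The
#' default geometry reproduces the peribronchial lamina propria used for the
#' tissue simulations: 3652 sites of 7 um x 7 um, i.e. an area of 178,948 um^2
#' (approximately 0.179 mm^2).
#'
#' Sites are ranked by the distance of their centre from the origin (ties
#' broken deterministically by the `(i, j)` index), and the closest
#' `target_site_count` sites with centre distance at least `inner_radius` are
#' retained; the outer radius is the centre distance of the last retained
#' site.  This is equivalent to adjusting the outer radius by bisection on the
#' rasterized count, with a deterministic rule for cocircular ties, so any
#' site count is attainable exactly.
#'
#' @param site_length side of one square site, micrometres.
#' @param target_site_count exact number of lattice sites wanted.
#' @param inner_radius inner ("lumen") radius, micrometres.
#' @param neighborhood `"moore"` (8 neighbours, default) or `"von_neumann"`
#'   (4 neighbours).  Missing neighbours at the inner and outer rim are simply
#'   absent (zero-flux, reflecting borders).
#' @return An object of class `lattice_domain`: list with `site_length`,
#'   `sites` (n x 2 integer matrix of `(i, j)`), `centers` (n x 2 matrix, um),
#'   `inner_radius`, `outer_radius` (um), `area_um2`, `area_mm2`, `roi`
#'   (polygonal region-of-interest, see [roi_annulus()]), and `nbr`
#'   (n x 8 matrix of 1-based neighbour row indices, `NA` where absent).
#' @examples
#' dom <- build_domain()
#' nrow(dom$sites)   # 3652
#' dom$area_um2      # 178948
#' @export
build_domain <- function(site_length = 7, target_site_count = 3652,
                         inner_radius = 150,
                         neighborhood = c("moore", "von_neumann")) {
  neighborhood <- match.arg(neighborhood)
  if (site_length <= 0) stop("site_length must be > 0")
  if (target_site_count < 1) {
    stop("target_site_count must be >= 1 (attainable range is 1 upward)")
  }
  if (inner_radius < 0) stop("inner_radius must be >= 0")

  # candidate square of indices large enough to hold the annulus
  # area needed ~ target * L^2 + hole; solve for a safe outer bound
  r_guess <- sqrt(target_site_count * site_length^2 / pi + inner_radius^2)
  r_max <- r_guess + 4 * site_length
  repeat {
    imax <- ceiling(r_max / site_length) + 1
    idx <- seq.int(-imax, imax - 1)
    g <- expand.grid(i = idx, j = idx)
    cx <- (g$i + 0.5) * site_length
    cy <- (g$j + 0.5) * site_length
    r <- sqrt(cx^2 + cy^2)
    ok <- r >= inner_radius
    if (sum(ok) >= target_site_count) break
    r_max <- r_max * 1.5
  }
  g <- g[ok, , drop = FALSE]
  r <- r[ok]
  ord <- order(r, g$i, g$j)
  take <- ord[seq_len(target_site_count)]
  sites <- as.matrix(g[take, c("i", "j")])
  dimnames(sites) <- list(NULL, c("i", "j"))
  storage.mode(sites) <- "integer"
  outer_radius <- max(r[take])

  centers <- cbind(x = (sites[, 1] + 0.5) * site_length,
                   y = (sites[, 2] + 0.5) * site_length)

  dom <- list(
    site_length = site_length,
    sites = sites,
    centers = centers,
    n_sites = nrow(sites),
    inner_radius = inner_radius,
    outer_radius = outer_radius,
    area_um2 = nrow(sites) * site_length^2,
    area_mm2 = nrow(sites) * site_length^2 / 1e6,
    neighborhood = neighborhood,
    roi = roi_annulus(inner_radius, outer_radius)
  )
  dom$nbr <- .build_neighbor_table(sites, neighborhood)
  class(dom) <- "lattice_domain"
  dom
}

# n x 8 matrix of 1-based row indices of lattice neighbours, NA-padded
.build_neighbor_table <- function(sites, neighborhood) {
  n <- nrow(sites)
  imin <- min(sites[, 1]); jmin <- min(sites[, 2])
  w <- max(sites[, 1]) - imin + 1L
  h <- max(sites[, 2]) - jmin + 1L
  lut <- integer(w * h)                 # 0 = absent
  key <- (sites[, 1] - imin) * h + (sites[, 2] - jmin) + 1L
  lut[key] <- seq_len(n)
  if (neighborhood == "moore") {
    di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    di <- c(-1L, 1L, 0L, 0L)
    dj <- c(0L, 0L, -1L, 1L)
  }
  nbr <- matrix(NA_integer_, n, 8)
  for (k in seq_along(di)) {
    ii <- sites[, 1] + di[k] - imin
    jj <- sites[, 2] + dj[k] - jmin
    inside <- ii >= 0L & ii < w & jj >= 0L & jj < h
    kk <- ii * h + jj + 1L
    hit <- integer(n)
    hit[inside] <- lut[kk[inside]]
    nbr[, k] <- ifelse(hit > 0L, hit, NA_integer_)
  }
  nbr
}

#' Moore (or von Neumann) neighbours of a lattice site
#'
#' Returns the in-domain neighbours of `site`; neighbours falling outside the
#' annulus are absent (reflecting, zero-flux borders -- no wraparound).
#'
#' @param domain a [build_domain()] object.
#' @param site integer vector `c(i, j)`; must be a site of the domain.
#' @return integer matrix of neighbour `(i, j)` indices (0 to 8 rows).
#' @export
neighbors <- function(domain, site) {
  ix <- .site_index(domain, site)
  if (is.na(ix)) stop("site (", site[1], ", ", site[2], ") is not in the domain")
  nb <- domain$nbr[ix, ]
  nb <- nb[!is.na(nb)]
  domain$sites[nb, , drop = FALSE]
}

.site_index <- function(domain, site) {
  hit <- which(domain$sites[, 1] == site[1] & domain$sites[, 2] == site[2])
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Annular region of interest
#'
#' Polygonal approximation of an annulus centred at the origin, with the exact
#' radii retained so that containment tests are radial (exact) rather than
#' polygonal.
#'
#' @param inner_radius,outer_radius radii in micrometres.
#' @param n_vertices vertices per ring for the polygon approximation.
#' @return object of class `roi` with `type = "annulus"`.
#' @export
roi_annulus <- function(inner_radius, outer_radius, n_vertices = 128) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  structure(list(
    type = "annulus",
    inner_radius = inner_radius,
    outer_radius = outer_radius,
    outer = cbind(x = outer_radius * cos(th), y = outer_radius * sin(th)),
    hole = if (inner_radius > 0)
      cbind(x = inner_radius * cos(th), y = inner_radius * sin(th)),
    area_um2 = pi * (outer_radius^2 - inner_radius^2)
  ), class = "roi")
}

#' Rectangular region of interest
#'
#' @param width,height rectangle extent in micrometres (origin at lower-left
#'   corner).
#' @return object of class `roi` with `type = "rect"`.
#' @export
roi_rect <- function(width, height) {
  structure(list(
    type = "rect", width = width, height = height,
    outer = cbind(x = c(0, width, width, 0), y = c(0, 0, height, height)),
    hole = NULL,
    area_um2 = width * height
  ), class = "roi")
}

#' Test whether points fall inside a region of interest
#'
#' Annuli and rectangles are tested exactly; generic polygons (with an
#' optional hole) by even-odd ray casting.
#'
#' @param roi an `roi` object.
#' @param x,y point coordinates, micrometres.
#' @param tol points within `tol` of the boundary are treated as outside
#'   (used by the ROI-edge triangle filter); default 0 keeps boundary points
#'   inside.
#' @return logical vector.
#' @export
roi_contains <- function(roi, x, y, tol = 0) {
  if (roi$type == "annulus") {
    r <- sqrt(x^2 + y^2)
    return(r >= roi$inner_radius + tol & r <= roi$outer_radius - tol)
  }
  if (roi$type == "rect") {
    return(x >= tol & x <= roi$width - tol & y >= tol & y <= roi$height - tol)
  }
  inside <- .pip(roi$outer, x, y)
  if (!is.null(roi$hole)) inside <- inside & !.pip(roi$hole, x, y)
  inside
}

# even-odd point-in-polygon
.pip <- function(poly, x, y) {
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > y) != (py[j] > y)
    xi <- px[j] + (y - py[j]) * (px[i] - px[j]) / (py[i] - py[j])
    inside <- xor(inside, cross & (x < xi))
    j <- i
  }
  inside
}

#' Draw uniform points inside a region of interest
#'
#' Annulus: exact inverse-CDF radial sampling; rectangle: direct; polygon:
#' rejection from the bounding box.
#'
#' @param roi an `roi` object.
#' @param n number of points.
#' @return n x 2 matrix of coordinates (um).
#' @export
roi_runif <- function(roi, n) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  if (roi$type == "annulus") {
    r <- sqrt(stats::runif(n, roi$inner_radius^2, roi$outer_radius^2))
    th <- stats::runif(n, 0, 2 * pi)
    return(cbind(x = r * cos(th), y = r * sin(th)))
  }
  if (roi$type == "rect") {
    return(cbind(x = stats::runif(n, 0, roi$width),
                 y = stats::runif(n, 0, roi$height)))
  }
  xr <- range(roi$outer[, 1]); yr <- range(roi$outer[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 16
    cand <- cbind(stats::runif(m, xr[1], xr[2]), stats::runif(m, yr[1], yr[2]))
    keep <- roi_contains(roi, cand[, 1], cand[, 2])
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' @export
print.lattice_domain <- function(x, ...) {
  cat("Annular lattice domain\n")
  cat(sprintf("  sites:        %d (%.0f um^2 each, side %.3g um)\n",
              x$n_sites, x$site_length^2, x$site_length))
  cat(sprintf("  radii:        %.1f - %.1f um\n", x$inner_radius, x$outer_radius))
  cat(sprintf("  area:         %.0f um^2 (%.5f mm^2)\n", x$area_um2, x$area_mm2))
  cat(sprintf("  neighborhood: %s\n", x$neighborhood))
  invisible(x)
}

#' Write / read a lattice domain as plain text
#'
#' A JSON-like header line (`# key=value ...`) followed by one `i j` site pair
#' per line, so a domain can be archived with simulation outputs.
#'
#' @param domain a `lattice_domain`.
#' @param path file path.
#' @export
write_domain <- function(domain, path) {
  hdr <- sprintf("# site_length=%.10g inner_radius=%.10g outer_radius=%.10g area_um2=%.10g neighborhood=%s",
                 domain$site_length, domain$inner_radius, domain$outer_radius,
                 domain$area_um2, domain$neighborhood)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(domain$sites, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_domain
#' @param path file path.
#' @export
read_domain <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  vals <- strsplit(kv, "=", fixed = TRUE)
  h <- stats::setNames(lapply(vals, `[`, 2), vapply(vals, `[`, "", 1))
  sites <- as.matrix(utils::read.table(path, skip = 1,
                                       col.names = c("i", "j")))
  storage.mode(sites) <- "integer"
  L <- as.numeric(h$site_length)
  dom <- list(
    site_length = L,
    sites = sites,
    centers = cbind(x = (sites[, 1] + 0.5) * L, y = (sites[, 2] + 0.5) * L),
    n_sites = nrow(sites),
    inner_radius = as.numeric(h$inner_radius),
    outer_radius = as.numeric(h$outer_radius),
    area_um2 = nrow(sites) * L^2,
    area_mm2 = nrow(sites) * L^2 / 1e6,
    neighborhood = h$neighborhood,
    roi = roi_annulus(as.numeric(h$inner_radius), as.numeric(h$outer_radius))
  )
  dom$nbr <- .build_neighbor_table(sites, h$neighborhood)
  class(dom) <- "lattice_domain"
  dom
}
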