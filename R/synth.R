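#' Specification of a synthetic histology-like point pattern
#'
#' Describes a two-class pattern with tunable fibrocyte-to-CD8
#' cross-attraction, emulating segmented immunohistochemistry centroids:
#' CD8+ T cells are a Poisson process (optionally Thomas-clustered), and each
#' fibrocyte is, with a probability increasing in `attraction`, relocated to
#' a Gaussian offset from a uniformly chosen CD8 point (a cross-type
#' Neyman-Scott construction).  `attraction = 0` gives complete spatial
#' randomness for both types.
#'
#' @param rhoC,rhoF intensities, cells/mm^2 (healthy-like defaults 660 and
#'   106).
#' @param attraction dimensionless >= 0; the relocation probability is
#'   `attraction / (1 + attraction)`.
#' @param dispersion Gaussian offset scale for relocated fibrocytes, um.
#' @param roi region of interest.
#' @param thomas_C optional `list(parent_density, offspring_sd)` (parents per
#'   mm^2, um): cluster the CD8 points instead of placing them uniformly.
#' @param fixed_counts if `TRUE`, use `round(rho * area)` points instead of
#'   Poisson counts.
#' @return object of class `pattern_spec`.
#' @export
pattern_spec <- function(rhoC = 660, rhoF = 106, attraction = 0,
                         dispersion = 10, roi = roi_rect(500, 360),
                         thomas_C = NULL, fixed_counts = FALSE) {
  if (rhoC < 0 || rhoF < 0) stop("densities must be >= 0")
  if (attraction < 0) stop("attraction must be >= 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  structure(list(rhoC = rhoC, rhoF = rhoF, attraction = attraction,
                 dispersion = dispersion, roi = roi, thomas_C = thomas_C,
                 fixed_counts = fixed_counts),
            class = "pattern_spec")
}

#' Generate a synthetic two-class point pattern
#'
#' @param spec a [pattern_spec()].
#' @return a [point_pattern()].
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  area <- spec$roi$area_um2 / 1e6

  nC <- if (spec$fixed_counts) round(spec$rhoC * area)
        else stats::rpois(1, spec$rhoC * area)
  nF <- if (spec$fixed_counts) round(spec$rhoF * area)
        else stats::rpois(1, spec$rhoF * area)

  if (is.null(spec$thomas_C)) {
    pc <- roi_runif(spec$roi, nC)
  } else {
    np <- max(1, stats::rpois(1, spec$thomas_C$parent_density * area))
    par <- roi_runif(spec$roi, np)
    pick <- sample.int(np, nC, replace = TRUE)
    pc <- .gaussian_in_roi(spec$roi, par[pick, 1, drop = TRUE],
                           par[pick, 2, drop = TRUE],
                           spec$thomas_C$offspring_sd)
  }

  pf <- roi_runif(spec$roi, nF)
  p_rel <- spec$attraction / (1 + spec$attraction)
  if (nF > 0 && nC > 0 && p_rel > 0) {
    rel <- stats::runif(nF) < p_rel
    if (any(rel)) {
      anchors <- sample.int(nC, sum(rel), replace = TRUE)
      moved <- .gaussian_in_roi(spec$roi, pc[anchors, 1], pc[anchors, 2],
                                spec$dispersion)
      pf[rel, ] <- moved
    }
  }

  point_pattern(rep(c("C", "F"), c(nC, nF)),
                c(pc[, 1], pf[, 1]), c(pc[, 2], pf[, 2]),
                roi = spec$roi, check = FALSE)
}

# Gaussian offsets resampled until inside the ROI (fallback: project to a
# uniform draw after 50 rejections, which keeps the sampler total)
.gaussian_in_roi <- function(roi, cx, cy, sd) {
  n <- length(cx)
  out <- cbind(x = cx + stats::rnorm(n, 0, sd), y = cy + stats::rnorm(n, 0, sd))
  for (tries in seq_len(50)) {
    bad <- !roi_contains(roi, out[, 1], out[, 2])
    if (!any(bad)) break
    out[bad, 1] <- cx[bad] + stats::rnorm(sum(bad), 0, sd)
    out[bad, 2] <- cy[bad] + stats::rnorm(sum(bad), 0, sd)
  }
  bad <- !roi_contains(roi, out[, 1], out[, 2])
  if (any(bad)) out[bad, ] <- roi_runif(roi, sum(bad))
  out
}

#' Specification of a synthetic motility track
#'
#' Alternating free / contact bouts with geometric lengths whose means hit the
#' target contact coefficient in expectation; per-interval displacements have
#' gamma-distributed magnitudes with the bout's mean speed and uniform
#' directions.
#'
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames.
#' @param free_speed,contact_speed mean speeds, um/min.
#' @param contact_coef target fraction of frames in contact, in `[0, 1]`.
#' @param mean_bout mean total bout length (frames) controlling alternation
#'   granularity.
#' @return object of class `track_spec`.
#' @export
track_spec <- function(n_frames = 100, frame_interval = 2,
                       free_speed = 4, contact_speed = 1.5,
                       contact_coef = 0.3, mean_bout = 10) {
  if (free_speed < 0 || contact_speed < 0) stop("speeds must be >= 0")
  if (contact_coef < 0 || contact_coef > 1) stop("contact_coef must be in [0, 1]")
  structure(list(n_frames = n_frames, frame_interval = frame_interval,
                 free_speed = free_speed, contact_speed = contact_speed,
                 contact_coef = contact_coef, mean_bout = mean_bout),
            class = "track_spec")
}

#' Generate a synthetic motility track
#'
#' @param spec a [track_spec()].
#' @return a [cell_track()].
#' @export
generate_track <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  n <- spec$n_frames
  # bout state per frame
  if (spec$contact_coef == 0) {
    flags <- rep(FALSE, n)
  } else if (spec$contact_coef == 1) {
    flags <- rep(TRUE, n)
  } else {
    mc <- max(1e-9, spec$mean_bout * spec$contact_coef)
    mf <- max(1e-9, spec$mean_bout * (1 - spec$contact_coef))
    flags <- logical(0)
    state <- stats::runif(1) < spec$contact_coef
    while (length(flags) < n) {
      m <- if (state) mc else mf
      len <- 1 + stats::rgeom(1, prob = 1 / m)  # mean m, support >= 1
      flags <- c(flags, rep(state, len))
      state <- !state
    }
    flags <- flags[seq_len(n)]
  }

  t <- (seq_len(n) - 1) * spec$frame_interval
  # displacement of interval i uses the state of frame i
  st <- flags[-n]
  mu <- ifelse(st, spec$contact_speed, spec$free_speed) * spec$frame_interval
  shape <- 4
  mag <- ifelse(mu > 0, stats::rgamma(n - 1, shape = shape, rate = shape / pmax(mu, 1e-12)), 0)
  th <- stats::runif(n - 1, 0, 2 * pi)
  x <- cumsum(c(0, mag * cos(th)))
  y <- cumsum(c(0, mag * sin(th)))
  cell_track(t, x, y, flags)
}
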