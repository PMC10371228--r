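#' Single-cell motility track
#'
#' A time series of positions for one tracked CD8+ T cell with a per-frame
#' flag marking direct contact with a fibrocyte (as scored on live-imaging
#' movies, default frame interval 2 minutes).
#'
#' @param t time stamps, minutes (strictly increasing).
#' @param x,y positions, micrometres.
#' @param contact logical per-frame contact flags.
#' @return object of class `cell_track`.
#' @export
cell_track <- function(t, x, y, contact) {
  if (length(unique(c(length(t), length(x), length(y), length(contact)))) != 1) {
    stop("t, x, y, contact must have equal length")
  }
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 contact = as.logical(contact)),
            class = "cell_track")
}

#' Speed and contact metrics of a motility track
#'
#' Computes the standard live-imaging readouts: mean speed (track length over
#' tracking duration), mean free speed (path length while not in contact over
#' time spent free), mean contact speed (path length while in contact over
#' time in contact), the contact coefficient (fraction of observed frames in
#' contact), and the durations of the individual contacts (maximal contiguous
#' runs of flagged frames, each frame counting one frame interval).  Each
#' inter-frame displacement is attributed to the contact state of its
#' starting frame.  A partition with no time (all-free or all-contact tracks)
#' yields `NA` for the corresponding speed, not zero.
#'
#' @param track a [cell_track()] (>= 2 frames).
#' @return list with `mean_speed`, `mean_free_speed`, `mean_contact_speed`
#'   (um/min), `contact_coefficient`, and `contact_durations` (minutes).
#' @export
track_contact_metrics <- function(track) {
  n <- length(track$t)
  if (n < 2) stop("track must have at least 2 frames")
  dt <- diff(track$t)
  seg <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  state <- track$contact[-n]          # state at the start of each interval

  total_t <- sum(dt)
  free_t <- sum(dt[!state]); contact_t <- sum(dt[state])
  mean_speed <- sum(seg) / total_t
  mean_free_speed <- if (free_t > 0) sum(seg[!state]) / free_t else NA_real_
  mean_contact_speed <- if (contact_t > 0) sum(seg[state]) / contact_t else NA_real_

  contact_coefficient <- mean(track$contact)

  # contact durations: run lengths of flagged frames x frame interval
  frame_int <- stats::median(dt)
  r <- rle(track$contact)
  contact_durations <- r$lengths[r$values] * frame_int

  list(mean_speed = mean_speed,
       mean_free_speed = mean_free_speed,
       mean_contact_speed = mean_contact_speed,
       contact_coefficient = contact_coefficient,
       contact_durations = contact_durations)
}

#' Read / write tracks as CSV
#'
#' Columns `t_min,x_um,y_um,contact`.
#'
#' @param track a `cell_track`.
#' @param path file path.
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(data.frame(t_min = track$t, x_um = track$x,
                              y_um = track$y, contact = track$contact),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(path) {
  df <- utils::read.csv(path)
  cell_track(df$t_min, df$x_um, df$y_um, df$contact)
}
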