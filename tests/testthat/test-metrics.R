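test_that("interaction density follows the dilation-radius rule", {
  roi <- roi_rect(100, 100)
  pair <- function(d) point_pattern(c("C", "F"), c(50, 50 + d), c(50, 50),
                                    roi = roi)
  expect_equal(interacting_density(pair(3), 3.6)$n_interacting, 1)
  expect_equal(interacting_density(pair(5), 3.6)$n_interacting, 0)
  expect_equal(interacting_density(pair(3), 3.6)$density, 1 / 0.01)
  # radius 0 counts only exact coincidences
  co <- point_pattern(c("C", "F"), c(50, 50), c(50, 50), roi = roi)
  expect_equal(interacting_density(co, 0)$n_interacting, 1)
  expect_equal(interacting_density(pair(1e-3), 0)$n_interacting, 0)
})

test_that("interaction count equals a brute-force scan and is monotone in r", {
  set.seed(21)
  roi <- roi_rect(500, 500)
  pts <- roi_runif(roi, 200)
  ty <- rep(c("C", "F"), c(150, 50))
  pat <- point_pattern(ty, pts[, 1], pts[, 2], roi = roi)
  brute <- function(r) {
    ci <- which(ty == "C"); fi <- which(ty == "F")
    hits <- 0
    for (i in ci) {
      for (j in fi) {
        if (sqrt((pts[i, 1] - pts[j, 1])^2 + (pts[i, 2] - pts[j, 2])^2) <= r) {
          hits <- hits + 1; break
        }
      }
    }
    hits
  }
  radii <- c(3.6, 10, 25, 60)
  got <- vapply(radii, function(r) interacting_density(pat, r)$n_interacting, 0L)
  expect_equal(got, vapply(radii, brute, 0))
  expect_true(all(diff(got) >= 0))
})

test_that("pixel dilations convert to micrometres via the reference scale", {
  expect_equal(dilation_px_to_um(8), 3.6)
  expect_equal(dilation_px_to_um(4), 1.8)
  expect_equal(dilation_px_to_um(10), 4.5)
  expect_equal(dilation_px_to_um(8, c(px = 2, um = 1.8)), 7.2)
})

test_that("minimal distances match a brute-force scan and bin at 7 um", {
  set.seed(22)
  roi <- roi_rect(400, 400)
  pts <- roi_runif(roi, 300)
  ty <- rep(c("C", "F"), c(250, 50))
  pat <- point_pattern(ty, pts[, 1], pts[, 2], roi = roi)
  st <- min_distance_stats(pat, "F", "C", bin_width = 7)
  fi <- which(ty == "F"); ci <- which(ty == "C")
  ref <- brute_min_dist(pts[fi, 1], pts[fi, 2], pts[ci, 1], pts[ci, 2])
  expect_equal(st$distances, ref)
  expect_equal(st$mean, mean(ref))
  expect_equal(sum(st$counts), length(fi))
  expect_equal(diff(st$breaks), rep(7, length(st$breaks) - 1))
  # same-type mode excludes the self-match
  stc <- min_distance_stats(pat, "C", "C")
  refc <- brute_min_dist(pts[ci, 1], pts[ci, 2], pts[ci, 1], pts[ci, 2],
                         exclude_same_index = TRUE)
  expect_equal(stc$distances, refc)
  expect_true(all(stc$distances > 0))
})

test_that("minimal-distance statistics are isometry invariant", {
  set.seed(23)
  roi <- roi_rect(300, 300)
  pts <- roi_runif(roi, 80)
  ty <- rep(c("C", "F"), c(60, 20))
  m0 <- min_distance_stats(point_pattern(ty, pts[, 1], pts[, 2], roi = roi),
                           "F", "C")
  a <- pi / 5
  rx <- pts[, 1] * cos(a) - pts[, 2] * sin(a) + 120
  ry <- pts[, 1] * sin(a) + pts[, 2] * cos(a) - 40
  m1 <- min_distance_stats(point_pattern(ty, rx, ry, area_mm2 = 0.09,
                                         check = FALSE), "F", "C")
  expect_equal(m1$mean, m0$mean)
  expect_equal(m1$counts, m0$counts)
})

test_that("coincident and missing types resolve without crashing", {
  roi <- roi_rect(50, 50)
  co <- point_pattern(c("C", "F"), c(10, 10), c(10, 10), roi = roi)
  st <- min_distance_stats(co, "F", "C")
  expect_equal(st$mean, 0)
  expect_equal(st$counts[1], 1)
  onlyC <- point_pattern("C", 10, 10, roi = roi)
  st2 <- min_distance_stats(onlyC, "F", "C")
  expect_true(is.na(st2$mean))
  expect_equal(st2$n_from, 0)
})

test_that("random-placement null behaves monotonically below percolation", {
  dom_roi <- roi_rect(600, 600)
  set.seed(24)
  n0 <- random_null_mixed_density(250, 0, dom_roi, 40, replicates = 10)
  expect_equal(n0$median, 0)               # no fibrocytes, no mixed clusters
  set.seed(24)
  lo <- random_null_mixed_density(250, 30, dom_roi, 40, replicates = 40)
  set.seed(24)
  hi <- random_null_mixed_density(250, 90, dom_roi, 40, replicates = 40)
  expect_gte(hi$median, lo$median)
  # sparser two-class pattern has fewer mixed clusters than a denser one
  set.seed(25)
  d1 <- random_null_mixed_density(180, 30, dom_roi, 40, replicates = 40)
  set.seed(25)
  d2 <- random_null_mixed_density(420, 70, dom_roi, 40, replicates = 40)
  expect_gt(d2$median, d1$median)
})

test_that("track metrics reproduce hand-computed toy examples", {
  # 4 frames, 5 um per 2-min interval, contact on the last two frames
  tr <- cell_track(c(0, 2, 4, 6), c(0, 5, 10, 15), c(0, 0, 0, 0),
                   c(FALSE, FALSE, TRUE, TRUE))
  m <- track_contact_metrics(tr)
  expect_equal(m$mean_speed, 2.5)
  expect_equal(m$contact_coefficient, 0.5)
  expect_equal(m$mean_free_speed, 2.5)
  expect_equal(m$mean_contact_speed, 2.5)
  # run lengths: (T,T,F,T) -> contacts of 4 and 2 minutes
  tr2 <- cell_track(c(0, 2, 4, 6), c(0, 1, 2, 3), c(0, 0, 0, 0),
                    c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(track_contact_metrics(tr2)$contact_durations, c(4, 2))
  # all-contact track: coefficient 1, free partition absent (not zero)
  tr3 <- cell_track(c(0, 2, 4), c(0, 3, 6), c(0, 0, 0), c(TRUE, TRUE, TRUE))
  m3 <- track_contact_metrics(tr3)
  expect_equal(m3$contact_coefficient, 1)
  expect_true(is.na(m3$mean_free_speed))
  expect_error(cell_track(c(0, 0), 1:2, 1:2, c(TRUE, TRUE)), "increasing")
})
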