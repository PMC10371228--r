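test_that("CSR patterns reproduce the Poisson nearest-neighbour mean", {
  # for a Poisson process of intensity rho, E[nearest-neighbour distance]
  # = 1 / (2 sqrt(rho)); measured F -> C with independent CSR components.
  roi <- roi_rect(2000, 2000)
  rho <- 600                      # per mm^2
  expected_um <- 1 / (2 * sqrt(rho)) * 1000
  set.seed(31)
  means <- vapply(1:30, function(i) {
    pat <- generate_pattern(pattern_spec(rhoC = rho, rhoF = 100,
                                        attraction = 0, roi = roi))
    min_distance_stats(pat, "F", "C")$mean
  }, 0)
  se <- stats::sd(means) / sqrt(30)
  # 3 SE Monte-Carlo band plus a 3% allowance for boundary inflation
  # (points near the ROI edge have no neighbours outside it)
  expect_lt(abs(mean(means) - expected_um), 3 * se + 0.03 * expected_um)
})

test_that("cross-attraction shrinks the F -> C minimal distance", {
  roi <- roi_rect(800, 800)
  set.seed(32)
  m <- function(attr) {
    vapply(1:50, function(i) {
      pat <- generate_pattern(pattern_spec(660, 106, attraction = attr,
                                          dispersion = 8, roi = roi))
      min_distance_stats(pat, "F", "C")$mean
    }, 0)
  }
  m0 <- m(0); m5 <- m(5)
  expect_lt(median(m5), median(m0))
})

test_that("realized counts are Poisson-consistent with the intensities", {
  roi <- roi_rect(500, 500)
  area <- 0.25
  set.seed(33)
  counts <- t(vapply(1:100, function(i) {
    pat <- generate_pattern(pattern_spec(660, 106, roi = roi))
    c(sum(pat$type == "C"), sum(pat$type == "F"))
  }, c(0, 0)))
  for (k in 1:2) {
    rho <- c(660, 106)[k]
    se <- sqrt(rho * area / 100) / area
    expect_lt(abs(mean(counts[, k]) / area - rho), 3 * se)
  }
  # all points inside the ROI
  pat <- generate_pattern(pattern_spec(660, 106, attraction = 3, roi = roi))
  expect_true(all(roi_contains(roi, pat$x, pat$y)))
})

test_that("track generation round-trips through the contact metrics", {
  set.seed(34)
  # extreme coefficients are exact
  t1 <- generate_track(track_spec(n_frames = 50, contact_coef = 1))
  expect_equal(track_contact_metrics(t1)$contact_coefficient, 1)
  t0 <- generate_track(track_spec(n_frames = 50, contact_coef = 0))
  expect_equal(track_contact_metrics(t0)$contact_coefficient, 0)
  # intermediate target recovered up to binomial error (pooled frames)
  coefs <- vapply(1:40, function(i) {
    track_contact_metrics(generate_track(
      track_spec(n_frames = 100, contact_coef = 0.5)))$contact_coefficient
  }, 0)
  se <- stats::sd(coefs) / sqrt(40)
  expect_lt(abs(mean(coefs) - 0.5), 3 * se)
  # speeds recovered within Monte-Carlo error
  sp <- t(vapply(1:40, function(i) {
    m <- track_contact_metrics(generate_track(
      track_spec(n_frames = 200, free_speed = 4, contact_speed = 1.5,
                 contact_coef = 0.4)))
    c(m$mean_free_speed, m$mean_contact_speed)
  }, c(0, 0)))
  expect_lt(abs(mean(sp[, 1]) - 4), 3 * stats::sd(sp[, 1]) / sqrt(40))
  expect_lt(abs(mean(sp[, 2]) - 1.5), 3 * stats::sd(sp[, 2]) / sqrt(40))
})

test_that("pattern CSV IO round-trips exactly", {
  roi <- roi_rect(300, 300)
  set.seed(35)
  pat <- generate_pattern(pattern_spec(400, 80, roi = roi))
  f <- withr::local_tempfile(fileext = ".csv")
  write_pattern_csv(pat, f)
  pat2 <- read_pattern_csv(f)
  expect_equal(pat2$type, pat$type)
  expect_equal(pat2$x, pat$x)
  expect_equal(pat2$area_mm2, pat$area_mm2)
})
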