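test_that("triangulation agrees with the empty-circumcircle oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(8:20, 1)
    x <- runif(n, 0, 100); y <- runif(n, 0, 100)
    e <- delaunay_edges(x, y)
    ref <- brute_delaunay_edges(x, y)
    got <- e[order(e[, 1], e[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(ref))
  }
})

test_that("threshold clustering matches the oracle end to end", {
  roi <- roi_rect(200, 200)
  for (seed in 5:7) {
    set.seed(seed)
    n <- 15
    pts <- roi_runif(roi, n)
    ty <- sample(c("C", "F"), n, replace = TRUE)
    pat <- point_pattern(ty, pts[, 1], pts[, 2], roi = roi)
    rep_ <- delaunay_threshold_clusters(pat, threshold = 40,
                                        min_cluster_size = 2)
    # oracle: brute-force Delaunay edges, same threshold, union-find
    e <- brute_delaunay_edges(pts[, 1], pts[, 2])
    len <- sqrt((pts[e[, 1], 1] - pts[e[, 2], 1])^2 +
                (pts[e[, 1], 2] - pts[e[, 2], 2])^2)
    e <- e[len < 40, , drop = FALSE]
    comp <- fibrocyteCA:::.components(n, e)
    ref_sets <- unname(Filter(function(s) length(s) >= 2,
                              split(seq_len(n), comp)))
    got_sets <- rep_$members
    canon <- function(sets) {
      if (length(sets) == 0) return(list())
      sets <- lapply(sets, function(x) as.integer(sort(x)))
      sets[order(vapply(sets, min, 1L))]
    }
    expect_equal(canon(got_sets), canon(ref_sets))
  }
})

test_that("two-point patterns resolve by the strict 40 um threshold", {
  roi <- roi_rect(200, 200)
  near <- point_pattern(c("C", "F"), c(50, 80), c(50, 50), roi = roi)
  rep1 <- delaunay_threshold_clusters(near, 40, 2)
  expect_equal(nrow(rep1$clusters), 1)
  expect_equal(rep1$clusters$kind, "mixed")
  expect_equal(rep1$clusters$size, 2)
  expect_true(rep1$degenerate)          # < 3 points: pairwise fallback
  far <- point_pattern(c("C", "F"), c(50, 100), c(50, 50), roi = roi)
  expect_equal(nrow(delaunay_threshold_clusters(far, 40, 2)$clusters), 0)
  at <- point_pattern(c("C", "F"), c(50, 90), c(50, 50), roi = roi)
  expect_equal(nrow(delaunay_threshold_clusters(at, 40, 2)$clusters), 0)
})

test_that("clusters form a partition of a subset of the points", {
  set.seed(12)
  roi <- roi_rect(300, 300)
  pts <- roi_runif(roi, 60)
  pat <- point_pattern(sample(c("C", "F"), 60, TRUE), pts[, 1], pts[, 2],
                       roi = roi)
  rep_ <- delaunay_threshold_clusters(pat, 35, 2)
  all_members <- unlist(rep_$members)
  expect_equal(anyDuplicated(all_members), 0)
  expect_true(all(all_members %in% seq_len(60)))
  expect_equal(rep_$clusters$size,
               vapply(rep_$members, length, 0L))
  expect_true(all(rep_$clusters$size >= 2))
  # kind is consistent with composition
  expect_true(all((rep_$clusters$kind == "mixed") ==
                  (rep_$clusters$n_C > 0 & rep_$clusters$n_F > 0)))
})

test_that("triangles crossing the ROI hole are removed", {
  # two blobs on opposite sides of the lumen; the gap between them (~46 um)
  # is under the 60 um threshold, so only the hole-crossing triangle removal
  # can keep them apart
  roi <- roi_annulus(20, 150)
  set.seed(77)
  blob <- function(cx, cy, ty) {
    ang <- runif(6, 0, 2 * pi); r <- sqrt(runif(6)) * 12
    list(x = cx + r * cos(ang), y = cy + r * sin(ang), ty = rep(ty, 6))
  }
  b1 <- blob(35, 0, "C"); b2 <- blob(-35, 0, "F")
  pat <- point_pattern(c(b1$ty, b2$ty), c(b1$x, b2$x), c(b1$y, b2$y),
                       roi = roi, check = FALSE)
  with_roi <- delaunay_threshold_clusters(pat, 60, 2)
  expect_true(all(with_roi$clusters$kind %in% c("CD8-only", "Fib-only")))
  expect_equal(sum(with_roi$clusters$kind == "mixed"), 0)
  # without an ROI the cross-lumen edges survive and merge the two blobs
  pat2 <- point_pattern(c(b1$ty, b2$ty), c(b1$x, b2$x), c(b1$y, b2$y),
                        area_mm2 = roi$area_um2 / 1e6)
  no_roi <- delaunay_threshold_clusters(pat2, 60, 2)
  expect_equal(sum(no_roi$clusters$kind == "mixed"), 1)
})

test_that("collinear points fall back to pairwise edges with a flag", {
  roi <- roi_rect(200, 50)
  pat <- point_pattern(c("C", "F", "C"), c(10, 40, 70), c(25, 25, 25),
                      roi = roi)
  rep_ <- delaunay_threshold_clusters(pat, 40, 2)
  expect_true(rep_$degenerate)
  expect_equal(nrow(rep_$clusters), 1)   # chain 10-40-70 connected at < 40
  expect_equal(rep_$clusters$size, 3)
})
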