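# shared helpers: small domains, parameter tweaking, brute-force oracles

small_domain <- function(n_sites = 400, inner = 50, L = 7) {
  build_domain(site_length = L, target_site_count = n_sites,
               inner_radius = inner)
}

tweak_params <- function(p, ...) {
  o <- utils::modifyList(unclass(p), list(...))
  class(o) <- "dynamics_params"
  validate_params(o)
  o
}

# brute-force Delaunay: a triangle (i,j,k) belongs to the triangulation iff
# no other point lies strictly inside its circumcircle
brute_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    ax <- x[i]; ay <- y[i]; bx <- x[j]; by <- y[j]; cx <- x[k]; cy <- y[k]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) next  # collinear
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    r2 <- (ax - ux)^2 + (ay - uy)^2
    empty <- TRUE
    for (m in seq_len(n)) {
      if (m %in% c(i, j, k)) next
      if ((x[m] - ux)^2 + (y[m] - uy)^2 < r2 - 1e-9) { empty <- FALSE; break }
    }
    if (empty) edges <- rbind(edges, c(i, j), c(i, k), c(j, k))
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# O(n^2) nearest-neighbour scan, independent of the package implementation
brute_min_dist <- function(fx, fy, tx, ty, exclude_same_index = FALSE) {
  vapply(seq_along(fx), function(i) {
    d <- sqrt((tx - fx[i])^2 + (ty - fy[i])^2)
    if (exclude_same_index) d[i] <- Inf
    min(d)
  }, 0)
}

expect_ledger_balanced <- function(trajectory, n0C, n0F) {
  for (r in unique(trajectory$replicate)) {
    tr <- trajectory[trajectory$replicate == r, ]
    dNC <- diff(c(n0C, tr$N_C))
    dNF <- diff(c(n0F, tr$N_F))
    expect_equal(dNC, tr$iC_sta + tr$iC_exa + tr$pC_basal + tr$pC_induced -
                   tr$dC_basal - tr$dC_induced, ignore_attr = TRUE)
    expect_equal(dNF, tr$iF_sta + tr$iF_exa - tr$dF, ignore_attr = TRUE)
  }
}
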