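test_that("iteration bookkeeping matches the 3-minute clock", {
  expect_identical(iterations_for(20, 3), 3504000L)
  expect_identical(iterations_for(7, 3), 1226400L)
  expect_identical(iterations_for(1 / 175200, 3), 1L)
  expect_error(iterations_for(0, 3), "years")
  expect_error(iterations_for(1, 7), "divide")
})

test_that("healthy seeding yields the expected counts on distinct sites", {
  dom <- build_domain()
  set.seed(42)
  st <- seed_initial(dom, 660, 106)
  expect_equal(sum(st$occ == 1), 118)
  expect_equal(sum(st$occ == 2), 19)
  expect_true(all(st$occ %in% 0:2))          # one cell per site by encoding
  st0 <- seed_initial(dom, 0, 0)
  expect_equal(sum(st0$occ), 0)
  expect_error(seed_initial(small_domain(100), 20000, 20000), "sites")
})

test_that("null dynamics leave the state unchanged", {
  dom <- small_domain()
  set.seed(1)
  st <- seed_initial(dom, 600, 100)
  res <- run_steps(st, dom, dynamics_params(), 50, month_len = 50)
  expect_identical(res$state$occ, st$occ)
  expect_true(all(res$ledger[, 1:9] == 0))
})

test_that("certain death empties the CD8 population in one step", {
  dom <- small_domain()
  set.seed(2)
  st <- seed_initial(dom, 600, 100)
  p <- dynamics_params(p_dC = 1, p_dC_plus = 1)
  res <- run_steps(st, dom, p, 1, month_len = 1)
  expect_equal(res$N_C, 0)
  expect_equal(res$N_F, sum(st$occ == 2))
  expect_equal(unname(res$ledger[1, "dC_basal"]), sum(st$occ == 1))
})

test_that("per-step death count matches the binomial expectation", {
  dom <- small_domain()
  set.seed(3)
  st <- seed_initial(dom, 900, 0)
  N <- sum(st$occ == 1)
  q <- 0.02
  p <- dynamics_params(p_dC = q, p_dC_plus = q)
  deaths <- vapply(1:400, function(i) {
    run_steps(st, dom, p, 1, month_len = 1)$ledger[1, "dC_basal"]
  }, 0)
  se <- sqrt(N * q * (1 - q) / 400)
  expect_lt(abs(mean(deaths) - N * q), 3 * se)
})

test_that("division respects site exclusion and fails silently when crowded", {
  dom <- small_domain(100, 20)
  st <- seed_initial(dom, 0, 0)
  st$occ[] <- 1L                       # full lattice of C cells
  p <- dynamics_params(p_C = 1, p_C_F = 1)
  res <- run_steps(st, dom, p, 3, month_len = 3)
  expect_equal(res$N_C, dom$n_sites)   # no room: population unchanged
  expect_true(all(res$state$occ == 1L))
})

test_that("exacerbation bursts follow the annual schedule", {
  dom <- small_domain()
  set.seed(4)
  st <- seed_initial(dom, 300, 50)
  yr <- STEPS_PER_YEAR()
  # control-style parameters: no exacerbation entry at the year boundary
  p0 <- dynamics_params(p_iexa_F = 0, exac_burst = 10)
  st_late <- st; st_late$t <- yr - 1L  # next step crosses the boundary
  res <- run_steps(st_late, dom, p0, 1, month_len = 1)
  expect_equal(unname(res$ledger[1, "iF_exa"]), 0)
  # certain entry: exactly burst-size F cells added
  p1 <- dynamics_params(p_iexa_F = 1, exac_burst = 5)
  res <- run_steps(st_late, dom, p1, 1, month_len = 1)
  expect_equal(unname(res$ledger[1, "iF_exa"]), 5)
  expect_equal(res$N_F, sum(st$occ == 2) + 5)
  # full lattice: no additions possible
  full <- st_late; full$occ[] <- 2L
  res <- run_steps(full, dom, p1, 1, month_len = 1)
  expect_equal(unname(res$ledger[1, "iF_exa"]), 0)
  # standalone burst operation mirrors the in-run behaviour
  st2 <- annual_exacerbation(st, dom, p0)
  expect_identical(st2$occ, st$occ)
  st3 <- annual_exacerbation(st, dom, p1)
  expect_equal(sum(st3$occ == 2L), sum(st$occ == 2L) + 5)
  expect_identical(annual_exacerbation(full, dom, p1)$occ, full$occ)
})

test_that("monthly ledgers balance exactly for both species", {
  dom <- small_domain()
  p <- dynamics_params(p_ista_C = 0.3, p_ista_F = 0.2, p_iexa_F = 0.5,
                       exac_burst = 4, p_C = 0.002, p_C_F = 0.01,
                       p_dC = 0.001, p_dC_plus = 0.004, p_dF = 0.002,
                       p_move_C = 0.5, p_move_F = 0.2, beta_F = 1)
  sim <- simulate_tissue(dom, p, years = 1200 / 175200, replicates = 3,
                         seed = 7, n0C = 600, n0F = 100, month_len = 100)
  n0C <- round(600 * dom$area_mm2); n0F <- round(100 * dom$area_mm2)
  expect_ledger_balanced(sim$trajectory, n0C, n0F)
  # occupancy stays one cell per site (encoding) and tallies match the ledger
  last <- sim$trajectory[sim$trajectory$month == max(sim$trajectory$month), ]
  for (r in seq_along(sim$final_states)) {
    st <- sim$final_states[[r]]
    expect_true(all(st$occ %in% 0:2))
    expect_equal(sum(st$occ == 1), last$N_C[last$replicate == r])
    expect_equal(sum(st$occ == 2), last$N_F[last$replicate == r])
  }
})

test_that("identical seeds give bit-identical trajectories", {
  dom <- small_domain()
  p <- tweak_params(default_params("copd"), p_ista_C = 0.05, p_ista_F = 0.02,
                    p_dC = 0.001, p_dC_plus = 0.002, p_dF = 0.001)
  s1 <- simulate_tissue(dom, p, years = 600 / 175200, replicates = 2,
                        seed = 99, month_len = 100)
  s2 <- simulate_tissue(dom, p, years = 600 / 175200, replicates = 2,
                        seed = 99, month_len = 100)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$final_states, s2$final_states)
  s3 <- simulate_tissue(dom, p, years = 600 / 175200, replicates = 2,
                        seed = 100, month_len = 100)
  expect_false(identical(s1$trajectory, s3$trajectory))
})

test_that("non-interacting limit matches the birth-death-immigration mean", {
  dom <- small_domain(400, 30)
  # immigration i, basal death d, basal division b, no interactions:
  # stationary mean N* = i / (d - b)
  i <- 0.05; d <- 0.002; b <- 0.001
  p <- dynamics_params(p_ista_C = i, p_C = b, p_C_F = b,
                       p_dC = d, p_dC_plus = d, p_move_C = 0.5)
  st <- seed_initial(dom, 0, 0)
  ends <- vapply(1:16, function(r) {
    set.seed(1000 + r)
    run_steps(st, dom, p, 20000, month_len = 20000)$N_C
  }, 0)
  nstar <- i / (d - b)
  # stationary variance of the BDI chain: N* * d / (d - b)
  se <- sqrt(nstar * d / (d - b) / 16)
  expect_lt(abs(mean(ends) - nstar), 3 * se)
})

test_that("COPD dynamics outgrow control dynamics", {
  dom <- build_domain()
  ctrl <- simulate_tissue(dom, default_params("control"), years = 1,
                          replicates = 8, seed = 11)
  copd <- simulate_tissue(dom, default_params("copd"), years = 1,
                          replicates = 8, seed = 11)
  sc <- summary(ctrl); so <- summary(copd)
  expect_gt(so["dens_C", "median"], sc["dens_C", "median"])
  expect_gt(so["dens_F", "median"], sc["dens_F", "median"])
})
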