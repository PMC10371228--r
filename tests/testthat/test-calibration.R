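test_that("mean-field right-hand side honours its closure limits", {
  dom <- build_domain()
  parms <- list(params = dynamics_params(), n_sites = dom$n_sites,
                steps_per_year = 175200)
  expect_equal(mean_field_rhs(0, c(100, 20), parms)[[1]], c(0, 0))
  # with no fibrocytes the CD8 growth term uses the basal rate only
  p <- dynamics_params(p_C = 1e-5, p_C_F = 1e-3)
  parms$params <- p
  d0 <- mean_field_rhs(0, c(100, 0), parms)[[1]][1]
  expect_equal(d0, 100 * 1e-5 * (1 - (100 / dom$n_sites)^8) * 175200,
               tolerance = 1e-10)
})

test_that("fibrocyte fixed point matches long-run stochastic simulation", {
  dom <- small_domain(400, 30)
  iF <- 0.02; dF <- 4e-4            # N* = 50, relaxation ~ 2500 steps
  p <- dynamics_params(p_ista_F = iF, p_dF = dF, p_move_F = 0.2)
  st <- seed_initial(dom, 0, 0)
  ends <- vapply(1:16, function(r) {
    set.seed(2000 + r)
    run_steps(st, dom, p, 25000, month_len = 25000)$N_F
  }, 0)
  nstar <- iF / dF
  se <- sqrt(nstar / 16)            # Poisson stationary variance
  expect_lt(abs(mean(ends) - nstar), 3 * se)
})

test_that("calibration lands the mean-field endpoints on the targets", {
  fit <- calibrate()
  expect_true(all(abs(fit$report$residual / fit$report$observed) < 0.02))
  # narrative structure: COPD differs from control only in p_C_F, beta_F,
  # exacerbation inflow
  same <- c("p_ista_C", "p_ista_F", "p_C", "p_dC", "p_dC_plus", "p_dF",
            "p_move_C", "p_move_F", "k_crowd")
  for (nm in same) {
    expect_equal(fit$copd_params[[nm]], fit$control_params[[nm]])
  }
  expect_gt(fit$copd_params$p_C_F, fit$control_params$p_C_F)
  expect_gt(fit$copd_params$p_iexa_F, 0)
  expect_equal(fit$control_params$p_iexa_F, 0)
})

test_that("a stationary target admits a near-zero net-flow fit", {
  # target equal to the initial state: fitted rates must keep the system flat
  tg <- calibration_targets(control_C = 660.0001, control_F = 106,
                            copd_C = 661, copd_F = 212)
  fit <- calibrate(tg)
  tr <- integrate_mean_field(fit$control_params, 20, c(660, 106))
  expect_equal(tr$dens_C[nrow(tr)], 660, tolerance = 0.01)
  expect_equal(tr$dens_F[nrow(tr)], 106, tolerance = 0.01)
})

test_that("infiltration and death rates are recovered from ledgers", {
  dom <- small_domain(900, 40)
  truth <- dynamics_params(p_ista_C = 0.03, p_ista_F = 0.02,
                           p_C = 1e-5, p_C_F = 1e-5,
                           p_dC = 2e-4, p_dC_plus = 2e-4, p_dF = 2e-4,
                           p_move_C = 0.3, p_move_F = 0.1)
  sim <- simulate_tissue(dom, truth, years = 0.5, replicates = 4, seed = 55,
                         n0C = 1500, n0F = 1000)
  est <- recover_rates(sim)
  expect_lt(abs(est["p_ista_C"] / truth$p_ista_C - 1), 0.10)
  expect_lt(abs(est["p_ista_F"] / truth$p_ista_F - 1), 0.10)
  expect_lt(abs(est["p_dC"] / truth$p_dC - 1), 0.10)
  expect_lt(abs(est["p_dF"] / truth$p_dF - 1), 0.10)
})

test_that("mean-field trajectory tracks the ensemble mean when non-interacting", {
  dom <- small_domain(400, 30)
  p <- dynamics_params(p_ista_C = 0.03, p_C = 5e-4, p_C_F = 5e-4,
                       p_dC = 1e-3, p_dC_plus = 1e-3, p_move_C = 0.3)
  n_steps <- 10000
  ends <- vapply(1:32, function(r) {
    set.seed(3000 + r)
    st <- seed_initial(dom, 0, 0)
    run_steps(st, dom, p, n_steps, month_len = n_steps)$N_C
  }, 0)
  mf <- integrate_mean_field(p, n_steps / 175200, c(0, 0), dom,
                             dt = n_steps / 175200 / 50)
  pred <- mf$dens_C[nrow(mf)] * dom$area_mm2
  se <- stats::sd(ends) / sqrt(32)
  expect_lt(abs(mean(ends) - pred), 3 * se)
})
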