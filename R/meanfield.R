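#' Observed density targets used for calibration
#'
#' The quantities the rate calibration aims at: initial healthy densities,
#' 20-year endpoint medians for the control and COPD scenarios, and the
#' characteristic times of the slow processes (all in cells/mm^2 and years).
#'
#' @param initial_C,initial_F healthy seeding densities.
#' @param control_C,control_F control endpoint medians.
#' @param copd_C,copd_F COPD endpoint medians.
#' @param plateau_F_years time for the fibrocyte population to become
#'   stationary under COPD dynamics.
#' @return object of class `calibration_targets`.
#' @export
calibration_targets <- function(initial_C = 660, initial_F = 106,
                                control_C = 754, control_F = 106,
                                copd_C = 1187, copd_F = 212,
                                plateau_F_years = 7) {
  v <- c(initial_C, initial_F, control_C, control_F, copd_C, copd_F)
  if (any(v <= 0)) stop("densities must be > 0")
  if (control_C > copd_C || control_F > copd_F) {
    stop("control endpoints must not exceed COPD endpoints")
  }
  structure(list(initial_C = initial_C, initial_F = initial_F,
                 control_C = control_C, control_F = control_F,
                 copd_C = copd_C, copd_F = copd_F,
                 plateau_F_years = plateau_F_years),
            class = "calibration_targets")
}

#' Mean-field right-hand side of the automaton
#'
#' Deterministic closure of the stochastic update rule under the
#' independent-site approximation: the probability that a CD8+ T cell has at
#' least one fibrocyte among its 8 Moore neighbours is
#' `q_F = 1 - (1 - N_F/S)^8`, and the probability of `k_crowd` or more CD8
#' neighbours is a binomial tail `q_Ck = P[Bin(8, N_C/S) >= k_crowd]`.
#' Exacerbation bursts are discrete annual impulses, handled as integration
#' events by [integrate_mean_field()] so the deterministic endpoint sits at
#' the same phase of the annual sawtooth as the automaton's final state.
#' State and rates are in cell counts per step; the returned derivative is
#' per year (multiplied by the steps-per-year conversion), which is the time
#' unit used for integration.
#'
#' @param t time (years; unused, autonomous system).
#' @param y state `c(N_C, N_F)` in cell counts.
#' @param parms list with `params` (a [dynamics_params()]), `n_sites`, and
#'   `steps_per_year`.
#' @return list of derivatives, deSolve convention.
#' @export
mean_field_rhs <- function(t, y, parms) {
  p <- parms$params
  S <- parms$n_sites
  spy <- parms$steps_per_year
  NC <- max(y[1], 0); NF <- max(y[2], 0)
  qF <- 1 - (1 - min(NF / S, 1))^8
  qCk <- 1 - stats::pbinom(p$k_crowd - 1, 8, min(NC / S, 1))
  avail <- 1 - min((NC + NF) / S, 1)^8   # division needs an empty neighbour
  birth <- (p$p_C * (1 - qF) + p$p_C_F * qF) * avail * NC
  death <- (p$p_dC * (1 - qCk) + p$p_dC_plus * qCk) * NC
  dNC <- (p$p_ista_C + birth - death) * spy
  dNF <- (p$p_ista_F - p$p_dF * NF) * spy
  list(c(dNC, dNF))
}

#' Integrate the mean-field model
#'
#' @param params a [dynamics_params()].
#' @param years duration.
#' @param init initial densities `c(C, F)` in cells/mm^2.
#' @param domain a [build_domain()] (supplies site count and area).
#' @param dt output time step, years.
#' @return data.frame with `year`, `dens_C`, `dens_F` (cells/mm^2).
#' @export
integrate_mean_field <- function(params, years, init = c(660, 106),
                                 domain = build_domain(), dt = 1 / 12) {
  y0 <- init * domain$area_mm2
  times <- seq(0, years, by = dt)
  impulse <- params$exac_burst * params$p_iexa_F
  ev <- NULL
  final_burst <- 0
  if (impulse > 0 && params$exac_per_year > 0) {
    # annual exacerbation impulses, matching the automaton's schedule
    # (fired at every year boundary, including the final one; the impulse
    # coinciding with the end of integration is added after the solve, since
    # the solver reports the pre-event state at its last time point)
    tev <- seq(1 / params$exac_per_year, years, by = 1 / params$exac_per_year)
    if (length(tev) && abs(tev[length(tev)] - years) < 1e-9) {
      final_burst <- impulse
      tev <- tev[-length(tev)]
    }
    if (length(tev)) {
      times <- sort(unique(c(times, tev)))
      ev <- list(data = data.frame(var = "NF", time = tev, value = impulse,
                                   method = "add"))
    }
  }
  out <- deSolve::ode(y = c(NC = y0[1], NF = y0[2]), times = times,
                      func = mean_field_rhs,
                      parms = list(params = params, n_sites = domain$n_sites,
                                   steps_per_year = STEPS_PER_YEAR()),
                      rtol = 1e-8, atol = 1e-8, events = ev)
  out[nrow(out), "NF"] <- out[nrow(out), "NF"] + final_burst
  data.frame(year = out[, "time"],
             dens_C = out[, "NC"] / domain$area_mm2,
             dens_F = out[, "NF"] / domain$area_mm2)
}

#' Calibrate per-step rates against observed densities
#'
#' Fits the free rates of the dynamics so that integrating the mean-field
#' companion model for 20 years from the healthy densities reproduces the
#' observed endpoint medians.  The COPD set differs from control only in the
#' contact-induced division probability `p_C_F`, the fibrocyte chemotaxis
#' weight `beta_F`, and the exacerbation inflow `p_iexa_F`; all other rates
#' are shared.  Free parameters and their targets:
#' \itemize{
#'   \item `p_ista_F`: closed form, stationarity of the control fibrocyte
#'     population at its initial density;
#'   \item `p_dF`: closed form from the fibrocyte plateau time (stationary
#'     state reached, to 95%, after `plateau_F_years` under COPD dynamics);
#'   \item `p_iexa_F`: root of the COPD fibrocyte endpoint;
#'   \item `p_ista_C`: root of the control CD8 endpoint;
#'   \item `p_C_F` (COPD): root of the COPD CD8 endpoint.
#' }
#' The remaining rates (`base`) are fixed biological choices documented in
#' [default_params()].  An optional multiplicative `closure_correction` on
#' the fibrocyte-neighbourhood occupancy compensates the independent-site
#' approximation when the stochastic model is run with chemotactic
#' clustering (see the methods vignette).
#'
#' @param targets a [calibration_targets()].
#' @param base named list of the fixed rates (defaults from
#'   [default_params()]'s rate set).
#' @param domain a [build_domain()].
#' @param years horizon over which endpoints are matched.
#' @param closure_correction multiplier applied to the mean-field `q_F` when
#'   solving for the COPD `p_C_F` (1 = plain mean field).
#' @return object of class `mf_calibration`: `control_params`, `copd_params`,
#'   `report` (data.frame: target, observed, fitted, residual).
#' @export
calibrate <- function(targets = calibration_targets(),
                      base = .default_rates(), domain = build_domain(),
                      years = 20, closure_correction = 1) {
  A <- domain$area_mm2
  spy <- STEPS_PER_YEAR()

  # fibrocytes: linear kinetics, closed form + 1-D root
  p_dF <- log(20) / (targets$plateau_F_years * spy)  # 95% of the gap closed
  p_ista_F <- p_dF * targets$initial_F * A

  make_ctrl <- function(p_ista_C, p_C_F) {
    dynamics_params(p_ista_C = p_ista_C, p_ista_F = p_ista_F,
                    p_C = base$p_C, p_C_F = p_C_F,
                    p_dC = base$p_dC, p_dC_plus = base$p_dC_plus,
                    k_crowd = base$k_crowd, p_dF = p_dF,
                    p_move_C = base$p_move_C, p_move_F = base$p_move_F,
                    scenario_label = "control")
  }
  endpoint <- function(par, init) {
    tr <- integrate_mean_field(par, years, init, domain, dt = 1 / 4)
    unlist(tr[nrow(tr), c("dens_C", "dens_F")])
  }
  init <- c(targets$initial_C, targets$initial_F)

  # control CD8 endpoint -> p_ista_C
  f_c <- function(pi_c) {
    endpoint(make_ctrl(pi_c, base$p_C_F_control), init)[1] - targets$control_C
  }
  p_ista_C <- stats::uniroot(f_c, c(1e-6, 0.5), tol = 1e-10)$root
  control_params <- make_ctrl(p_ista_C, base$p_C_F_control)

  # COPD fibrocyte endpoint -> p_iexa_F
  make_copd <- function(p_iexa_F, p_C_F) {
    dynamics_params(p_ista_C = p_ista_C, p_ista_F = p_ista_F,
                    p_iexa_F = p_iexa_F, exac_burst = base$exac_burst,
                    exac_per_year = 1L,
                    p_C = base$p_C, p_C_F = p_C_F,
                    p_dC = base$p_dC, p_dC_plus = base$p_dC_plus,
                    k_crowd = base$k_crowd, p_dF = p_dF,
                    p_move_C = base$p_move_C, p_move_F = base$p_move_F,
                    beta_F = base$beta_F_copd,
                    scenario_label = "copd")
  }
  f_f <- function(pe) {
    endpoint(make_copd(pe, base$p_C_F_copd), init)[2] - targets$copd_F
  }
  p_iexa_F <- stats::uniroot(f_f, c(0, 1), tol = 1e-10)$root

  # COPD CD8 endpoint -> p_C_F, with optional closure correction on q_F
  f_cf <- function(pcf) {
    par <- make_copd(p_iexa_F, pcf)
    if (closure_correction != 1) {
      # inflate the effective contact probability by scaling p_C_F's lever
      par$p_C_F <- par$p_C + (pcf - par$p_C) * closure_correction
    }
    endpoint(par, init)[1] - targets$copd_C
  }
  p_C_F_copd <- stats::uniroot(f_cf, c(base$p_C, 1e-3), tol = 1e-12)$root
  copd_params <- make_copd(p_iexa_F, p_C_F_copd)

  ec <- endpoint(control_params, init)
  eo <- endpoint(copd_params, init)
  report <- data.frame(
    target = c("control_C", "control_F", "copd_C", "copd_F"),
    observed = c(targets$control_C, targets$control_F,
                 targets$copd_C, targets$copd_F),
    fitted = c(ec, eo))
  report$residual <- report$fitted - report$observed
  if (any(abs(report$residual / report$observed) > 0.02)) {
    stop("calibration did not converge within 2%: ",
         paste(sprintf("%s %+0.1f", report$target, report$residual),
               collapse = ", "))
  }

  structure(list(control_params = control_params, copd_params = copd_params,
                 report = report, targets = targets, domain_area = A),
            class = "mf_calibration")
}

#' @export
print.mf_calibration <- function(x, ...) {
  cat("Mean-field rate calibration\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Mean-field trajectory predicted by a calibration
#'
#' @param object an `mf_calibration`.
#' @param scenario `"control"` or `"copd"`.
#' @param years horizon.
#' @param ... unused.
#' @return data.frame from [integrate_mean_field()].
#' @export
predict.mf_calibration <- function(object, scenario = c("control", "copd"),
                                   years = 20, ...) {
  scenario <- match.arg(scenario)
  p <- if (scenario == "control") object$control_params else object$copd_params
  integrate_mean_field(p, years, c(object$targets$initial_C,
                                   object$targets$initial_F))
}

#' Stochastic simulation from a calibration's parameter sets
#'
#' @param object an `mf_calibration`.
#' @param nsim replicates.
#' @param seed master seed.
#' @param scenario `"control"` or `"copd"`.
#' @param years horizon.
#' @param domain simulation domain.
#' @param ... passed to [simulate_tissue()].
#' @return a `ca_sim`.
#' @export
simulate.mf_calibration <- function(object, nsim = 8, seed = 1,
                                    scenario = c("control", "copd"),
                                    years = 20, domain = build_domain(), ...) {
  scenario <- match.arg(scenario)
  p <- if (scenario == "control") object$control_params else object$copd_params
  simulate_tissue(domain, p, years = years, replicates = nsim, seed = seed,
                  n0C = object$targets$initial_C,
                  n0F = object$targets$initial_F, ...)
}

#' @export
coef.mf_calibration <- function(object, ...) {
  c(p_ista_C = object$control_params$p_ista_C,
    p_ista_F = object$control_params$p_ista_F,
    p_dF = object$control_params$p_dF,
    p_iexa_F = object$copd_params$p_iexa_F,
    p_C_F_control = object$control_params$p_C_F,
    p_C_F_copd = object$copd_params$p_C_F)
}

#' Stochastic refinement of a mean-field calibration
#'
#' The independent-site closure misses the spatial correlations the automaton
#' builds up (daughters born adjacent, chemotactic contact enrichment), so
#' rates fitted on the mean-field endpoints leave the stochastic model a few
#' percent off its targets.  This step runs full stochastic ensembles with
#' the mean-field-calibrated rates, measures the ensemble-mean endpoint
#' offsets, and re-solves the two CD8-side rates (`p_ista_C`, COPD `p_C_F`)
#' against offset-compensated targets — one secant iteration through the
#' mean-field roots, which suffices because the offsets are small and smooth
#' in the rates.
#'
#' @param fit an [calibrate()] result.
#' @param domain the simulation domain.
#' @param replicates stochastic ensemble size per scenario.
#' @param years horizon (matching the calibration horizon).
#' @param seed master seed for the ensembles.
#' @return an `mf_calibration` with refined `control_params`, `copd_params`;
#'   the `report` gains the measured stochastic endpoints.
#' @export
refine_calibration <- function(fit, domain = build_domain(), replicates = 16,
                               years = 20, seed = 1) {
  tg <- fit$targets
  mean_end <- function(params, sd) {
    sim <- simulate_tissue(domain, params, years = years,
                           replicates = replicates, seed = sd)
    tr <- sim$trajectory
    colMeans(tr[tr$month == max(tr$month), c("dens_C", "dens_F")])
  }
  ec <- mean_end(fit$control_params, seed)
  eo <- mean_end(fit$copd_params, seed + 1L)

  # compensate the targets by the measured closure offset and re-root
  tg2 <- tg
  tg2$control_C <- tg$control_C^2 / ec[["dens_C"]]
  tg2$copd_C <- tg$copd_C^2 / eo[["dens_C"]]
  base <- .default_rates()
  base$p_C_F_control <- fit$control_params$p_C_F
  base$p_dC <- fit$control_params$p_dC
  base$p_dC_plus <- fit$control_params$p_dC_plus
  base$k_crowd <- fit$control_params$k_crowd
  base$p_move_C <- fit$control_params$p_move_C
  base$p_move_F <- fit$control_params$p_move_F
  base$beta_F_copd <- fit$copd_params$beta_F
  base$exac_burst <- fit$copd_params$exac_burst
  ref <- calibrate(tg2, base = base, domain = domain, years = years)
  ref$targets <- tg
  ref$report$stochastic_mean <- c(ec[["dens_C"]], ec[["dens_F"]],
                                  eo[["dens_C"]], eo[["dens_F"]])
  ref
}

#' Write a calibration's parameter sets to a params file
#'
#' Emits a YAML file directly consumable as the `params` block of a run
#' configuration, plus the fit report as CSV alongside.
#'
#' @param fit an `mf_calibration`.
#' @param path YAML output path (the report goes to `<path>_report.csv`).
#' @export
write_calibration <- function(fit, path) {
  drop_label <- function(p) {
    p <- unclass(p); p$scenario_label <- NULL; p
  }
  yaml::write_yaml(list(control = drop_label(fit$control_params),
                        copd = drop_label(fit$copd_params)), path)
  utils::write.csv(fit$report, paste0(path, "_report.csv"), row.names = FALSE)
  invisible(path)
}

#' Recover infiltration and death rates from monthly ledgers
#'
#' Moment estimators from a simulation trajectory: infiltration rates are
#' total stable-state entries over total steps; death rates are total deaths
#' over total cell-steps of exposure (population size integrated over time,
#' approximated by the trapezoid of the monthly snapshots).  Used as the
#' parameter-recovery check of the simulator's bookkeeping.
#'
#' @param sim a [simulate_tissue()] result.
#' @param n0C,n0F the initial counts (exposure of the first month's start).
#' @return named vector with `p_ista_C`, `p_ista_F`, `p_dF`, `p_dC`
#'   (the C death estimate pools basal and crowding-induced deaths and is
#'   therefore an effective rate).
#' @export
recover_rates <- function(sim, n0C = NULL, n0F = NULL) {
  tr <- sim$trajectory
  month_len <- STEPS_PER_MONTH()
  reps <- split(tr, tr$replicate)
  if (is.null(n0C)) n0C <- round(sim$n0C * sim$domain$area_mm2)
  if (is.null(n0F)) n0F <- round(sim$n0F * sim$domain$area_mm2)
  tot <- function(col) sum(tr[[col]])
  n_steps_total <- sum(vapply(reps, nrow, 0L)) * month_len

  exposure <- function(col, n0) {
    sum(vapply(reps, function(d) {
      nv <- c(n0, d[[col]])
      sum((nv[-1] + nv[-length(nv)]) / 2) * month_len
    }, 0))
  }
  expC <- exposure("N_C", n0C)
  expF <- exposure("N_F", n0F)

  c(p_ista_C = tot("iC_sta") / n_steps_total,
    p_ista_F = tot("iF_sta") / n_steps_total,
    p_dF = if (expF > 0) tot("dF") / expF else NA_real_,
    p_dC = if (expC > 0) (tot("dC_basal") + tot("dC_induced")) / expC
           else NA_real_)
}
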