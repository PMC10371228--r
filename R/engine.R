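STEPS_PER_YEAR <- function(step_minutes = 3) as.integer(365 * 24 * 60 / step_minutes)
STEPS_PER_MONTH <- function(step_minutes = 3) STEPS_PER_YEAR(step_minutes) %/% 12L

#' Number of iterations for a simulated duration
#'
#' One simulated year is 365 days; with the default 3-minute step a 20-year
#' run is 3,504,000 iterations and one month is exactly 14,600 iterations.
#'
#' @param years simulated duration (may be fractional as long as the implied
#'   iteration count is integral).
#' @param step_minutes step length in minutes; must divide an hour evenly.
#' @return integer iteration count.
#' @examples
#' iterations_for(20)   # 3504000
#' @export
iterations_for <- function(years, step_minutes = 3) {
  if (years <= 0) stop("years must be > 0")
  if (60 %% step_minutes != 0) {
    stop("step_minutes must divide an hour evenly")
  }
  n <- years * 365 * 24 * (60 / step_minutes)
  if (abs(n - round(n)) > 1e-6) {
    stop("duration does not correspond to a whole number of iterations")
  }
  as.integer(round(n))
}

#' Randomly seed the lattice at given densities
#'
#' Places `round(density x area)` cells of each type uniformly at random on
#' distinct sites.  At the default healthy densities (660 CD8+ T cells/mm^2,
#' 106 fibrocytes/mm^2) on the default domain this yields 118 C and 19 F
#' cells.
#'
#' @param domain a [build_domain()] object.
#' @param n0C,n0F initial densities, cells/mm^2.
#' @return object of class `ca_state`: list with `occ` (integer occupancy per
#'   site: 0 empty, 1 C, 2 F), `t` (elapsed iterations) and the domain
#'   dimensions.
#' @export
seed_initial <- function(domain, n0C = 660, n0F = 106) {
  if (n0C < 0 || n0F < 0) stop("densities must be >= 0")
  nC <- round(n0C * domain$area_mm2)
  nF <- round(n0F * domain$area_mm2)
  if (nC + nF > domain$n_sites) {
    stop("requested ", nC + nF, " cells but domain has only ",
         domain$n_sites, " sites")
  }
  occ <- integer(domain$n_sites)
  if (nC + nF > 0) {
    pick <- sample.int(domain$n_sites, nC + nF)
    occ[pick[seq_len(nC)]] <- 1L
    if (nF > 0) occ[pick[nC + seq_len(nF)]] <- 2L
  }
  structure(list(occ = occ, t = 0L, n_sites = domain$n_sites),
            class = "ca_state")
}

#' @export
print.ca_state <- function(x, ...) {
  cat(sprintf("ca_state: %d C, %d F on %d sites (t = %d steps)\n",
              sum(x$occ == 1L), sum(x$occ == 2L), x$n_sites, x$t))
  invisible(x)
}

#' Apply one exacerbation burst to a state
#'
#' Offers `exac_burst` entry slots; each is taken with probability
#' `p_iexa_F` (fibrocyte) and `p_iexa_C` (CD8), the entrant landing on a
#' uniformly chosen empty site.  Control parameter sets carry zero entry
#' probabilities, so the state is returned unchanged.  During a simulation
#' run the engine applies the same burst at every year boundary; this
#' function exposes the operation for direct use and testing.
#'
#' @param state a `ca_state`.
#' @param domain the matching domain.
#' @param params a [dynamics_params()].
#' @return the updated `ca_state`.
#' @export
annual_exacerbation <- function(state, domain, params) {
  validate_params(params)
  occ <- state$occ
  for (b in seq_len(params$exac_burst)) {
    for (ty in c(2L, 1L)) {
      p <- if (ty == 2L) params$p_iexa_F else params$p_iexa_C
      if (p > 0 && any(occ == 0L) && stats::runif(1) < p) {
        empty <- which(occ == 0L)
        occ[empty[sample.int(length(empty), 1)]] <- ty
      }
    }
  }
  state$occ <- occ
  state
}

#' Advance the automaton by a number of steps
#'
#' Low-level access to the stochastic engine: runs `n_steps` 3-minute
#' iterations of the update rule (exacerbation schedule, Bernoulli
#' infiltration onto empty sites, then each cell in a fresh random order
#' attempts one action with priority death, division (C only), movement) and
#' returns the updated state together with the monthly event ledger.
#'
#' @param state a [seed_initial()] state.
#' @param domain the matching domain.
#' @param params a [dynamics_params()] object.
#' @param n_steps number of iterations to run.
#' @param month_len ledger aggregation window, iterations.
#' @param step_minutes step length in minutes (fixes the annual schedule).
#' @return list with `state` (advanced `ca_state`), `ledger` (matrix, one row
#'   per completed month: infiltration / division / death counts split into
#'   basal and induced components, plus end-of-month `N_C`, `N_F`) and
#'   `residual_events` (event counts since the last completed month).
#' @export
run_steps <- function(state, domain, params, n_steps,
                      month_len = STEPS_PER_MONTH(step_minutes),
                      step_minutes = 3) {
  stopifnot(inherits(state, "ca_state"), inherits(domain, "lattice_domain"))
  validate_params(params)
  nbr0 <- domain$nbr - 1L
  nbr0[is.na(nbr0)] <- -1L
  res <- cpp_run_phase(state$occ, nbr0, unclass(params),
                       as.integer(n_steps), as.integer(month_len),
                       STEPS_PER_YEAR(step_minutes), as.integer(state$t))
  new_state <- structure(list(occ = res$occ, t = state$t + as.integer(n_steps),
                              n_sites = domain$n_sites), class = "ca_state")
  list(state = new_state, ledger = res$ledger,
       residual_events = res$residual_events,
       N_C = res$N_C, N_F = res$N_F)
}

#' Simulate tissue dynamics over years, with replicates
#'
#' Runs the cellular automaton for one or more consecutive phases (e.g. 20
#' years of COPD dynamics followed by 7 years of therapy dynamics), replicated
#' with independent seeds, and collects monthly population ledgers and final
#' states.
#'
#' @param domain a [build_domain()] object.
#' @param params either a single [dynamics_params()] object or a list of
#'   phases, each `list(params = <dynamics_params>, years = <years>)`.
#' @param years duration in years when `params` is a single parameter set.
#' @param replicates number of independent replicates.
#' @param seed master seed; per-replicate seeds are drawn from it
#'   (`set.seed(seed)` then one `sample.int(2^31 - 1)` draw per replicate), so
#'   a run is fully reproducible and each replicate is independent.
#' @param n0C,n0F initial seeding densities, cells/mm^2.
#' @param init_states optional list of `ca_state` objects (one per replicate)
#'   to start from instead of random seeding, e.g. COPD burn-in states for
#'   therapy runs.
#' @param step_minutes iteration length, minutes.
#' @param month_len ledger aggregation window in iterations (default one
#'   calendar month, 14,600 steps; shorten for sub-month diagnostic runs).
#'   Durations that are not whole months drop the trailing partial window
#'   from the ledger.
#' @return object of class `ca_sim`: list with `trajectory` (data.frame:
#'   replicate, month, year, N_C, N_F, dens_C, dens_F and the monthly event
#'   ledger both as raw counts and per mm^2), `final_states`, `domain`,
#'   `phases`, `seeds`.
#' @examples
#' dom <- build_domain(7, 400, 50)
#' sim <- simulate_tissue(dom, default_params("control"), years = 1/12,
#'                        replicates = 2, seed = 1)
#' summary(sim)
#' @export
simulate_tissue <- function(domain, params, years = NULL, replicates = 1,
                            seed = 1, n0C = 660, n0F = 106,
                            init_states = NULL, step_minutes = 3,
                            month_len = STEPS_PER_MONTH(step_minutes)) {
  if (inherits(params, "dynamics_params")) {
    if (is.null(years)) stop("years must be given with a single parameter set")
    phases <- list(list(params = params, years = years))
  } else {
    phases <- params
    for (ph in phases) {
      stopifnot(inherits(ph$params, "dynamics_params"), ph$years > 0)
    }
  }
  if (!is.null(init_states) && length(init_states) != replicates) {
    stop("init_states must have one state per replicate")
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)

  total_steps <- sum(vapply(phases,
                            function(ph) iterations_for(ph$years, step_minutes),
                            0L))
  if (total_steps < month_len) {
    stop("run shorter than one ledger window; pass a smaller month_len")
  }
  traj <- vector("list", replicates)
  finals <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    state <- if (is.null(init_states)) seed_initial(domain, n0C, n0F)
             else init_states[[r]]
    led_all <- NULL
    for (ph in phases) {
      n_steps <- iterations_for(ph$years, step_minutes)
      res <- run_steps(state, domain, ph$params, n_steps, month_len,
                       step_minutes)
      state <- res$state
      led_all <- rbind(led_all, res$ledger)
    }
    finals[[r]] <- state
    df <- as.data.frame(led_all)
    df$replicate <- r
    df$month <- seq_len(nrow(df))
    traj[[r]] <- df
  }
  trajectory <- do.call(rbind, traj)
  trajectory$year <- trajectory$month * month_len / STEPS_PER_YEAR(step_minutes)
  trajectory$dens_C <- trajectory$N_C / domain$area_mm2
  trajectory$dens_F <- trajectory$N_F / domain$area_mm2
  for (nm in c("iC_sta", "iC_exa", "iF_sta", "iF_exa", "pC_basal",
               "pC_induced", "dC_basal", "dC_induced", "dF")) {
    trajectory[[paste0(nm, "_mm2")]] <- trajectory[[nm]] / domain$area_mm2
  }
  first <- c("replicate", "month", "year", "N_C", "N_F", "dens_C", "dens_F")
  trajectory <- trajectory[, c(first, setdiff(names(trajectory), first))]

  structure(list(trajectory = trajectory, final_states = finals,
                 domain = domain, phases = phases, seeds = rep_seeds,
                 n0C = n0C, n0F = n0F),
            class = "ca_sim")
}

#' @export
print.ca_sim <- function(x, ...) {
  labels <- vapply(x$phases, function(p) p$params$scenario_label, "")
  yrs <- vapply(x$phases, function(p) p$years, 0)
  cat("Cellular-automaton tissue simulation\n")
  cat("  phases:    ", paste(sprintf("%s (%g y)", labels, yrs), collapse = " -> "), "\n")
  cat("  replicates:", length(x$final_states), "\n")
  s <- summary(x)
  cat(sprintf("  final medians: %.0f C/mm^2, %.0f F/mm^2\n",
              s["dens_C", "median"], s["dens_F", "median"]))
  invisible(x)
}

#' Summary of endpoint densities across replicates
#'
#' @param object a `ca_sim`.
#' @param probs quantiles reported alongside the median.
#' @param ... unused.
#' @return matrix with rows `dens_C`, `dens_F` (cells/mm^2 at the final
#'   month): median and the requested quantiles across replicates.
#' @export
summary.ca_sim <- function(object, probs = c(0.025, 0.975), ...) {
  tr <- object$trajectory
  last <- tr[tr$month == max(tr$month), ]
  out <- rbind(
    dens_C = c(median = stats::median(last$dens_C),
               stats::quantile(last$dens_C, probs)),
    dens_F = c(median = stats::median(last$dens_F),
               stats::quantile(last$dens_F, probs)))
  out
}

#' Plot population trajectories
#'
#' Monthly mean densities across replicates with a shaded +/- 1 SD band.
#'
#' @param x a `ca_sim`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ca_sim <- function(x, ...) {
  tr <- x$trajectory
  agg <- stats::aggregate(tr[, c("dens_C", "dens_F")],
                          by = list(month = tr$month), FUN = mean)
  sdv <- stats::aggregate(tr[, c("dens_C", "dens_F")],
                          by = list(month = tr$month), FUN = stats::sd)
  yr <- agg$month / 12
  graphics::matplot(yr, agg[, c("dens_C", "dens_F")], type = "l", lty = 1,
                    col = c("#c2428a", "#3f9c5b"),
                    xlab = "years", ylab = "cells / mm^2", ...)
  if (nrow(tr) > length(yr)) {
    for (k in c("dens_C", "dens_F")) {
      col <- if (k == "dens_C") "#c2428a33" else "#3f9c5b33"
      graphics::polygon(c(yr, rev(yr)),
                        c(agg[[k]] + sdv[[k]], rev(agg[[k]] - sdv[[k]])),
                        border = NA, col = col)
    }
  }
  graphics::legend("topleft", c("CD8+ T cells", "fibrocytes"), lty = 1,
                   col = c("#c2428a", "#3f9c5b"), bty = "n")
  invisible(x)
}

#' Convert a lattice state to a typed point pattern
#'
#' One point per occupied site, placed at the site centre in micrometres;
#' the pattern area is the lattice area so that densities agree with the
#' automaton's own counts.
#'
#' @param state a `ca_state`.
#' @param domain the matching domain.
#' @return a [point_pattern()] object.
#' @export
state_to_point_pattern <- function(state, domain) {
  stopifnot(length(state$occ) == domain$n_sites)
  keep <- state$occ != 0L
  point_pattern(type = c("C", "F")[state$occ[keep]],
                x = domain$centers[keep, 1],
                y = domain$centers[keep, 2],
                roi = domain$roi,
                area_mm2 = domain$area_mm2)
}

#' Write the monthly trajectory of a simulation to CSV
#'
#' @param sim a `ca_sim`.
#' @param path file path.
#' @export
write_trajectory_csv <- function(sim, path) {
  utils::write.csv(sim$trajectory, path, row.names = FALSE)
  invisible(path)
}
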