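#' Per-step dynamics parameters for one scenario
#'
#' All probabilities are per 3-minute iteration unless noted.  Infiltration is
#' Bernoulli per step (at most one cell of each type enters per step, on a
#' uniformly chosen empty site).  Exacerbation fires on an annual schedule:
#' `exac_per_year` times per simulated year, each event offering `exac_burst`
#' entry slots that are filled independently with probability `p_iexa_F`
#' (resp. `p_iexa_C`).
#'
#' @param p_ista_C,p_ista_F stable-state infiltration probabilities per step.
#' @param p_iexa_C,p_iexa_F per-slot entry probabilities during an
#'   exacerbation burst (0 in the control scenario).
#' @param exac_burst number of candidate entries per exacerbation event.
#' @param exac_per_year exacerbation events per year.
#' @param p_C basal division probability of a CD8+ T cell.
#' @param p_C_F division probability when at least one fibrocyte occupies the
#'   cell's Moore neighbourhood (contact-induced proliferation); must be
#'   `>= p_C`.
#' @param p_dC basal death probability of a CD8+ T cell.
#' @param p_dC_plus death probability when `k_crowd` or more CD8+ T cells
#'   occupy the Moore neighbourhood (crowding-induced death); must be
#'   `>= p_dC`.
#' @param k_crowd neighbour-count threshold for crowding-induced death.
#' @param p_dF fibrocyte death probability (fibrocytes do not proliferate).
#' @param p_move_C,p_move_F per-step movement attempt probabilities.
#' @param beta_C,beta_F chemotaxis bias weights: a moving cell picks an empty
#'   Moore neighbour `s'` with weight `exp(beta * n_opp(s'))` where
#'   `n_opp(s')` counts opposite-type cells around `s'`; `beta = 0` gives an
#'   unbiased random walk.
#' @param scenario_label free-text label.
#' @return object of class `dynamics_params` (a validated named list).
#' @seealso [default_params()], [apply_therapy()], [calibrate()]
#' @export
dynamics_params <- function(p_ista_C = 0, p_ista_F = 0,
                            p_iexa_C = 0, p_iexa_F = 0,
                            exac_burst = 20L, exac_per_year = 1L,
                            p_C = 0, p_C_F = p_C,
                            p_dC = 0, p_dC_plus = p_dC, k_crowd = 3L,
                            p_dF = 0,
                            p_move_C = 0, p_move_F = 0,
                            beta_C = 0, beta_F = 0,
                            scenario_label = "custom") {
  p <- list(p_ista_C = p_ista_C, p_ista_F = p_ista_F,
            p_iexa_C = p_iexa_C, p_iexa_F = p_iexa_F,
            exac_burst = as.integer(exac_burst),
            exac_per_year = as.integer(exac_per_year),
            p_C = p_C, p_C_F = p_C_F,
            p_dC = p_dC, p_dC_plus = p_dC_plus, k_crowd = as.integer(k_crowd),
            p_dF = p_dF,
            p_move_C = p_move_C, p_move_F = p_move_F,
            beta_C = beta_C, beta_F = beta_F,
            scenario_label = scenario_label)
  validate_params(p)
  class(p) <- "dynamics_params"
  p
}

validate_params <- function(p) {
  probs <- c("p_ista_C", "p_ista_F", "p_iexa_C", "p_iexa_F", "p_C", "p_C_F",
             "p_dC", "p_dC_plus", "p_dF", "p_move_C", "p_move_F")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("parameter '", nm, "' must be a probability in [0, 1], got ", v)
    }
  }
  if (p$p_C_F < p$p_C) stop("p_C_F must be >= p_C")
  if (p$p_dC_plus < p$p_dC) stop("p_dC_plus must be >= p_dC")
  if (p$k_crowd < 0) stop("k_crowd must be >= 0")
  if (p$exac_burst < 0) stop("exac_burst must be >= 0")
  if (p$exac_per_year < 0) stop("exac_per_year must be >= 0")
  invisible(TRUE)
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("Dynamics parameters [", x$scenario_label, "]\n", sep = "")
  cat(sprintf("  infiltration/step: C %.4g  F %.4g\n", x$p_ista_C, x$p_ista_F))
  cat(sprintf("  exacerbation:      C %.3g  F %.3g  (burst %d, %d/yr)\n",
              x$p_iexa_C, x$p_iexa_F, x$exac_burst, x$exac_per_year))
  cat(sprintf("  C division:        basal %.4g  F-contact %.4g\n", x$p_C, x$p_C_F))
  cat(sprintf("  C death:           basal %.4g  crowded(>=%d) %.4g\n",
              x$p_dC, x$k_crowd, x$p_dC_plus))
  cat(sprintf("  F death:           %.4g\n", x$p_dF))
  cat(sprintf("  movement:          C %.3g (beta %.3g)  F %.3g (beta %.3g)\n",
              x$p_move_C, x$beta_C, x$p_move_F, x$beta_F))
  invisible(x)
}

#' Calibrated default scenarios
#'
#' Per-step rates for the healthy (control) and COPD scenarios.  The numbers
#' ship with the package and are the output of the calibration pipeline
#' ([calibrate()]) run at its defaults: the mean-field companion model is
#' fitted so that, starting from the healthy densities (660 CD8+ T cells/mm^2
#' and 106 fibrocytes/mm^2), the 20-year endpoints land on the observed
#' medians (control 754 and 106 per mm^2; COPD 1187 and 212 per mm^2), with a
#' subsequent stochastic refinement of the infiltration and contact-division
#' rates against the full automaton (see the methods vignette).  Fixed
#' biological choices: mean tissue CD8 residence 90 days, basal division every
#' 300 days, crowding threshold 2 with a six-fold death raise, fibrocyte
#' turnover log(20)/7 per year (stationary, to 95 percent, after ~7 years),
#' fibrocyte chemotaxis towards CD8 cells in COPD only.
#'
#' @param scenario `"control"` or `"copd"`.
#' @return a [dynamics_params()] object.
#' @export
default_params <- function(scenario = c("control", "copd")) {
  scenario <- match.arg(scenario)
  base <- .default_rates()
  if (scenario == "control") {
    dynamics_params(
      p_ista_C = base$p_ista_C, p_ista_F = base$p_ista_F,
      p_C = base$p_C, p_C_F = base$p_C_F_control,
      p_dC = base$p_dC, p_dC_plus = base$p_dC_plus, k_crowd = base$k_crowd,
      p_dF = base$p_dF,
      p_move_C = base$p_move_C, p_move_F = base$p_move_F,
      beta_C = 0, beta_F = 0,
      scenario_label = "control")
  } else {
    dynamics_params(
      p_ista_C = base$p_ista_C, p_ista_F = base$p_ista_F,
      p_iexa_F = base$p_iexa_F, exac_burst = base$exac_burst,
      exac_per_year = 1L,
      p_C = base$p_C, p_C_F = base$p_C_F_copd,
      p_dC = base$p_dC, p_dC_plus = base$p_dC_plus, k_crowd = base$k_crowd,
      p_dF = base$p_dF,
      p_move_C = base$p_move_C, p_move_F = base$p_move_F,
      beta_C = 0, beta_F = base$beta_F_copd,
      scenario_label = "copd")
  }
}

# calibrated rate set (see default_params docs and the methods vignette)
.default_rates <- function() {
  list(
    p_dC          = 1 / 43200,     # 90-day mean residence, 3-min steps
    p_dC_plus     = 6 / 43200,     # crowding-induced death (k_crowd >= 2)
    k_crowd       = 2L,
    p_C           = 1 / 144000,    # basal division every ~300 days
    p_C_F_control = 6.944e-05,     # 10 x basal (contact-induced)
    p_C_F_copd    = 1.79588e-04,   # calibrated + refined, COPD endpoint
    p_ista_C      = 2.29530e-03,   # calibrated + refined, control endpoint
    p_dF          = 2.4427e-06,    # log(20) / 7 years: stationary after ~7 y
    p_ista_F      = 4.6334e-05,    # stationary at 106 fibrocytes/mm^2
    p_iexa_F      = 0.33027,       # annual burst inflow to double F by 20 y
    exac_burst    = 20L,
    p_move_C      = 0.5,
    p_move_F      = 0.1,
    beta_F_copd   = 0.5
  )
}

#' Derive therapy dynamics from the COPD and control parameter sets
#'
#' Therapies are parameter edits applied to the COPD set: `placebo` leaves it
#' unchanged; `total` replaces it by the control set (an ideal treatment
#' restoring all cellular processes); `cd54` restores the contact-induced
#' division probability `p_C_F` to its control value (anti-CD54 blocks the
#' fibrocyte-CD8 contact that drives induced proliferation); `cxcr12` restores
#' the fibrocyte displacement behaviour (`p_move_F`, `beta_F`) to control
#' values (CXCR1/2 antagonism removes the CXCL8-driven chemotaxis); `dual`
#' applies both edits (the edits touch disjoint fields, so composition order
#' is irrelevant).
#'
#' @param copd_params,control_params [dynamics_params()] objects.
#' @param therapy one of `"placebo"`, `"total"`, `"cd54"`, `"cxcr12"`,
#'   `"dual"`.
#' @param cd54_factor optional scaling: `p_C_F` is moved towards the control
#'   value by this fraction (1 = fully restored, default).
#' @return a [dynamics_params()] object.
#' @export
apply_therapy <- function(copd_params, control_params,
                          therapy = c("placebo", "total", "cd54", "cxcr12", "dual"),
                          cd54_factor = 1) {
  therapy <- match.arg(therapy)
  out <- unclass(copd_params)
  if (therapy == "placebo") {
    out$scenario_label <- "placebo"
  } else if (therapy == "total") {
    out <- unclass(control_params)
    out$scenario_label <- "total_inhibition"
  } else {
    if (therapy %in% c("cd54", "dual")) {
      out$p_C_F <- out$p_C_F + cd54_factor * (control_params$p_C_F - out$p_C_F)
    }
    if (therapy %in% c("cxcr12", "dual")) {
      out$p_move_F <- control_params$p_move_F
      out$beta_F <- control_params$beta_F
    }
    out$scenario_label <- therapy
  }
  validate_params(out)
  class(out) <- "dynamics_params"
  out
}
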