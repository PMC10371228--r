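#' Load and validate a run configuration
#'
#' Configurations are YAML with four blocks, all optional: `domain` (geometry),
#' `params` (per-scenario rate overrides applied on top of
#' [default_params()]), `scenario` (label, years, replicates, seed) and
#' `metrics` (threshold, dilation radius, bin width, minimum cluster size).
#' Every missing field is filled with the package default and reported in the
#' returned object's `defaults_filled` so a run manifest can record them.
#'
#' @param path YAML file path, or a list already parsed.
#' @return object of class `run_config`: validated list with `domain`,
#'   `params` (named list of `dynamics_params`), `scenario`, `metrics`,
#'   `defaults_filled`.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("configuration must be a YAML mapping")

  filled <- character(0)
  take <- function(block, field, default) {
    v <- cfg[[block]][[field]]
    if (is.null(v)) {
      filled <<- c(filled, paste0(block, ".", field))
      default
    } else v
  }

  domain <- list(
    site_length = take("domain", "site_length", 7),
    n_sites = take("domain", "n_sites", 3652L),
    inner_radius = take("domain", "inner_radius", 150),
    neighborhood = take("domain", "neighborhood", "moore"))
  if (domain$site_length <= 0) stop("domain.site_length must be > 0")
  if (domain$n_sites < 1) stop("domain.n_sites must be >= 1")

  scenario <- list(
    label = take("scenario", "label", "control"),
    years = take("scenario", "years", 20),
    replicates = take("scenario", "replicates", 8L),
    seed = take("scenario", "seed", 1L),
    n0C = take("scenario", "n0C", 660),
    n0F = take("scenario", "n0F", 106))
  if (scenario$years <= 0) stop("scenario.years must be > 0")
  if (scenario$replicates < 1) stop("scenario.replicates must be >= 1")

  metrics <- list(
    threshold_um = take("metrics", "threshold_um", 40),
    radius_um = take("metrics", "radius_um", 3.6),
    bin_um = take("metrics", "bin_um", 7),
    min_cluster_size = take("metrics", "min_cluster_size", 2L))
  if (metrics$threshold_um <= 0) stop("metrics.threshold_um must be > 0")

  params <- list()
  for (lab in c("control", "copd")) {
    base <- unclass(default_params(lab))
    over <- cfg$params[[lab]]
    if (!is.null(over)) {
      unknown <- setdiff(names(over), names(base))
      if (length(unknown)) {
        stop("unknown parameter field(s) in params.", lab, ": ",
             paste(unknown, collapse = ", "))
      }
      base[names(over)] <- over
    }
    tryCatch(validate_params(base),
             error = function(e) stop("params.", lab, ": ",
                                      conditionMessage(e), call. = FALSE))
    class(base) <- "dynamics_params"
    params[[lab]] <- base
  }

  structure(list(domain = domain, params = params, scenario = scenario,
                 metrics = metrics, defaults_filled = filled),
            class = "run_config")
}

#' Serialize a run configuration back to YAML
#'
#' `load_run_config(save_run_config(cfg, f))` is the identity on the
#' validated fields.
#'
#' @param config a `run_config`.
#' @param path output path.
#' @export
save_run_config <- function(config, path) {
  out <- list(domain = config$domain,
              params = lapply(config$params, function(p) {
                p <- unclass(p); p
              }),
              scenario = config$scenario,
              metrics = config$metrics)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to re-run an artifact bit-identically: the
#' configuration (inline), the seeds actually used, and the package and R
#' versions.
#'
#' @param path manifest output path (YAML).
#' @param config a `run_config`.
#' @param seeds integer vector of the per-replicate seeds used.
#' @param extra optional named list of additional entries.
#' @export
write_manifest <- function(path, config, seeds, extra = list()) {
  man <- c(list(
    package = "fibrocyteCA",
    package_version = as.character(utils::packageVersion("fibrocyteCA")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seeds = as.integer(seeds),
    defaults_filled = config$defaults_filled,
    config = list(domain = config$domain, scenario = config$scenario,
                  metrics = config$metrics,
                  params = lapply(config$params, unclass))),
    extra)
  yaml::write_yaml(man, path, precision = 15)
  invisible(path)
}
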