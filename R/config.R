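#' Load and validate a model configuration file
#'
#' Reads the single-file YAML configuration holding every model input (cycle
#' settings, comparator survival parameters, all cost/utility/clinical
#' parameters with their sensitivity ranges and distributions, and the
#' composition of the two treatment arms). The package ships the published
#' input set as `system.file("params", "orient32.yaml", package = "psmce")`,
#' which is the default.
#'
#' @param path Path to a YAML configuration; `NULL` for the shipped one.
#' @return A validated configuration object of class `psmce_config`.
#' @export
load_ce_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("params", "orient32.yaml", package = "psmce")
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg$source_path <- path
  validate_ce_config(cfg)
}

#' @rdname load_ce_config
#' @param cfg A raw configuration list.
#' @export
validate_ce_config <- function(cfg) {
  problems <- character()
  need <- function(ok, msg) if (!ok) problems <<- c(problems, msg)

  need(is.list(cfg$model), "missing section: model")
  for (f in c("cycle_days", "horizon_years", "annual_discount",
              "days_per_month", "wtp_per_qaly"))
    need(is.numeric(cfg$model[[f]]), paste0("model.", f, " missing or non-numeric"))

  need(is.list(cfg$curves), "missing section: curves")
  for (cv in c("pfs_reference", "os_reference")) {
    need(!is.null(cfg$curves[[cv]]$family), paste0("curves.", cv, ".family missing"))
    need(is.list(cfg$curves[[cv]]$params), paste0("curves.", cv, ".params missing"))
  }

  need(is.list(cfg$parameters) && length(cfg$parameters) > 0,
       "missing section: parameters")
  for (nm in names(cfg$parameters)) {
    p <- cfg$parameters[[nm]]
    for (f in c("base", "low", "high"))
      need(is.numeric(p[[f]]), paste0("parameters.", nm, ".", f, " missing"))
    need(!is.null(p$distribution) &&
           p$distribution %in% c("beta", "gamma", "lognormal", "fixed"),
         paste0("parameters.", nm, ".distribution invalid"))
    if (is.numeric(p$low) && is.numeric(p$base) && is.numeric(p$high))
      need(p$low <= p$base && p$base <= p$high,
           paste0("parameters.", nm, ": need low <= base <= high"))
  }

  need(is.list(cfg$arms) &&
         all(c("comparator", "intervention") %in% names(cfg$arms)),
       "arms must define 'comparator' and 'intervention'")
  for (an in intersect(c("comparator", "intervention"), names(cfg$arms))) {
    a <- cfg$arms[[an]]
    for (f in c("name", "drug_costs", "subsequent_drug",
                "subsequent_proportion", "subsequent_max_months",
                "ae_incidence"))
      need(!is.null(a[[f]]), paste0("arms.", an, ".", f, " missing"))
    refs <- c(unlist(a$drug_costs), a$subsequent_drug,
              a$subsequent_proportion, unlist(a$ae_incidence))
    for (r in refs)
      need(r %in% names(cfg$parameters),
           paste0("arms.", an, " references unknown parameter '", r, "'"))
  }
  for (r in unlist(cfg$ae_costs))
    need(r %in% names(cfg$parameters),
         paste0("ae_costs references unknown parameter '", r, "'"))

  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  class(cfg) <- "psmce_config"
  cfg
}

#' Base-case parameter values
#'
#' @param config A `psmce_config`.
#' @return Named numeric vector of every parameter's base value.
#' @export
base_params <- function(config) {
  stopifnot(inherits(config, "psmce_config"))
  vapply(config$parameters, function(p) p$base, numeric(1))
}

#' Sensitivity-analysis parameter table
#'
#' @param config A `psmce_config`.
#' @return Data frame with columns `name`, `base`, `low`, `high`,
#'   `distribution` — one row per model parameter.
#' @export
param_table <- function(config) {
  stopifnot(inherits(config, "psmce_config"))
  data.frame(name = names(config$parameters),
             base = vapply(config$parameters, function(p) p$base, numeric(1)),
             low = vapply(config$parameters, function(p) p$low, numeric(1)),
             high = vapply(config$parameters, function(p) p$high, numeric(1)),
             distribution = vapply(config$parameters,
                                   function(p) p$distribution, character(1)),
             row.names = NULL)
}

# reference curves of the comparator arm
.reference_curves <- function(config) {
  list(pfs = parsurv(config$curves$pfs_reference$family,
                     unlist(config$curves$pfs_reference$params)),
       os = parsurv(config$curves$os_reference$family,
                    unlist(config$curves$os_reference$params)))
}

.model_config_from <- function(config) {
  m <- config$model
  model_config(cycle_days = m$cycle_days, horizon_years = m$horizon_years,
               annual_discount = m$annual_discount,
               days_per_month = m$days_per_month,
               half_cycle_correction = isTRUE(m$half_cycle_correction),
               wtp_per_qaly = m$wtp_per_qaly)
}

# number of treated cycles implied by a cap in months (dose at each cycle
# start while start time <= cap)
.cap_cycles <- function(months, mcfg) {
  if (is.null(months)) return(Inf)
  floor(months * mcfg$days_per_month / mcfg$cycle_days) + 1
}

# a duration stated in months, as a whole number of cycles
.duration_cycles <- function(months, mcfg) {
  if (is.null(months) || is.infinite(months)) return(Inf)
  round(months * mcfg$days_per_month / mcfg$cycle_days)
}

#' Build the two treatment arms from a configuration
#'
#' Assembles [arm_spec()] objects for the comparator (sorafenib: published
#' parametric PFS/OS curves) and the intervention (curves derived via the
#' hazard ratios), using a full parameter vector — the base case by default,
#' or a perturbed/sampled vector during sensitivity analysis.
#'
#' @param config A `psmce_config`.
#' @param pars Named parameter vector; defaults to [base_params()].
#' @return List with elements `comparator`, `intervention` (both
#'   `arm_spec`), and `model` (a [model_config()]).
#' @export
build_arms <- function(config, pars = base_params(config)) {
  stopifnot(inherits(config, "psmce_config"))
  miss <- setdiff(names(config$parameters), names(pars))
  if (length(miss))
    stop("missing parameter value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  curves <- .reference_curves(config)
  mcfg <- .model_config_from(config)
  utils_ <- c(u_pfd = unname(pars["u_pfd"]), u_pd = unname(pars["u_pd"]))
  ae_cost_names <- unlist(config$ae_costs)
  # prices are quoted per treatment cycle of `price_cycle_days` days (one
  # q3w administration); accrue pro rata if the model cycle differs
  price_scale <- mcfg$cycle_days / (config$model$price_cycle_days %||% 21)

  one_arm <- function(a, pfs, os) {
    ae_names <- unlist(a$ae_incidence)
    arm_spec(
      name = a$name, pfs_curve = pfs, os_curve = os,
      drug_cost_per_cycle = sum(pars[unlist(a$drug_costs)]) * price_scale,
      test_cost_per_cycle = unname(pars["cost_test"]) * price_scale,
      max_treatment_cycles = .cap_cycles(a$max_treatment_months, mcfg),
      ae = ae_profile(name = ae_names,
                      incidence = unname(pars[ae_names]),
                      cost_per_event = unname(pars[ae_cost_names]),
                      disutility = unname(pars["disutility_g3"]),
                      duration_cycles = 1),
      utilities = utils_,
      subsequent_proportion = unname(pars[a$subsequent_proportion]),
      subsequent_drug_cost_per_cycle =
        unname(pars[a$subsequent_drug]) * price_scale,
      subsequent_max_cycles = .duration_cycles(a$subsequent_max_months, mcfg),
      bsc_cost_per_cycle = unname(pars["cost_bsc"]) * price_scale)
  }

  comp <- one_arm(config$arms$comparator, curves$pfs, curves$os)
  intv <- one_arm(config$arms$intervention,
                  apply_hr(curves$pfs, unname(pars["hr_pfs"])),
                  apply_hr(curves$os, unname(pars["hr_os"])))
  list(comparator = comp, intervention = intv, model = mcfg)
}
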