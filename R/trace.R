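#' Model configuration
#'
#' Global settings of the partitioned-survival cohort model: 21-day cycles,
#' 3% annual discounting of both costs and outcomes, and a lifetime horizon.
#'
#' @param cycle_days Cycle length in days.
#' @param horizon_years Simulation horizon in years. The default 40 years is
#'   effectively lifetime for this population (under 0.3% of the comparator
#'   cohort remains alive).
#' @param annual_discount Annual discount rate applied to costs, life-years
#'   and QALYs.
#' @param days_per_month Days per month used for month/cycle conversion.
#' @param half_cycle_correction Average adjacent cycle-boundary occupancies
#'   (trapezoidal accrual) instead of using the cycle-start occupancy.
#' @param wtp_per_qaly Willingness-to-pay threshold in USD per QALY (three
#'   times 2020 Chinese per-capita GDP).
#' @return An object of class `model_config`.
#' @export
model_config <- function(cycle_days = 21, horizon_years = 40,
                         annual_discount = 0.03, days_per_month = 30.4375,
                         half_cycle_correction = TRUE,
                         wtp_per_qaly = 30552) {
  if (annual_discount < 0 || annual_discount >= 1)
    stop("'annual_discount' must be in [0, 1)", call. = FALSE)
  n_cycles <- floor(horizon_years * 365.25 / cycle_days)
  if (n_cycles < 1)
    stop("horizon shorter than one cycle", call. = FALSE)
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 annual_discount = annual_discount,
                 days_per_month = days_per_month,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 wtp_per_qaly = wtp_per_qaly, n_cycles = n_cycles),
            class = "model_config")
}

#' Adverse-event profile of a treatment arm
#'
#' Grade >=3 adverse events incur a one-time management cost and a one-time
#' QALY decrement (`incidence * disutility * duration`) at model entry.
#'
#' @param name Character vector of event names.
#' @param incidence Per-patient incidences in \[0, 1\].
#' @param cost_per_event Management cost per event, USD.
#' @param disutility Utility decrement while the event lasts.
#' @param duration_cycles Duration of the decrement, in cycles.
#' @return A data frame of class `ae_profile`.
#' @export
ae_profile <- function(name = character(), incidence = numeric(),
                       cost_per_event = numeric(), disutility = numeric(),
                       duration_cycles = 1) {
  stopifnot(length(name) == length(incidence),
            length(name) == length(cost_per_event))
  if (any(incidence < 0 | incidence > 1))
    stop("incidences must lie in [0, 1]", call. = FALSE)
  if (any(cost_per_event < 0))
    stop("AE costs must be >= 0", call. = FALSE)
  out <- data.frame(name = name, incidence = incidence,
                    cost_per_event = cost_per_event,
                    disutility = rep_len(disutility, length(name)),
                    duration_cycles = rep_len(duration_cycles, length(name)))
  class(out) <- c("ae_profile", "data.frame")
  out
}

#' Treatment arm specification
#'
#' Bundles everything the cohort trace needs for one strategy: its
#' progression-free and overall survival curves, per-cycle first-line drug
#' and monitoring costs with an optional treatment cap, the grade >=3
#' adverse-event profile, and post-progression care (a fraction receiving
#' active subsequent therapy, the remainder best supportive care).
#'
#' @param name Arm label.
#' @param pfs_curve,os_curve `survcurve` objects (months). PFS is clipped to
#'   OS at evaluation.
#' @param drug_cost_per_cycle,test_cost_per_cycle First-line drug and
#'   monitoring cost per cycle (USD), accrued against progression-free
#'   occupancy while treatment continues.
#' @param max_treatment_cycles First-line treatment cap in cycles (`Inf` for
#'   treat-to-progression).
#' @param ae An [ae_profile()].
#' @param utilities Named list or vector with `u_pfd` and `u_pd`.
#' @param subsequent_proportion Fraction of progressors receiving active
#'   subsequent therapy.
#' @param subsequent_drug_cost_per_cycle Its per-cycle cost (USD).
#' @param subsequent_max_cycles Maximum cycles of subsequent therapy per
#'   patient, counted in time since progression (`Inf` for until death).
#' @param bsc_cost_per_cycle Best-supportive-care cost per cycle, accrued by
#'   the non-subsequent-therapy fraction of the progressed state.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(name, pfs_curve, os_curve,
                     drug_cost_per_cycle, test_cost_per_cycle = 0,
                     max_treatment_cycles = Inf,
                     ae = ae_profile(),
                     utilities = c(u_pfd = 0.76, u_pd = 0.68),
                     subsequent_proportion = 0,
                     subsequent_drug_cost_per_cycle = 0,
                     subsequent_max_cycles = Inf,
                     bsc_cost_per_cycle = 0) {
  stopifnot(inherits(pfs_curve, "survcurve"), inherits(os_curve, "survcurve"))
  costs <- c(drug_cost_per_cycle, test_cost_per_cycle,
             subsequent_drug_cost_per_cycle, bsc_cost_per_cycle)
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  if (subsequent_proportion < 0 || subsequent_proportion > 1)
    stop("'subsequent_proportion' must be in [0, 1]", call. = FALSE)
  u <- unlist(utilities)
  if (any(u < 0 | u > 1)) stop("utilities must be in [0, 1]", call. = FALSE)
  structure(list(name = name, pfs_curve = pfs_curve, os_curve = os_curve,
                 drug_cost_per_cycle = drug_cost_per_cycle,
                 test_cost_per_cycle = test_cost_per_cycle,
                 max_treatment_cycles = max_treatment_cycles,
                 ae = ae, u_pfd = unname(u["u_pfd"]), u_pd = unname(u["u_pd"]),
                 subsequent_proportion = subsequent_proportion,
                 subsequent_drug_cost_per_cycle = subsequent_drug_cost_per_cycle,
                 subsequent_max_cycles = subsequent_max_cycles,
                 bsc_cost_per_cycle = bsc_cost_per_cycle),
            class = "arm_spec")
}

#' Health-state occupancy at a time point
#'
#' Partitioned-survival occupancy: progression-free = PFS (clipped to OS),
#' progressed = OS - PFS, dead = 1 - OS.
#'
#' @param arm An [arm_spec()].
#' @param t Times in months.
#' @return A matrix with columns `p_pfd`, `p_pd`, `p_death`, rows summing
#'   to 1.
#' @export
occupancy <- function(arm, t) {
  os <- surv_prob(arm$os_curve, t)
  pfs <- pmin(surv_prob(arm$pfs_curve, t), os)
  cbind(p_pfd = pfs, p_pd = pmax(os - pfs, 0), p_death = 1 - os)
}

#' Run the discounted cohort trace for one arm
#'
#' Evaluates state occupancy at every cycle boundary over the horizon and
#' accumulates discounted costs, life-years and QALYs per cycle.
#'
#' Accounting rules: life-years and QALYs accrue to alive-state occupancy
#' (trapezoidal between boundaries when half-cycle correction is on);
#' first-line drug and monitoring costs accrue to progression-free occupancy
#' while the cycle index is below the treatment cap; the subsequent-therapy
#' fraction of the progressed state accrues second-line drug cost for at most
#' `subsequent_max_cycles` of post-progression time (implemented as a rolling
#' window over incident progression, capped by progressed occupancy), the
#' remainder accrues best-supportive-care cost; grade >=3 adverse-event costs
#' and QALY decrements are one-time at model entry. All flows are discounted
#' at the annual rate converted to the cycle scale.
#'
#' @param arm An [arm_spec()].
#' @param config A [model_config()].
#' @return A data frame of class `cohort_trace`, one row per cycle, with
#'   columns `cycle`, `t_start` (months), `p_pfd`, `p_pd`, `p_death`
#'   (cycle-start occupancy), `discounted_cost`, `discounted_ly`,
#'   `discounted_qaly`.
#' @examples
#' cfg <- model_config(horizon_years = 5)
#' arm <- arm_spec("sorafenib",
#'                 pfs_curve = parsurv("lognormal", c(1.121355, 0.7702185)),
#'                 os_curve = parsurv("loglogistic", c(0.01822555, 1.694566)),
#'                 drug_cost_per_cycle = 790)
#' tr <- build_trace(arm, cfg)
#' arm_totals(tr)
#' @export
build_trace <- function(arm, config = model_config()) {
  stopifnot(inherits(arm, "arm_spec"), inherits(config, "model_config"))
  H <- config$n_cycles
  cyc_months <- config$cycle_days / config$days_per_month
  cyc_years <- config$cycle_days / 365.25
  tb <- (0:H) * cyc_months                       # cycle boundaries, months
  occ <- occupancy(arm, tb)
  disc_b <- (1 + config$annual_discount)^(-(tb / 12))

  mid <- function(x) (x[-1L] + x[-length(x)]) / 2
  if (config$half_cycle_correction) {
    o_pfd <- mid(occ[, "p_pfd"]); o_pd <- mid(occ[, "p_pd"])
    o_os <- o_pfd + o_pd
    d <- mid(disc_b)
  } else {
    o_pfd <- occ[-(H + 1L), "p_pfd"]; o_pd <- occ[-(H + 1L), "p_pd"]
    o_os <- o_pfd + o_pd
    d <- disc_b[-(H + 1L)]
  }

  ly <- o_os * d * cyc_years
  qaly <- (arm$u_pfd * o_pfd + arm$u_pd * o_pd) * d * cyc_years

  treat <- as.numeric(seq_len(H) <= arm$max_treatment_cycles)
  cost <- o_pfd * treat * (arm$drug_cost_per_cycle +
                             arm$test_cost_per_cycle) * d

  # subsequent therapy: rolling window of incident progression (PFS drops)
  # over the last subsequent_max_cycles cycles, capped by PD occupancy
  pfs_b <- occ[, "p_pfd"]
  inc_prog <- pmax(-diff(pfs_b), 0)
  k <- floor(min(arm$subsequent_max_cycles, H))
  on_subs <- if (k < 1) rep(0, H) else if (k >= H) cumsum(inc_prog) else {
    f <- stats::filter(inc_prog, rep(1, k), sides = 1)
    f[seq_len(k - 1L)] <- cumsum(inc_prog)[seq_len(k - 1L)]
    as.numeric(f)
  }
  on_subs <- pmin(on_subs, o_pd)
  cost <- cost + arm$subsequent_proportion * on_subs *
    arm$subsequent_drug_cost_per_cycle * d
  cost <- cost + (1 - arm$subsequent_proportion) * o_pd *
    arm$bsc_cost_per_cycle * d

  # one-time AE burden at model entry (undiscounted: t = 0)
  if (nrow(arm$ae) > 0) {
    cost[1L] <- cost[1L] + sum(arm$ae$incidence * arm$ae$cost_per_event)
    qaly[1L] <- qaly[1L] - sum(arm$ae$incidence * arm$ae$disutility *
                                 arm$ae$duration_cycles) * cyc_years
  }

  out <- data.frame(cycle = seq_len(H), t_start = tb[-(H + 1L)],
                    p_pfd = occ[-(H + 1L), "p_pfd"],
                    p_pd = occ[-(H + 1L), "p_pd"],
                    p_death = occ[-(H + 1L), "p_death"],
                    discounted_cost = cost, discounted_ly = ly,
                    discounted_qaly = qaly)
  attr(out, "arm_name") <- arm$name
  class(out) <- c("cohort_trace", "data.frame")
  out
}

#' Totals of a cohort trace
#'
#' @param trace A `cohort_trace` from [build_trace()].
#' @return Named numeric vector: `cost` (USD), `ly` (years), `qaly`.
#' @export
arm_totals <- function(trace) {
  stopifnot(inherits(trace, "cohort_trace"))
  c(cost = sum(trace$discounted_cost), ly = sum(trace$discounted_ly),
    qaly = sum(trace$discounted_qaly))
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(paste0("Model config: %g-day cycles over %g years ",
                     "(%d cycles), %.1f%% annual discount, HCC %s, ",
                     "WTP $%s/QALY\n"),
              x$cycle_days, x$horizon_years, x$n_cycles,
              100 * x$annual_discount,
              if (x$half_cycle_correction) "on" else "off",
              format(x$wtp_per_qaly, big.mark = ",")))
  invisible(x)
}

#' @export
print.arm_spec <- function(x, ...) {
  cat(sprintf("Arm '%s': drug+test $%g/cycle (cap %s cycles), %d AEs,\n",
              x$name, x$drug_cost_per_cycle + x$test_cost_per_cycle,
              format(x$max_treatment_cycles), nrow(x$ae)))
  cat(sprintf("  subsequent therapy %.0f%% @ $%g/cycle (max %s cycles), BSC $%g/cycle\n",
              100 * x$subsequent_proportion,
              x$subsequent_drug_cost_per_cycle,
              format(x$subsequent_max_cycles), x$bsc_cost_per_cycle))
  invisible(x)
}
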