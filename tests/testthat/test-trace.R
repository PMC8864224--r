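test_that("cohort occupancies are conserved and death is absorbing", {
  m <- psm()
  for (tr in m$traces) {
    expect_true(all(abs(tr$p_pfd + tr$p_pd + tr$p_death - 1) < 1e-12))
    expect_true(all(diff(tr$p_death) >= -1e-15))
    expect_true(all(tr$p_pfd >= 0 & tr$p_pfd <= 1))
    expect_true(all(tr$p_pd >= 0 & tr$p_pd <= 1))
  }
  expect_equal(as.numeric(occupancy(m$arms$comparator, 0)), c(1, 0, 0))
})

test_that("occupancy follows the partitioned-survival identities", {
  arm <- exp_arm()
  t <- c(0, 2, 7.3, 20)
  occ <- occupancy(arm, t)
  expect_equal(occ[, "p_death"], 1 - surv_prob(arm$os_curve, t))
  expect_equal(occ[, "p_pfd"], pmin(surv_prob(arm$pfs_curve, t),
                                    surv_prob(arm$os_curve, t)))
  # identical PFS and OS curves leave no room for the progressed state
  same <- arm_spec("same", pfs_curve = parsurv("exponential", 0.1),
                   os_curve = parsurv("exponential", 0.1),
                   drug_cost_per_cycle = 0)
  expect_true(all(occupancy(same, t)[, "p_pd"] == 0))
  # at the comparator's median OS, half the cohort has died
  sor <- psm()$arms$comparator
  expect_equal(unname(occupancy(sor, 10.63)[, "p_death"]), 0.5, tolerance = 1e-3)
})

test_that("degenerate configuration reduces totals to the OS area", {
  cfg <- model_config(horizon_years = 10, annual_discount = 0,
                      wtp_per_qaly = 30552)
  arm <- exp_arm(utilities = c(u_pfd = 1, u_pd = 1))
  tot <- arm_totals(build_trace(arm, cfg))
  expect_equal(tot[["cost"]], 0)
  expect_equal(tot[["qaly"]], tot[["ly"]])
  r <- log(2) / 10
  auc_years <- (1 - exp(-r * 120)) / r / 12   # analytic truncated mean
  expect_equal(tot[["ly"]], auc_years, tolerance = 5e-3)
})

test_that("discounted exponential totals match the closed-form integral", {
  r <- log(2) / 10                       # per month
  cfg <- model_config(horizon_years = 10)
  arm <- exp_arm(rate_os = r, utilities = c(u_pfd = 1, u_pd = 1))
  tot <- arm_totals(build_trace(arm, cfg))
  d <- log(1.03) / 12                    # continuous-time discount per month
  closed <- (1 - exp(-(r + d) * 120)) / (r + d) / 12
  expect_equal(tot[["ly"]], closed, tolerance = 5e-3)
})

test_that("discounting shrinks totals and costs never leak into outcomes", {
  base <- psm()
  cfg0 <- edit_config(base$config, function(cfg) {
    cfg$model$annual_discount <- 0
    cfg
  })
  undisc <- psm(cfg0)
  for (a in c("comparator", "intervention")) {
    expect_gt(undisc$totals[[a]][["ly"]], base$totals[[a]][["ly"]])
    expect_gt(undisc$totals[[a]][["qaly"]], base$totals[[a]][["qaly"]])
    expect_gt(undisc$totals[[a]][["cost"]], base$totals[[a]][["cost"]])
    # utilities <= 1 bound QALYs by life-years
    expect_lte(base$totals[[a]][["qaly"]], base$totals[[a]][["ly"]])
  }
  # doubling every cost leaves the outcome side untouched
  pars2 <- base$pars
  costs <- grep("^(cost_|ae_cost_)", names(pars2))
  pars2[costs] <- 2 * pars2[costs]
  doubled <- psm(base$config, pars2)
  for (a in c("comparator", "intervention")) {
    expect_equal(doubled$totals[[a]][["ly"]], base$totals[[a]][["ly"]])
    expect_equal(doubled$totals[[a]][["qaly"]], base$totals[[a]][["qaly"]])
  }
  expect_equal(doubled$ce$incremental_cost, 2 * base$ce$incremental_cost,
               tolerance = 1e-12)
})

test_that("halving the cycle length moves totals by less than 1%", {
  base <- psm()
  half <- psm(edit_config(base$config, function(cfg) {
    cfg$model$cycle_days <- 10.5
    cfg
  }))
  for (a in c("comparator", "intervention"))
    for (q in c("cost", "ly", "qaly"))
      expect_lt(abs(half$totals[[a]][[q]] / base$totals[[a]][[q]] - 1), 0.01)
})

test_that("adverse-event burden enters once, at model entry", {
  cfg <- model_config(horizon_years = 2)
  ae <- ae_profile(name = "anaemia", incidence = 0.5, cost_per_event = 100,
                   disutility = 0.2, duration_cycles = 2)
  with_ae <- build_trace(exp_arm(ae = ae), cfg)
  without <- build_trace(exp_arm(), cfg)
  expect_equal(with_ae$discounted_cost[1] - without$discounted_cost[1],
               0.5 * 100)
  expect_equal(with_ae$discounted_qaly[1] - without$discounted_qaly[1],
               -0.5 * 0.2 * 2 * 21 / 365.25)
  expect_equal(with_ae$discounted_cost[-1], without$discounted_cost[-1])
  expect_equal(with_ae$discounted_qaly[-1], without$discounted_qaly[-1])
})

test_that("first-line, subsequent-therapy and supportive-care costs accrue to the right states", {
  cfg <- model_config(horizon_years = 5, annual_discount = 0,
                      half_cycle_correction = FALSE)
  # only BSC, paid by the whole progressed state when nobody gets therapy
  bsc_only <- exp_arm(subsequent_proportion = 0, bsc_cost_per_cycle = 100)
  tr <- build_trace(bsc_only, cfg)
  expect_equal(sum(tr$discounted_cost), 100 * sum(tr$p_pd))
  # with p = 0.4 on an uncapped second line, the PD state splits 40/60
  split <- exp_arm(subsequent_proportion = 0.4,
                   subsequent_drug_cost_per_cycle = 250,
                   subsequent_max_cycles = Inf, bsc_cost_per_cycle = 100)
  tr2 <- build_trace(split, cfg)
  expect_equal(sum(tr2$discounted_cost),
               0.4 * 250 * sum(tr2$p_pd) + 0.6 * 100 * sum(tr2$p_pd),
               tolerance = 1e-10)
  # a finite cap can only reduce second-line exposure
  capped <- exp_arm(subsequent_proportion = 0.4,
                    subsequent_drug_cost_per_cycle = 250,
                    subsequent_max_cycles = 6, bsc_cost_per_cycle = 100)
  tr3 <- build_trace(capped, cfg)
  expect_lt(sum(tr3$discounted_cost), sum(tr2$discounted_cost))
  # treatment cap stops drug cost accrual at the cap
  rx <- arm_spec("rx", pfs_curve = parsurv("exponential", 0.05),
                 os_curve = parsurv("exponential", 0.02),
                 drug_cost_per_cycle = 500, max_treatment_cycles = 10)
  tr4 <- build_trace(rx, cfg)
  expect_equal(sum(tr4$discounted_cost), 500 * sum(tr4$p_pfd[1:10]))
})

test_that("a sub-cycle horizon is rejected", {
  expect_error(model_config(horizon_years = 0.01), "one cycle")
})
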