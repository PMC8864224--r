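test_that("sampling distributions respect their support and moments", {
  set.seed(1)
  n <- 1e5
  hr <- sample_param(list(base = 0.570, low = 0.430, high = 0.750,
                          distribution = "lognormal"), n)
  expect_true(all(hr > 0))
  expect_equal(median(hr), 0.570, tolerance = 0.01)   # median = e^meanlog
  u <- sample_param(list(base = 0.760, low = 0.610, high = 0.910,
                         distribution = "beta"), n)
  expect_true(all(u >= 0 & u <= 1))
  expect_lt(abs(mean(u) - 0.760), 0.005)
  expect_equal(sd(u), (0.910 - 0.610) / (2 * 1.96), tolerance = 0.02)
  cost <- sample_param(list(base = 804, low = 643, high = 965,
                            distribution = "gamma"), n)
  expect_true(all(cost >= 0))
  expect_lt(abs(mean(cost) / 804 - 1), 0.005)
  fx <- sample_param(list(base = 3, low = 1, high = 9,
                          distribution = "fixed"), 100)
  expect_true(all(fx == 3))
  # degenerate range collapses to the base value
  zero <- sample_param(list(base = 0, low = 0, high = 0,
                            distribution = "beta"), 10)
  expect_true(all(zero == 0))
})

test_that("infeasible beta moments fall back with a warning", {
  expect_warning(
    s <- sample_param(list(base = 0.5, low = 0, high = 4,
                           distribution = "beta"), 1000),
    "infeasible")
  expect_true(all(s >= 0 & s <= 1))
})

test_that("a zero-width range reproduces the base-case ICER at both ends", {
  cfg <- edit_config(edit = function(cfg) {
    cfg$parameters$cost_test$low <- cfg$parameters$cost_test$base
    cfg$parameters$cost_test$high <- cfg$parameters$cost_test$base
    cfg
  })
  tor <- owsa(cfg, parameters = c("cost_test", "hr_os"))
  base_icer <- attr(tor, "base_icer")
  row <- tor[tor$param == "cost_test", ]
  expect_equal(row$icer_at_low, base_icer)
  expect_equal(row$icer_at_high, base_icer)
  expect_equal(row$swing, 0)
  expect_identical(tor$param[nrow(tor)], "cost_test")  # ranked last
  expect_gt(tor[tor$param == "hr_os", "swing"], 0)
})

test_that("the OS hazard ratio dominates the tornado", {
  tor <- owsa()
  expect_identical(tor$param[1], "hr_os")
  expect_true(all(tor$swing >= 0, na.rm = TRUE))
  expect_true(!is.unsorted(rev(tor$swing)))
})

test_that("the PSA is seed-reproducible and collapses when nothing varies", {
  d1 <- psa(n_iter = 25, seed = 123)
  d2 <- psa(n_iter = 25, seed = 123)
  expect_identical(d1, d2)
  d3 <- psa(n_iter = 25, seed = 124)
  expect_false(identical(d1$delta_cost, d3$delta_cost))

  cfg_fix <- edit_config(edit = function(cfg) {
    for (nm in names(cfg$parameters))
      cfg$parameters[[nm]]$distribution <- "fixed"
    cfg
  })
  d0 <- psa(cfg_fix, n_iter = 4, seed = 9)
  base <- psm(cfg_fix)
  expect_true(all(abs(d0$delta_cost - base$ce$incremental_cost) < 1e-9))
  expect_true(all(abs(d0$delta_qaly - base$ce$incremental_qaly) < 1e-12))
})

test_that("the acceptability curve behaves like a CDF of the NMB sign", {
  set.seed(7)
  d <- psa(n_iter = 200, seed = 7)
  cc <- ceac(d, wtp_grid = seq(0, 60000, by = 5000))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  expect_equal(cc$prob_cost_effective[1], mean(d$delta_cost < 0))
  # monotone non-decreasing whenever every draw gains QALYs
  if (all(d$delta_qaly >= 0))
    expect_true(all(diff(cc$prob_cost_effective) >= 0))
  # the far-right limit approaches P(delta QALY > 0)
  expect_equal(prob_ce(d, wtp = 1e9), mean(d$delta_qaly > 0))
})
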