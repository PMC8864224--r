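test_that("exponential MLE matches the closed form under censoring", {
  set.seed(11)
  d <- simulate_ipd(parsurv("exponential", 0.08), n = 300, admin_time = 15,
                    dropout_rate = 0.01)
  f <- fit_parsurv(d$time_months, d$event, "exponential")
  closed <- sum(d$event) / sum(d$time_months)
  expect_true(f$converged)
  expect_equal(unname(coef(f)), closed, tolerance = 1e-8)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
})

test_that("uncensored log-normal fit recovers parameters and equals the log-moment MLE", {
  set.seed(21)
  d <- simulate_ipd(pfs_lognormal(), n = 500)
  f <- fit_parsurv(d$time_months, d$event, "lognormal")
  lt <- log(d$time_months)
  # oracle: for uncensored data the MLE is the mean/sd (1/n) of log times
  expect_equal(unname(coef(f)["mu"]), mean(lt), tolerance = 1e-5)
  expect_equal(unname(coef(f)["sigma"]),
               sqrt(mean((lt - mean(lt))^2)), tolerance = 1e-4)
  # parameter recovery of the published PFS model
  expect_lt(abs(coef(f)["mu"] - 1.121355), 0.1)
  expect_lt(abs(coef(f)["sigma"] - 0.7702185), 0.1)
})

test_that("fits agree with an independent survival-regression implementation", {
  set.seed(31)
  d <- simulate_ipd(parsurv("weibull", c(1.4, 11)), n = 400, admin_time = 30)
  f <- fit_parsurv(d$time_months, d$event, "weibull")
  ref <- survival::survreg(survival::Surv(time_months, event) ~ 1, data = d,
                           dist = "weibull")
  expect_equal(f$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(coef(f)["scale"]), unname(exp(coef(ref))),
               tolerance = 1e-4)
  expect_equal(unname(coef(f)["shape"]), 1 / ref$scale, tolerance = 1e-4)
  set.seed(32)
  d2 <- simulate_ipd(pfs_lognormal(), n = 400, admin_time = 12)
  f2 <- fit_parsurv(d2$time_months, d2$event, "lognormal")
  ref2 <- flexsurv::flexsurvreg(survival::Surv(time_months, event) ~ 1,
                                data = d2, dist = "lnorm")
  expect_equal(f2$loglik, as.numeric(logLik(ref2)), tolerance = 1e-6)
  expect_equal(unname(coef(f2)), unname(ref2$res[, "est"]),
               tolerance = 1e-4)
})

test_that("non-exponential data is recognized as such by AIC", {
  # gamma far from 1 makes the log-logistic clearly non-exponential
  set.seed(41)
  d <- simulate_ipd(os_loglogistic(), n = 800)
  f_ll <- fit_parsurv(d$time_months, d$event, "loglogistic")
  f_ex <- fit_parsurv(d$time_months, d$event, "exponential")
  expect_lt(f_ll$aic, f_ex$aic)
})

test_that("AIC selection honours minimum, then parsimony, then family order", {
  mk_fit <- function(family, aic, npar) {
    structure(list(model = parsurv("exponential", 1), loglik = npar - aic / 2,
                   aic = aic, n_params = npar, converged = TRUE, n = 100,
                   n_event = 90, family = family), class = "parsurv_fit")
  }
  single <- mk_fit("weibull", 120, 2)
  expect_identical(select_parsurv(list(single)), single)
  picked <- select_parsurv(list(mk_fit("gompertz", 101.9, 2),
                                mk_fit("weibull", 100.0, 2)))
  expect_identical(picked$family, "weibull")
  picked <- select_parsurv(list(mk_fit("gengamma", 100, 3),
                                mk_fit("exponential", 100, 1)))
  expect_identical(picked$family, "exponential")
  picked <- select_parsurv(list(mk_fit("loglogistic", 100, 2),
                                mk_fit("weibull", 100, 2)))
  expect_identical(picked$family, "weibull")  # fixed family order
  expect_error(select_parsurv(list()), "empty")
})

test_that("non-convergence is flagged, and bad inputs are rejected", {
  expect_error(fit_parsurv(1:5, rep(1, 5), "weibull"), "at least 10")
  expect_error(fit_parsurv(1:20, rep(0, 20), "weibull"), "at least 1 event")
  f <- fit_parsurv_all(rexp(50, 0.1) + 1, rep(1, 50),
                       families = c("exponential", "weibull"))
  expect_named(f, c("exponential", "weibull"))
  expect_true(all(vapply(f, function(x) isTRUE(x$converged), logical(1))))
})
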