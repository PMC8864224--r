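# published comparator-arm survival parameters (months)
pfs_lognormal <- function() parsurv("lognormal", c(mu = 1.121355, sigma = 0.7702185))
os_loglogistic <- function() parsurv("loglogistic", c(lambda = 0.01822555, gamma = 1.694566))

# one representative valid parameterization per family, for invariant sweeps
family_examples <- function() list(
  exponential = parsurv("exponential", 0.07),
  weibull = parsurv("weibull", c(shape = 1.3, scale = 12)),
  lognormal = pfs_lognormal(),
  loglogistic = os_loglogistic(),
  gompertz = parsurv("gompertz", c(shape = 0.05, rate = 0.04)),
  gengamma = parsurv("gengamma", c(mu = 2.2, sigma = 0.9, Q = 0.6))
)

# a minimal two-arm setup with analytically tractable exponential curves
exp_arm <- function(rate_os = log(2) / 10, rate_pfs = log(2) / 4, ...) {
  arm_spec("analytic",
           pfs_curve = parsurv("exponential", rate_pfs),
           os_curve = parsurv("exponential", rate_os),
           drug_cost_per_cycle = 0, ...)
}

# a deep copy of the shipped config with field edits applied
edit_config <- function(cfg = load_ce_config(), edit) {
  cfg2 <- unserialize(serialize(cfg, NULL))
  edit(cfg2)
}
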