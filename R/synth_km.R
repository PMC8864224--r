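#' Simulate pseudo individual patient data from a survival curve
#'
#' Draws event times by inverse-CDF sampling from a parametric (or
#' hazard-ratio derived) survival curve, with independent exponential dropout
#' and administrative censoring. This stands in for trial IPD, which is not
#' published: fitted curves can then be validated by parameter recovery.
#'
#' @param model A `survcurve` object.
#' @param n Number of patients.
#' @param admin_time Administrative censoring time in months (`Inf` for
#'   none); emulates the trial's follow-up limit.
#' @param dropout_rate Exponential dropout rate per month (0 for none).
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `time_months` and `event`
#'   (1 = event, 0 = censored).
#' @examples
#' pfs <- parsurv("lognormal", c(mu = 1.121355, sigma = 0.7702185))
#' d <- simulate_ipd(pfs, n = 200, admin_time = 19, seed = 7)
#' table(d$event)
#' @export
simulate_ipd <- function(model, n, admin_time = Inf, dropout_rate = 0,
                         seed = NULL) {
  stopifnot(inherits(model, "survcurve"))
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (admin_time <= 0) stop("'admin_time' must be > 0", call. = FALSE)
  if (dropout_rate < 0) stop("'dropout_rate' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- stats::runif(n)
  tev <- .inv_cdf(model, u)
  tdrop <- if (dropout_rate > 0) stats::rexp(n, dropout_rate) else
    rep(Inf, n)
  tcens <- pmin(tdrop, admin_time)
  data.frame(time_months = pmin(tev, tcens),
             event = as.integer(tev <= tcens))
}

# inverse CDF: closed form for parsurv; for hr_curve S_ref^hr = 1-p means
# S_ref = (1-p)^(1/hr), so reuse the reference quantile
.inv_cdf <- function(model, p) {
  if (inherits(model, "parsurv"))
    return(.fam(model$family)$quant(p, model$params))
  if (inherits(model, "hr_curve"))
    return(.inv_cdf(model$reference, 1 - (1 - p)^(1 / model$hr)))
  vapply(p, function(pi) {
    hi <- 1
    while (surv_prob(model, hi) > 1 - pi && hi < 1e9) hi <- hi * 2
    stats::uniroot(function(t) surv_prob(model, t) - (1 - pi), c(0, hi),
                   tol = 1e-10)$root
  }, numeric(1))
}

#' @export
simulate.parsurv <- function(object, nsim = 1, seed = NULL, ...) {
  simulate_ipd(object, n = nsim, seed = seed, ...)
}

#' Kaplan-Meier estimate as curve coordinates
#'
#' Product-limit estimate (via [survival::survfit]) returned as the
#' (time, survival) coordinate pairs a curve digitizer would produce,
#' prefixed with the (0, 1) anchor.
#'
#' @param ipd Data frame with `time_months` and `event` columns.
#' @return A data frame of class `km_points` with columns `time_months`,
#'   `survival`, `n_risk`.
#' @export
km_curve <- function(ipd) {
  stopifnot(nrow(ipd) >= 1L)
  sf <- survival::survfit(survival::Surv(time_months, event) ~ 1, data = ipd)
  out <- data.frame(time_months = c(0, sf$time),
                    survival = c(1, sf$surv),
                    n_risk = c(sf$n, sf$n.risk))
  class(out) <- c("km_points", "data.frame")
  out
}

.validate_km_points <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("time_months", "survival") %in% names(points)))
  if (is.unsorted(points$time_months, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (points$time_months[1] != 0 || points$survival[1] != 1)
    stop("curve must start at (0, 1)", call. = FALSE)
  if (any(diff(points$survival) > 1e-12))
    stop("survival must be non-increasing", call. = FALSE)
  if (any(points$survival < 0 | points$survival > 1))
    stop("survival must lie in [0, 1]", call. = FALSE)
  invisible(points)
}

#' Emulate graph digitization of a Kaplan-Meier curve
#'
#' Resamples the step function on a regular time grid and adds truncated
#' Gaussian reading error on the probability axis, clipped to \[0, 1\] and
#' re-monotonized by a cumulative minimum — the error structure of manually
#' digitized published curves. Time-axis reading error is not modelled.
#'
#' @param points A `km_points` data frame (see [km_curve()]).
#' @param grid_step Grid spacing in months.
#' @param jitter_sd Standard deviation of the probability reading error.
#' @param seed Optional integer seed.
#' @return A `km_points` data frame on the regular grid (no `n_risk`).
#' @export
digitize_km <- function(points, grid_step, jitter_sd = 0, seed = NULL) {
  .validate_km_points(points)
  if (grid_step <= 0) stop("'grid_step' must be > 0", call. = FALSE)
  if (jitter_sd < 0) stop("'jitter_sd' must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tmax <- max(points$time_months)
  grid <- seq(0, tmax, by = grid_step)
  # right-continuous step function: survival after the last observed drop
  s <- stats::approx(points$time_months, points$survival, xout = grid,
                     method = "constant", f = 0, rule = 2)$y
  if (jitter_sd > 0) {
    err <- stats::rnorm(length(s), 0, jitter_sd)
    err <- pmin(pmax(err, -2 * jitter_sd), 2 * jitter_sd)
    s <- s + err
    s[1] <- 1
  }
  s <- pmin(pmax(s, 0), 1)
  s <- cummin(s)
  out <- data.frame(time_months = grid, survival = s)
  class(out) <- c("km_points", "data.frame")
  out
}

#' Reconstruct pseudo-IPD from digitized curve coordinates
#'
#' Risk-set reconstruction: interval event counts are recovered from the
#' relative survival drops scaled by a running number at risk, starting from
#' an assumed initial cohort size; patients still at risk at the last
#' coordinate are censored there. Dropout within the curve span is not
#' reconstructed (not identifiable from the coordinates alone), so this is a
#' stand-in for full risk-table based reconstruction.
#'
#' @param points A `km_points` data frame.
#' @param n_risk Assumed number of patients at risk at time 0. The default,
#'   200, is the scale of the published trial's comparator arm.
#' @param event_at Where in the interval reconstructed events are placed:
#'   `"right"` (default, the drop is observed at the coordinate) or `"mid"`.
#' @return A pseudo-IPD data frame (`time_months`, `event`).
#' @examples
#' pfs <- parsurv("lognormal", c(1.121355, 0.7702185))
#' km <- km_curve(simulate_ipd(pfs, 500, seed = 1))
#' dig <- digitize_km(km, grid_step = 0.5, jitter_sd = 0.01, seed = 2)
#' fit <- fit_parsurv(data = ipd_from_km(dig), family = "lognormal")
#' @export
ipd_from_km <- function(points, n_risk = 200, event_at = c("right", "mid")) {
  .validate_km_points(points)
  event_at <- match.arg(event_at)
  if (n_risk < 1) stop("'n_risk' must be >= 1", call. = FALSE)
  tt <- points$time_months
  ss <- points$survival
  n_at <- n_risk
  times <- numeric(0)
  events <- integer(0)
  for (i in seq_len(length(tt) - 1L)) {
    if (n_at <= 0) break
    s0 <- ss[i]; s1 <- ss[i + 1L]
    if (s0 <= 0) break
    d <- round(n_at * (s0 - s1) / s0)
    d <- min(max(d, 0L), n_at)
    if (d > 0) {
      tev <- if (event_at == "right") tt[i + 1L] else
        (tt[i] + tt[i + 1L]) / 2
      times <- c(times, rep(tev, d))
      events <- c(events, rep(1L, d))
      n_at <- n_at - d
    }
  }
  if (n_at > 0) {
    times <- c(times, rep(tt[length(tt)], n_at))
    events <- c(events, rep(0L, n_at))
  }
  data.frame(time_months = times, event = events)
}

#' Read / write pseudo-IPD and curve coordinates as CSV
#'
#' The exchange formats are plain CSV: pseudo-IPD has columns
#' `time_months,event`; curve coordinates have `time_months,survival`.
#'
#' @param path File path.
#' @return `read_ipd()` returns a data frame; `write_ipd()` its input,
#'   invisibly.
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_months", "event") %in% names(d)))
  d
}

#' @rdname read_ipd
#' @param ipd Pseudo-IPD data frame.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd[, c("time_months", "event")], path,
                   row.names = FALSE)
  invisible(ipd)
}
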