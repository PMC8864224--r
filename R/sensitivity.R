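#' Sample a parameter from its sensitivity distribution
#'
#' Draws from the distribution assigned to a parameter in the input table:
#' beta and gamma are moment-matched to mean = base and
#' sd = (high - low) / (2 * 1.96) (ranges are read as 95% intervals);
#' log-normal (hazard ratios) uses `meanlog = log(base)` and
#' `sdlog = (log(high) - log(low)) / (2 * 1.96)`; `fixed` (or a zero-width
#' range) returns the base value. Infeasible beta moments (variance too
#' large for the unit interval) fall back to sd = 0.2 * base with a warning.
#'
#' @param spec One-row data frame (or list) with `base`, `low`, `high`,
#'   `distribution`.
#' @param n Number of draws.
#' @return Numeric vector of `n` draws, within the distribution's support.
#' @export
sample_param <- function(spec, n = 1) {
  base <- spec$base; s <- (spec$high - spec$low) / (2 * 1.96)
  switch(spec$distribution,
    fixed = rep(base, n),
    lognormal = {
      if (s <= 0 || spec$low <= 0) return(rep(base, n))
      sdlog <- (log(spec$high) - log(spec$low)) / (2 * 1.96)
      stats::rlnorm(n, meanlog = log(base), sdlog = sdlog)
    },
    gamma = {
      if (s <= 0 || base <= 0) return(rep(base, n))
      stats::rgamma(n, shape = base^2 / s^2, rate = base / s^2)
    },
    beta = {
      if (s <= 0 || base <= 0 || base >= 1) return(rep(base, n))
      if (s^2 >= base * (1 - base)) {
        warning(sprintf(
          "infeasible beta moments for base %.3g; falling back to sd = 0.2*base",
          base), call. = FALSE)
        s <- 0.2 * base
      }
      v <- base * (1 - base) / s^2 - 1
      stats::rbeta(n, base * v, (1 - base) * v)
    },
    stop("unknown distribution: ", spec$distribution, call. = FALSE))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the full deterministic model once at each parameter's low and
#' high bound, all other parameters at base, and ranks parameters by the
#' absolute ICER swing. A model failure or a non-positive incremental effect
#' at an extreme is flagged in the `note` column, never dropped silently.
#'
#' @param config Configuration (object, path, or `NULL` for shipped).
#' @param parameters Optional character vector restricting the analysis to a
#'   subset of parameters.
#' @return A data frame of class `psm_owsa`, sorted by decreasing swing,
#'   with attributes `base_icer` and `wtp`.
#' @export
owsa <- function(config = NULL, parameters = NULL) {
  if (!inherits(config, "psmce_config")) config <- load_ce_config(config)
  ptab <- param_table(config)
  if (!is.null(parameters)) ptab <- ptab[ptab$name %in% parameters, ]
  pars0 <- base_params(config)
  base <- psm(config, pars0)

  eval_at <- function(name, value) {
    p <- pars0; p[name] <- value
    tryCatch({
      m <- psm(config, p)
      list(icer = m$ce$icer_per_qaly, note = m$ce$classification)
    }, error = function(e) list(icer = NA_real_,
                                note = paste("error:", conditionMessage(e))))
  }

  rows <- lapply(seq_len(nrow(ptab)), function(i) {
    lo <- eval_at(ptab$name[i], ptab$low[i])
    hi <- eval_at(ptab$name[i], ptab$high[i])
    data.frame(param = ptab$name[i], low = ptab$low[i], high = ptab$high[i],
               icer_at_low = lo$icer, icer_at_high = hi$icer,
               swing = abs(hi$icer - lo$icer),
               note = if (lo$note != "icer" || hi$note != "icer")
                 paste(lo$note, hi$note, sep = "/") else "")
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$param), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$ce$icer_per_qaly
  attr(out, "wtp") <- base$ce$wtp
  class(out) <- c("psm_owsa", "data.frame")
  out
}

#' @export
print.psm_owsa <- function(x, n = 10, ...) {
  cat(sprintf("One-way sensitivity analysis (base ICER $%s/QALY)\n",
              format(round(attr(x, "base_icer")), big.mark = ",")))
  y <- as.data.frame(x)
  y$icer_at_low <- round(y$icer_at_low)
  y$icer_at_high <- round(y$icer_at_high)
  y$swing <- round(y$swing)
  print(utils::head(y, n), row.names = FALSE)
  if (nrow(y) > n) cat("...", nrow(y) - n, "more parameters\n")
  invisible(x)
}

#' @export
plot.psm_owsa <- function(x, n = 12, ...) {
  y <- utils::head(x, n)
  y <- y[rev(seq_len(nrow(y))), ]
  base <- attr(x, "base_icer")
  lo <- pmin(y$icer_at_low, y$icer_at_high)
  hi <- pmax(y$icer_at_low, y$icer_at_high)
  op <- graphics::par(mar = c(4, 12, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = range(c(lo, hi, base), na.rm = TRUE),
                 ylim = c(0.5, nrow(y) + 0.5), yaxt = "n",
                 xlab = "ICER ($/QALY)", ylab = "", ...)
  graphics::segments(lo, seq_len(nrow(y)), hi, seq_len(nrow(y)), lwd = 8,
                     col = "steelblue")
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(y)), labels = y$param, las = 1,
                 cex.axis = 0.8)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo simulation: each iteration samples every non-fixed parameter
#' independently from its assigned distribution ([sample_param()]), rebuilds
#' both arms, and records incremental cost and QALYs. Reproducible under a
#' fixed seed.
#'
#' @param config Configuration (object, path, or `NULL` for shipped).
#' @param n_iter Number of iterations (the published analysis uses 10,000).
#' @param seed Integer seed.
#' @return A data frame of class `psm_psa`: one row per iteration with
#'   `delta_cost`, `delta_qaly`, `delta_ly` and every sampled parameter;
#'   attributes `wtp` and `n_failed` (failed-and-resampled iterations).
#' @examples
#' \donttest{
#' draws <- psa(n_iter = 200, seed = 1)
#' prob_ce(draws, wtp = 30552)
#' }
#' @export
psa <- function(config = NULL, n_iter = 10000, seed = NULL) {
  if (!inherits(config, "psmce_config")) config <- load_ce_config(config)
  if (n_iter < 1) stop("'n_iter' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ptab <- param_table(config)
  draws <- matrix(NA_real_, n_iter, nrow(ptab),
                  dimnames = list(NULL, ptab$name))
  for (j in seq_len(nrow(ptab)))
    draws[, j] <- sample_param(ptab[j, ], n_iter)

  dc <- dq <- dly <- numeric(n_iter)
  n_failed <- 0L
  for (i in seq_len(n_iter)) {
    repeat {
      res <- tryCatch(psm(config, draws[i, ]), error = function(e) NULL)
      if (!is.null(res)) break
      n_failed <- n_failed + 1L
      for (j in seq_len(nrow(ptab)))
        draws[i, j] <- sample_param(ptab[j, ], 1)
    }
    dc[i] <- res$ce$incremental_cost
    dq[i] <- res$ce$incremental_qaly
    dly[i] <- res$ce$incremental_ly
  }
  if (n_failed > 0)
    message(n_failed, " iteration(s) failed and were resampled")
  out <- data.frame(iter = seq_len(n_iter), delta_cost = dc,
                    delta_qaly = dq, delta_ly = dly)
  out <- cbind(out, as.data.frame(draws))
  attr(out, "wtp") <- config$model$wtp_per_qaly
  attr(out, "n_failed") <- n_failed
  class(out) <- c("psm_psa", "data.frame")
  out
}

#' Probability of cost-effectiveness at a threshold
#'
#' Fraction of PSA iterations with positive net monetary benefit.
#'
#' @param draws A `psm_psa`.
#' @param wtp Willingness-to-pay threshold(s), USD/QALY.
#' @return Numeric vector of probabilities, one per `wtp`.
#' @export
prob_ce <- function(draws, wtp = attr(draws, "wtp")) {
  stopifnot(inherits(draws, "psm_psa"))
  vapply(wtp, function(w) mean(draws$delta_qaly * w - draws$delta_cost > 0),
         numeric(1))
}

#' Cost-effectiveness acceptability curve
#'
#' @param draws A `psm_psa`.
#' @param wtp_grid Vector of willingness-to-pay thresholds (USD/QALY).
#' @return A data frame of class `psm_ceac` with columns `wtp` and
#'   `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 60000, by = 1000)) {
  stopifnot(inherits(draws, "psm_psa"), length(wtp_grid) > 0)
  out <- data.frame(wtp = wtp_grid,
                    prob_cost_effective = prob_ce(draws, wtp_grid))
  class(out) <- c("psm_ceac", "data.frame")
  out
}

#' @export
print.psm_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (%d resampled failures)\n", nrow(x),
              attr(x, "n_failed")))
  cat(sprintf("mean dCost $%s, mean dQALY %.3f, P(CE at $%s/QALY) = %.3f\n",
              format(round(mean(x$delta_cost)), big.mark = ","),
              mean(x$delta_qaly),
              format(attr(x, "wtp"), big.mark = ","), prob_ce(x)))
  invisible(x)
}

#' @export
plot.psm_psa <- function(x, wtp = attr(x, "wtp"), ...) {
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "incremental QALYs", ylab = "incremental cost ($)",
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey")
  graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}

#' @export
plot.psm_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "willingness-to-pay ($/QALY)",
                 ylab = "P(cost-effective)", ...)
  invisible(x)
}
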