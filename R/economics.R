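#' Incremental cost-effectiveness of two strategies
#'
#' Computes incremental cost, life-years and QALYs of an intervention versus
#' a comparator, the ICER per QALY and per LY, and the net monetary benefit
#' at a willingness-to-pay threshold. When the incremental effect is not
#' positive the ICER is not a meaningful ratio; the result is classified
#' instead (`"dominant"`: cheaper and more effective; `"dominated"`: costlier
#' and less effective; `"undefined"`: zero incremental effect).
#'
#' @param intervention,comparator Named vectors `c(cost, ly, qaly)` as
#'   returned by [arm_totals()], or `cohort_trace` objects.
#' @param wtp Willingness-to-pay threshold, USD/QALY.
#' @param labels Length-2 character vector of strategy names.
#' @return An object of class `ce_result`.
#' @examples
#' icer(c(cost = 59018, ly = 3.30, qaly = 2.30),
#'      c(cost = 29351, ly = 1.47, qaly = 1.03))
#' @export
icer <- function(intervention, comparator, wtp = 30552,
                 labels = c("intervention", "comparator")) {
  if (inherits(intervention, "cohort_trace")) {
    labels[1] <- attr(intervention, "arm_name") %||% labels[1]
    intervention <- arm_totals(intervention)
  }
  if (inherits(comparator, "cohort_trace")) {
    labels[2] <- attr(comparator, "arm_name") %||% labels[2]
    comparator <- arm_totals(comparator)
  }
  stopifnot(all(is.finite(intervention)), all(is.finite(comparator)))
  dc <- unname(intervention["cost"] - comparator["cost"])
  dly <- unname(intervention["ly"] - comparator["ly"])
  dq <- unname(intervention["qaly"] - comparator["qaly"])
  classification <-
    if (dq > 0 && dc < 0) "dominant"
    else if (dq < 0 && dc > 0) "dominated"
    else if (dq == 0) "undefined"
    else "icer"
  structure(list(
    arms = data.frame(arm = labels,
                      cost = c(intervention["cost"], comparator["cost"]),
                      ly = c(intervention["ly"], comparator["ly"]),
                      qaly = c(intervention["qaly"], comparator["qaly"]),
                      row.names = NULL),
    incremental_cost = dc, incremental_ly = dly, incremental_qaly = dq,
    icer_per_qaly = if (dq > 0) dc / dq else NA_real_,
    icer_per_ly = if (dly > 0) dc / dly else NA_real_,
    classification = classification, wtp = wtp,
    nmb_at_wtp = dq * wtp - dc), class = "ce_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cost-effectiveness decision at a threshold
#'
#' The intervention is adopted iff its net monetary benefit at the threshold
#' is strictly positive — equivalent, for a positive incremental effect, to
#' the ICER lying strictly below the threshold. An ICER exactly at the
#' threshold is therefore not cost-effective.
#'
#' @param result A `ce_result` from [icer()].
#' @param wtp Willingness-to-pay threshold (defaults to the one stored in
#'   `result`).
#' @return `TRUE` iff cost-effective at `wtp`.
#' @export
decide <- function(result, wtp = result$wtp) {
  stopifnot(inherits(result, "ce_result"))
  result$incremental_qaly * wtp - result$incremental_cost > 0
}

#' @export
print.ce_result <- function(x, ...) {
  arms <- x$arms
  arms$cost <- round(arms$cost)
  arms$ly <- round(arms$ly, 2)
  arms$qaly <- round(arms$qaly, 2)
  cat("Cost-effectiveness results\n")
  print(arms, row.names = FALSE)
  cat(sprintf("incremental: $%s, %.2f LYs, %.2f QALYs\n",
              format(round(x$incremental_cost), big.mark = ","),
              x$incremental_ly, x$incremental_qaly))
  if (x$classification == "icer") {
    cat(sprintf("ICER: $%s/QALY",
                format(round(x$icer_per_qaly), big.mark = ",")))
    if (!is.na(x$icer_per_ly))
      cat(sprintf(" ($%s/LY)", format(round(x$icer_per_ly), big.mark = ",")))
    cat("\n")
  } else {
    cat(sprintf("ICER: %s\n", x$classification))
  }
  cat(sprintf("NMB at WTP $%s: $%s -> %scost-effective\n",
              format(x$wtp, big.mark = ","),
              format(round(x$nmb_at_wtp), big.mark = ","),
              if (decide(x)) "" else "NOT "))
  invisible(x)
}

#' Export a `ce_result` as a Table-2 style list (for JSON serialization)
#'
#' @param x A `ce_result`.
#' @return A nested list mirroring the published base-case table layout.
#' @export
ce_report <- function(x) {
  stopifnot(inherits(x, "ce_result"))
  arms <- split(x$arms[-1], x$arms$arm)
  list(arms = lapply(arms, as.list),
       incremental = list(cost = x$incremental_cost, ly = x$incremental_ly,
                          qaly = x$incremental_qaly),
       icer = list(per_ly = x$icer_per_ly, per_qaly = x$icer_per_qaly),
       classification = x$classification,
       wtp = x$wtp, nmb_at_wtp = x$nmb_at_wtp,
       cost_effective = decide(x))
}
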