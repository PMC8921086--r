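#' Net monetary benefit of a strategy result
#'
#' `NMB = WTP * QALYs - cost`, on the unrounded model outputs.
#'
#' @param result A `strategy_result` (or any list with `total_cost` and
#'   `total_qaly`).
#' @param wtp Willingness-to-pay per QALY (non-negative).
#' @return Net monetary benefit in currency units.
#' @examples
#' compute_nmb(list(total_cost = 0, total_qaly = 1), wtp = 100000)  # 1e5
#' @export
compute_nmb <- function(result, wtp) {
  stopifnot(wtp >= 0)
  wtp * result$total_qaly - result$total_cost
}

#' Compare two strategy results
#'
#' Computes incremental cost, incremental effectiveness, the incremental
#' cost-effectiveness ratio (ICER), per-strategy net monetary benefit, and
#' a dominance classification, all for `a` relative to `b`. The ICER is
#' undefined (`NA`) when the QALY difference is zero; decisions (dominance,
#' preference) are made on NMB, which is sign-unambiguous in the dominant
#' quadrant.
#'
#' @param a,b `strategy_result` objects computed from the same parameters.
#' @param wtp Willingness-to-pay per QALY.
#' @return An object of class `cea_comparison`: list with `delta_cost`,
#'   `delta_qaly`, `icer`, `nmb` (named vector for both strategies),
#'   `dominance` (`"dominant"`, `"dominated"` or `"tradeoff"` for `a`),
#'   `preferred` (strategy with the higher NMB), `wtp`, and the two inputs.
#' @export
compare_strategies <- function(a, b, wtp) {
  stopifnot(wtp >= 0)
  dc <- a$total_cost - b$total_cost
  dq <- a$total_qaly - b$total_qaly
  icer <- if (dq == 0) NA_real_ else dc / dq
  nmb <- c(compute_nmb(a, wtp), compute_nmb(b, wtp))
  names(nmb) <- c(a$strategy, b$strategy)
  dominance <- if (dc < 0 && dq > 0) {
    "dominant"
  } else if (dc > 0 && dq < 0) {
    "dominated"
  } else {
    "tradeoff"
  }
  preferred <- names(nmb)[which.max(nmb)]
  structure(
    list(delta_cost = dc, delta_qaly = dq, icer = icer, nmb = nmb,
         dominance = dominance, preferred = preferred, wtp = wtp,
         a = a, b = b),
    class = "cea_comparison"
  )
}

#' Base-case cost-effectiveness analysis
#'
#' Runs both staging strategies under one parameter set and compares
#' CE-MR/CT against CE-CT.
#'
#' @param params An `mstage_params` object (default: [default_params()]).
#' @param wtp Willingness-to-pay per QALY; defaults to `params$wtp`.
#' @return A `cea_comparison` (CE-MR/CT as `a`, CE-CT as `b`).
#' @examples
#' bc <- base_case()
#' bc$dominance  # "dominant"
#' @export
base_case <- function(params = default_params(), wtp = params$wtp) {
  validate_params(params)
  compare_strategies(
    run_strategy("CE-MR/CT", params),
    run_strategy("CE-CT", params),
    wtp = wtp
  )
}

#' @export
print.cea_comparison <- function(x, ...) {
  fmt <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat(sprintf("Cost-effectiveness comparison: %s vs %s (WTP $%s/QALY)\n",
              x$a$strategy, x$b$strategy, fmt(x$wtp)))
  for (r in list(x$a, x$b)) {
    cat(sprintf("  %-9s cost $%s, %.4f QALYs, NMB $%s\n", r$strategy,
                fmt(r$total_cost), r$total_qaly, fmt(x$nmb[[r$strategy]])))
  }
  cat(sprintf("  incremental: cost $%s, QALYs %+.4f, ICER %s\n",
              fmt(x$delta_cost), x$delta_qaly,
              if (is.na(x$icer)) "undefined" else paste0("$", fmt(x$icer), "/QALY")))
  cat(sprintf("  %s is %s; preferred: %s\n",
              x$a$strategy, x$dominance, x$preferred))
  invisible(x)
}

#' Serialize a comparison as a plain list (for JSON reports)
#'
#' @param x A `cea_comparison`.
#' @param ... Unused.
#' @return A named list of base-case quantities.
#' @export
as.list.cea_comparison <- function(x, ...) {
  list(
    wtp = x$wtp,
    strategies = list(
      list(name = x$a$strategy, cost = x$a$total_cost,
           qaly = x$a$total_qaly, nmb = unname(x$nmb[[x$a$strategy]])),
      list(name = x$b$strategy, cost = x$b$total_cost,
           qaly = x$b$total_qaly, nmb = unname(x$nmb[[x$b$strategy]]))
    ),
    delta_cost = x$delta_cost,
    delta_qaly = x$delta_qaly,
    icer = if (is.na(x$icer)) NULL else x$icer,
    dominance = x$dominance,
    preferred = x$preferred
  )
}
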