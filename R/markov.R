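# 7-state internal transition matrix for one cycle.
#
# Competing risks are composed death-first: the state's death probability is
# applied, then non-death transitions act on survivors, which keeps every
# row stochastic for any valid probability inputs (including perturbed ones
# in the sensitivity analyses).
.tmat7 <- function(params, cycle) {
  st <- params$structure
  d_m1 <- if (st$m1_mortality_onset == "deferred" && cycle == 1L) {
    0
  } else {
    params$p_death_m1
  }
  d_m0 <- params$p_death_m0
  d_loc <- if (identical(st$r1_mortality, "m0")) d_m0 else st$r1_mortality

  P <- matrix(0, 7L, 7L, dimnames = list(.STATES7, .STATES7))
  # Alive, non-resectable: metastatic disease, no surgery.
  P[1L, 1L] <- 1 - d_m1
  P[1L, 7L] <- d_m1
  # Alive, resected, disease-free.
  s_ned <- 1 - d_m0
  p_met <- s_ned * params$p_met_after_resection
  p_loc <- if (st$r1_split_timing == "annual") {
    (s_ned - p_met) * params$p_r1
  } else {
    0
  }
  P[2L, 2L] <- s_ned - p_met - p_loc
  P[2L, 3L] <- p_loc
  P[2L, 5L] <- p_met
  P[2L, 7L] <- d_m0
  # Alive, resected, R1-situation / local recurrence (both phases).
  s_loc <- 1 - d_loc
  for (i in 3:4) {
    P[i, 4L] <- s_loc * (1 - params$p_met_after_resection)
    P[i, 5L] <- s_loc * params$p_met_after_resection
    P[i, 7L] <- d_loc
  }
  # Alive, resected, metastatic (both phases).
  for (i in 5:6) {
    P[i, 6L] <- 1 - d_m1
    P[i, 7L] <- d_m1
  }
  # Dead: absorbing.
  P[7L, 7L] <- 1
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  P
}

#' Per-cycle transition matrix over the five model states
#'
#' Builds the row-stochastic 5x5 transition matrix for a given annual cycle.
#' Non-resectable and resected-metastatic patients die with the annual
#' metastatic mortality (deferred past cycle 1 when the structural flag
#' `m1_mortality_onset = "deferred"` is set); resected disease-free patients
#' die with the non-metastatic mortality, progress to metastasis with the
#' annual post-resection metastasis probability applied to survivors
#' (death-first composition), and, under the `"annual"` R1 interpretation,
#' move to the R1/local-recurrence state; R1/local-recurrence patients can
#' also progress to metastasis. Death is absorbing.
#'
#' @param params An `mstage_params` object.
#' @param cycle Cycle index (1-based).
#' @return A 5x5 matrix with rows and columns named
#'   `NONRES, RES_NED, RES_LOC, RES_MET, DEAD`; every row sums to 1.
#' @examples
#' P <- build_transition_matrix(default_params(), cycle = 2)
#' P["NONRES", "DEAD"]      # 0.5074
#' P["RES_NED", "RES_MET"]  # (1 - 0.029) * 0.38
#' @export
build_transition_matrix <- function(params, cycle) {
  validate_params(params)
  stopifnot(length(cycle) == 1L, cycle >= 1)
  P7 <- .tmat7(params, as.integer(cycle))
  # The two phases of RES_LOC (and RES_MET) share identical transition rows,
  # so collapsing columns and dropping the duplicate phase rows is exact.
  agg <- matrix(0, 7L, 5L, dimnames = list(.STATES7, MSTAGE_STATES))
  agg[cbind(1:7, c(1L, 2L, 3L, 3L, 4L, 4L, 5L))] <- 1
  P <- (P7 %*% agg)[c(1L, 2L, 3L, 5L, 7L), , drop = FALSE]
  rownames(P) <- MSTAGE_STATES
  stopifnot(all(abs(rowSums(P) - 1) < 1e-12))
  P
}

#' Discount factor for an annual cycle
#'
#' @param rate Annual discount rate (fraction, e.g. 0.03).
#' @param cycle Number of elapsed years (0-based time point).
#' @return `1 / (1 + rate)^cycle`.
#' @examples
#' discount_factor(0.03, 1)  # 0.9708738
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 0))
  1 / (1 + rate)^cycle
}

# Per-cycle reward vectors over the 7 internal states.
# Returns list(cost =, utility =). "First year" variants key either on
# global cycle 1 or on the first-year phase of a state, per the
# first_year_reference flag.
.rewards7 <- function(params, cycle) {
  st <- params$structure
  global_fy <- cycle == 1L
  if (st$first_year_reference == "global") {
    fy <- c(NED = global_fy, LOC_Y1 = global_fy, LOC_LATER = global_fy,
            MET_Y1 = global_fy, MET_LATER = global_fy)
  } else {
    # RES_NED is only ever entered at model start, so its first year is
    # global cycle 1 in either convention.
    fy <- c(NED = global_fy, LOC_Y1 = TRUE, LOC_LATER = FALSE,
            MET_Y1 = TRUE, MET_LATER = FALSE)
  }
  cost_ned <- if (fy[["NED"]]) params$cost_post_surgery_y1 else params$cost_post_surgery_later
  u_ned <- if (fy[["NED"]]) params$u_m0_post_surgery_y1 else params$u_m0_post_surgery_later
  u_loc <- function(first) {
    if (first) params$u_m0_post_surgery_y1 else params$u_m0_post_surgery_later
  }
  cost_met <- function(first) {
    params$cost_m1_after_surgery +
      (if (params$structure$met_followup && !first) params$cost_post_surgery_later else 0)
  }
  list(
    cost = c(params$cost_m1_therapy, cost_ned,
             params$cost_local_recurrence, params$cost_local_recurrence,
             cost_met(fy[["MET_Y1"]]), cost_met(fy[["MET_LATER"]]), 0),
    utility = c(params$u_m1_no_surgery, u_ned,
                u_loc(fy[["LOC_Y1"]]), u_loc(fy[["LOC_LATER"]]),
                params$u_m1_post_surgery, params$u_m1_post_surgery,
                params$u_dead)
  )
}

#' Per-state reward schedule for a cycle
#'
#' Annual cost and utility attached to each model state in a given cycle,
#' including the first-year variants for resected states. The R1/local
#' recurrence and resected-metastatic states are reported in two phases
#' (first year in state / later) because rewards may differ by time since
#' state entry under `first_year_reference = "state_entry"`.
#'
#' @inheritParams build_transition_matrix
#' @return A data frame with columns `state`, `phase`, `cost`, `utility`.
#' @export
reward_schedule <- function(params, cycle) {
  validate_params(params)
  stopifnot(cycle >= 1)
  rw <- .rewards7(params, as.integer(cycle))
  data.frame(
    state = c("NONRES", "RES_NED", "RES_LOC", "RES_LOC", "RES_MET",
              "RES_MET", "DEAD"),
    phase = c("all", "all", "year1", "later", "year1", "later", "all"),
    cost = rw$cost,
    utility = rw$utility,
    row.names = NULL
  )
}

# Lean totals for one arm: no trace, minimal allocation. Shared by the
# cohort runner, DSA, PSA, threshold and structure search.
.arm_totals <- function(params, strategy, alloc = NULL) {
  if (is.null(alloc)) alloc <- allocate(strategy, params)
  s <- .expand7(alloc$state_probs)
  H <- params$horizon
  accrual <- params$structure$accrual
  r <- params$discount_rate
  P1 <- .tmat7(params, 1L)
  P2 <- if (H > 1L) .tmat7(params, 2L) else P1
  rw1 <- .rewards7(params, 1L)
  rw2 <- if (H > 1L) .rewards7(params, 2L) else rw1
  cost <- alloc$upfront_cost
  qaly <- 0
  for (k in seq_len(H)) {
    P <- if (k == 1L) P1 else P2
    rw <- if (k == 1L) rw1 else rw2
    snext <- drop(s %*% P)
    occ <- switch(accrual,
      start = s,
      end = snext,
      half = (s + snext) / 2
    )
    tk <- switch(accrual, start = k - 1, end = k, half = k - 0.5)
    d <- 1 / (1 + r)^tk
    cost <- cost + sum(occ * rw$cost) * d
    qaly <- qaly + sum(occ * rw$utility) * d
    s <- snext
  }
  c(cost = cost, qaly = qaly)
}

#' Run the Markov cohort simulation for one strategy
#'
#' Propagates the initial allocation through the annual-cycle transition
#' matrices over the model horizon, accruing discounted costs and QALYs.
#' Reward accrual timing follows the `accrual` structural flag: rewards are
#' valued on the cycle-start occupancy (discounted at the start of the
#' cycle), the cycle-end occupancy (discounted at the end), or their
#' average (half-cycle correction, discounted at mid-cycle). The upfront
#' diagnostic/surgical cost is added undiscounted at cycle 0.
#'
#' @param alloc An `initial_allocation` from [allocate()].
#' @param params The `mstage_params` used to build the allocation.
#' @param trace Logical; keep the full cohort trace (default `TRUE`).
#' @return An object of class `strategy_result`: list with `strategy`,
#'   `total_cost`, `total_qaly`, `upfront_cost` and (when `trace = TRUE`)
#'   `trace`, a data frame with one row per cycle: occupancy of the five
#'   states, discounted cost and QALY increments, and cumulative totals.
#' @examples
#' res <- run_strategy("CE-MR/CT", default_params())
#' c(res$total_cost, res$total_qaly)
#' @export
run_cohort <- function(alloc, params, trace = TRUE) {
  stopifnot(inherits(alloc, "initial_allocation"))
  validate_params(params)
  if (params$horizon < 1) stop("horizon must be >= 1", call. = FALSE)
  H <- params$horizon
  s <- .expand7(alloc$state_probs)
  accrual <- params$structure$accrual
  r <- params$discount_rate
  occ5 <- matrix(0, H + 1L, 5L, dimnames = list(NULL, MSTAGE_STATES))
  occ5[1L, ] <- .collapse5(s)
  dcost <- dqaly <- numeric(H + 1L)
  dcost[1L] <- alloc$upfront_cost
  for (k in seq_len(H)) {
    P <- .tmat7(params, k)
    rw <- .rewards7(params, k)
    snext <- drop(s %*% P)
    occ <- switch(accrual, start = s, end = snext, half = (s + snext) / 2)
    tk <- switch(accrual, start = k - 1, end = k, half = k - 0.5)
    d <- 1 / (1 + r)^tk
    dcost[k + 1L] <- sum(occ * rw$cost) * d
    dqaly[k + 1L] <- sum(occ * rw$utility) * d
    s <- snext
    occ5[k + 1L, ] <- .collapse5(s)
  }
  res <- list(
    strategy = alloc$strategy,
    total_cost = sum(dcost),
    total_qaly = sum(dqaly),
    upfront_cost = alloc$upfront_cost
  )
  if (trace) {
    res$trace <- data.frame(
      cycle = 0:H,
      occ5,
      disc_cost = dcost,
      disc_qaly = dqaly,
      cum_cost = cumsum(dcost),
      cum_qaly = cumsum(dqaly),
      check.names = FALSE
    )
  }
  class(res) <- "strategy_result"
  res
}

#' @rdname run_cohort
#' @param strategy `"CE-CT"` or `"CE-MR/CT"`.
#' @export
run_strategy <- function(strategy, params, trace = TRUE) {
  run_cohort(allocate(strategy, params), params, trace = trace)
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: discounted cost $%s, effectiveness %.4f QALYs\n",
              x$strategy, format(round(x$total_cost), big.mark = ","),
              x$total_qaly))
  invisible(x)
}

#' Write a cohort trace to CSV
#'
#' @param result A `strategy_result` with a trace.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(result, path) {
  stopifnot(inherits(result, "strategy_result"), !is.null(result$trace))
  write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
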