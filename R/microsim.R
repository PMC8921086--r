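#' Individual-level microsimulation of one staging strategy
#'
#' Samples each patient's diagnostic branch, surgical outcome and
#' cycle-by-cycle state transitions from exactly the probabilities used by
#' the cohort engine ([build_transition_matrix()] is the single source of
#' transition truth), accruing per-patient discounted cost and QALYs under
#' the same reward-accrual convention. Serves as a brute-force oracle for
#' [run_cohort()]: means converge to the cohort totals as `n` grows.
#'
#' @param strategy `"CE-CT"` or `"CE-MR/CT"`.
#' @param params An `mstage_params` object.
#' @param n Number of simulated patients.
#' @param seed Integer RNG seed; the caller's RNG state is untouched.
#' @param n_trajectories Number of per-patient state sequences to retain
#'   (default 100).
#' @return An object of class `microsim_result`: list with `strategy`, `n`,
#'   `seed`, `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly` (standard
#'   errors of the means) and `trajectories`, a data frame of retained
#'   state sequences (columns `patient`, `cycle`, `state`).
#' @examples
#' ms <- simulate_patients("CE-CT", default_params(), n = 2000, seed = 42)
#' c(ms$mean_cost, ms$se_cost)
#' @export
simulate_patients <- function(strategy, params, n, seed,
                              n_trajectories = 100L) {
  strategy <- .match_strategy(strategy)
  validate_params(params)
  stopifnot(n >= 1)
  alloc <- allocate(strategy, params)
  s0 <- .expand7(alloc$state_probs)
  H <- params$horizon
  accrual <- params$structure$accrual
  r <- params$discount_rate
  uses_mri <- strategy == "CE-MR/CT"

  .with_seed(seed, {
    state <- sample.int(7L, n, replace = TRUE, prob = s0)
    # Patients reclassified to non-resectable (state NONRES at entry) are
    # the only ones not operated.
    cost <- rep(params$cost_ct + (if (uses_mri) params$cost_mri else 0), n) +
      params$cost_surgery * (state != 1L)
    qaly <- numeric(n)
    n_keep <- min(n, as.integer(n_trajectories))
    traj <- matrix(NA_integer_, n_keep, H + 1L)
    traj[, 1L] <- state[seq_len(n_keep)]
    for (k in seq_len(H)) {
      P <- .tmat7(params, k)
      cumP <- t(apply(P, 1L, cumsum))
      rw <- .rewards7(params, k)
      u <- runif(n)
      nxt <- integer(n)
      for (st in unique(state)) {
        idx <- which(state == st)
        nxt[idx] <- findInterval(u[idx], cumP[st, ]) + 1L
      }
      nxt <- pmin(nxt, 7L)  # guard against u == 1 boundary
      d <- 1 / (1 + r)^(switch(accrual, start = k - 1, end = k, half = k - 0.5))
      cost_k <- switch(accrual,
        start = rw$cost[state],
        end = rw$cost[nxt],
        half = (rw$cost[state] + rw$cost[nxt]) / 2
      )
      qaly_k <- switch(accrual,
        start = rw$utility[state],
        end = rw$utility[nxt],
        half = (rw$utility[state] + rw$utility[nxt]) / 2
      )
      cost <- cost + cost_k * d
      qaly <- qaly + qaly_k * d
      state <- nxt
      traj[, k + 1L] <- state[seq_len(n_keep)]
    }
    state5 <- c("NONRES", "RES_NED", "RES_LOC", "RES_LOC",
                "RES_MET", "RES_MET", "DEAD")
    trajectories <- data.frame(
      patient = rep(seq_len(n_keep), each = H + 1L),
      cycle = rep(0:H, times = n_keep),
      state = state5[as.integer(t(traj))]
    )
    structure(
      list(strategy = strategy, n = as.integer(n), seed = as.integer(seed),
           mean_cost = mean(cost), mean_qaly = mean(qaly),
           se_cost = sd(cost) / sqrt(n), se_qaly = sd(qaly) / sqrt(n),
           trajectories = trajectories),
      class = "microsim_result"
    )
  })
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("Microsimulation, %s: n = %s (seed %d)\n", x$strategy,
              format(x$n, big.mark = ","), x$seed))
  cat(sprintf("  cost  $%s (se %.1f)\n  QALYs %.4f (se %.5f)\n",
              format(round(x$mean_cost, 1), big.mark = ","), x$se_cost,
              x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Generate random valid parameter scenarios for stress testing
#'
#' Produces seeded random parameter sets spanning edge regions of the input
#' space (near-zero and near-one probabilities, zero costs, zero discount,
#' all structural-flag combinations), for property-based testing of the
#' cohort engine against the microsimulation oracle. The first three
#' scenarios are fixed stipulated edges: a perfect CT classifier
#' (`p_ct_fp = 0`), certain metastatic death (`p_death_m1 = 1`), and a
#' zero-cost zero-discount configuration.
#'
#' @param n_scenarios Number of scenarios (>= 1).
#' @param seed Integer RNG seed.
#' @return List of validated `mstage_params` objects.
#' @export
generate_test_scenarios <- function(n_scenarios, seed) {
  stopifnot(n_scenarios >= 1)
  base <- default_params()
  .with_seed(seed, {
    edge_prob <- function() {
      u <- runif(1)
      if (u < 0.10) 0 else if (u < 0.20) 1 else runif(1)
    }
    rand_flags <- function() {
      structure_flags(
        accrual = sample(c("start", "end", "half"), 1L),
        utility_set = sample(c("low", "high"), 1L),
        r1_split_timing = sample(c("annual", "at_entry"), 1L),
        first_year_reference = sample(c("global", "state_entry"), 1L),
        m1_mortality_onset = sample(c("deferred", "immediate"), 1L),
        met_followup = sample(c(TRUE, FALSE), 1L)
      )
    }
    rand_params <- function() {
      p <- base
      p$p_ct_tp <- edge_prob()
      p$p_ct_fp <- 1 - p$p_ct_tp
      for (f in c("p_mri_detect", "p_r1", "p_met_after_resection",
                  "p_surgery_death", "p_death_m1", "p_death_m0")) {
        p[[f]] <- edge_prob()
      }
      for (f in setdiff(.util_fields, "u_dead")) p[[f]] <- runif(1)
      for (f in .cost_fields) {
        p[[f]] <- if (runif(1) < 0.10) 0 else runif(1, 0, 80000)
      }
      p$discount_rate <- if (runif(1) < 0.25) 0 else runif(1, 0, 0.10)
      p$horizon <- sample(1:8, 1L)
      p$structure <- rand_flags()
      p
    }
    fixed1 <- base
    fixed1$p_ct_tp <- 1; fixed1$p_ct_fp <- 0
    fixed2 <- base
    fixed2$p_death_m1 <- 1
    fixed3 <- base
    for (f in .cost_fields) fixed3[[f]] <- 0
    fixed3$discount_rate <- 0
    fixed <- list(fixed1, fixed2, fixed3)
    out <- fixed[seq_len(min(3L, n_scenarios))]
    while (length(out) < n_scenarios) out <- c(out, list(rand_params()))
    lapply(out, function(p) { validate_params(p); p })
  })
}
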