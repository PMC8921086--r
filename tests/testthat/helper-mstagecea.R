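# Published base-case results used as reproduction targets.
published <- list(
  cost_cect = 187601, qaly_cect = 2.337,
  cost_cemrct = 185597, qaly_cemrct = 2.347,
  nmb_cemrct = 49133, nmb_cect = 46117,
  crossover_pct = 98.88
)

# A no-transition, no-death parameter set: every patient stays in the state
# they enter, with flat utility u and no discounting. Useful for exact
# closed-form expectations.
frozen_params <- function(u = 0.8) {
  p <- default_params()
  p$p_surgery_death <- 0
  p$p_death_m1 <- 0
  p$p_death_m0 <- 0
  p$p_met_after_resection <- 0
  p$p_r1 <- 0
  p$discount_rate <- 0
  p$u_m0_post_surgery_y1 <- u
  p$u_m0_post_surgery_later <- u
  p
}

# Hand-build an initial allocation for engine tests.
manual_allocation <- function(probs, upfront = 0, strategy = "CE-CT") {
  stopifnot(length(probs) == 5, abs(sum(probs) - 1) < 1e-12)
  names(probs) <- c("NONRES", "RES_NED", "RES_LOC", "RES_MET", "DEAD")
  structure(
    list(strategy = strategy, state_probs = probs, upfront_cost = upfront,
         operated = 1),
    class = "initial_allocation"
  )
}
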