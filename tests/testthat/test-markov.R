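test_that("transition matrix entries follow the death-first composition", {
  p <- default_params()
  P <- build_transition_matrix(p, cycle = 2)
  expect_equal(rownames(P), MSTAGE_STATES)
  expect_equal(unname(P["NONRES", ]), c(1 - 0.5074, 0, 0, 0, 0.5074))
  # metastasis probability applied to survivors of non-metastatic death
  expect_equal(P[["RES_NED", "RES_MET"]], (1 - 0.029) * 0.38)
  expect_equal(P[["RES_MET", "DEAD"]], 0.5074)
  expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 0, 1))
})

test_that("deferred metastatic mortality empties the M1 death column in cycle 1 only", {
  p <- default_params()  # m1_mortality_onset = "deferred"
  P1 <- build_transition_matrix(p, cycle = 1)
  expect_equal(P1[["NONRES", "DEAD"]], 0)
  expect_equal(P1[["RES_MET", "DEAD"]], 0)
  expect_equal(P1[["RES_NED", "DEAD"]], 0.029)  # M0 mortality unaffected
  p_imm <- default_params(structure = structure_flags(m1_mortality_onset = "immediate"))
  P1i <- build_transition_matrix(p_imm, cycle = 1)
  expect_equal(P1i[["NONRES", "DEAD"]], 0.5074)
})

test_that("every generated matrix is row-stochastic with absorbing death", {
  base <- default_params()
  for (s in 1:40) {
    p <- perturb_params(base, 0.4, seed = s)
    for (k in 1:3) {
      P <- build_transition_matrix(p, cycle = k)
      expect_true(all(P >= 0 & P <= 1))
      expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
      expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 0, 1))
    }
  }
})

test_that("discount factors follow the closed form", {
  expect_equal(discount_factor(0.03, 0), 1)
  expect_equal(discount_factor(0.03, 1), 1 / 1.03)
  expect_equal(discount_factor(0, 0:10), rep(1, 11))
})

test_that("a cohort that starts dead accrues only the upfront cost", {
  p <- default_params()
  p$p_surgery_death <- 1
  a <- allocate("CE-CT", p)
  expect_equal(a$state_probs[["DEAD"]], 1)
  r <- run_cohort(a, p)
  expect_equal(r$total_qaly, 0)
  expect_equal(r$total_cost, a$upfront_cost)
})

test_that("a static metastatic cohort accrues horizon times the M1 utility", {
  p <- frozen_params()
  a <- manual_allocation(c(0, 0, 0, 1, 0))
  r <- run_cohort(a, p)
  expect_equal(r$total_qaly, 5 * 0.6)
})

test_that("a static disease-free cohort accrues the first-year/later utility split", {
  p <- default_params()
  p$p_death_m0 <- 0
  p$p_met_after_resection <- 0
  p$p_r1 <- 0
  p$discount_rate <- 0
  r <- run_cohort(manual_allocation(c(0, 1, 0, 0, 0)), p)
  expect_equal(r$total_qaly, 0.726 + 4 * 0.797)
  expect_equal(r$total_cost, 36126 + 4 * 1126)
})

test_that("traces conserve occupancy and death occupancy is non-decreasing", {
  base <- default_params()
  for (s in 1:25) {
    p <- perturb_params(base, 0.3, seed = s)
    for (strat in strategies()) {
      r <- run_strategy(strat, p)
      occ <- as.matrix(r$trace[, MSTAGE_STATES])
      expect_equal(unname(rowSums(occ)), rep(1, p$horizon + 1), tolerance = 1e-9)
      expect_true(all(diff(r$trace$DEAD) >= -1e-12))
      expect_equal(r$total_cost, sum(r$trace$disc_cost))
      expect_equal(r$total_qaly, sum(r$trace$disc_qaly))
      expect_gte(r$total_cost, r$upfront_cost)
      expect_gte(r$total_qaly, 0)
    }
  }
})

test_that("higher mortality weakly lowers effectiveness", {
  base <- default_params()
  for (field in c("p_death_m1", "p_death_m0", "p_surgery_death")) {
    for (s in 1:5) {
      p <- perturb_params(base, 0.2, seed = s)
      grid <- seq(0.05, 0.95, length.out = 5)
      q <- vapply(grid, function(v) {
        run_strategy("CE-CT", .set_param(p, field, v), trace = FALSE)$total_qaly
      }, numeric(1))
      expect_true(all(diff(q) <= 1e-12),
                  label = paste("QALY non-increasing in", field))
    }
  }
})

test_that("discounting monotonically shrinks both totals", {
  p <- default_params()
  rates <- c(0, 0.015, 0.03, 0.06, 0.10)
  res <- lapply(rates, function(r) {
    p$discount_rate <- r
    run_strategy("CE-MR/CT", p, trace = FALSE)
  })
  costs <- vapply(res, `[[`, numeric(1), "total_cost")
  qalys <- vapply(res, `[[`, numeric(1), "total_qaly")
  expect_true(all(diff(costs) < 0))
  expect_true(all(diff(qalys) < 0))
})

test_that("accrual conventions order totals as start >= half >= end", {
  # with all rewards positive and occupancy of alive states declining,
  # cycle-start accrual dominates the half-cycle correction, which
  # dominates cycle-end accrual
  for (strat in strategies()) {
    tot <- vapply(c("start", "half", "end"), function(acc) {
      p <- default_params(structure = structure_flags(accrual = acc))
      run_strategy(strat, p, trace = FALSE)$total_qaly
    }, numeric(1))
    expect_true(all(diff(tot) < 0))
  }
})
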