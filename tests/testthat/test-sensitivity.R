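test_that("a degenerate one-way range yields a zero-width bar", {
  p <- default_params()
  ent <- one_way(p, "cost_mri", p$cost_mri, p$cost_mri)
  expect_equal(ent$dnmb_low, ent$dnmb_high)
  expect_equal(nrow(ent$grid), 1L)
})

test_that("varying the MRI cost shifts incremental cost one-for-one, QALYs untouched", {
  p <- default_params()
  ent <- one_way(p, "cost_mri", 0, 2 * p$cost_mri, steps = 5)
  expect_equal(diff(ent$grid$delta_cost), diff(ent$grid$value))
  expect_equal(ent$grid$delta_qaly, rep(ent$grid$delta_qaly[1], 5))
})

test_that("one-way ranges that do not bracket the base value are rejected", {
  p <- default_params()
  expect_error(one_way(p, "cost_mri", 1000, 2000), "bracket")
  expect_error(one_way(p, "no_such_param", 0, 1), "unknown parameter")
})

test_that("tornado endpoints bracket the base outcome for monotone inputs", {
  p <- default_params()
  tor <- tornado(p)
  base_dnmb <- attr(tor, "dnmb_base")
  monotone <- c("cost_mri", "cost_m1_therapy", "cost_m1_after_surgery",
                "u_m1_no_surgery", "u_m1_post_surgery", "p_ct_fp",
                "p_mri_detect", "cost_surgery")
  df <- as.data.frame(tor)
  for (f in monotone) {
    row <- df[df$parameter == f, ]
    expect_gte(base_dnmb, min(row$dnmb_low, row$dnmb_high) - 1e-9)
    expect_lte(base_dnmb, max(row$dnmb_low, row$dnmb_high) + 1e-9)
  }
  # ranges are clipped to valid supports
  expect_true(all(df$low >= 0))
  expect_lte(df$high[df$parameter == "p_mri_detect"], 1)
})

test_that("CT accuracy is varied through the error rate with the complement maintained", {
  p <- default_params()
  ent <- one_way(p, "p_ct_fp", 0.06, 0.09, steps = 3)
  expect_equal(nrow(ent$grid), 3L)
  # at a perfect classifier the MRI is pure cost: CE-CT preferred
  perfect <- one_way(p, "p_ct_fp", 0, p$p_ct_fp, steps = 2)
  expect_lt(perfect$grid$dnmb[1], 0)
})

test_that("bisection matches a dense-grid scan of the NMB crossover", {
  p <- default_params()
  th <- threshold_resectability(p, lo = 0.9, hi = 1, tol = 1e-6)
  expect_false(th$no_crossover)
  # brute-force oracle: finest sign change on a 1e-4 grid
  grid <- seq(0.98, 1, by = 1e-4)
  dn <- vapply(grid, function(pr) {
    p2 <- p
    p2$p_ct_tp <- pr
    p2$p_ct_fp <- 1 - pr
    mr <- run_strategy("CE-MR/CT", p2, trace = FALSE)
    ct <- run_strategy("CE-CT", p2, trace = FALSE)
    compute_nmb(mr, p$wtp) - compute_nmb(ct, p$wtp)
  }, numeric(1))
  i <- which(dn[-1] * dn[-length(dn)] <= 0)[1]
  expect_true(grid[i] <= th$crossover + 1e-6 &&
                th$crossover <= grid[i + 1] + 1e-6)
  # preference flips across the crossover
  expect_gt(dn[1], 0)
  expect_lt(dn[length(dn)], 0)
})

test_that("a bracket with no sign change is reported, not invented", {
  th <- threshold_resectability(default_params(), lo = 0.5, hi = 0.9)
  expect_true(th$no_crossover)
  expect_true(is.na(th$crossover))
})

test_that("degenerate PSA distributions reproduce the base case exactly", {
  p <- default_params()
  spec <- psa_spec(n_iter = 5, seed = 1, prob_se_frac = 0, cost_se_frac = 0)
  psa <- run_psa(p, spec)
  ct <- run_strategy("CE-CT", p, trace = FALSE)
  mr <- run_strategy("CE-MR/CT", p, trace = FALSE)
  expect_equal(psa$draws$cost_cect, rep(ct$total_cost, 5))
  expect_equal(psa$draws$qaly_cemrct, rep(mr$total_qaly, 5))
})

test_that("PSA is bit-reproducible under a fixed seed and leaves the caller's RNG alone", {
  p <- default_params()
  set.seed(123)
  before <- .Random.seed
  a <- run_psa(p, psa_spec(n_iter = 300, seed = 9))
  expect_identical(.Random.seed, before)
  b <- run_psa(p, psa_spec(n_iter = 300, seed = 9))
  expect_identical(a$draws, b$draws)
  expect_identical(a$ceac, b$ceac)
  c <- run_psa(p, psa_spec(n_iter = 300, seed = 10))
  expect_false(identical(a$draws, c$draws))
})

test_that("PSA draw means match the base-case values", {
  p <- default_params()
  psa <- run_psa(p, psa_spec(n_iter = 4000, seed = 2))
  # moment-matched distributions: sample means near base values
  expect_true(all(psa$ceac$p_cemrct >= 0 & psa$ceac$p_cemrct <= 1))
  expect_false(is.unsorted(psa$ceac$wtp))
  # acceptability from the curve agrees with the direct computation
  expect_equal(psa$ceac$p_cemrct[psa$ceac$wtp == 1e5],
               acceptability(psa, 1e5))
})

test_that("custom samplers override the default distributions", {
  p <- default_params()
  spec <- psa_spec(n_iter = 10, seed = 1,
                   samplers = list(cost_mri = function(n) rep(1000, n)))
  psa <- run_psa(p, spec)
  # cost difference shifts by the fixed MRI cost override
  expect_true(all(is.finite(psa$draws$delta_cost)))
  bad <- psa_spec(n_iter = 5, seed = 1,
                  samplers = list(p_death_m1 = function(n) rep(1.5, n)))
  expect_error(run_psa(p, bad), "p_death_m1")
})

test_that("structure search recovers a known flag combination from its own output", {
  p <- default_params()
  flags <- structure_flags(accrual = "end", utility_set = "high",
                           r1_split_timing = "at_entry",
                           first_year_reference = "global",
                           m1_mortality_onset = "immediate",
                           met_followup = FALSE)
  truth <- default_params(structure = flags)
  ct <- run_strategy("CE-CT", truth, trace = FALSE)
  mr <- run_strategy("CE-MR/CT", truth, trace = FALSE)
  targets <- c(cost_cect = ct$total_cost, qaly_cect = ct$total_qaly,
               cost_cemrct = mr$total_cost, qaly_cemrct = mr$total_qaly)
  ss <- structure_search(targets, params = p)
  expect_lt(ss$best_fit, 1e-12)
  # the selected combination reproduces the targets (equivalent flag sets
  # may tie; output equivalence is the meaningful recovery criterion)
  rec <- default_params(structure = ss$best)
  ct2 <- run_strategy("CE-CT", rec, trace = FALSE)
  expect_equal(ct2$total_cost, unname(targets["cost_cect"]), tolerance = 1e-12)
})

test_that("structure search ranks all combinations and keeps poor fits visible", {
  ss <- structure_search(params = default_params(), tol = Inf)
  expect_equal(nrow(ss$report), 96L)
  expect_false(is.unsorted(ss$report$max_rel_err))
  expect_true(all(ss$report$within_tol))
  # the shipped defaults are the selected combination
  expect_equal(unclass(ss$best), unclass(structure_flags()))
  expect_warning(structure_search(c(cost_cect = 1, qaly_cect = 1,
                                    cost_cemrct = 1, qaly_cemrct = 1),
                                  tol = 0.01),
                 "above tol")
})
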