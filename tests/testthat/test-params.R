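test_that("bundled base-case file loads and matches the in-memory defaults", {
  path <- system.file("extdata", "basecase_params.yaml", package = "mstagecea")
  p <- load_params(path)
  d <- default_params()
  expect_equal(p$p_ct_tp, 0.9225)
  expect_equal(p$p_ct_fp, 0.0775)
  expect_equal(p$cost_surgery, 42869)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$horizon, 5L)
  expect_equal(unclass(p)[order(names(p))], unclass(d)[order(names(d))],
               ignore_attr = TRUE)
})

test_that("both published M0 post-surgery utility pairs are selectable", {
  low <- default_params("low")
  high <- default_params("high")
  expect_equal(c(low$u_m0_post_surgery_y1, low$u_m0_post_surgery_later),
               c(0.726, 0.797))
  expect_equal(c(high$u_m0_post_surgery_y1, high$u_m0_post_surgery_later),
               c(0.79, 0.87))
})

test_that("validation rejects out-of-range and inconsistent inputs, naming the field", {
  p <- default_params()
  p$p_death_m1 <- 1.2
  expect_error(validate_params(p), "p_death_m1")

  p <- default_params()
  p$cost_mri <- -1
  expect_error(validate_params(p), "cost_mri")

  p <- default_params()
  p$p_ct_fp <- 0.10  # no longer complements p_ct_tp
  expect_error(validate_params(p), "p_ct_tp.*p_ct_fp|sum to 1")

  p <- default_params()
  p$u_dead <- 0.1
  expect_error(validate_params(p), "u_dead")

  p <- default_params()
  p$horizon <- 0L
  expect_error(validate_params(p), "horizon")

  p <- default_params()
  p$wtp <- NULL
  expect_error(validate_params(p), "wtp")
})

test_that("loader errors on malformed files and applies default flags when omitted", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  p <- default_params()

  # missing key
  raw <- yaml::read_yaml(system.file("extdata", "basecase_params.yaml",
                                     package = "mstagecea"))
  bad <- raw
  bad$p_death_m1 <- NULL
  yaml::write_yaml(bad, tmp)
  expect_error(load_params(tmp), "p_death_m1")

  # unknown key
  bad <- raw
  bad$typo_field <- 1
  yaml::write_yaml(bad, tmp)
  expect_error(load_params(tmp), "typo_field")

  # out-of-range value caught at load time
  bad <- raw
  bad$p_death_m1 <- 1.2
  yaml::write_yaml(bad, tmp)
  expect_error(load_params(tmp), "p_death_m1")

  # structure omitted entirely -> documented defaults
  nostruct <- raw
  nostruct$structure <- NULL
  yaml::write_yaml(nostruct, tmp)
  loaded <- load_params(tmp)
  expect_equal(unclass(loaded$structure), unclass(structure_flags()))
})

test_that("parameter files round-trip in YAML and JSON and the writer is byte-stable", {
  p <- default_params()
  for (ext in c(".yaml", ".json")) {
    f1 <- withr::local_tempfile(fileext = ext)
    f2 <- withr::local_tempfile(fileext = ext)
    write_params(p, f1)
    p2 <- load_params(f1)
    expect_equal(unclass(p2)[order(names(p2))], unclass(p)[order(names(p))],
                 ignore_attr = TRUE)
    write_params(p2, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})

test_that("perturb_params is seeded, reproducible, and respects invariants", {
  base <- default_params()
  expect_equal(perturb_params(base, 0, seed = 1), base)
  expect_equal(perturb_params(base, 0.2, seed = 7),
               perturb_params(base, 0.2, seed = 7))
  expect_false(identical(perturb_params(base, 0.2, seed = 7),
                         perturb_params(base, 0.2, seed = 8)))
  # does not disturb the caller's RNG stream
  set.seed(99)
  before <- .Random.seed
  invisible(perturb_params(base, 0.2, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("perturbed parameter sets always pass validation", {
  base <- default_params()
  for (s in 1:1000) {
    expect_silent(validate_params(perturb_params(base, 0.2, seed = s)))
  }
})
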