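# Parameters eligible for one-way variation. CT accuracy is varied through
# the false-positive (error) rate, with the true-positive probability kept
# as its complement: +/-25% on a probability of 0.9225 would leave [0, 1].
.oneway_params <- function() {
  c("p_ct_fp", "p_mri_detect", "p_r1", "p_met_after_resection",
    "p_surgery_death", "p_death_m1", "p_death_m0",
    .cost_fields,
    "u_m1_post_surgery", "u_m1_no_surgery",
    "u_m0_post_surgery_y1", "u_m0_post_surgery_later",
    "discount_rate", "wtp")
}

# Set one scalar model input, maintaining the TP/FP complement invariant.
.set_param <- function(params, name, value) {
  if (!name %in% .all_fields) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  params[[name]] <- value
  if (name == "p_ct_fp") params$p_ct_tp <- 1 - value
  if (name == "p_ct_tp") params$p_ct_fp <- 1 - value
  params
}

# Both arms' discounted totals sharing transition/reward construction.
.pair_totals <- function(params) {
  ct <- .arm_totals(params, "CE-CT")
  mr <- .arm_totals(params, "CE-MR/CT")
  c(cost_cect = ct[["cost"]], qaly_cect = ct[["qaly"]],
    cost_cemrct = mr[["cost"]], qaly_cemrct = mr[["qaly"]])
}

# Incremental NMB of CE-MR/CT over CE-CT at a given WTP.
.incr_nmb <- function(params, wtp = params$wtp) {
  v <- .pair_totals(params)
  wtp * (v[["qaly_cemrct"]] - v[["qaly_cect"]]) -
    (v[["cost_cemrct"]] - v[["cost_cect"]])
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Reruns both strategies over a grid of values of one model input, all
#' others held at base values, and records incremental cost, incremental
#' effectiveness, ICER and incremental NMB (CE-MR/CT minus CE-CT) at each
#' grid point. Varying `p_ct_fp` (or `p_ct_tp`) keeps the complement
#' invariant `p_ct_tp + p_ct_fp = 1`.
#'
#' @param params Base `mstage_params`.
#' @param parameter Name of the input to vary.
#' @param low,high Range endpoints; must bracket the base value.
#' @param steps Number of grid points (>= 2 unless `low == high`).
#' @param wtp Willingness-to-pay used for the NMB outcome (base WTP unless
#'   `parameter == "wtp"`, in which case the varied value is used).
#' @return An object of class `tornado_entry`: list with `parameter`,
#'   `base`, `low`, `high`, a `grid` data frame, and the incremental NMB at
#'   the two endpoints (`dnmb_low`, `dnmb_high`).
#' @export
one_way <- function(params, parameter, low, high, steps = 11L,
                    wtp = params$wtp) {
  validate_params(params)
  base <- params[[parameter]]
  if (is.null(base)) stop("unknown parameter '", parameter, "'", call. = FALSE)
  if (!(low <= base && base <= high)) {
    stop("range [", low, ", ", high, "] must bracket the base value ",
         base, " of '", parameter, "'", call. = FALSE)
  }
  values <- if (low == high) low else seq(low, high, length.out = max(2L, steps))
  rows <- lapply(values, function(v) {
    p2 <- .set_param(params, parameter, v)
    validate_params(p2)
    tot <- .pair_totals(p2)
    dc <- tot[["cost_cemrct"]] - tot[["cost_cect"]]
    dq <- tot[["qaly_cemrct"]] - tot[["qaly_cect"]]
    w <- if (parameter == "wtp") v else wtp
    data.frame(value = v, cost_cect = tot[["cost_cect"]],
               qaly_cect = tot[["qaly_cect"]],
               cost_cemrct = tot[["cost_cemrct"]],
               qaly_cemrct = tot[["qaly_cemrct"]],
               delta_cost = dc, delta_qaly = dq,
               icer = if (dq == 0) NA_real_ else dc / dq,
               dnmb = w * dq - dc)
  })
  grid <- do.call(rbind, rows)
  structure(
    list(parameter = parameter, base = base, low = values[1L],
         high = values[length(values)], grid = grid,
         dnmb_low = grid$dnmb[1L], dnmb_high = grid$dnmb[nrow(grid)]),
    class = "tornado_entry"
  )
}

#' Tornado analysis over all model inputs
#'
#' Runs [one_way()] for every eligible input at a symmetric relative range
#' around its base value (clipped to the valid support) and ranks the
#' entries by the spread of the incremental-NMB outcome. CT accuracy is
#' varied through the false-positive rate; `start_age` and `horizon` are
#' structural and not varied.
#'
#' @param params Base `mstage_params`.
#' @param rel_range Relative half-width of every range (default 0.25).
#' @param wtp Willingness-to-pay for the NMB outcome.
#' @param parameters Character vector of inputs to vary (default: all
#'   eligible).
#' @return An object of class `mstage_tornado`: data frame with one row per
#'   parameter (`parameter`, `base`, `low`, `high`, `dnmb_low`,
#'   `dnmb_high`, `icer_low`, `icer_high`, `width`), sorted by decreasing
#'   `width`, with the base-case incremental NMB in attribute `dnmb_base`.
#' @export
tornado <- function(params, rel_range = 0.25, wtp = params$wtp,
                    parameters = .oneway_params()) {
  validate_params(params)
  stopifnot(rel_range >= 0, rel_range < 1)
  clip <- function(v, f) {
    if (f %in% c(.prob_fields, .util_fields)) pmin(1, pmax(0, v)) else pmax(0, v)
  }
  rows <- lapply(parameters, function(f) {
    base <- params[[f]]
    lo <- clip(base * (1 - rel_range), f)
    hi <- clip(base * (1 + rel_range), f)
    ent <- one_way(params, f, lo, hi, steps = 2L, wtp = wtp)
    data.frame(
      parameter = f, base = base, low = lo, high = hi,
      dnmb_low = ent$dnmb_low, dnmb_high = ent$dnmb_high,
      icer_low = ent$grid$icer[1L], icer_high = ent$grid$icer[nrow(ent$grid)],
      width = abs(ent$dnmb_high - ent$dnmb_low)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dnmb_base") <- .incr_nmb(params, wtp)
  attr(out, "wtp") <- wtp
  class(out) <- c("mstage_tornado", "data.frame")
  out
}

#' Threshold analysis on the CT resectability-classification probability
#'
#' Finds, by bisection, the probability of correct resectability
#' classification (`p_ct_tp`, with `p_ct_fp` its complement) at which the
#' net monetary benefit of the two strategies crosses: below the crossover
#' the added MRI is preferred (false-positive resections are averted),
#' above it CT alone is preferred (the MRI is pure cost).
#'
#' @param params Base `mstage_params`.
#' @param lo,hi Bracket for the search (`lo < hi`).
#' @param tol Absolute tolerance on the crossover probability.
#' @param wtp Willingness-to-pay used for the NMB.
#' @param curve_steps Number of grid points of the reported NMB-vs-p curve.
#' @return An object of class `threshold_result`: list with `crossover`
#'   (probability, or `NA` if the NMB difference does not change sign on
#'   the bracket), `no_crossover`, `bracket`, `tol`, `wtp`, and `curve`, a
#'   data frame of `p`, `nmb_cect`, `nmb_cemrct`, `dnmb` over the bracket.
#' @examples
#' \donttest{
#' th <- threshold_resectability(default_params())
#' th$crossover  # about 0.989
#' }
#' @export
threshold_resectability <- function(params, lo = 0.80, hi = 1.0, tol = 1e-5,
                                    wtp = params$wtp, curve_steps = 41L) {
  validate_params(params)
  stopifnot(lo < hi, lo >= 0, hi <= 1, tol > 0)
  g <- function(p) .incr_nmb(.set_param(params, "p_ct_tp", p), wtp)
  ps <- seq(lo, hi, length.out = curve_steps)
  curve <- do.call(rbind, lapply(ps, function(p) {
    p2 <- .set_param(params, "p_ct_tp", p)
    v <- .pair_totals(p2)
    nct <- wtp * v[["qaly_cect"]] - v[["cost_cect"]]
    nmr <- wtp * v[["qaly_cemrct"]] - v[["cost_cemrct"]]
    data.frame(p = p, nmb_cect = nct, nmb_cemrct = nmr, dnmb = nmr - nct)
  }))
  flo <- g(lo); fhi <- g(hi)
  if (sign(flo) == sign(fhi)) {
    out <- list(crossover = NA_real_, no_crossover = TRUE,
                bracket = c(lo, hi), f_bracket = c(flo, fhi),
                tol = tol, wtp = wtp, curve = curve)
    class(out) <- "threshold_result"
    return(out)
  }
  a <- lo; b <- hi; fa <- flo
  while (b - a > tol) {
    m <- (a + b) / 2
    fm <- g(m)
    if (fm == 0) { a <- b <- m; break }
    if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else b <- m
  }
  out <- list(crossover = (a + b) / 2, no_crossover = FALSE,
              bracket = c(lo, hi), f_bracket = c(flo, fhi),
              tol = tol, wtp = wtp, curve = curve)
  class(out) <- "threshold_result"
  out
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$no_crossover) {
    cat(sprintf("No NMB crossover on [%.4f, %.4f] (dNMB %+.0f to %+.0f)\n",
                x$bracket[1], x$bracket[2], x$f_bracket[1], x$f_bracket[2]))
  } else {
    cat(sprintf("NMB crossover at resectability classification p = %.4f (%.2f%%)\n",
                x$crossover, 100 * x$crossover))
    cat("  CE-MR/CT preferred below, CE-CT above\n")
  }
  invisible(x)
}

#' Specification of the probabilistic sensitivity analysis
#'
#' Probabilities and utilities are drawn from Beta distributions and costs
#' from Gamma distributions, each moment-matched to the base-case value as
#' mean with a standard error proportional to the mean (Beta SDs are capped
#' at 95% of the maximal SD compatible with the mean; parameters with base
#' value 0 or, for probabilities, 1 are held fixed). All draws are
#' independent. Individual parameters can be given custom samplers.
#'
#' @param n_iter Number of Monte Carlo iterations (default 30000).
#' @param seed Integer RNG seed.
#' @param prob_se_frac Standard error of probability/utility draws as a
#'   fraction of the mean (default 0.10).
#' @param cost_se_frac Standard error of cost draws as a fraction of the
#'   mean (default 0.20).
#' @param wtp_grid WTP grid of the acceptability curve (default $0 to
#'   $200,000 in $5,000 steps).
#' @param samplers Optional named list of `function(n)` overrides returning
#'   `n` draws for a parameter.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(n_iter = 30000L, seed = 1L, prob_se_frac = 0.10,
                     cost_se_frac = 0.20,
                     wtp_grid = seq(0, 200000, by = 5000),
                     samplers = list()) {
  stopifnot(n_iter >= 1, prob_se_frac >= 0, cost_se_frac >= 0,
            !is.unsorted(wtp_grid), all(wtp_grid >= 0))
  structure(
    list(n_iter = as.integer(n_iter), seed = as.integer(seed),
         prob_se_frac = prob_se_frac, cost_se_frac = cost_se_frac,
         wtp_grid = wtp_grid, samplers = samplers),
    class = "psa_spec"
  )
}

# Moment-matched samplers. Mean equals the base value exactly.
.draw_beta <- function(n, m, se) {
  if (se <= 0 || m <= 0 || m >= 1) return(rep(m, n))
  se <- min(se, 0.95 * sqrt(m * (1 - m)))
  v <- se^2
  k <- m * (1 - m) / v - 1
  rbeta(n, m * k, (1 - m) * k)
}

.draw_gamma <- function(n, m, se) {
  if (se <= 0 || m <= 0) return(rep(m, n))
  shape <- (m / se)^2
  rgamma(n, shape = shape, rate = shape / m)
}

#' Probabilistic sensitivity analysis
#'
#' Draws joint parameter sets per the [psa_spec()] distributions, runs both
#' staging strategies for every draw, and estimates the acceptability of
#' CE-MR/CT (fraction of iterations in which it has the higher NMB) across
#' the WTP grid. The CT false-positive probability is kept the complement
#' of the drawn true-positive probability, and the dead-state utility stays
#' zero. Fully reproducible for a fixed seed; the caller's RNG state is
#' untouched.
#'
#' @param params Base `mstage_params`.
#' @param spec A `psa_spec`.
#' @return An object of class `psa_result`: list with `spec`, `draws` (data
#'   frame: per-iteration cost and QALYs of both strategies plus
#'   `delta_cost` and `delta_qaly`) and `ceac` (data frame: `wtp`,
#'   `p_cemrct`, the acceptability of CE-MR/CT).
#' @export
run_psa <- function(params, spec = psa_spec()) {
  validate_params(params)
  stopifnot(inherits(spec, "psa_spec"))
  n <- spec$n_iter
  drawn <- c(setdiff(.prob_fields, "p_ct_fp"),
             setdiff(.util_fields, "u_dead"), .cost_fields)
  draws <- .with_seed(spec$seed, {
    out <- vector("list", length(drawn))
    names(out) <- drawn
    for (f in drawn) {
      m <- params[[f]]
      out[[f]] <- if (!is.null(spec$samplers[[f]])) {
        spec$samplers[[f]](n)
      } else if (f %in% .cost_fields) {
        .draw_gamma(n, m, spec$cost_se_frac * m)
      } else {
        .draw_beta(n, m, spec$prob_se_frac * m)
      }
    }
    out
  })
  bad <- vapply(draws, function(v) any(v < 0) || length(v) != n, logical(1))
  probish <- c(setdiff(.prob_fields, "p_ct_fp"), setdiff(.util_fields, "u_dead"))
  bad <- bad | vapply(names(draws), function(f) {
    f %in% probish && any(draws[[f]] > 1)
  }, logical(1))
  if (any(bad)) {
    stop("PSA sampler produced values outside the valid support for: ",
         paste(names(draws)[bad], collapse = ", "), call. = FALSE)
  }
  res <- matrix(NA_real_, n, 4L,
                dimnames = list(NULL, c("cost_cect", "qaly_cect",
                                        "cost_cemrct", "qaly_cemrct")))
  p_i <- params
  for (i in seq_len(n)) {
    for (f in drawn) p_i[[f]] <- draws[[f]][i]
    p_i$p_ct_fp <- 1 - p_i$p_ct_tp
    res[i, ] <- .pair_totals(p_i)
  }
  dcost <- res[, "cost_cemrct"] - res[, "cost_cect"]
  dqaly <- res[, "qaly_cemrct"] - res[, "qaly_cect"]
  ceac <- data.frame(
    wtp = spec$wtp_grid,
    p_cemrct = vapply(spec$wtp_grid,
                      function(w) mean(w * dqaly - dcost > 0), numeric(1))
  )
  structure(
    list(spec = spec,
         draws = data.frame(iteration = seq_len(n), res,
                            delta_cost = dcost, delta_qaly = dqaly),
         ceac = ceac),
    class = "psa_result"
  )
}

#' Acceptability of CE-MR/CT at a given WTP
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay per QALY.
#' @return Fraction of PSA iterations in which CE-MR/CT has the higher NMB.
#' @export
acceptability <- function(psa, wtp) {
  stopifnot(inherits(psa, "psa_result"), wtp >= 0)
  mean(wtp * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d)\n", x$spec$n_iter, x$spec$seed))
  for (w in intersect(c(0, 50000, 100000), x$ceac$wtp)) {
    cat(sprintf("  acceptability of CE-MR/CT at WTP $%s: %.3f\n",
                format(w, big.mark = ","), acceptability(x, w)))
  }
  invisible(x)
}

#' Search the structural-assumption space against published base-case results
#'
#' The published model description leaves several structural choices open
#' (reward accrual timing, which M0 post-surgery utility pair applies, how
#' the 80% R1 proportion enters, first-year reward reference, onset of
#' metastatic mortality, follow-up costs of metastatic post-surgery
#' patients). This enumerates every combination, runs the base case under
#' each, and ranks combinations by the maximum relative error against the
#' four published base-case values (cost and QALYs of both strategies).
#' Deterministic; a poor best fit is reported, not hidden.
#'
#' @param targets Named numeric vector with elements `cost_cect`,
#'   `qaly_cect`, `cost_cemrct`, `qaly_cemrct`. Defaults to the published
#'   base-case results.
#' @param params Base `mstage_params`; its numeric inputs are held fixed
#'   while structural flags (and with them the active M0 utility pair) are
#'   enumerated.
#' @param tol Maximum relative error regarded as an acceptable fit; the
#'   best combination is returned regardless, with a warning if it exceeds
#'   `tol`.
#' @return A list with `best` (the selected `mstage_structure`), `best_fit`
#'   (its maximum relative error) and `report` (data frame of all
#'   combinations with their four outputs and errors, ranked best first).
#' @export
structure_search <- function(targets = c(cost_cect = 187601, qaly_cect = 2.337,
                                         cost_cemrct = 185597, qaly_cemrct = 2.347),
                             params = default_params(), tol = Inf) {
  validate_params(params)
  stopifnot(all(c("cost_cect", "qaly_cect", "cost_cemrct", "qaly_cemrct")
                %in% names(targets)))
  combos <- expand.grid(
    accrual = c("start", "end", "half"),
    utility_set = c("low", "high"),
    r1_split_timing = c("annual", "at_entry"),
    first_year_reference = c("global", "state_entry"),
    m1_mortality_onset = c("deferred", "immediate"),
    met_followup = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    fl <- do.call(structure_flags, as.list(combos[i, ]))
    p2 <- params
    p2$structure <- fl
    pair <- .utility_pairs[[fl$utility_set]]
    p2$u_m0_post_surgery_y1 <- unname(pair["y1"])
    p2$u_m0_post_surgery_later <- unname(pair["later"])
    v <- .pair_totals(p2)
    err <- max(abs(v - targets[names(v)]) / abs(targets[names(v)]))
    cbind(combos[i, ], as.data.frame(as.list(v)), max_rel_err = err)
  })
  report <- do.call(rbind, rows)
  report <- report[order(report$max_rel_err), , drop = FALSE]
  rownames(report) <- NULL
  report$within_tol <- report$max_rel_err <= tol
  best_row <- report[1L, , drop = FALSE]
  best <- do.call(structure_flags, as.list(
    best_row[, c("accrual", "utility_set", "r1_split_timing",
                 "first_year_reference", "m1_mortality_onset",
                 "met_followup")]
  ))
  if (is.finite(tol) && best_row$max_rel_err > tol) {
    warning("best structural fit has max relative error ",
            signif(best_row$max_rel_err, 3), ", above tol = ", tol,
            call. = FALSE)
  }
  list(best = best, best_fit = best_row$max_rel_err, report = report)
}
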