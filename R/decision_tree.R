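#' Staging strategies
#'
#' The two compared strategies for initial M-staging: contrast-enhanced CT
#' alone (`"CE-CT"`) and CT plus additional contrast-enhanced liver MRI
#' (`"CE-MR/CT"`).
#'
#' @return Character vector of the two strategy names.
#' @export
strategies <- function() c("CE-CT", "CE-MR/CT")

.match_strategy <- function(strategy) {
  if (!is.character(strategy) || length(strategy) != 1L ||
      !strategy %in% strategies()) {
    stop("unknown strategy '", paste(strategy, collapse = ","),
         "'; expected one of: ", paste(strategies(), collapse = ", "),
         call. = FALSE)
  }
  strategy
}

#' Map a staging strategy to its initial cohort allocation
#'
#' Implements the diagnostic decision tree. The modeled cohort is patients
#' classified as resectable on CE-CT; the CT false-positive fraction carries
#' occult metastases. Under CE-CT alone every patient is operated: true
#' positives enter the resected disease-free pathway (split into the
#' R1/local-recurrence state at entry when `r1_split_timing = "at_entry"`),
#' false positives enter the resected-metastatic state, and a fraction
#' `p_surgery_death` of all operated patients dies perioperatively. Under
#' CE-MR/CT the added MRI reclassifies a fraction `p_ct_fp * p_mri_detect`
#' to non-resectable (no surgery, palliative therapy); the remainder
#' proceeds as under CE-CT. Upfront cost is imaging plus surgery for the
#' operated fraction; perioperative deaths accrue the upfront cost but no
#' utility.
#'
#' @param strategy `"CE-CT"` or `"CE-MR/CT"`.
#' @param params An `mstage_params` object.
#' @return An object of class `initial_allocation`: list with `strategy`,
#'   `state_probs` (named length-5 probability vector over
#'   `r paste(MSTAGE_STATES, collapse = ", ")`), `upfront_cost` (expected
#'   one-time cost per cohort member) and `operated` (operated fraction).
#' @examples
#' allocate("CE-CT", default_params())$upfront_cost     # 692 + 42869
#' allocate("CE-MR/CT", default_params())$state_probs[["NONRES"]]  # 0.0775
#' @export
allocate <- function(strategy, params) {
  strategy <- .match_strategy(strategy)
  validate_params(params)
  uses_mri <- strategy == "CE-MR/CT"

  reclass <- if (uses_mri) params$p_ct_fp * params$p_mri_detect else 0
  operated <- 1 - reclass
  m0 <- params$p_ct_tp                       # truly resectable, operated
  m1 <- operated - m0                        # occult metastases, operated
  dead <- operated * params$p_surgery_death
  surv <- 1 - params$p_surgery_death
  if (params$structure$r1_split_timing == "at_entry") {
    ned <- m0 * surv * (1 - params$p_r1)
    loc <- m0 * surv * params$p_r1
  } else {
    ned <- m0 * surv
    loc <- 0
  }
  probs <- c(
    NONRES = reclass,
    RES_NED = ned,
    RES_LOC = loc,
    RES_MET = m1 * surv,
    DEAD = dead
  )
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  upfront <- params$cost_ct + (if (uses_mri) params$cost_mri else 0) +
    params$cost_surgery * operated
  structure(
    list(strategy = strategy, state_probs = probs,
         upfront_cost = upfront, operated = operated),
    class = "initial_allocation"
  )
}

#' @export
print.initial_allocation <- function(x, ...) {
  cat(sprintf("Initial allocation, %s (operated fraction %.4f, upfront $%s)\n",
              x$strategy, x$operated,
              format(round(x$upfront_cost, 2), big.mark = ",")))
  print(round(x$state_probs, 6))
  invisible(x)
}

# 5-state allocation -> 7-state internal occupancy row (entrants are in the
# first-year phase of their state).
.expand7 <- function(state_probs) {
  c(state_probs[["NONRES"]], state_probs[["RES_NED"]],
    state_probs[["RES_LOC"]], 0, state_probs[["RES_MET"]], 0,
    state_probs[["DEAD"]])
}

# 7-state occupancy -> public 5-state vector.
.collapse5 <- function(s7) {
  c(NONRES = s7[1L], RES_NED = s7[2L], RES_LOC = s7[3L] + s7[4L],
    RES_MET = s7[5L] + s7[6L], DEAD = s7[7L])
}
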