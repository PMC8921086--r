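# Field groups used by validation, perturbation and the PSA.
.prob_fields <- c(
  "p_ct_tp", "p_ct_fp", "p_mri_detect", "p_r1", "p_met_after_resection",
  "p_surgery_death", "p_death_m1", "p_death_m0"
)
.util_fields <- c(
  "u_m1_post_surgery", "u_m1_no_surgery",
  "u_m0_post_surgery_y1", "u_m0_post_surgery_later", "u_dead"
)
.cost_fields <- c(
  "cost_ct", "cost_mri", "cost_surgery", "cost_m1_therapy",
  "cost_post_surgery_y1", "cost_post_surgery_later",
  "cost_m1_after_surgery", "cost_local_recurrence"
)
.scalar_fields <- c("start_age", "horizon", "discount_rate", "wtp")
.all_fields <- c(.scalar_fields, .prob_fields, .cost_fields, .util_fields)

# Published M0 post-surgery utility pairs (first year / following years).
# Two pairs circulate in the source literature; both are selectable.
.utility_pairs <- list(
  low  = c(y1 = 0.726, later = 0.797),
  high = c(y1 = 0.79,  later = 0.87)
)

#' Structural configuration flags
#'
#' The published model description leaves several structural choices open;
#' each is captured as an explicit flag rather than a silent assumption.
#' The defaults are the combination selected by [structure_search()] against
#' the published base-case results.
#'
#' @param accrual When state rewards are accrued within an annual cycle:
#'   `"start"` (cycle-start occupancy, discounted at the start of the cycle),
#'   `"end"` (post-transition occupancy, discounted at the end of the cycle),
#'   or `"half"` (half-cycle correction: the average of the two, discounted
#'   at mid-cycle).
#' @param utility_set Which published utility pair applies to resected,
#'   metastasis-free patients: `"low"` (0.726 first year, 0.797 after) or
#'   `"high"` (0.79 / 0.87).
#' @param r1_split_timing How the 80% R1-resection proportion is applied:
#'   `"annual"` (an 80%/year hazard of moving from the disease-free resected
#'   state into the R1/local-recurrence state) or `"at_entry"` (80% of
#'   resected survivors start in the R1/local-recurrence state at cycle 0).
#' @param r1_mortality Annual death probability of the R1/local-recurrence
#'   state: `"m0"` (use `p_death_m0`) or an explicit probability.
#' @param first_year_reference Whether "first year" cost/utility variants key
#'   on `"global"` model cycle 1 (surgery happens at model entry) or on
#'   `"state_entry"` (time since entering the state).
#' @param m1_mortality_onset `"deferred"` (metastatic mortality first applies
#'   in the second model year, reading the published annual figure as the
#'   mortality of prevalent metastatic disease) or `"immediate"`.
#' @param met_followup Logical; whether metastatic post-surgery patients pay
#'   the post-surgery follow-up cost in addition to metastatic therapy after
#'   the first year.
#'
#' @return A named list of class `mstage_structure`.
#' @seealso [structure_search()], [default_params()]
#' @export
structure_flags <- function(accrual = c("start", "end", "half"),
                            utility_set = c("low", "high"),
                            r1_split_timing = c("annual", "at_entry"),
                            r1_mortality = "m0",
                            first_year_reference = c("global", "state_entry"),
                            m1_mortality_onset = c("deferred", "immediate"),
                            met_followup = TRUE) {
  accrual <- match.arg(accrual)
  utility_set <- match.arg(utility_set)
  r1_split_timing <- match.arg(r1_split_timing)
  first_year_reference <- match.arg(first_year_reference)
  m1_mortality_onset <- match.arg(m1_mortality_onset)
  if (is.character(r1_mortality)) {
    if (!identical(r1_mortality, "m0")) {
      stop("structure flag 'r1_mortality' must be \"m0\" or a probability",
           call. = FALSE)
    }
  } else {
    if (!is.numeric(r1_mortality) || length(r1_mortality) != 1L ||
        is.na(r1_mortality) || r1_mortality < 0 || r1_mortality > 1) {
      stop("structure flag 'r1_mortality' must be \"m0\" or a probability",
           call. = FALSE)
    }
  }
  if (!is.logical(met_followup) || length(met_followup) != 1L ||
      is.na(met_followup)) {
    stop("structure flag 'met_followup' must be TRUE or FALSE", call. = FALSE)
  }
  structure(
    list(
      accrual = accrual,
      utility_set = utility_set,
      r1_split_timing = r1_split_timing,
      r1_mortality = r1_mortality,
      first_year_reference = first_year_reference,
      m1_mortality_onset = m1_mortality_onset,
      met_followup = met_followup
    ),
    class = "mstage_structure"
  )
}

#' Base-case model parameters
#'
#' Returns the full base-case input set of the staging model: diagnostic
#' test performance of CT for resectability, one-time imaging and surgery
#' costs, annual therapy/follow-up costs, health-state utilities, and annual
#' transition probabilities, together with the structural flags.
#'
#' @param utility_set Which published M0 post-surgery utility pair to load,
#'   see [structure_flags()].
#' @param structure Optional `mstage_structure` overriding all flags. When
#'   given, its `utility_set` selects the utility pair.
#'
#' @return A named list of class `mstage_params`.
#' @examples
#' p <- default_params()
#' p$cost_surgery   # 42869
#' p$discount_rate  # 0.03
#' @export
default_params <- function(utility_set = c("low", "high"), structure = NULL) {
  if (is.null(structure)) {
    utility_set <- match.arg(utility_set)
    structure <- structure_flags(utility_set = utility_set)
  } else {
    stopifnot(inherits(structure, "mstage_structure"))
    utility_set <- structure$utility_set
  }
  pair <- .utility_pairs[[utility_set]]
  p <- list(
    start_age = 70L,
    horizon = 5L,
    discount_rate = 0.03,
    wtp = 100000,
    p_ct_tp = 0.9225,
    p_ct_fp = 0.0775,
    p_mri_detect = 1.0,
    cost_ct = 692,
    cost_mri = 615,
    cost_surgery = 42869,
    cost_m1_therapy = 60000,
    cost_post_surgery_y1 = 36126,
    cost_post_surgery_later = 1126,
    cost_m1_after_surgery = 60000,
    cost_local_recurrence = 30000,
    u_m1_post_surgery = 0.6,
    u_m1_no_surgery = 0.65,
    u_m0_post_surgery_y1 = unname(pair["y1"]),
    u_m0_post_surgery_later = unname(pair["later"]),
    u_dead = 0,
    p_r1 = 0.8,
    p_met_after_resection = 0.38,
    p_surgery_death = 0.037,
    p_death_m1 = 0.5074,
    p_death_m0 = 0.029,
    structure = structure
  )
  class(p) <- "mstage_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks all model invariants: probabilities and utilities in \[0, 1\],
#' non-negative costs, horizon at least one cycle, complementary CT
#' true-positive/false-positive probabilities, and a dead-state utility of
#' zero. Errors name the offending field.
#'
#' @param params An `mstage_params` object (or plain named list with the
#'   same fields).
#' @return Invisibly `TRUE` if valid; otherwise an error is thrown.
#' @export
validate_params <- function(params) {
  missing <- setdiff(c(.all_fields, "structure"), names(params))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- params[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", field, "' must be a single number", call. = FALSE)
    }
    v
  }
  for (f in c(.prob_fields, .util_fields)) {
    v <- num1(f)
    if (v < 0 || v > 1) {
      stop("parameter '", f, "' must lie in [0, 1], got ", format(v),
           call. = FALSE)
    }
  }
  for (f in .cost_fields) {
    v <- num1(f)
    if (v < 0) stop("parameter '", f, "' must be >= 0", call. = FALSE)
  }
  if (num1("horizon") < 1 || num1("horizon") != round(num1("horizon"))) {
    stop("parameter 'horizon' must be an integer >= 1", call. = FALSE)
  }
  if (num1("wtp") < 0) stop("parameter 'wtp' must be >= 0", call. = FALSE)
  if (num1("discount_rate") < 0) {
    stop("parameter 'discount_rate' must be >= 0", call. = FALSE)
  }
  if (num1("start_age") < 0) {
    stop("parameter 'start_age' must be >= 0", call. = FALSE)
  }
  if (abs(params$p_ct_tp + params$p_ct_fp - 1) > 1e-12) {
    stop("parameters 'p_ct_tp' and 'p_ct_fp' must sum to 1", call. = FALSE)
  }
  if (params$u_dead != 0) {
    stop("parameter 'u_dead' must equal 0", call. = FALSE)
  }
  s <- params$structure
  if (!inherits(s, "mstage_structure")) {
    # re-validate plain lists coming from files
    do.call(structure_flags, s)
  }
  invisible(TRUE)
}

#' Load model parameters from a YAML or JSON file
#'
#' The format is detected from the file extension (`.yaml`/`.yml` or
#' `.json`). A `structure` block is optional; omitted flags take the
#' defaults of [structure_flags()]. The bundled base-case file is at
#' `system.file("extdata", "basecase_params.yaml", package = "mstagecea")`.
#'
#' @param path Path to a parameter file.
#' @return A validated `mstage_params` object.
#' @examples
#' p <- load_params(system.file("extdata", "basecase_params.yaml",
#'                              package = "mstagecea"))
#' p$p_ct_tp  # 0.9225
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unrecognized parameter file extension '.", ext,
         "' (expected .yaml, .yml or .json)", call. = FALSE)
  )
  unknown <- setdiff(names(raw), c(.all_fields, "structure"))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(.all_fields, names(raw))
  if (length(missing)) {
    stop("missing parameter field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sraw <- raw$structure
  if (is.null(sraw)) sraw <- list()
  flags <- do.call(structure_flags, sraw)
  p <- raw[.all_fields]
  p$horizon <- as.integer(p$horizon)
  p$start_age <- as.integer(p$start_age)
  p$structure <- flags
  class(p) <- "mstage_params"
  validate_params(p)
  p
}

#' Write model parameters to a YAML or JSON file
#'
#' The writer is canonical: writing, re-loading and writing again produces
#' byte-identical files, so parameter sets can be diffed and versioned.
#'
#' @param params An `mstage_params` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- unclass(params)[c(.all_fields, "structure")]
  out$structure <- unclass(out$structure)
  ext <- tolower(tools::file_ext(path))
  txt <- switch(ext,
    yaml = ,
    yml = yaml::as.yaml(out, precision = 12L),
    json = jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    stop("unrecognized parameter file extension '.", ext, "'", call. = FALSE)
  )
  writeLines(txt, path)
  invisible(path)
}

#' Randomly perturb a parameter set
#'
#' Test-fixture generator: every probability, utility and cost is perturbed
#' independently and uniformly within a relative band around its base value,
#' then clipped back to its valid support; the CT true-/false-positive pair
#' is re-coupled (`p_ct_fp = 1 - p_ct_tp`) and the dead-state utility stays
#' zero. Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param base An `mstage_params` object.
#' @param relative_width Fraction in \[0, 1): half-width of the relative
#'   perturbation band.
#' @param seed Integer seed.
#' @return A validated `mstage_params` object.
#' @export
perturb_params <- function(base, relative_width, seed) {
  validate_params(base)
  stopifnot(relative_width >= 0, relative_width < 1)
  p <- base
  .with_seed(seed, {
    jitter <- function(v, lo, hi) {
      pmin(hi, pmax(lo, v * stats::runif(length(v), 1 - relative_width,
                                         1 + relative_width)))
    }
    for (f in setdiff(.prob_fields, "p_ct_fp")) {
      p[[f]] <- jitter(base[[f]], 0, 1)
    }
    p$p_ct_fp <- 1 - p$p_ct_tp
    for (f in setdiff(.util_fields, "u_dead")) {
      p[[f]] <- jitter(base[[f]], 0, 1)
    }
    for (f in .cost_fields) p[[f]] <- jitter(base[[f]], 0, Inf)
  })
  validate_params(p)
  p
}

#' @export
print.mstage_params <- function(x, ...) {
  cat("M-staging model parameters\n")
  cat(sprintf("  horizon %d annual cycles from age %d, discount %.1f%%, WTP $%s/QALY\n",
              x$horizon, x$start_age, 100 * x$discount_rate,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  CT resectability classification: TP %.4f / FP %.4f; MRI detection %.2f\n",
              x$p_ct_tp, x$p_ct_fp, x$p_mri_detect))
  cat(sprintf("  costs: CT $%s, MRI $%s, surgery $%s\n",
              format(x$cost_ct, big.mark = ","),
              format(x$cost_mri, big.mark = ","),
              format(x$cost_surgery, big.mark = ",")))
  cat(sprintf("  structure: accrual=%s, utilities=%s, R1 split=%s, M1 onset=%s\n",
              x$structure$accrual, x$structure$utility_set,
              x$structure$r1_split_timing, x$structure$m1_mortality_onset))
  invisible(x)
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable md5 of a parameter set, embedded in CLI artifacts.
.params_hash <- function(params) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_params(params, tmp)
  unname(tools::md5sum(tmp))
}
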