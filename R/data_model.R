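#' @keywords internal
"_PACKAGE"

# Column layout of a trial table. A row is one trial x one outcome, two arms
# only (wide per-arm columns keep the 2-arm assumption explicit). Exactly one
# of the dichotomous / continuous field sets is populated per row.
.dich_cols <- c("events_exp", "randomised_exp", "lost_exp",
                "events_ctl", "randomised_ctl", "lost_ctl")
.cont_cols <- c("mean_exp", "sd_exp", "analysed_exp", "lost_exp",
                "mean_ctl", "sd_ctl", "analysed_ctl", "lost_ctl")

#' Risk-of-bias domain names
#'
#' The seven bias domains recorded per trial: sequence generation, allocation
#' concealment, blinding of participants/providers, blinding of outcome
#' assessors, incomplete outcome data, selective outcome reporting, and
#' funding. Each takes one of `"low"`, `"high"`, `"unclear"`.
#'
#' @return Character vector of the seven column names.
#' @export
rob_domains <- function() {
  c("rob_sequence", "rob_allocation", "rob_blinding_participants",
    "rob_blinding_assessors", "rob_incomplete_data",
    "rob_selective_reporting", "rob_funding")
}

.trial_cols <- function() {
  c("trial_id", "year", "outcome_id",
    "events_exp", "randomised_exp", "lost_exp",
    "events_ctl", "randomised_ctl", "lost_ctl",
    "mean_exp", "sd_exp", "analysed_exp",
    "mean_ctl", "sd_ctl", "analysed_ctl",
    rob_domains())
}

#' Construct a table of trial records
#'
#' Builds and validates a trial table (one row per trial per outcome, two arms
#' per trial). Dichotomous rows carry events/randomised/lost per arm
#' (analysed = randomised - lost); continuous rows carry mean/SD/analysed/lost
#' per arm. Risk-of-bias domains default to `"unclear"` when omitted.
#'
#' @param df data.frame with the documented column names; missing optional
#'   columns are filled with `NA` ("unclear" for bias domains).
#' @return A validated `octostep_trials` data.frame.
#' @export
trial_table <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("trial_id", "year", "outcome_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (cc in setdiff(.trial_cols(), names(df)))
    df[[cc]] <- if (cc %in% rob_domains()) "unclear" else NA
  df <- df[, .trial_cols()]
  df$trial_id <- as.character(df$trial_id)
  df$outcome_id <- as.character(df$outcome_id)
  df$year <- as.integer(df$year)
  for (cc in union(.dich_cols, .cont_cols)) df[[cc]] <- as.numeric(df[[cc]])
  for (cc in rob_domains()) df[[cc]] <- as.character(df[[cc]])
  validate_trials(df)
  class(df) <- c("octostep_trials", "data.frame")
  df
}

#' Data type of each trial row
#'
#' @param trials trial table.
#' @return `"dichotomous"` or `"continuous"` per row.
#' @export
trial_data_type <- function(trials) {
  has_d <- !is.na(trials$events_exp)
  ifelse(has_d, "dichotomous", "continuous")
}

#' Validate a trial table
#'
#' Checks the per-row invariants: counts non-negative; events <= analysed <=
#' randomised per arm; lost = randomised - analysed (dichotomous); SDs > 0 and
#' analysed >= 2 flagged downstream (continuous); exactly one field set
#' populated. Failures name the offending row, trial and field.
#'
#' @param trials data.frame in the trial-table layout.
#' @return Invisibly `TRUE`; stops with a validation error otherwise.
#' @export
validate_trials <- function(trials) {
  bad <- character(0)
  note <- function(i, msg)
    bad <<- c(bad, sprintf("row %d (trial '%s'): %s", i, trials$trial_id[i], msg))
  for (i in seq_len(nrow(trials))) {
    r <- trials[i, ]
    d_set <- !is.na(r[.dich_cols[c(1, 2, 4, 5)]])
    c_set <- !is.na(r[c("mean_exp", "sd_exp", "mean_ctl", "sd_ctl")])
    if (all(d_set) && any(c_set)) { note(i, "both dichotomous and continuous fields populated"); next }
    if (all(d_set)) {
      for (arm in c("exp", "ctl")) {
        ev <- r[[paste0("events_", arm)]]; nr <- r[[paste0("randomised_", arm)]]
        lo <- r[[paste0("lost_", arm)]]
        if (is.na(lo)) lo <- 0
        if (any(c(ev, nr, lo) < 0)) note(i, paste0(arm, " arm: negative count"))
        an <- nr - lo
        if (an < 0) note(i, sprintf("%s arm: lost (%d) exceeds randomised (%d)", arm, lo, nr))
        else if (ev > an) note(i, sprintf("%s arm: events (%d) exceed analysed (%d)", arm, ev, an))
      }
    } else if (all(c_set)) {
      for (arm in c("exp", "ctl")) {
        sdv <- r[[paste0("sd_", arm)]]; an <- r[[paste0("analysed_", arm)]]
        lo <- r[[paste0("lost_", arm)]]
        if (is.na(an)) note(i, paste0(arm, " arm: analysed count missing"))
        else if (an < 0 || (!is.na(lo) && lo < 0)) note(i, paste0(arm, " arm: negative count"))
        if (!is.na(sdv) && sdv <= 0) note(i, paste0(arm, " arm: SD must be > 0"))
      }
    } else {
      note(i, "neither the dichotomous nor the continuous field set is fully populated")
    }
    dom <- unlist(r[rob_domains()])
    okd <- dom %in% c("low", "high", "unclear")
    if (!all(okd)) note(i, paste0("invalid risk-of-bias judgement in ",
                                  paste(rob_domains()[!okd], collapse = ", ")))
  }
  if (length(bad)) stop("trial validation failed:\n  ", paste(bad, collapse = "\n  "))
  invisible(TRUE)
}

#' Read trial records from CSV
#'
#' Reads a UTF-8, comma-separated file with a header row in the documented
#' trial-table layout and validates every row. Row order is preserved.
#'
#' @param path path to the CSV file.
#' @return A validated `octostep_trials` data.frame.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("trial_id", "year", "outcome_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing required column(s): ", paste(miss, collapse = ", "))
  trial_table(df)
}

#' Write trial records to CSV
#'
#' Inverse of [read_trials_csv()]: `read_trials_csv(write_trials_csv(x, f))`
#' reproduces `x` field for field.
#'
#' @param trials trial table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Overall risk-of-bias classification
#'
#' A trial is classified overall `"low"` risk of bias only when all seven bias
#' domains are judged low; any high or unclear domain makes it `"high"`
#' (unclear is conservatively treated as not-low).
#'
#' @param trials trial table (or any data.frame carrying the seven
#'   `rob_*` columns).
#' @return Character vector, `"low"` or `"high"` per row.
#' @export
overall_risk_of_bias <- function(trials) {
  dom <- as.data.frame(trials)[, rob_domains(), drop = FALSE]
  if (any(is.na(dom))) stop("validation error: missing risk-of-bias domain judgement")
  all_low <- apply(dom == "low", 1L, all)
  ifelse(all_low, "low", "high")
}

#' Specify an outcome for analysis
#'
#' Captures the per-outcome analysis plan: its role in the outcome hierarchy,
#' data type, direction of benefit, the anticipated intervention effect used
#' for the required information size and the Bayes factor, and the anticipated
#' control-group risk (dichotomous) or standard deviation (continuous).
#'
#' @param outcome_id outcome identifier matching the trial table.
#' @param role `"primary"`, `"secondary"` or `"exploratory"`.
#' @param data_type `"dichotomous"` or `"continuous"`.
#' @param benefit_direction `"lower"` if a lower event risk / lower mean is
#'   beneficial (e.g. mortality), `"higher"` otherwise.
#' @param mu_A anticipated intervention effect on the analysis scale
#'   (log ratio for ratio measures, mean difference otherwise); must be
#'   non-zero.
#' @param p_c anticipated control-group event proportion (dichotomous).
#' @param anticipated_sd anticipated outcome standard deviation (continuous).
#' @param measure effect measure: `"logRR"` (default), `"logOR"` or `"RD"` for
#'   dichotomous outcomes; `"MD"` or `"SMD"` for continuous outcomes.
#' @param heterogeneity_fallback diversity percentage substituted when the
#'   observed D-squared is zero in a random-effects information-size
#'   calculation (default 25).
#' @param realistic logical; is `mu_A` considered a realistic anticipated
#'   effect? Drives the GRADE imprecision cascade (default `TRUE`).
#' @return An `outcome_spec` object.
#' @export
outcome_spec <- function(outcome_id, role = c("primary", "secondary", "exploratory"),
                         data_type = c("dichotomous", "continuous"),
                         benefit_direction = c("lower", "higher"),
                         mu_A, p_c = NULL, anticipated_sd = NULL,
                         measure = NULL, heterogeneity_fallback = 25,
                         realistic = TRUE) {
  role <- match.arg(role)
  data_type <- match.arg(data_type)
  benefit_direction <- match.arg(benefit_direction)
  if (is.null(measure))
    measure <- if (data_type == "dichotomous") "logRR" else "MD"
  ok <- if (data_type == "dichotomous") c("logRR", "logOR", "RD") else c("MD", "SMD")
  measure <- match.arg(measure, ok)
  if (!is.numeric(mu_A) || length(mu_A) != 1L || mu_A == 0)
    stop("mu_A must be a single non-zero number")
  if (data_type == "dichotomous") {
    if (is.null(p_c) || p_c <= 0 || p_c >= 1)
      stop("p_c must be in (0, 1) for a dichotomous outcome")
  } else {
    if (is.null(anticipated_sd) || anticipated_sd <= 0)
      stop("anticipated_sd must be > 0 for a continuous outcome")
  }
  if (heterogeneity_fallback < 0 || heterogeneity_fallback >= 100)
    stop("heterogeneity_fallback must be a percentage in [0, 100)")
  structure(list(outcome_id = as.character(outcome_id), role = role,
                 data_type = data_type, benefit_direction = benefit_direction,
                 mu_A = mu_A, p_c = p_c, anticipated_sd = anticipated_sd,
                 measure = measure,
                 heterogeneity_fallback = heterogeneity_fallback,
                 realistic = isTRUE(realistic)),
            class = "outcome_spec")
}

#' Review-level configuration
#'
#' @param alpha_base base two-sided type-I error before multiplicity
#'   adjustment (default 0.05).
#' @param beta type-II error for the required information size (default 0.10;
#'   10% or 20% are the recommended choices).
#' @param m number of primary outcomes used in the multiplicity adjustment
#'   (default: counted from the outcome specs at run time).
#' @param conservative_selection choose the fixed/random result with the
#'   larger P-value as the main result (default `TRUE`).
#' @param hksj use the Hartung-Knapp-Sidik-Jonkman variance and t-based
#'   inference for the random-effects result (default `TRUE`).
#' @param funnel_min_trials minimum number of trials for funnel-plot based
#'   assessment (default 10).
#' @param bf_threshold Bayes factor significance threshold (default 0.1).
#' @param dominance_threshold weight percentage above which one or two trials
#'   dominate the fixed-effect analysis (default 80).
#' @param scenario_sd_multiplier SD multiplier for continuous attrition
#'   scenarios, 1 or 2 (default 2).
#' @param seed integer seed used wherever the pipeline needs randomness.
#' @return A `review_config` object.
#' @export
review_config <- function(alpha_base = 0.05, beta = 0.10, m = NULL,
                          conservative_selection = TRUE, hksj = TRUE,
                          funnel_min_trials = 10, bf_threshold = 0.1,
                          dominance_threshold = 80, scenario_sd_multiplier = 2,
                          seed = 1L) {
  if (alpha_base <= 0 || alpha_base >= 1) stop("alpha_base must be in (0, 1)")
  if (beta <= 0 || beta >= 1) stop("beta must be in (0, 1)")
  if (!is.null(m) && m < 1) stop("m must be >= 1")
  if (!scenario_sd_multiplier %in% c(1, 2))
    stop("scenario_sd_multiplier must be 1 or 2")
  structure(list(alpha_base = alpha_base, beta = beta, m = m,
                 conservative_selection = isTRUE(conservative_selection),
                 hksj = isTRUE(hksj), funnel_min_trials = funnel_min_trials,
                 bf_threshold = bf_threshold,
                 dominance_threshold = dominance_threshold,
                 scenario_sd_multiplier = scenario_sd_multiplier,
                 seed = as.integer(seed)),
            class = "review_config")
}

#' Read a review configuration file
#'
#' Reads a YAML (or JSON; YAML is a superset) file with a `config` block of
#' [review_config()] fields and an `outcomes` list of [outcome_spec()] fields.
#'
#' @param path path to the configuration file.
#' @return List with elements `config` (a `review_config`) and `outcomes`
#'   (list of `outcome_spec`).
#' @export
read_review_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$outcomes)) stop("config file has no 'outcomes' block")
  cfg <- do.call(review_config, as.list(raw$config %||% list()))
  outs <- lapply(raw$outcomes, function(o) do.call(outcome_spec, as.list(o)))
  names(outs) <- vapply(outs, `[[`, "", "outcome_id")
  list(config = cfg, outcomes = outs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
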