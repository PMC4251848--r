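# Attrition-bias scenario analyses (best-worst / worst-best imputation of
# participants lost to follow-up) and the low-vs-high risk-of-bias subgroup
# comparison. The two extreme scenarios bound the uncertainty due to missing
# outcome data; the subgroup comparison designates the low-risk-of-bias pooled
# result as the basis for the main conclusion.

#' Dichotomous attrition scenario
#'
#' Re-includes participants lost to follow-up with extreme imputed outcomes.
#' Under `best_worst`, everyone lost in the experimental arm is assumed to
#' have had the beneficial outcome and everyone lost in the control arm the
#' harmful one; `worst_best` is the reverse. Beneficial is resolved through
#' the outcome's benefit direction (for a harmful-event outcome such as
#' mortality, beneficial = no event). Denominators become the randomised
#' counts (intention-to-treat accounting) and the pooling is re-run.
#'
#' @param trials trial table rows for one dichotomous outcome.
#' @param scenario `"best_worst"` or `"worst_best"`.
#' @param benefit_direction `"lower"` if a lower event risk is beneficial.
#' @param measure effect measure for re-pooling.
#' @param level confidence level for re-pooling.
#' @param hksj,dominance_threshold passed to [pool_pair()].
#' @param primary optional primary `pooled_result` for the delta.
#' @return A `scenario_result`: adjusted trial table, fitted `model_pair`,
#'   `delta_vs_primary`.
#' @export
scenario_dichotomous <- function(trials, scenario = c("best_worst", "worst_best"),
                                 benefit_direction = c("lower", "higher"),
                                 measure = "logRR", level = 0.95, hksj = TRUE,
                                 dominance_threshold = 80, primary = NULL) {
  scenario <- match.arg(scenario)
  benefit_direction <- match.arg(benefit_direction)
  adj <- as.data.frame(trials)
  if (any(is.na(adj$lost_exp)) || any(is.na(adj$lost_ctl)))
    stop("lost counts missing for trial(s): ",
         paste(adj$trial_id[is.na(adj$lost_exp) | is.na(adj$lost_ctl)],
               collapse = ", "))
  event_is_beneficial <- benefit_direction == "higher"
  exp_beneficial <- scenario == "best_worst"
  # an arm gains its lost participants as events iff the outcome imputed for
  # that arm (beneficial/harmful) coincides with the event

  adj$events_exp <- adj$events_exp +
    ifelse(exp_beneficial == event_is_beneficial, adj$lost_exp, 0L)
  adj$events_ctl <- adj$events_ctl +
    ifelse(exp_beneficial == event_is_beneficial, 0L, adj$lost_ctl)
  adj$lost_exp <- 0L; adj$lost_ctl <- 0L     # denominators = randomised
  adj <- trial_table(adj)
  eff <- trial_effects(adj, measure)
  pooled <- pool_pair(eff, level, hksj, dominance_threshold)
  structure(list(scenario = scenario, adjusted_trials = adj, pooled = pooled,
                 delta_vs_primary = if (!is.null(primary))
                   primary_result(pooled)$theta - primary$theta else NA_real_),
            class = "scenario_result")
}

#' Continuous attrition scenario
#'
#' Imputes each lost participant at the observed group mean plus (beneficial)
#' or minus (harmful) `j` standard deviations, with the direction resolved by
#' the benefit direction of the outcome, then recomputes the combined mean and
#' SD exactly from sums and sums of squares and re-runs the pooling.
#'
#' @inheritParams scenario_dichotomous
#' @param j SD multiplier, 1 or 2 (default 2).
#' @param benefit_direction `"higher"` if a higher mean is beneficial.
#' @return A `scenario_result`.
#' @export
scenario_continuous <- function(trials, scenario = c("best_worst", "worst_best"),
                                benefit_direction = c("lower", "higher"),
                                j = 2, measure = "MD", level = 0.95,
                                hksj = TRUE, dominance_threshold = 80,
                                primary = NULL) {
  scenario <- match.arg(scenario)
  benefit_direction <- match.arg(benefit_direction)
  if (!j %in% c(1, 2)) stop("j must be 1 or 2")
  adj <- as.data.frame(trials)
  if (any(is.na(adj$lost_exp)) || any(is.na(adj$lost_ctl)))
    stop("lost counts missing for trial(s): ",
         paste(adj$trial_id[is.na(adj$lost_exp) | is.na(adj$lost_ctl)],
               collapse = ", "))
  s_benef <- if (benefit_direction == "higher") 1 else -1
  exp_beneficial <- scenario == "best_worst"
  impute_arm <- function(m, s, n, lost, beneficial) {
    if (lost == 0) return(c(m, s, n))
    v <- m + (if (beneficial) s_benef else -s_benef) * j * s
    n2 <- n + lost
    ss <- (n - 1) * s^2 + n * m^2 + lost * v^2   # exact sums of squares
    m2 <- (n * m + lost * v) / n2
    s2 <- sqrt((ss - n2 * m2^2) / (n2 - 1))
    c(m2, s2, n2)
  }
  for (i in seq_len(nrow(adj))) {
    e <- impute_arm(adj$mean_exp[i], adj$sd_exp[i], adj$analysed_exp[i],
                    adj$lost_exp[i], exp_beneficial)
    c_ <- impute_arm(adj$mean_ctl[i], adj$sd_ctl[i], adj$analysed_ctl[i],
                     adj$lost_ctl[i], !exp_beneficial)
    adj$mean_exp[i] <- e[1]; adj$sd_exp[i] <- e[2]; adj$analysed_exp[i] <- e[3]
    adj$mean_ctl[i] <- c_[1]; adj$sd_ctl[i] <- c_[2]; adj$analysed_ctl[i] <- c_[3]
  }
  adj$lost_exp <- 0L; adj$lost_ctl <- 0L
  adj <- trial_table(adj)
  eff <- trial_effects(adj, measure)
  pooled <- pool_pair(eff, level, hksj, dominance_threshold)
  structure(list(scenario = scenario, adjusted_trials = adj, pooled = pooled,
                 delta_vs_primary = if (!is.null(primary))
                   primary_result(pooled)$theta - primary$theta else NA_real_),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Attrition scenario '%s': pooled (%s) theta = %.4f",
              x$scenario, x$pooled$primary_model,
              primary_result(x$pooled)$theta))
  if (!is.na(x$delta_vs_primary))
    cat(sprintf(" (delta vs primary analysis %+.4f)", x$delta_vs_primary))
  cat("\n")
  invisible(x)
}

#' Low- vs high-risk-of-bias subgroup comparison
#'
#' Pools each risk-of-bias subgroup under the stated model and tests for a
#' between-subgroup difference with
#' \eqn{Q_{between} = \sum_g w_g(\hat\theta_g - \hat\theta)^2},
#' \eqn{w_g = 1/v_g}, referred to chi-squared with G-1 degrees of freedom.
#' The low-risk-only pooled result is returned as the designated basis of the
#' main conclusion. With a single non-empty subgroup the output is
#' descriptive only (test skipped with a notice).
#'
#' @param effects data.frame from [trial_effects()] (carries the `rob`
#'   column), or any effects data.frame plus a `rob` vector.
#' @param rob optional overall risk-of-bias vector (`"low"`/`"high"`) if not a
#'   column of `effects`.
#' @param model `"fixed"` or `"random"` (the model of the primary analysis).
#' @param level confidence level.
#' @param hksj use HKSJ for random-effects subgroup fits.
#' @return List with `subgroups` (named list of `pooled_result`),
#'   `low_risk_pooled`, `Q_between`, `df`, `p`, `tested`.
#' @export
rob_subgroup_comparison <- function(effects, rob = NULL,
                                    model = c("random", "fixed"),
                                    level = 0.95, hksj = TRUE) {
  model <- match.arg(model)
  e <- as_effects(effects)
  rob <- rob %||% effects$rob
  if (is.null(rob)) stop("risk-of-bias classification not available")
  stopifnot(length(rob) == nrow(e))
  fit1 <- function(sub) {
    if (model == "fixed") fixed_effect_pool(sub, level)
    else if (nrow(sub) >= 2 && hksj) hksj_adjust(sub, level = level)
    else dersimonian_laird_pool(sub, level)
  }
  groups <- split(seq_len(nrow(e)), factor(rob, levels = c("low", "high")))
  groups <- groups[vapply(groups, length, 1L) > 0]
  fits <- lapply(groups, function(ix) fit1(e[ix, , drop = FALSE]))
  G <- length(fits)
  out <- list(subgroups = fits,
              low_risk_pooled = fits[["low"]],
              Q_between = NA_real_, df = NA_integer_, p = NA_real_,
              tested = FALSE)
  if (G >= 2) {
    th <- vapply(fits, `[[`, 0, "theta")
    wg <- 1 / vapply(fits, `[[`, 0, "se")^2
    pooled <- sum(wg * th) / sum(wg)
    out$Q_between <- sum(wg * (th - pooled)^2)
    out$df <- G - 1L
    out$p <- stats::pchisq(out$Q_between, G - 1, lower.tail = FALSE)
    out$tested <- TRUE
  } else {
    message("only one risk-of-bias subgroup present; interaction test skipped")
  }
  out
}
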