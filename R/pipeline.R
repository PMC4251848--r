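# Orchestration: run the eight assessment steps per outcome, combine the
# significance gates, apply the GRADE imprecision cascade, and emit the
# structured verdict report.

#' GRADE imprecision cascade
#'
#' Translates trial-sequential-analysis boundary status into the number of
#' quality levels to downgrade for imprecision. With a realistic anticipated
#' effect: any boundary (benefit, harm or futility) crossed means no
#' downgrade, none crossed means two levels. With an unrealistic anticipated
#' effect the analysis is repeated with the CI limit closest to no effect
#' (crossed: no downgrade), then with the meta-analysis point estimate
#' (crossed: one level; not crossed: two levels).
#'
#' @param tsa_main main `tsa_result` (or logical: any boundary crossed).
#' @param tsa_ci_limit sensitivity rerun with the CI-limit anticipated effect
#'   (required when `realistic = FALSE`).
#' @param tsa_point_estimate sensitivity rerun with the point-estimate
#'   anticipated effect (required when `realistic = FALSE`).
#' @param realistic is the pre-specified anticipated effect realistic?
#' @return Integer downgrade: 0, 1 or 2.
#' @export
grade_imprecision <- function(tsa_main, tsa_ci_limit = NULL,
                              tsa_point_estimate = NULL, realistic = TRUE) {
  crossed <- function(x) {
    if (inherits(x, "tsa_result")) x$crossing != "none"
    else if (is.character(x)) x != "none"
    else isTRUE(x)
  }
  if (realistic) return(if (crossed(tsa_main)) 0L else 2L)
  if (is.null(tsa_ci_limit) || is.null(tsa_point_estimate))
    stop("unrealistic anticipated effect requires both sensitivity trial sequential analyses")
  if (crossed(tsa_ci_limit)) return(0L)
  if (crossed(tsa_point_estimate)) 1L else 2L
}

#' Number needed to treat
#'
#' Reciprocal of the absolute risk difference, with its direction. Equal
#' risks are not estimable.
#'
#' @param risk_exp,risk_ctl event proportions in the two arms.
#' @param benefit_direction `"lower"` if a lower event risk is beneficial.
#' @return List with `value` (positive real or `NA`), `direction`
#'   (`"benefit"`, `"harm"` or `"not-estimable"`).
#' @export
nnt <- function(risk_exp, risk_ctl, benefit_direction = "lower") {
  stopifnot(risk_exp >= 0, risk_exp <= 1, risk_ctl >= 0, risk_ctl <= 1)
  if (risk_exp == risk_ctl)
    return(list(value = NA_real_, direction = "not-estimable"))
  benefit <- (risk_exp < risk_ctl) == (benefit_direction == "lower")
  list(value = 1 / abs(risk_ctl - risk_exp),
       direction = if (benefit) "benefit" else "harm")
}

# CI limit closest to no effect; NULL when it crosses the null or is zero
.ci_limit_nearest_null <- function(ci, point) {
  lim <- ci[which.min(abs(ci))]
  if (lim == 0 || sign(lim) != sign(point)) NULL else lim
}

.clinical_checklist <- function(spec, nnt_block) {
  items <- c(
    "Judge whether the size of the pooled effect is clinically relevant, not only statistically significant.",
    "Weigh beneficial effects against harms; even rare serious adverse effects may rule out use.",
    "Do not extrapolate beyond the populations included in the trials.",
    if (spec$data_type == "dichotomous" && !is.null(nnt_block) &&
        !is.na(nnt_block$value))
      sprintf("Number needed to treat: %.1f (%s) - relate to the minimal clinically relevant difference.",
              nnt_block$value, nnt_block$direction)
    else
      "Relate the effect and its adjusted confidence interval to the minimal clinically relevant difference.",
    "If the outcome is a surrogate, question its clinical implications (indirectness).",
    "If the effect is smaller than that of an existing intervention, clinical significance is doubtful.")
  items
}

.analyse_outcome <- function(sub, spec, config, threshold) {
  notes <- character(0)
  is_primary <- spec$role == "primary"
  alpha_out <- if (is_primary) threshold$alpha_adjusted else threshold$alpha_base
  level <- 1 - alpha_out
  if (!is_primary) notes <- c(notes, "secondary/exploratory outcome: unadjusted threshold, hypothesis-generating")

  ## Step 1: both models, conservative selection at the adjusted level
  effects <- trial_effects(sub, spec$measure)
  pair <- pool_pair(effects, level, config$hksj, config$dominance_threshold)
  if (!config$conservative_selection)
    pair$primary_model <- "random"
  conserv <- primary_result(pair)
  if (pair$dominance_flag)
    notes <- c(notes, sprintf("one/two trials carry >= %g%% of the fixed-effect weight: fixed-effect result may be preferable", config$dominance_threshold))

  ## Step 2: heterogeneity reporting flag
  het <- pair$het
  substantial_het <- !is.na(het$I2) && het$I2 > 0.5
  if (substantial_het)
    notes <- c(notes, "substantial statistical heterogeneity: consider subgroup/sensitivity analyses and whether all trials belong in the main analysis")

  ## Step 4: information size and trial sequential analysis
  model <- pair$primary_model
  D2_obs <- if (model == "random") pair$D2 else 0
  ris <- required_information_size(spec, alpha_out, config$beta, D2 = D2_obs,
                                   apply_fallback = model == "random")
  ts_main <- tsa(effects, ris, model = model)
  run_sens <- function(mu) {
    if (is.null(mu) || mu == 0) return(NULL)
    tryCatch(tsa(effects,
                 required_information_size(spec, alpha_out, config$beta,
                                           D2 = D2_obs,
                                           apply_fallback = model == "random",
                                           mu_A = mu),
                 model = model),
             error = function(e) NULL)
  }
  ts_point <- run_sens(conserv$theta)
  ts_cil <- run_sens(.ci_limit_nearest_null(conserv$ci, conserv$theta))
  ris_reached <- ts_main$looks$t[nrow(ts_main$looks)] >= 1

  ## Step 5: Bayes factor, primary outcomes only
  bf_main <- bf_scept <- NULL
  if (is_primary) {
    bf_main <- bayes_factor(conserv$theta, conserv$se, spec$mu_A,
                            config$bf_threshold)
    mu_scept <- if (spec$measure %in% c("logRR", "logOR"))
      sceptical_effect(exp(spec$mu_A)) else spec$mu_A / 2
    bf_scept <- bayes_factor(conserv$theta, conserv$se, mu_scept,
                             config$bf_threshold)
    if (bf_main$significant && !ris_reached)
      notes <- c(notes, "required information size not reached: interpret even a Bayes factor < threshold with caution")
  }

  ## Step 6: attrition scenarios and risk-of-bias subgroups
  scen <- function(s) {
    tryCatch(
      if (spec$data_type == "dichotomous")
        scenario_dichotomous(sub, s, spec$benefit_direction, spec$measure,
                             level, config$hksj, config$dominance_threshold,
                             primary = conserv)
      else
        scenario_continuous(sub, s, spec$benefit_direction,
                            config$scenario_sd_multiplier, spec$measure,
                            level, config$hksj, config$dominance_threshold,
                            primary = conserv),
      error = function(e) { notes <<- c(notes, paste0("scenario ", s, " skipped: ", conditionMessage(e))); NULL })
  }
  best_worst <- scen("best_worst")
  worst_best <- scen("worst_best")
  robcmp <- suppressMessages(
    rob_subgroup_comparison(effects, model = model, level = level,
                            hksj = config$hksj))
  if (is.null(robcmp$low_risk_pooled))
    notes <- c(notes, "no low-risk-of-bias trials: main conclusion cannot rest on low-risk trials")

  ## Step 7: publication bias
  pb <- suppressWarnings(
    publication_bias_block(effects, sub, conserv,
                           config$funnel_min_trials, level))
  if (!pb$assessed)
    notes <- c(notes, sprintf("publication bias not assessed (fewer than %d trials)", config$funnel_min_trials))

  ## Step 8: significance gates, GRADE imprecision, checklist
  gate_p <- conserv$p < alpha_out
  gate_tsa <- ts_main$crossing %in% c("benefit", "harm")
  gate_bf <- if (is_primary) bf_main$significant else TRUE
  significant <- gate_p && gate_tsa && gate_bf
  grade <- tryCatch(
    grade_imprecision(ts_main, ts_cil, ts_point, realistic = spec$realistic),
    error = function(e) { notes <<- c(notes, paste0("GRADE imprecision not rated: ", conditionMessage(e))); NA_integer_ })
  nnt_block <- NULL
  if (spec$data_type == "dichotomous") {
    risk_ctl <- sum(sub$events_ctl) /
      sum(sub$randomised_ctl - ifelse(is.na(sub$lost_ctl), 0, sub$lost_ctl))
    risk_exp <- switch(spec$measure,
                       logRR = risk_ctl * exp(conserv$theta),
                       logOR = stats::plogis(stats::qlogis(risk_ctl) + conserv$theta),
                       RD = risk_ctl + conserv$theta)
    if (risk_exp > 0 && risk_exp < 1)
      nnt_block <- nnt(risk_exp, risk_ctl, spec$benefit_direction)
  }
  checklist <- if (significant) .clinical_checklist(spec, nnt_block) else character(0)

  structure(list(
    outcome_id = spec$outcome_id, role = spec$role, spec = spec, k = nrow(effects),
    pair = pair, conservative = conserv, threshold = threshold,
    alpha_used = alpha_out,
    heterogeneity = c(het, list(D2 = pair$D2, dominance = pair$dominance_flag,
                                substantial = substantial_het)),
    ris = ris, tsa = ts_main, tsa_point = ts_point, tsa_ci_limit = ts_cil,
    ris_reached = ris_reached,
    bayes = list(main = bf_main, sceptical = bf_scept),
    sensitivity = list(best_worst = best_worst, worst_best = worst_best,
                       rob_subgroups = robcmp),
    publication_bias = pb,
    gates = c(p = gate_p, tsa = gate_tsa, bayes_factor = gate_bf),
    statistically_significant = significant,
    grade_imprecision_downgrade = grade,
    nnt = nnt_block,
    clinical_significance_checklist = checklist,
    notes = notes), class = "outcome_verdict")
}

#' Run the eight-step assessment
#'
#' Fits the full assessment for every specified outcome: (1) fixed- and
#' random-effects pooling with conservative-result selection, (2)
#' heterogeneity diagnostics, (3) multiplicity-adjusted thresholds, (4)
#' diversity-adjusted required information size and trial sequential
#' analysis, (5) Bayes factors for primary outcomes, (6) attrition scenarios
#' and risk-of-bias subgroups, (7) publication-bias assessment, and (8) the
#' statistical-significance gate with the GRADE imprecision cascade and a
#' clinical-significance checklist for outcomes passing the gate.
#'
#' @param trials a trial table from [trial_table()] / [read_trials_csv()].
#' @param outcomes an [outcome_spec()] or list of them.
#' @param config a [review_config()].
#' @return An `eight_steps` object: a list of per-outcome `outcome_verdict`s
#'   plus the shared threshold and configuration.
#' @export
eight_steps <- function(trials, outcomes, config = review_config()) {
  stopifnot(inherits(config, "review_config"))
  if (inherits(outcomes, "outcome_spec")) outcomes <- list(outcomes)
  names(outcomes) <- vapply(outcomes, `[[`, "", "outcome_id")
  trials <- if (inherits(trials, "octostep_trials")) trials else trial_table(trials)
  analysed <- unique(trials$outcome_id)
  unspec <- setdiff(analysed, names(outcomes))
  if (length(unspec))
    stop("no outcome specification for analysed outcome(s): ",
         paste(unspec, collapse = ", "))
  m <- config$m %||% max(1L, sum(vapply(outcomes, `[[`, "", "role") == "primary"))
  threshold <- adjusted_alpha(config$alpha_base, m)
  set.seed(config$seed)
  verdicts <- list()
  for (spec in outcomes) {
    sub <- trials[trials$outcome_id == spec$outcome_id, , drop = FALSE]
    if (nrow(sub) == 0L) {
      message("outcome '", spec$outcome_id, "' has no trials; skipped")
      next
    }
    verdicts[[spec$outcome_id]] <- .analyse_outcome(sub, spec, config, threshold)
  }
  structure(list(verdicts = verdicts, threshold = threshold, config = config,
                 m = m), class = "eight_steps")
}

#' @export
print.outcome_verdict <- function(x, ...) {
  cat(sprintf("Outcome '%s' (%s, k = %d trials)\n", x$outcome_id, x$role, x$k))
  cat(sprintf("  conservative result (%s): theta = %.4f, %g%% CI [%.4f, %.4f], P = %.4g (threshold %.4g)\n",
              x$pair$primary_model, x$conservative$theta,
              100 * x$conservative$level, x$conservative$ci[1],
              x$conservative$ci[2], x$conservative$p, x$alpha_used))
  cat(sprintf("  heterogeneity: I2 = %s, D2 = %.3f%s\n",
              if (is.na(x$heterogeneity$I2)) "n/a"
              else sprintf("%.1f%%", 100 * x$heterogeneity$I2),
              x$heterogeneity$D2,
              if (x$heterogeneity$dominance) " [weight dominance]" else ""))
  cat(sprintf("  TSA: DIS = %d, information fraction %.3f, crossing = %s; adjusted CI [%.4f, %.4f]\n",
              x$ris$dis, x$tsa$looks$t[nrow(x$tsa$looks)], x$tsa$crossing,
              x$tsa$adjusted_ci[1], x$tsa$adjusted_ci[2]))
  if (!is.null(x$bayes$main))
    cat(sprintf("  Bayes factor: %.4g (sceptical %.4g)\n",
                x$bayes$main$bf, x$bayes$sceptical$bf))
  cat(sprintf("  gates [P %s | TSA %s | BF %s] -> %s; GRADE imprecision downgrade: %s\n",
              ifelse(x$gates["p"], "pass", "fail"),
              ifelse(x$gates["tsa"], "pass", "fail"),
              ifelse(x$gates["bayes_factor"], "pass", "fail"),
              if (x$statistically_significant) "STATISTICALLY SIGNIFICANT"
              else "not statistically significant",
              ifelse(is.na(x$grade_imprecision_downgrade), "not rated",
                     x$grade_imprecision_downgrade)))
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' @export
print.eight_steps <- function(x, ...) {
  cat(sprintf("Eight-step assessment: %d outcome(s), %d primary (adjusted alpha %.4g)\n\n",
              length(x$verdicts), x$m, x$threshold$alpha_adjusted))
  for (v in x$verdicts) { print(v); cat("\n") }
  invisible(x)
}

#' @export
summary.eight_steps <- function(object, ...) {
  rows <- lapply(object$verdicts, function(v) {
    data.frame(outcome = v$outcome_id, role = v$role, k = v$k,
               model = v$pair$primary_model, theta = v$conservative$theta,
               ci_low = v$conservative$ci[1], ci_high = v$conservative$ci[2],
               p = v$conservative$p, alpha = v$alpha_used,
               I2 = v$heterogeneity$I2, D2 = v$heterogeneity$D2,
               dis = v$ris$dis,
               information_fraction = v$tsa$looks$t[nrow(v$tsa$looks)],
               tsa_crossing = v$tsa$crossing,
               bayes_factor = if (!is.null(v$bayes$main)) v$bayes$main$bf else NA_real_,
               significant = v$statistically_significant,
               grade_downgrade = v$grade_imprecision_downgrade,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.eight_steps", "data.frame")
  out
}

# plain-list serialisation of one verdict for the JSON report
.verdict_report <- function(v) {
  pr <- function(p) if (is.null(p)) NULL else
    list(model = p$model, theta = p$theta, se = p$se, ci = p$ci,
         level = p$level, p_value = p$p, tau2 = p$tau2, I2 = p$I2, Q = p$Q)
  bf <- function(b) if (is.null(b)) NULL else
    list(bf = b$bf, mu_A = b$mu_A, threshold = b$threshold,
         significant = b$significant)
  ts <- function(t) if (is.null(t)) NULL else
    list(model = t$model, crossing = t$crossing, crossing_look = t$crossing_look,
         adjusted_ci = t$adjusted_ci, dis = t$ris$dis, mu_A = t$ris$mu_A,
         information_fraction = t$looks$t[nrow(t$looks)],
         looks = t$looks)
  sc <- function(s) if (is.null(s)) NULL else
    list(scenario = s$scenario,
         pooled = pr(primary_result(s$pooled)),
         delta_vs_primary = s$delta_vs_primary)
  list(outcome_id = v$outcome_id, role = v$role, k = v$k,
       adjusted_threshold = list(m = v$threshold$m,
                                 alpha_base = v$threshold$alpha_base,
                                 alpha_adjusted = v$threshold$alpha_adjusted,
                                 bonferroni = v$threshold$bonferroni,
                                 ci_level = v$threshold$ci_level),
       alpha_used = v$alpha_used,
       pooled = list(fixed = pr(v$pair$fixed), random = pr(v$pair$random),
                     primary_model = v$pair$primary_model,
                     conservative = pr(v$conservative)),
       heterogeneity = v$heterogeneity[c("Q", "I2", "tau2", "df", "D2",
                                         "dominance", "substantial")],
       information_size = list(n_fixed = v$ris$n_fixed, dis = v$ris$dis,
                               D2_used = v$ris$D2_used,
                               fallback_used = v$ris$fallback_used,
                               alpha = v$ris$alpha_used, beta = v$ris$beta_used,
                               mu_A = v$ris$mu_A),
       tsa = list(main = ts(v$tsa), point_estimate = ts(v$tsa_point),
                  ci_limit = ts(v$tsa_ci_limit), ris_reached = v$ris_reached),
       bayes_factor = list(main = bf(v$bayes$main),
                           sceptical = bf(v$bayes$sceptical)),
       sensitivity = list(
         best_worst = sc(v$sensitivity$best_worst),
         worst_best = sc(v$sensitivity$worst_best),
         rob_subgroups = list(
           tested = v$sensitivity$rob_subgroups$tested,
           Q_between = v$sensitivity$rob_subgroups$Q_between,
           df = v$sensitivity$rob_subgroups$df,
           p = v$sensitivity$rob_subgroups$p,
           low_risk_pooled = pr(v$sensitivity$rob_subgroups$low_risk_pooled))),
       publication_bias = list(
         assessed = v$publication_bias$assessed,
         flag_suppressed = v$publication_bias$flag_suppressed,
         egger = v$publication_bias$egger,
         begg = v$publication_bias$begg[c("tau", "z", "p")],
         harbord = v$publication_bias$harbord[c("intercept", "se", "t", "p")],
         trimfill = if (!is.null(v$publication_bias$trimfill))
           list(k0 = v$publication_bias$trimfill$k0,
                side = v$publication_bias$trimfill$side,
                adjusted = pr(primary_result(v$publication_bias$trimfill$adjusted)))),
       gates = as.list(v$gates),
       statistically_significant = v$statistically_significant,
       grade_imprecision_downgrade = v$grade_imprecision_downgrade,
       nnt = v$nnt,
       clinical_significance_checklist = v$clinical_significance_checklist,
       notes = v$notes)
}

#' Write the structured JSON report
#'
#' Serialises an [eight_steps()] fit to JSON. Identical inputs and seed
#' produce byte-identical reports.
#'
#' @param fit an `eight_steps` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
report_json <- function(fit, path) {
  stopifnot(inherits(fit, "eight_steps"))
  obj <- list(
    threshold = list(m = fit$m, alpha_base = fit$threshold$alpha_base,
                     alpha_adjusted = fit$threshold$alpha_adjusted,
                     ci_level = fit$threshold$ci_level),
    config = unclass(fit$config),
    outcomes = lapply(fit$verdicts, .verdict_report))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write the human-readable summary table
#'
#' One row per outcome (the [summary.eight_steps()] table) as TSV.
#'
#' @param fit an `eight_steps` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
report_tsv <- function(fit, path) {
  utils::write.table(summary(fit), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
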