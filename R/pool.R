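# Pooling engines: inverse-variance fixed effect, DerSimonian-Laird random
# effects, and the Hartung-Knapp-Sidik-Jonkman variance adjustment. All three
# accept an arbitrary two-sided confidence level so that multiplicity-adjusted
# intervals come out of the same code path.

new_pooled_result <- function(model, theta, se, level, p, weights, Q, tau2, df,
                              dist = c("normal", "t"), t_df = NA_real_,
                              trial_id = NULL, note = NULL) {
  dist <- match.arg(dist)
  crit <- if (dist == "normal") stats::qnorm(1 - (1 - level) / 2)
          else stats::qt(1 - (1 - level) / 2, t_df)
  k <- length(weights)
  structure(list(model = model, k = k, theta = theta, se = se,
                 ci = c(theta - crit * se, theta + crit * se), level = level,
                 p = p, weights = weights / sum(weights),
                 Q = Q, tau2 = tau2,
                 I2 = if (k >= 2) max(0, (Q - (k - 1)) / Q) else NA_real_,
                 df = k - 1, dist = dist, t_df = t_df,
                 trial_id = trial_id, note = note),
            class = "pooled_result")
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools trial effects under the common-effect assumption with weights
#' \eqn{w_i = 1/se_i^2}: \eqn{\hat\theta = \sum w_i \theta_i / \sum w_i},
#' \eqn{SE = 1/\sqrt{\sum w_i}}, normal CI and P, and Cochran's
#' \eqn{Q = \sum w_i(\theta_i - \hat\theta)^2}.
#'
#' @param effects data.frame with `theta` and `se` columns (e.g. from
#'   [trial_effects()]), or a list of per-trial estimates.
#' @param level two-sided confidence level (default 0.95).
#' @return A `pooled_result`.
#' @export
fixed_effect_pool <- function(effects, level = 0.95) {
  e <- as_effects(effects)
  if (nrow(e) < 1L) stop("no effects to pool")
  stopifnot(all(e$se > 0))
  w <- 1 / e$se^2
  theta <- sum(w * e$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (e$theta - theta)^2)
  p <- 2 * stats::pnorm(-abs(theta / se))
  new_pooled_result("fixed", theta, se, level, p, w, Q, 0, length(w) - 1,
                    trial_id = e$trial_id)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-trial variance
#' \eqn{\tau^2 = \max(0, (Q - (k-1))/C)} with
#' \eqn{C = \sum w_i - \sum w_i^2/\sum w_i}, then inverse-variance pooling with
#' starred weights \eqn{w^*_i = 1/(se_i^2 + \tau^2)} and normal quantiles.
#' With a single trial the fixed-effect result is returned tagged `"DL"` with
#' \eqn{\tau^2 = 0}.
#'
#' @inheritParams fixed_effect_pool
#' @return A `pooled_result` with the `Q` of the fixed-effect fit.
#' @export
dersimonian_laird_pool <- function(effects, level = 0.95) {
  e <- as_effects(effects)
  if (nrow(e) < 1L) stop("no effects to pool")
  if (nrow(e) == 1L) {
    out <- fixed_effect_pool(e, level)
    out$model <- "DL"
    return(out)
  }
  w <- 1 / e$se^2
  k <- length(w)
  theta_f <- sum(w * e$theta) / sum(w)
  Q <- sum(w * (e$theta - theta_f)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  ws <- 1 / (e$se^2 + tau2)
  theta <- sum(ws * e$theta) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  p <- 2 * stats::pnorm(-abs(theta / se))
  new_pooled_result("DL", theta, se, level, p, ws, Q, tau2, k - 1,
                    trial_id = e$trial_id)
}

#' Hartung-Knapp-Sidik-Jonkman adjustment
#'
#' Keeps the DerSimonian-Laird point estimate but replaces its variance with
#' \eqn{[\sum w^*_i(\theta_i - \hat\theta)^2/(k-1)] / \sum w^*_i} and bases the
#' CI and P on a t distribution with \eqn{k-1} degrees of freedom. Implemented
#' unmodified (no variance floor); if the weighted dispersion is exactly zero
#' the DL standard error is reused with a warning.
#'
#' @inheritParams fixed_effect_pool
#' @param dl optional precomputed [dersimonian_laird_pool()] result on the
#'   same effects.
#' @return A `pooled_result` with t-based inference.
#' @export
hksj_adjust <- function(effects, dl = NULL, level = 0.95) {
  e <- as_effects(effects)
  k <- nrow(e)
  if (k < 2L) stop("HKSJ requires k >= 2 trials")
  if (is.null(dl)) dl <- dersimonian_laird_pool(e, level)
  ws <- 1 / (e$se^2 + dl$tau2)
  q <- sum(ws * (e$theta - dl$theta)^2) / (k - 1)
  degenerate <- q <= 1e-24 * (sum(ws * e$theta^2) / (k - 1) + 1e-300)
  if (degenerate) {
    warning("zero weighted dispersion: HKSJ variance degenerate, falling back to DL standard error")
    se <- dl$se
  } else {
    se <- sqrt(q / sum(ws))
  }
  p <- 2 * stats::pt(-abs(dl$theta / se), df = k - 1)
  new_pooled_result("HKSJ", dl$theta, se, level, p, ws, dl$Q, dl$tau2, k - 1,
                    dist = "t", t_df = k - 1, trial_id = e$trial_id)
}

#' Heterogeneity statistics
#'
#' Cochran's Q, \eqn{I^2 = \max(0, (Q - (k-1))/Q)} and the DerSimonian-Laird
#' \eqn{\tau^2} for a set of trial effects. With fewer than two trials all
#' statistics are `NA` (not applicable).
#'
#' @inheritParams fixed_effect_pool
#' @return List with `Q`, `I2`, `tau2`, `df`, `p` (chi-squared P for Q).
#' @export
heterogeneity_stats <- function(effects) {
  e <- as_effects(effects)
  k <- nrow(e)
  if (k < 2L)
    return(list(Q = NA_real_, I2 = NA_real_, tau2 = NA_real_, df = NA_integer_,
                p = NA_real_))
  fe <- fixed_effect_pool(e)
  dl <- dersimonian_laird_pool(e)
  list(Q = fe$Q, I2 = if (fe$Q > 0) max(0, (fe$Q - (k - 1)) / fe$Q) else 0,
       tau2 = dl$tau2, df = k - 1L,
       p = stats::pchisq(fe$Q, k - 1, lower.tail = FALSE))
}

#' Diversity (D-squared)
#'
#' The share of the random-effects variance attributable to between-trial
#' variability: \eqn{D^2 = (v_R - v_F)/v_R} with \eqn{v = SE^2} from the
#' random- and fixed-effect fits of the same trials. Always at least as large
#' as \eqn{I^2} on the same data.
#'
#' @param fixed,random `pooled_result` objects fitted on the same effects.
#' @return D-squared, clipped to `[0, 1)`.
#' @export
diversity_d2 <- function(fixed, random) {
  v_f <- fixed$se^2; v_r <- random$se^2
  if (v_r == 0) stop("random-effects variance is zero")
  min(max(0, (v_r - v_f) / v_r), 1 - 1e-12)
}

#' Weight-dominance diagnostic
#'
#' Flags a fixed-effect meta-analysis in which one or two trials carry at
#' least `threshold` percent of the total weight — a setting where the
#' random-effects model may inappropriately down-weight the most precise
#' trials.
#'
#' @param fixed a fixed-effect `pooled_result`.
#' @param threshold percentage of total weight (default 80).
#' @return Logical flag.
#' @export
weight_dominance_flag <- function(fixed, threshold = 80) {
  sh <- sort(fixed$weights, decreasing = TRUE)
  sum(sh[seq_len(min(2L, length(sh)))]) >= threshold / 100
}

#' Fit the fixed/random model pair
#'
#' Fits the fixed-effect and random-effects (DerSimonian-Laird, optionally
#' HKSJ-adjusted) models, computes D-squared and the weight-dominance flag,
#' and applies the conservative-result rule: the model with the larger
#' P-value is designated primary (ties go to random effects).
#'
#' @inheritParams fixed_effect_pool
#' @param hksj use the HKSJ adjustment for the random-effects result when
#'   `k >= 2` (default `TRUE`).
#' @param dominance_threshold percentage for [weight_dominance_flag()].
#' @return A `model_pair` with elements `fixed`, `random`, `D2`,
#'   `primary_model`, `dominance_flag`, `het` (heterogeneity block).
#' @export
pool_pair <- function(effects, level = 0.95, hksj = TRUE, dominance_threshold = 80) {
  e <- as_effects(effects)
  fe <- fixed_effect_pool(e, level)
  dl <- dersimonian_laird_pool(e, level)
  re <- if (hksj && nrow(e) >= 2L) hksj_adjust(e, dl, level) else dl
  pair <- structure(list(fixed = fe, random = re, dl = dl,
                         D2 = diversity_d2(fe, re),
                         dominance_flag = weight_dominance_flag(fe, dominance_threshold),
                         het = heterogeneity_stats(e)),
                    class = "model_pair")
  pair$primary_model <- select_primary_result(pair)
  pair
}

#' Conservative-result selection
#'
#' Returns the model (fixed or random) with the larger P-value; both results
#' are always retained in the pair. Exact ties resolve to the random-effects
#' model, whose assumption is usually the more realistic.
#'
#' @param pair a `model_pair`.
#' @return `"fixed"` or `"random"`.
#' @export
select_primary_result <- function(pair) {
  if (pair$fixed$p > pair$random$p) "fixed" else "random"
}

#' Extract the primary pooled result from a model pair
#'
#' @param pair a `model_pair`.
#' @return The `pooled_result` designated primary by the conservative rule.
#' @export
primary_result <- function(pair) {
  if (pair$primary_model == "fixed") pair$fixed else pair$random
}

#' Forest-plot data export
#'
#' Per-trial estimates, CIs and weight shares under both models, plus pooled
#' rows, as a plain data.frame suitable for writing to TSV.
#'
#' @param effects effects data.frame with `trial_id`, `theta`, `se`.
#' @param pair the fitted `model_pair` on those effects.
#' @return data.frame with one row per trial and one per pooled model.
#' @export
forest_data <- function(effects, pair) {
  e <- as_effects(effects)
  z <- stats::qnorm(1 - (1 - pair$fixed$level) / 2)
  rows <- data.frame(row = e$trial_id, theta = e$theta,
                     ci_low = e$theta - z * e$se, ci_high = e$theta + z * e$se,
                     weight_fixed = pair$fixed$weights,
                     weight_random = pair$random$weights,
                     stringsAsFactors = FALSE)
  pooled <- data.frame(row = c("pooled (fixed)", "pooled (random)"),
                       theta = c(pair$fixed$theta, pair$random$theta),
                       ci_low = c(pair$fixed$ci[1], pair$random$ci[1]),
                       ci_high = c(pair$fixed$ci[2], pair$random$ci[2]),
                       weight_fixed = NA_real_, weight_random = NA_real_,
                       stringsAsFactors = FALSE)
  rbind(rows, pooled)
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("%s-effect pooled result (k = %d)\n",
              switch(x$model, fixed = "Fixed", DL = "DerSimonian-Laird random",
                     HKSJ = "HKSJ random", x$model), x$k))
  cat(sprintf("  theta = %.4f  SE = %.4f  %g%% CI [%.4f, %.4f]  P = %.4g\n",
              x$theta, x$se, 100 * x$level, x$ci[1], x$ci[2], x$p))
  if (x$k >= 2)
    cat(sprintf("  Q = %.3f (df = %d)  tau2 = %.4f  I2 = %.1f%%\n",
                x$Q, x$df, x$tau2, 100 * x$I2))
  invisible(x)
}

#' @export
print.model_pair <- function(x, ...) {
  cat("Fixed-effect vs random-effects model pair\n")
  print(x$fixed); print(x$random)
  cat(sprintf("  D2 = %.3f  primary (conservative) model: %s%s\n", x$D2,
              x$primary_model,
              if (x$dominance_flag) "  [one/two-trial weight dominance]" else ""))
  invisible(x)
}
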