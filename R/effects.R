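# Per-trial effect estimates. Ratio measures live on the log scale throughout;
# pooling, TSA and Bayes factors all operate on theta/se pairs.

#' Per-trial effect for a dichotomous outcome
#'
#' Computes the trial-level contrast and its large-sample standard error.
#' Tables containing a zero cell get 0.5 added to all four cells (per trial)
#' for the ratio measures; trials with zero events in both arms carry no
#' information about a ratio and are flagged `excluded` rather than erroring.
#'
#' @param events_exp,analysed_exp events and analysed participants,
#'   experimental arm.
#' @param events_ctl,analysed_ctl same for the control arm.
#' @param measure `"logRR"`, `"logOR"` or `"RD"`.
#' @param trial_id optional identifier carried through.
#' @return List with `theta`, `se`, `measure`, `corrected` (continuity
#'   correction applied), `excluded` (double-zero trial, ratio measures).
#' @export
dichotomous_effect <- function(events_exp, analysed_exp, events_ctl, analysed_ctl,
                               measure = c("logRR", "logOR", "RD"),
                               trial_id = NA_character_) {
  measure <- match.arg(measure)
  if (analysed_exp <= 0 || analysed_ctl <= 0) stop("analysed counts must be > 0")
  if (events_exp > analysed_exp || events_ctl > analysed_ctl)
    stop("events exceed analysed participants")
  a <- events_exp; n1 <- analysed_exp; c <- events_ctl; n2 <- analysed_ctl
  b <- n1 - a; d <- n2 - c
  if (a + c == 0 && b + d == 0) stop("undefined effect: empty 2x2 table")
  excluded <- FALSE; corrected <- FALSE
  if (measure %in% c("logRR", "logOR")) {
    if (a + c == 0) excluded <- TRUE          # double-zero: no ratio information
    if (any(c(a, b, c, d) == 0)) {
      corrected <- TRUE
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
      n1 <- a + b; n2 <- c + d
    }
  }
  if (measure == "logRR") {
    theta <- log((a / n1) / (c / n2))
    se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n2)
  } else if (measure == "logOR") {
    theta <- log((a * d) / (b * c))
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  } else {
    p1 <- a / n1; p2 <- c / n2
    theta <- p1 - p2
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    if (se == 0) { corrected <- TRUE
      a <- a + 0.5; c <- c + 0.5; n1 <- n1 + 1; n2 <- n2 + 1
      p1 <- a / n1; p2 <- c / n2
      se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    }
  }
  list(trial_id = trial_id, measure = measure, theta = theta, se = se,
       corrected = corrected, excluded = excluded)
}

#' Per-trial effect for a continuous outcome
#'
#' Mean difference with its exact standard error, or the standardised mean
#' difference as Hedges' g (small-sample corrected) with the standard
#' large-sample SE.
#'
#' @param mean_exp,sd_exp,n_exp experimental arm summary statistics.
#' @param mean_ctl,sd_ctl,n_ctl control arm summary statistics.
#' @param measure `"MD"` or `"SMD"`.
#' @param trial_id optional identifier carried through.
#' @return List with `theta`, `se`, `measure`.
#' @export
continuous_effect <- function(mean_exp, sd_exp, n_exp, mean_ctl, sd_ctl, n_ctl,
                              measure = c("MD", "SMD"),
                              trial_id = NA_character_) {
  measure <- match.arg(measure)
  if (n_exp < 2 || n_ctl < 2) stop("validation error: need >= 2 analysed per arm")
  if (sd_exp <= 0 || sd_ctl <= 0) stop("SDs must be > 0")
  if (measure == "MD") {
    theta <- mean_exp - mean_ctl
    se <- sqrt(sd_exp^2 / n_exp + sd_ctl^2 / n_ctl)
  } else {
    df <- n_exp + n_ctl - 2
    sp <- sqrt(((n_exp - 1) * sd_exp^2 + (n_ctl - 1) * sd_ctl^2) / df)
    d <- (mean_exp - mean_ctl) / sp
    # exact Hedges' small-sample bias correction
    J <- exp(lgamma(df / 2) - lgamma((df - 1) / 2)) / sqrt(df / 2)
    g <- J * d
    se <- sqrt((n_exp + n_ctl) / (n_exp * n_ctl) + g^2 / (2 * (n_exp + n_ctl)))
    theta <- g
  }
  list(trial_id = trial_id, measure = measure, theta = theta, se = se,
       corrected = FALSE, excluded = FALSE)
}

#' Effect estimates for every trial of one outcome
#'
#' Applies [dichotomous_effect()] or [continuous_effect()] row-wise, ordered by
#' publication year (ties by trial id) — the ordering used by the cumulative
#' z-curve. Double-zero trials are flagged and dropped from ratio-measure
#' pooling with a message.
#'
#' @param trials trial table rows for one outcome.
#' @param measure effect measure (see the per-type functions).
#' @param keep_excluded keep double-zero rows (flagged) instead of dropping.
#' @return data.frame with `trial_id`, `year`, `theta`, `se`, `n_total`
#'   (randomised participants, both arms), `rob` (overall risk of bias),
#'   `corrected`, `excluded`, ordered by year then id.
#' @export
trial_effects <- function(trials, measure = NULL, keep_excluded = FALSE) {
  trials <- as.data.frame(trials)
  type <- trial_data_type(trials)
  if (length(unique(type)) > 1L) stop("mixed dichotomous/continuous rows for one outcome")
  if (is.null(measure)) measure <- if (type[1] == "dichotomous") "logRR" else "MD"
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    r <- trials[i, ]
    if (type[i] == "dichotomous") {
      l_e <- if (is.na(r$lost_exp)) 0 else r$lost_exp
      l_c <- if (is.na(r$lost_ctl)) 0 else r$lost_ctl
      e <- dichotomous_effect(r$events_exp, r$randomised_exp - l_e,
                              r$events_ctl, r$randomised_ctl - l_c,
                              measure, trial_id = r$trial_id)
      n_tot <- r$randomised_exp + r$randomised_ctl
    } else {
      e <- continuous_effect(r$mean_exp, r$sd_exp, r$analysed_exp,
                             r$mean_ctl, r$sd_ctl, r$analysed_ctl,
                             measure, trial_id = r$trial_id)
      l_e <- if (is.na(r$lost_exp)) 0 else r$lost_exp
      l_c <- if (is.na(r$lost_ctl)) 0 else r$lost_ctl
      n_tot <- r$analysed_exp + l_e + r$analysed_ctl + l_c
    }
    out[[i]] <- data.frame(trial_id = r$trial_id, year = r$year,
                           theta = e$theta, se = e$se, n_total = n_tot,
                           corrected = e$corrected, excluded = e$excluded,
                           stringsAsFactors = FALSE)
  }
  eff <- do.call(rbind, out)
  eff$rob <- overall_risk_of_bias(trials)
  eff <- eff[order(eff$year, eff$trial_id), , drop = FALSE]
  if (any(eff$excluded) && !keep_excluded) {
    message(sum(eff$excluded), " double-zero trial(s) excluded from ratio-measure pooling: ",
            paste(eff$trial_id[eff$excluded], collapse = ", "))
    eff <- eff[!eff$excluded, , drop = FALSE]
  }
  attr(eff, "measure") <- measure
  rownames(eff) <- NULL
  eff
}

# Coerce the various accepted effect representations (data.frame with
# theta/se, or plain list of such) to a data.frame with theta and se columns.
as_effects <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("theta", "se") %in% names(effects)))
    return(effects)
  }
  if (is.list(effects) && !is.null(effects$theta)) effects <- list(effects)
  df <- do.call(rbind, lapply(effects, function(e)
    data.frame(trial_id = e$trial_id %||% NA_character_,
               theta = e$theta, se = e$se, stringsAsFactors = FALSE)))
  df
}
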