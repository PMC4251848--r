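# Synthetic review generator with known truth, for tests and
# operating-characteristic studies. Each trial draws its own latent effect
# from Normal(true_effect, tau^2); arm data are binomial (dichotomous) or
# normal summaries (continuous); losses are binomial and removed from the
# analysed counts. One random sub-stream per trial, indexed deterministically
# from the dataset seed, so changing k never reshuffles earlier trials.

#' Specification of a simulated review dataset
#'
#' @param k number of trials (>= 1).
#' @param true_effect true pooled effect (log relative risk for dichotomous,
#'   mean difference for continuous).
#' @param tau between-trial SD of the latent trial effects (>= 0).
#' @param data_type `"dichotomous"` or `"continuous"`.
#' @param control_risk control-arm event probability (dichotomous).
#' @param control_mean,control_sd control-arm distribution (continuous).
#' @param size_range per-arm randomised participants, drawn uniformly from
#'   `size_range[1]:size_range[2]`.
#' @param loss_rate per-participant probability of loss to follow-up.
#' @param suppress_rule `"none"`, or `"left-tail"`: each trial whose two-sided
#'   P exceeds `suppress_cutoff` and whose estimate lies on the null side of
#'   the funnel is removed with probability `suppress_prob` (emulates
#'   suppression of small unfavourable trials).
#' @param suppress_prob,suppress_cutoff parameters of the suppression rule.
#' @param outcome_id outcome identifier stamped on the records.
#' @param seed integer seed.
#' @return A `sim_spec` object.
#' @export
sim_spec <- function(k, true_effect = 0, tau = 0,
                     data_type = c("dichotomous", "continuous"),
                     control_risk = 0.2, control_mean = 0, control_sd = 1,
                     size_range = c(50, 400), loss_rate = 0.05,
                     suppress_rule = c("none", "left-tail"),
                     suppress_prob = 0.8, suppress_cutoff = 0.05,
                     outcome_id = "outcome_1", seed = 1L) {
  data_type <- match.arg(data_type)
  suppress_rule <- match.arg(suppress_rule)
  if (k < 1) stop("k must be >= 1")
  stopifnot(tau >= 0, loss_rate >= 0, loss_rate <= 1,
            suppress_prob >= 0, suppress_prob <= 1)
  if (data_type == "dichotomous" &&
      (control_risk <= 0 || control_risk >= 1))
    stop("control_risk must be in (0, 1)")
  structure(list(k = as.integer(k), true_effect = true_effect, tau = tau,
                 data_type = data_type, control_risk = control_risk,
                 control_mean = control_mean, control_sd = control_sd,
                 size_range = size_range, loss_rate = loss_rate,
                 suppress_rule = suppress_rule, suppress_prob = suppress_prob,
                 suppress_cutoff = suppress_cutoff,
                 outcome_id = outcome_id, seed = as.integer(seed)),
            class = "sim_spec")
}

# deterministic per-trial sub-stream index (kept below 2^31)
.trial_seed <- function(seed, i) as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)

#' Simulate a review dataset
#'
#' Generates a trial table satisfying all trial-record invariants, plus a
#' truth record retaining every latent value (per-trial effects, sizes,
#' losses, suppression). Fully reproducible from the seed.
#'
#' @param spec a [sim_spec()].
#' @return List with `trials` (an `octostep_trials` table) and `truth`.
#' @export
simulate_review <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  rows <- vector("list", spec$k)
  latent <- numeric(spec$k)
  for (i in seq_len(spec$k)) {
    set.seed(.trial_seed(spec$seed, i))
    delta <- stats::rnorm(1, spec$true_effect, spec$tau)
    latent[i] <- delta
    n_arm <- if (spec$size_range[1] == spec$size_range[2]) spec$size_range[1]
             else sample(spec$size_range[1]:spec$size_range[2], 1)
    lost_e <- stats::rbinom(1, n_arm, spec$loss_rate)
    lost_c <- stats::rbinom(1, n_arm, spec$loss_rate)
    an_e <- n_arm - lost_e; an_c <- n_arm - lost_c
    if (an_e < 2 || an_c < 2) stop("loss rate leaves fewer than 2 analysed participants")
    if (spec$data_type == "dichotomous") {
      p_c <- spec$control_risk
      p_e <- p_c * exp(delta)
      if (p_e <= 0 || p_e >= 1)
        stop("implied experimental risk outside (0, 1) for trial ", i)
      rows[[i]] <- data.frame(
        trial_id = sprintf("trial_%03d", i), year = 2000 + i,
        outcome_id = spec$outcome_id,
        events_exp = stats::rbinom(1, an_e, p_e), randomised_exp = n_arm,
        lost_exp = lost_e,
        events_ctl = stats::rbinom(1, an_c, p_c), randomised_ctl = n_arm,
        lost_ctl = lost_c, stringsAsFactors = FALSE)
    } else {
      m_e <- spec$control_mean + delta; sdv <- spec$control_sd
      rows[[i]] <- data.frame(
        trial_id = sprintf("trial_%03d", i), year = 2000 + i,
        outcome_id = spec$outcome_id,
        mean_exp = stats::rnorm(1, m_e, sdv / sqrt(an_e)),
        sd_exp = sdv * sqrt(stats::rchisq(1, an_e - 1) / (an_e - 1)),
        analysed_exp = an_e, lost_exp = lost_e,
        mean_ctl = stats::rnorm(1, spec$control_mean, sdv / sqrt(an_c)),
        sd_ctl = sdv * sqrt(stats::rchisq(1, an_c - 1) / (an_c - 1)),
        analysed_ctl = an_c, lost_ctl = lost_c, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    for (cc in setdiff(.trial_cols(), names(r)))
      r[[cc]] <- if (cc %in% rob_domains()) "low" else NA
    r[, .trial_cols()]
  }))
  suppressed <- rep(FALSE, spec$k)
  if (spec$suppress_rule == "left-tail") {
    eff <- trial_effects(trial_table(df), keep_excluded = TRUE)
    eff <- eff[match(df$trial_id, eff$trial_id), ]
    pvals <- 2 * stats::pnorm(-abs(eff$theta / eff$se))
    null_side <- if (spec$true_effect != 0)
      sign(eff$theta) != sign(spec$true_effect) | eff$theta == 0
    else eff$theta >= 0   # for a null truth, suppress the non-negative side
    set.seed(.trial_seed(spec$seed, 0L))
    cand <- pvals > spec$suppress_cutoff & null_side
    suppressed <- cand & stats::runif(spec$k) < spec$suppress_prob
    if (all(suppressed)) suppressed[1] <- FALSE   # keep at least one trial
    df <- df[!suppressed, , drop = FALSE]
  }
  list(trials = trial_table(df),
       truth = list(spec = spec, latent_effects = latent,
                    suppressed = suppressed))
}
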