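# Funnel-plot assessment of small-study effects: funnel data with
# significance-contour enhancement, the Egger, Begg and Harbord asymmetry
# tests, and the Duval-Tweedie trim-and-fill adjustment. Funnel-based
# assessment is only meaningful with enough trials (default 10); below that
# the funnel is flagged ineligible, and the tests warn when called directly.

.check_funnel_k <- function(k, min_trials, what) {
  if (k < min_trials)
    warning(sprintf("%s with %d trials (< %d): interpret with great caution",
                    what, k, min_trials))
}

#' Funnel-plot data
#'
#' Per-trial effects against their standard errors on the analysis (log)
#' scale, with contour bands at the conventional significance milestones and
#' the eligibility flag (at least `min_trials` trials, default 10). Contour
#' band polygons are emitted over an SE grid for plotting: the band at level p
#' passes through \eqn{|\theta| = z_{1-p/2} \cdot SE}.
#'
#' @param effects data.frame with `theta` and `se`.
#' @param pooled reference `pooled_result` (for the centre line).
#' @param min_trials eligibility threshold (default 10).
#' @param contour_levels significance milestones (default 0.10, 0.05, 0.01).
#' @return A `funnel_data` object: `points` (with each trial's two-sided P and
#'   contour band), `pooled_theta`, `eligible`, `contours` (SE-grid polygons),
#'   `any_significant`.
#' @export
funnel_data <- function(effects, pooled = NULL, min_trials = 10,
                        contour_levels = c(0.10, 0.05, 0.01)) {
  e <- as_effects(effects)
  k <- nrow(e)
  z <- abs(e$theta) / e$se
  pval <- 2 * stats::pnorm(-z)
  band <- vapply(pval, function(p) sum(p < contour_levels), 0L)
  se_grid <- seq(0, max(e$se) * 1.05, length.out = 50)
  contours <- do.call(rbind, lapply(contour_levels, function(lv) {
    zc <- stats::qnorm(1 - lv / 2)
    data.frame(level = lv, se = se_grid, theta_low = -zc * se_grid,
               theta_high = zc * se_grid)
  }))
  structure(list(points = data.frame(trial_id = e$trial_id %||% seq_len(k),
                                     theta = e$theta, se = e$se, p = pval,
                                     band = band, stringsAsFactors = FALSE),
                 pooled_theta = if (!is.null(pooled)) pooled$theta else NA_real_,
                 contour_levels = contour_levels, contours = contours,
                 eligible = k >= min_trials, k = k,
                 min_trials = min_trials,
                 any_significant = any(pval < 0.05)),
            class = "funnel_data")
}

#' @export
print.funnel_data <- function(x, ...) {
  cat(sprintf("Funnel data: %d trials (%s for funnel-based assessment)\n",
              x$k, if (x$eligible) "eligible" else "NOT eligible"))
  if (!x$any_significant)
    cat("  no trial is statistically significant: publication bias is not a plausible explanation for asymmetry\n")
  invisible(x)
}

#' Egger regression test for funnel asymmetry
#'
#' Ordinary least squares of the standard normal deviate \eqn{\theta_i/se_i}
#' on precision \eqn{1/se_i}; the intercept measures small-study asymmetry
#' and is tested against zero with k-2 degrees of freedom.
#'
#' @param effects data.frame with `theta` and `se` (k >= 3, SEs not all
#'   equal).
#' @param min_trials funnel eligibility threshold used for the caution
#'   warning.
#' @return List with `intercept`, `se`, `t`, `p`, `df`.
#' @export
egger_test <- function(effects, min_trials = 10) {
  e <- as_effects(effects)
  k <- nrow(e)
  if (k < 3) stop("Egger test needs at least 3 trials")
  if (length(unique(e$se)) == 1L)
    stop("degenerate design: all standard errors equal, precision has no spread")
  .check_funnel_k(k, min_trials, "Egger test")
  fit <- stats::lm(I(theta / se) ~ I(1 / se), data = e)
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], se = sm[1, 2], t = sm[1, 3], p = sm[1, 4],
       df = k - 2L)
}

#' Begg rank-correlation test for funnel asymmetry
#'
#' Kendall rank correlation between the variance-stabilised deviates
#' \eqn{(\theta_i - \hat\theta_F)/\sqrt{v_i - v_F}} and the variances
#' \eqn{v_i}, with the tie-corrected normal approximation for the P-value.
#' Trials with \eqn{v_i \le v_F} (possible only in degenerate settings) fall
#' back to the unstabilised denominator \eqn{\sqrt{v_i}} and are flagged.
#'
#' @inheritParams egger_test
#' @return List with `tau` (tau-b), `S` (Kendall score), `z`, `p`,
#'   `fallback_trials`.
#' @export
begg_test <- function(effects, min_trials = 10) {
  e <- as_effects(effects)
  k <- nrow(e)
  if (k < 3) stop("Begg test needs at least 3 trials")
  .check_funnel_k(k, min_trials, "Begg test")
  fe <- fixed_effect_pool(e)
  v <- e$se^2
  v_f <- fe$se^2
  denom2 <- v - v_f
  fallback <- denom2 <= 0
  denom2[fallback] <- v[fallback]
  u <- (e$theta - fe$theta) / sqrt(denom2)
  # Kendall score with tie-corrected normal approximation
  S <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    S <- S + sign(u[j] - u[i]) * sign(v[j] - v[i])
  n0 <- k * (k - 1) / 2
  tie_term <- function(x) {
    tt <- table(x); tt <- tt[tt > 1]
    list(n1 = sum(tt * (tt - 1) / 2),
         var = sum(tt * (tt - 1) * (2 * tt + 5)))
  }
  tu <- tie_term(u); tv <- tie_term(v)
  tau <- S / sqrt((n0 - tu$n1) * (n0 - tv$n1))
  varS <- (k * (k - 1) * (2 * k + 5) - tu$var - tv$var) / 18
  z <- if (varS > 0) S / sqrt(varS) else 0
  list(tau = tau, S = S, z = z, p = 2 * stats::pnorm(-abs(z)),
       fallback_trials = which(fallback))
}

#' Harbord score-based test for funnel asymmetry (dichotomous outcomes)
#'
#' For each 2x2 table, the score \eqn{Z_i = a_i - E_i} (observed minus
#' expected experimental events) and Fisher information \eqn{V_i}; the test
#' regresses \eqn{Z_i/\sqrt{V_i}} on \eqn{\sqrt{V_i}} (each response has unit
#' variance under the null, so ordinary least squares applies) and tests the
#' intercept with k-2 degrees of freedom. Designed for the log odds ratio
#' scale and applicable to dichotomous outcomes only.
#'
#' @param trials trial table rows for one dichotomous outcome.
#' @param min_trials funnel eligibility threshold for the caution warning.
#' @return List with `intercept`, `se`, `t`, `p`, `df`, and the per-trial
#'   `score` data.frame (Z, V).
#' @export
harbord_test <- function(trials, min_trials = 10) {
  trials <- as.data.frame(trials)
  if (any(trial_data_type(trials) != "dichotomous"))
    stop("not applicable: Harbord test requires dichotomous 2x2 tables")
  k <- nrow(trials)
  if (k < 3) stop("Harbord test needs at least 3 trials")
  .check_funnel_k(k, min_trials, "Harbord test")
  l_e <- ifelse(is.na(trials$lost_exp), 0, trials$lost_exp)
  l_c <- ifelse(is.na(trials$lost_ctl), 0, trials$lost_ctl)
  n1 <- trials$randomised_exp - l_e
  n2 <- trials$randomised_ctl - l_c
  a <- trials$events_exp; c_ <- trials$events_ctl
  N <- n1 + n2; mrg <- a + c_
  E <- n1 * mrg / N
  V <- n1 * n2 * mrg * (N - mrg) / (N^2 * (N - 1))
  if (any(V <= 0)) stop("degenerate 2x2 table (no events or all events) in the set")
  y <- (a - E) / sqrt(V); x <- sqrt(V)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)$coefficients
  list(intercept = sm[1, 1], se = sm[1, 2], t = sm[1, 3], p = sm[1, 4],
       df = k - 2L, score = data.frame(Z = a - E, V = V))
}

#' Duval-Tweedie trim-and-fill adjustment
#'
#' Iteratively estimates the number k0 of studies suppressed from one side of
#' the funnel, trims the k0 most extreme studies on the excess side,
#' re-centres by fixed-effect pooling, and repeats until k0 stabilises; the
#' trimmed studies are then restored together with their mirror images about
#' the trimmed centre, and both fixed- and random-effects results are
#' re-estimated on the augmented set. The L0 estimator
#' \eqn{(4 T_n - n(n+1))/(2n-1)} (rank sum of the excess side) is the
#' default; R0 (rightmost-run length minus 1) is available. Adjusted results
#' are hypothesis-generating only.
#'
#' @param effects data.frame with `theta` and `se` (k >= 3).
#' @param side `"auto"` (sign of the signed-rank imbalance), `"left"` or
#'   `"right"`: the side of the funnel with the excess of observed studies.
#' @param estimator `"L0"` (default) or `"R0"`.
#' @param level confidence level for the adjusted pooled results.
#' @param hksj use HKSJ for the adjusted random-effects result.
#' @param maxiter iteration cap.
#' @return A `trimfill_result`: `k0`, `side`, `filled` (imputed points),
#'   `adjusted` (a `model_pair` on observed + filled), `centre`.
#' @export
trim_and_fill <- function(effects, side = c("auto", "left", "right"),
                          estimator = c("L0", "R0"), level = 0.95,
                          hksj = TRUE, maxiter = 50L) {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  e <- as_effects(effects)
  n <- nrow(e)
  if (n < 3) stop("trim-and-fill needs at least 3 trials")
  flip <- FALSE
  if (side == "auto") {
    ctr <- fixed_effect_pool(e)$theta
    d <- e$theta - ctr
    r <- rank(abs(d))
    r[d == 0] <- 0
    side <- if (sum(r * sign(d)) >= 0) "right" else "left"
  }
  if (side == "left") { e$theta <- -e$theta; flip <- TRUE }
  # iterate: centre on the trimmed set, estimate k0 from all observed points
  k0 <- 0L
  for (it in seq_len(maxiter)) {
    ord <- order(e$theta)           # trim the k0 largest (right-side extreme)
    keep <- if (k0 > 0) ord[seq_len(n - k0)] else ord
    ctr <- fixed_effect_pool(e[keep, , drop = FALSE])$theta
    d <- e$theta - ctr
    nz <- d != 0                    # zero deviations excluded from the rank sum
    r <- rank(abs(d[nz]))           # midranks for ties
    nn <- sum(nz)
    k0_new <- if (estimator == "L0") {
      Tn <- sum(r[d[nz] > 0])
      max(0L, as.integer(round((4 * Tn - nn * (nn + 1)) / (2 * nn - 1))))
    } else {
      sgn <- sign(d[nz])[order(r)]  # signs ordered by |deviation| rank
      run <- 0L
      for (s in rev(sgn)) { if (s > 0) run <- run + 1L else break }
      max(0L, run - 1L)
    }
    k0_new <- min(k0_new, n - 1L)
    if (k0_new == k0 && it > 1L) break
    k0 <- k0_new
  }
  filled <- NULL
  if (k0 > 0) {
    ord <- order(e$theta)
    trimmed_idx <- ord[(n - k0 + 1):n]
    ctr <- fixed_effect_pool(e[ord[seq_len(n - k0)], , drop = FALSE])$theta
    filled <- data.frame(trial_id = paste0("fill_", seq_len(k0)),
                         theta = 2 * ctr - e$theta[trimmed_idx],
                         se = e$se[trimmed_idx], stringsAsFactors = FALSE)
  } else {
    ctr <- fixed_effect_pool(e)$theta
  }
  aug <- rbind(e[, c("theta", "se")],
               if (!is.null(filled)) filled[, c("theta", "se")])
  if (flip) {
    aug$theta <- -aug$theta
    ctr <- -ctr
    if (!is.null(filled)) filled$theta <- -filled$theta
  }
  structure(list(k0 = k0, side = side, filled = filled, centre = ctr,
                 adjusted = pool_pair(aug, level, hksj)),
            class = "trimfill_result")
}

#' @export
print.trimfill_result <- function(x, ...) {
  cat(sprintf("Trim-and-fill: k0 = %d imputed studies (%s side)\n", x$k0, x$side))
  cat(sprintf("  adjusted pooled (%s): %.4f [hypothesis generating]\n",
              x$adjusted$primary_model, primary_result(x$adjusted)$theta))
  invisible(x)
}

#' Publication-bias assessment block
#'
#' Applies the eligibility rule (no funnel-based assessment below
#' `min_trials` trials), runs the asymmetry tests and trim-and-fill when
#' eligible, and suppresses the publication-bias flag entirely when no trial
#' is individually significant (asymmetry then has no publication-bias
#' explanation).
#'
#' @param effects data.frame from [trial_effects()].
#' @param trials matching trial table rows (for the Harbord test), optional.
#' @param pooled reference `pooled_result`.
#' @param min_trials eligibility threshold (default 10).
#' @param level confidence level for trim-and-fill pooled results.
#' @return List with `assessed`, `funnel`, `egger`, `begg`, `harbord`,
#'   `trimfill`, `flag_suppressed`.
#' @export
publication_bias_block <- function(effects, trials = NULL, pooled = NULL,
                                   min_trials = 10, level = 0.95) {
  fd <- funnel_data(effects, pooled, min_trials)
  out <- list(assessed = fd$eligible, funnel = fd, egger = NULL, begg = NULL,
              harbord = NULL, trimfill = NULL,
              flag_suppressed = !fd$any_significant)
  if (!fd$eligible) return(out)
  out$egger <- tryCatch(egger_test(effects, min_trials), error = function(e) NULL)
  out$begg <- tryCatch(begg_test(effects, min_trials), error = function(e) NULL)
  if (!is.null(trials) && all(trial_data_type(trials) == "dichotomous"))
    out$harbord <- tryCatch(harbord_test(trials, min_trials),
                            error = function(e) NULL)
  out$trimfill <- tryCatch(trim_and_fill(effects, level = level),
                           error = function(e) NULL)
  out
}

#' Funnel plot-data export
#'
#' Writes the per-trial funnel points (with contour band ids and filled-point
#' markers when a trim-and-fill result is supplied) as TSV.
#'
#' @param fd a `funnel_data` object.
#' @param trimfill optional `trimfill_result` whose filled points are
#'   appended.
#' @param path optional output path.
#' @return The export data.frame, invisibly if written.
#' @export
funnel_export <- function(fd, trimfill = NULL, path = NULL) {
  pts <- fd$points
  pts$filled <- FALSE
  if (!is.null(trimfill) && !is.null(trimfill$filled)) {
    f <- trimfill$filled
    pts <- rbind(pts, data.frame(trial_id = f$trial_id, theta = f$theta,
                                 se = f$se, p = NA_real_, band = NA_integer_,
                                 filled = TRUE, stringsAsFactors = FALSE))
  }
  if (!is.null(path)) {
    utils::write.table(pts, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(pts))
  }
  pts
}
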