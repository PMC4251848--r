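# Fixture builders and independent oracles shared across test files.

# quick dichotomous trial table; vectors recycle across k trials
make_dich_trials <- function(k = 3, events_exp = 10, randomised_exp = 100,
                             lost_exp = 0, events_ctl = 20,
                             randomised_ctl = 100, lost_ctl = 0,
                             rob = "low", outcome_id = "out1",
                             year = NULL) {
  df <- data.frame(trial_id = sprintf("t%02d", seq_len(k)),
                   year = year %||% (2000 + seq_len(k)),
                   outcome_id = outcome_id,
                   events_exp = events_exp, randomised_exp = randomised_exp,
                   lost_exp = lost_exp, events_ctl = events_ctl,
                   randomised_ctl = randomised_ctl, lost_ctl = lost_ctl,
                   stringsAsFactors = FALSE)
  for (d in octostep::rob_domains()) df[[d]] <- rob
  octostep::trial_table(df)
}

make_cont_trials <- function(k = 3, mean_exp = 12, sd_exp = 4, analysed_exp = 16,
                             lost_exp = 0, mean_ctl = 10, sd_ctl = 4,
                             analysed_ctl = 16, lost_ctl = 0, rob = "low",
                             outcome_id = "out1") {
  df <- data.frame(trial_id = sprintf("t%02d", seq_len(k)),
                   year = 2000 + seq_len(k), outcome_id = outcome_id,
                   mean_exp = mean_exp, sd_exp = sd_exp,
                   analysed_exp = analysed_exp, lost_exp = lost_exp,
                   mean_ctl = mean_ctl, sd_ctl = sd_ctl,
                   analysed_ctl = analysed_ctl, lost_ctl = lost_ctl,
                   stringsAsFactors = FALSE)
  for (d in octostep::rob_domains()) df[[d]] <- rob
  octostep::trial_table(df)
}

make_effects <- function(theta, se, trial_id = NULL, year = NULL,
                         n_total = 100) {
  data.frame(trial_id = trial_id %||% sprintf("t%02d", seq_along(theta)),
             year = year %||% (2000 + seq_along(theta)),
             theta = theta, se = se, n_total = n_total,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent group-sequential boundary oracle: fixed full-range Simpson grid
# with explicit continuation masking, bounds found by bisection on the
# incremental crossing probability. Deliberately a different discretisation
# and search than the package engine.
oracle_gs_bounds <- function(frac, spend, drift = 0, ngrid = 4001, zmax = 8,
                             onesided = FALSE) {
  stopifnot(ngrid %% 2 == 1)
  z <- seq(-zmax, zmax + if (onesided) 2 * abs(drift) else 0,
           length.out = ngrid)
  h <- z[2] - z[1]
  simp <- h / 3 * c(1, rep(c(4, 2), length.out = ngrid - 2), 1)
  K <- length(frac)
  bounds <- numeric(K)
  dens <- NULL
  for (k in seq_len(K)) {
    t1 <- frac[k]
    if (k == 1) {
      f_k <- stats::dnorm(z, drift * sqrt(t1), 1)
    } else {
      t0 <- frac[k - 1]
      s <- sqrt((t1 - t0) / t1)
      mu_inc <- drift * (t1 - t0) / sqrt(t1)
      kern <- outer(z, z * sqrt(t0 / t1) + mu_inc,
                    function(a, b) stats::dnorm(a, b, s))
      f_k <- as.numeric(kern %*% (simp * dens))
    }
    pik <- spend[k] - if (k == 1) 0 else spend[k - 1]
    if (onesided) {
      crossed <- function(b) sum((simp * f_k)[z <= b])
      lo <- min(z); hi <- max(z)
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        if (crossed(mid) < pik) lo <- mid else hi <- mid
      }
      bounds[k] <- (lo + hi) / 2
      dens <- f_k * (z > bounds[k])
    } else {
      crossed <- function(b) sum((simp * f_k)[abs(z) >= b])
      lo <- 0; hi <- max(z)
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        if (crossed(mid) > pik) lo <- mid else hi <- mid
      }
      bounds[k] <- (lo + hi) / 2
      dens <- f_k * (abs(z) < bounds[k])
    }
  }
  bounds
}

oracle_obf_spend <- function(t, a) 2 * (1 - stats::pnorm(stats::qnorm(1 - a / 2) / sqrt(pmin(t, 1))))
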