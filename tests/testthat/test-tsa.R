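sp_dich <- outcome_spec("o", "primary", "dichotomous", "lower",
                        mu_A = log(0.8), p_c = 0.10)
sp_cont <- outcome_spec("o2", "primary", "continuous", "lower",
                        mu_A = -0.5, anticipated_sd = 2)

test_that("required information size matches the power-formula worked example", {
  r0 <- required_information_size(sp_dich, 0.05, 0.10, D2 = 0,
                                  apply_fallback = FALSE)
  expect_equal(r0$n_fixed, 8606)
  expect_equal(r0$dis, r0$n_fixed)

  r25 <- required_information_size(sp_dich, 0.05, 0.10, D2 = 0.25)
  expect_equal(r25$dis, 11475)
  expect_false(r25$fallback_used)

  # zero observed diversity triggers the 25% fallback in a random-effects RIS
  rf <- required_information_size(sp_dich, 0.05, 0.10, D2 = 0)
  expect_true(rf$fallback_used)
  expect_equal(rf$D2_used, 0.25)
  expect_equal(rf$dis, 11475)

  expect_error(required_information_size(sp_dich, 0.05, 0.10, D2 = 1), "D2")
  big <- outcome_spec("o", "primary", "dichotomous", "higher", mu_A = 3, p_c = 0.3)
  expect_error(required_information_size(big, 0.05, 0.1, 0), "outside")
})

test_that("doubling the anticipated mean difference quarters the information size", {
  r1 <- required_information_size(sp_cont, 0.05, 0.10, 0, apply_fallback = FALSE)
  sp2 <- outcome_spec("o2", "primary", "continuous", "lower", mu_A = -1,
                      anticipated_sd = 2)
  r2 <- required_information_size(sp2, 0.05, 0.10, 0, apply_fallback = FALSE)
  expect_equal(r1$n_fixed_raw / r2$n_fixed_raw, 4, tolerance = 1e-12)
})

test_that("the O'Brien-Fleming spending function behaves at its anchors", {
  expect_equal(alpha_spent(1, 0.05), 0.05, tolerance = 1e-12)
  expect_equal(alpha_spent(0.5, 0.05),
               2 * (1 - pnorm(qnorm(0.975) / sqrt(0.5))), tolerance = 1e-15)
  expect_equal(alpha_spent(0.5, 0.05), 0.0055746, tolerance = 1e-5)
  expect_lt(alpha_spent(0.1, 0.05), 1e-8)
  expect_equal(alpha_spent(1.7, 0.05), 0.05)   # clamped above full information
  expect_error(alpha_spent(0, 0.05), "> 0")
})

test_that("a single look at full information gives the fixed-sample boundary", {
  b <- monitoring_boundaries(1, 0.05)
  expect_equal(b$upper, qnorm(0.975), tolerance = 1e-9)
  expect_equal(b$upper, 1.95996, tolerance = 1e-5)
})

test_that("boundaries match the independent recursive-integration oracle", {
  fr <- c(0.5, 1)
  b <- monitoring_boundaries(fr, 0.05)
  # first look is analytic: z quantile of half the spent error
  expect_equal(b$upper[1], qnorm(1 - alpha_spent(0.5, 0.05) / 2), tolerance = 1e-9)
  expect_equal(b$upper[1], 2.7718, tolerance = 1e-4)
  orc <- oracle_gs_bounds(fr, oracle_obf_spend(fr, 0.05))
  expect_equal(b$upper, orc, tolerance = 1e-3)

  fr4 <- c(0.25, 0.5, 0.75, 1)
  b4 <- monitoring_boundaries(fr4, 0.05, nodes = 1024)   # double resolution
  orc4 <- oracle_gs_bounds(fr4, oracle_obf_spend(fr4, 0.05))
  expect_equal(b4$upper, orc4, tolerance = 1e-3)
  expect_true(all(diff(b4$upper) <= 0))    # OBF boundaries shrink with information

  fr5 <- c(0.2, 0.45, 0.6, 0.8, 1)
  b5 <- monitoring_boundaries(fr5, 0.01)
  orc5 <- oracle_gs_bounds(fr5, oracle_obf_spend(fr5, 0.01))
  expect_equal(b5$upper, orc5, tolerance = 1e-3)

  expect_error(monitoring_boundaries(c(0.5, 0.5), 0.05), "strictly increasing")
  expect_error(monitoring_boundaries(c(-0.1, 0.5), 0.05), "> 0")
})

test_that("early looks with underflowing spending are capped and flagged", {
  b <- monitoring_boundaries(c(0.02, 0.5, 1), 0.05)
  expect_equal(b$upper[1], 8)
  expect_true(b$capped[1])
  expect_false(any(b$capped[-1]))
  # fractions beyond 1 fall back to the fixed-sample threshold
  b2 <- monitoring_boundaries(c(0.5, 1.2), 0.05)
  expect_true(b2$fixed_sample[2])
  expect_equal(b2$upper[2], qnorm(0.975), tolerance = 1e-12)
})

test_that("futility bounds close at the conventional value and match the oracle", {
  ris <- required_information_size(sp_dich, 0.05, 0.10, 0, apply_fallback = FALSE)
  # at full information with drift from an exactly-powered DIS the wedge
  # closes at (essentially) the fixed-sample critical value
  f1 <- futility_boundaries(1, 0.05, 0.10, drift = qnorm(0.975) + qnorm(0.90))
  expect_equal(f1$fut_upper, qnorm(0.975), tolerance = 1e-9)

  # very early look: wedge empty
  fe <- futility_boundaries(c(0.1, 1), 0.05, 0.10, drift = ris$drift)
  expect_false(fe$present[1])

  fr <- c(0.5, 1)
  fb <- futility_boundaries(fr, 0.05, 0.10, drift = ris$drift)
  spend_b <- 2 * (1 - pnorm(qnorm(1 - 0.10 / 2) / sqrt(fr)))
  orc <- oracle_gs_bounds(fr, spend_b, drift = ris$drift, onesided = TRUE)
  orc <- pmin(orc, qnorm(0.975))
  expect_equal(fb$fut_upper, orc, tolerance = 1e-2)
  expect_equal(fb$fut_lower, -fb$fut_upper)
  expect_error(futility_boundaries(fr, 0.05, 0.10, drift = -1), "drift")
})

test_that("the cumulative z-curve equals per-prefix pooling", {
  e1 <- make_effects(0.4, 0.2)
  z1 <- cumulative_z_curve(e1, "fixed", dis = 1000)
  expect_equal(z1$z, 2)

  opp <- make_effects(c(0.5, -0.5), c(0.2, 0.2))
  z2 <- cumulative_z_curve(opp, "fixed", dis = 1000)
  expect_equal(z2$z[2], 0, tolerance = 1e-12)

  e3 <- make_effects(c(0.3, 0.1, 0.5), c(0.3, 0.2, 0.25), n_total = c(120, 250, 90))
  for (model in c("fixed", "random")) {
    zc <- cumulative_z_curve(e3, model, dis = 700)
    for (k in 1:3) {
      fit <- if (model == "fixed") fixed_effect_pool(e3[1:k, ])
             else dersimonian_laird_pool(e3[1:k, ])
      expect_equal(zc$z[k], fit$theta / fit$se, tolerance = 1e-12)
      expect_equal(zc$t[k], sum(e3$n_total[1:k]) / 700, tolerance = 1e-12)
    }
  }
})

test_that("crossing assessment finds the first boundary crossing", {
  zc <- data.frame(look = 1:2, t = c(0.5, 0.9), z = c(1.0, 2.5))
  bd <- data.frame(t = c(0.5, 0.9), upper = c(2.77, 1.98), lower = -c(2.77, 1.98))
  cr <- assess_crossing(zc, bd)
  expect_equal(cr$crossing, "benefit")
  expect_equal(cr$look, 2L)

  none <- assess_crossing(data.frame(t = c(0.3, 0.5), z = c(0.4, -0.3)),
                          data.frame(t = c(0.3, 0.5), upper = c(4, 3.2),
                                     lower = -c(4, 3.2)))
  expect_equal(none$crossing, "none")

  # beyond full information the fixed-sample threshold applies
  late <- assess_crossing(data.frame(t = 1.2, z = 2.0),
                          data.frame(t = 1.2, upper = 8, lower = -8),
                          alpha = 0.05)
  expect_equal(late$crossing, "benefit")

  # negative z is benefit when the anticipated effect is negative
  harm <- assess_crossing(data.frame(t = 1.2, z = 2.0),
                          data.frame(t = 1.2, upper = 8, lower = -8),
                          benefit_sign = -1, alpha = 0.05)
  expect_equal(harm$crossing, "harm")

  fut <- assess_crossing(data.frame(t = c(0.8), z = c(0.2)),
                         data.frame(t = 0.8, upper = 2.4, lower = -2.4),
                         futility = data.frame(t = 0.8, fut_upper = 1.1,
                                               fut_lower = -1.1, present = TRUE))
  expect_equal(fut$crossing, "futility")
})

test_that("the TSA-adjusted CI widens to the current boundary", {
  expect_equal(tsa_adjusted_ci(0.5, 0.2, qnorm(0.975)),
               c(0.5 - qnorm(0.975) * 0.2, 0.5 + qnorm(0.975) * 0.2))
  ci <- tsa_adjusted_ci(0.5, 0.2, 2.7718)
  expect_equal(ci, c(-0.05436, 1.05436), tolerance = 1e-5)
  conv <- tsa_adjusted_ci(0.5, 0.2, qnorm(0.975))
  expect_true(ci[1] <= conv[1] && ci[2] >= conv[2])
})

test_that("the full TSA wrapper integrates z-curve, boundaries and verdicts", {
  # strong consistent effect over many participants: benefit crossed
  e <- make_effects(rep(log(0.7), 8), rep(0.09, 8), n_total = rep(1500, 8))
  ris <- required_information_size(sp_dich, 0.05, 0.10, 0, apply_fallback = FALSE)
  ts <- tsa(e, ris, model = "fixed")
  expect_s3_class(ts, "tsa_result")
  expect_equal(ts$benefit_sign, -1)        # benefit = risk reduction, log scale
  expect_equal(ts$crossing, "benefit")
  expect_equal(nrow(ts$looks), 8)
  expect_true(all(diff(ts$looks$t) > 0))
  out <- tsa_data(ts)
  expect_true(all(c("t", "z", "upper", "lower", "fut_upper") %in% names(out)))
})

test_that("simulated Brownian z-statistics cross at the spent-error rate", {
  # independent check of the boundary calibration: simulate the sequential
  # z process directly from its independent-increments structure
  fr <- seq(0.2, 1, by = 0.2)
  b <- monitoring_boundaries(fr, 0.05)
  nsim <- 40000
  set.seed(99)
  incr <- matrix(rnorm(nsim * 5), nsim, 5) %*% diag(sqrt(diff(c(0, fr))))
  w <- t(apply(incr, 1, cumsum))
  z <- sweep(w, 2, sqrt(fr), "/")
  crossed_by <- t(apply(abs(z) >= matrix(b$upper, nsim, 5, byrow = TRUE), 1, cummax))
  rate <- colMeans(crossed_by)
  target <- alpha_spent(fr, 0.05)
  mcse <- sqrt(target * (1 - target) / nsim)
  expect_true(all(abs(rate - target) < pmax(3 * mcse, 5e-4)))
})
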