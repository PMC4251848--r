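mirrored_effects <- function(k_half = 6, base_se = 0.1) {
  # exactly symmetric funnel about 0 with a spread of SEs
  se <- base_se * seq(1, 3, length.out = k_half)
  make_effects(c(se * 1.2, -se * 1.2), c(se, se))
}

test_that("funnel eligibility follows the 10-trial rule", {
  e9 <- make_effects(rnorm(9), runif(9, 0.1, 0.4))
  expect_false(funnel_data(e9)$eligible)
  e10 <- make_effects(rnorm(10), runif(10, 0.1, 0.4))
  expect_true(funnel_data(e10)$eligible)

  # the P = 0.05 contour passes through |theta| = 1.95996 * SE
  pt <- funnel_data(make_effects(qnorm(0.975) * 0.2, 0.2))
  expect_equal(pt$points$p, 0.05, tolerance = 1e-10)
  ctr <- pt$contours[pt$contours$level == 0.05, ]
  expect_equal(ctr$theta_high, qnorm(0.975) * ctr$se, tolerance = 1e-12)
})

test_that("publication-bias block gates on eligibility and significance", {
  set.seed(41)
  e9 <- make_effects(rnorm(9, 0, 0.05), runif(9, 0.1, 0.4))
  blk <- publication_bias_block(e9)
  expect_false(blk$assessed)
  expect_null(blk$egger)

  e12 <- make_effects(rnorm(12, 0, 0.01), rep_len(c(0.2, 0.3, 0.4), 12))
  blk2 <- publication_bias_block(e12)
  expect_true(blk2$assessed)
  expect_false(is.null(blk2$egger))
  # nothing individually significant: publication-bias flag suppressed
  expect_true(blk2$flag_suppressed)

  # tests remain callable below the threshold, with a warning
  expect_warning(egger_test(e9), "caution")
})

test_that("Egger regression matches the normal-equations oracle", {
  e <- mirrored_effects()              # 12 trials: no eligibility warning
  sym <- egger_test(e)
  expect_equal(sym$intercept, 0, tolerance = 1e-10)

  expect_error(egger_test(make_effects(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
  expect_error(egger_test(make_effects(rnorm(5), rep(0.2, 5))), "degenerate")

  set.seed(43)
  th <- rnorm(12, 0.3, 0.3); se <- runif(12, 0.08, 0.5)
  eg <- egger_test(make_effects(th, se))
  X <- cbind(1, 1 / se); y <- th / se
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (12 - 2)
  se_b <- sqrt(s2 * solve(t(X) %*% X)[1, 1])
  expect_equal(eg$intercept, beta[1], tolerance = 1e-10)
  expect_equal(eg$se, se_b, tolerance = 1e-10)
  expect_equal(eg$t, beta[1] / se_b, tolerance = 1e-10)
  expect_equal(eg$p, 2 * pt(-abs(beta[1] / se_b), 10), tolerance = 1e-12)
})

test_that("Begg rank correlation matches brute-force pair counting", {
  e <- mirrored_effects()
  sym <- begg_test(e)
  expect_lt(abs(sym$tau), 0.2)

  expect_error(begg_test(make_effects(c(1, 2), c(0.1, 0.2))), "at least 3")

  set.seed(47)
  th <- rnorm(11, 0.2, 0.4); se <- runif(11, 0.1, 0.5)
  e2 <- make_effects(th, se)
  bg <- begg_test(e2)
  fe <- fixed_effect_pool(e2)
  v <- se^2
  u <- (th - fe$theta) / sqrt(v - fe$se^2)
  S <- 0
  for (i in 1:10) for (j in (i + 1):11)
    S <- S + sign(u[j] - u[i]) * sign(v[j] - v[i])
  expect_equal(bg$S, S)
  expect_true(bg$p > 0 && bg$p <= 1)
})

test_that("Begg attains |tau| = 1 on a perfectly monotone configuration", {
  # construct so the standardised deviates strictly increase with variance
  se <- seq(0.2, 1, length.out = 6)
  th <- cumsum(se) * 2
  e <- make_effects(th, se)
  expect_warning(bg <- begg_test(e), "caution")
  expect_equal(abs(bg$tau), 1, tolerance = 1e-12)
})

test_that("Harbord score test matches hand-computed scores and information", {
  tr <- make_dich_trials(3, events_exp = c(10, 4, 20), randomised_exp = c(100, 40, 220),
                         events_ctl = c(15, 7, 25), randomised_ctl = c(100, 45, 200))
  expect_warning(hb <- harbord_test(tr), "caution")
  a <- c(10, 4, 20); c_ <- c(15, 7, 25); n1 <- c(100, 40, 220); n2 <- c(100, 45, 200)
  N <- n1 + n2; m1 <- a + c_
  Z <- a - n1 * m1 / N
  V <- n1 * n2 * m1 * (N - m1) / (N^2 * (N - 1))
  expect_equal(hb$score$Z, Z, tolerance = 1e-10)
  expect_equal(hb$score$V, V, tolerance = 1e-10)
  fit <- lm(I(Z / sqrt(V)) ~ I(sqrt(V)))
  expect_equal(hb$intercept, unname(coef(fit)[1]), tolerance = 1e-10)

  # balanced null tables: all scores zero, intercept zero
  bal <- make_dich_trials(4, events_exp = c(5, 10, 15, 20),
                          randomised_exp = c(50, 100, 150, 200),
                          events_ctl = c(5, 10, 15, 20),
                          randomised_ctl = c(50, 100, 150, 200))
  expect_warning(hb0 <- harbord_test(bal), "caution")
  expect_equal(hb0$intercept, 0, tolerance = 1e-10)

  expect_error(harbord_test(make_dich_trials(2)), "at least 3")
  expect_error(harbord_test(make_cont_trials(4)), "not applicable")
})

test_that("trim-and-fill is a fixed point on symmetric funnels", {
  e <- mirrored_effects()
  tf <- trim_and_fill(e)
  expect_equal(tf$k0, 0L)
  expect_null(tf$filled)
  expect_equal(primary_result(tf$adjusted)$theta,
               primary_result(pool_pair(e))$theta, tolerance = 1e-12)
  expect_error(trim_and_fill(make_effects(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("trim-and-fill k0 matches an independent L0 iteration and metafor", {
  # asymmetric fixture: mirrored set with its most-negative points deleted
  full <- mirrored_effects(8, 0.12)
  drop <- order(full$theta)[1:3]
  e <- full[-drop, , drop = FALSE]
  tf <- trim_and_fill(e, side = "right")

  # independent step-by-step iteration of the published L0 recursion
  th <- e$theta; se <- e$se; n <- length(th)
  k0 <- 0
  repeat {
    keep <- order(th)[seq_len(n - k0)]
    w <- 1 / se[keep]^2
    ctr <- sum(w * th[keep]) / sum(w)
    d <- th - ctr
    r <- rank(abs(d[d != 0]))
    Tn <- sum(r[d[d != 0] > 0])
    nn <- length(r)
    k0_new <- max(0, round((4 * Tn - nn * (nn + 1)) / (2 * nn - 1)))
    if (k0_new == k0) break
    k0 <- k0_new
  }
  expect_equal(tf$k0, as.integer(k0))
  expect_equal(tf$side, "right")
  if (tf$k0 > 0) {
    expect_equal(nrow(tf$filled), tf$k0)
    # filled points mirror the trimmed extremes about the trimmed centre
    expect_equal(sort(tf$centre - tf$filled$theta),
                 sort(sort(th, decreasing = TRUE)[seq_len(tf$k0)] - tf$centre),
                 tolerance = 1e-10)
  }

  # auto side detection picks the excess side
  expect_equal(trim_and_fill(e, side = "auto")$k0, tf$k0)

  skip_if_not_installed("metafor")
  rf <- metafor::rma(yi = e$theta, sei = e$se, method = "FE")
  mtf <- metafor::trimfill(rf, estimator = "L0")
  expect_equal(tf$k0, as.integer(mtf$k0))
})

test_that("funnel export marks filled points", {
  full <- mirrored_effects(8, 0.12)
  e <- full[-order(full$theta)[1:3], ]
  tf <- trim_and_fill(e, side = "right")
  fd <- funnel_data(e)
  ex <- funnel_export(fd, tf)
  expect_equal(sum(ex$filled), tf$k0)
  f <- tempfile(fileext = ".tsv")
  funnel_export(fd, tf, path = f)
  expect_true(file.exists(f))
})
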