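test_that("fixed-effect pooling matches hand computations", {
  one <- fixed_effect_pool(make_effects(0.3, 0.1))
  expect_equal(one$theta, 0.3)
  expect_equal(one$se, 0.1)

  two <- fixed_effect_pool(make_effects(c(-0.5, -0.5), c(0.1, 0.2)))
  expect_equal(two$theta, -0.5, tolerance = 1e-12)
  expect_equal(two$se, 1 / sqrt(125), tolerance = 1e-12)

  het <- fixed_effect_pool(make_effects(c(0, 1), c(0.1, 0.1)))
  expect_equal(het$theta, 0.5, tolerance = 1e-12)
  expect_equal(het$Q, 50, tolerance = 1e-12)
  expect_error(fixed_effect_pool(data.frame(theta = numeric(0), se = numeric(0))),
               "no effects")
})

test_that("DerSimonian-Laird pooling matches the worked example and truncates", {
  dl <- dersimonian_laird_pool(make_effects(c(0, 1), c(0.1, 0.1)))
  expect_equal(dl$tau2, 0.49, tolerance = 1e-12)   # C = 100, Q = 50
  expect_equal(dl$theta, 0.5, tolerance = 1e-12)
  expect_equal(dl$se, 0.5, tolerance = 1e-12)

  hom <- make_effects(c(0.2, 0.201, 0.199), c(0.3, 0.3, 0.3))
  dlh <- dersimonian_laird_pool(hom)
  expect_equal(dlh$tau2, 0)
  expect_equal(dlh$theta, fixed_effect_pool(hom)$theta, tolerance = 1e-12)
  expect_equal(dlh$se, fixed_effect_pool(hom)$se, tolerance = 1e-12)

  single <- dersimonian_laird_pool(make_effects(0.3, 0.1))
  expect_equal(single$model, "DL")
  expect_equal(single$tau2, 0)

  set.seed(11)
  for (i in 1:20) {
    e <- make_effects(rnorm(5), runif(5, 0.05, 0.5))
    expect_gte(dersimonian_laird_pool(e)$se, fixed_effect_pool(e)$se - 1e-12)
  }
})

test_that("HKSJ keeps the DL estimate, uses t inference, and handles degeneracy", {
  e <- make_effects(c(0, 1), c(0.1, 0.1))
  h <- hksj_adjust(e)
  expect_equal(h$theta, 0.5, tolerance = 1e-12)
  expect_equal(h$se, 0.5, tolerance = 1e-12)
  expect_equal(h$p, 0.5, tolerance = 1e-10)        # t statistic 1.0, 1 df
  expect_equal(h$dist, "t")

  same <- make_effects(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.3))
  expect_warning(hd <- hksj_adjust(same), "degenerate")
  expect_equal(hd$se, dersimonian_laird_pool(same)$se)

  expect_error(hksj_adjust(make_effects(0.3, 0.1)), "k >= 2")

  # under homogeneity HKSJ is usually at least as conservative as DL
  worse <- 0
  for (s in 1:200) {
    set.seed(s)
    e <- make_effects(rnorm(5, 0.2, 0.05), rep(0.05, 5))
    if (hksj_adjust(e)$p >= dersimonian_laird_pool(e)$p) worse <- worse + 1
  }
  expect_gte(worse / 200, 0.75)
})

test_that("heterogeneity statistics follow their definitions", {
  het <- heterogeneity_stats(make_effects(c(0, 1), c(0.1, 0.1)))
  expect_equal(het$I2, (50 - 1) / 50, tolerance = 1e-12)

  same <- heterogeneity_stats(make_effects(c(0.3, 0.3), c(0.1, 0.2)))
  expect_equal(same$Q, 0)
  expect_equal(same$I2, 0)

  # Q exactly k-1 sits on the I2 = 0 boundary
  k <- 3
  se <- rep(1, k)
  th <- c(-1, 0, 1) * sqrt((k - 1) / 2)  # gives Q = k - 1 exactly
  b <- heterogeneity_stats(make_effects(th, se))
  expect_equal(b$Q, k - 1, tolerance = 1e-12)
  expect_equal(b$I2, 0)

  na <- heterogeneity_stats(make_effects(0.2, 0.1))
  expect_true(is.na(na$Q) && is.na(na$I2))
})

test_that("diversity D2 relates the two model variances and bounds I2", {
  e <- make_effects(c(0, 1), c(0.1, 0.1))
  fe <- fixed_effect_pool(e); dl <- dersimonian_laird_pool(e)
  expect_equal(diversity_d2(fe, dl), 0.98, tolerance = 1e-12)

  hom <- make_effects(c(0.3, 0.3), c(0.1, 0.2))
  expect_equal(diversity_d2(fixed_effect_pool(hom), dersimonian_laird_pool(hom)), 0)

  mock_f <- structure(list(se = sqrt(0.1)), class = "pooled_result")
  mock_r <- structure(list(se = sqrt(0.2)), class = "pooled_result")
  expect_equal(diversity_d2(mock_f, mock_r), 0.5, tolerance = 1e-12)
  expect_error(diversity_d2(mock_f, structure(list(se = 0), class = "pooled_result")),
               "zero")

  set.seed(3)
  for (i in 1:20) {
    e <- make_effects(rnorm(6), runif(6, 0.05, 0.4))
    pair <- pool_pair(e, hksj = FALSE)
    if (pair$het$tau2 > 0)
      expect_gte(pair$D2, pair$het$I2 - 1e-12)
  }
})

test_that("conservative selection picks the larger P and ties go to random", {
  mk <- function(pf, pr) structure(list(fixed = list(p = pf), random = list(p = pr)),
                                   class = "model_pair")
  expect_equal(select_primary_result(mk(0.04, 0.12)), "random")
  expect_equal(select_primary_result(mk(0.30, 0.20)), "fixed")
  expect_equal(select_primary_result(mk(0.20, 0.20)), "random")

  hom <- make_effects(c(0.3, 0.3), c(0.1, 0.2))
  pair <- pool_pair(hom, hksj = FALSE)     # tau2 = 0: identical fits, tie
  expect_equal(pair$primary_model, "random")

  set.seed(5)
  for (i in 1:20) {
    e <- make_effects(rnorm(4, 0.3), runif(4, 0.05, 0.5))
    pair <- pool_pair(e)
    expect_gte(primary_result(pair)$p, max(pair$fixed$p, pair$random$p) - 1e-15)
  }
})

test_that("weight dominance flags one or two dominant trials", {
  mk <- function(shares) fixed_effect_pool(make_effects(rep(0.1, length(shares)),
                                                        1 / sqrt(shares)))
  expect_true(weight_dominance_flag(mk(c(0.85, 0.10, 0.05)), 80))
  expect_false(weight_dominance_flag(mk(rep(0.1, 10)), 80))
  expect_true(weight_dominance_flag(mk(c(0.45, 0.40, 0.15)), 80))
})

test_that("pooled estimates agree with brute-force weighted averages and metafor", {
  set.seed(9)
  for (i in 1:15) {
    k <- sample(2:4, 1)
    th <- rnorm(k); se <- runif(k, 0.05, 0.6)
    e <- make_effects(th, se)
    w <- 1 / se^2
    fe <- fixed_effect_pool(e)
    expect_equal(fe$theta, sum(w * th) / sum(w), tolerance = 1e-12)
    expect_equal(fe$se, sqrt(1 / sum(w)), tolerance = 1e-12)
    dl <- dersimonian_laird_pool(e)
    ws <- 1 / (se^2 + dl$tau2)
    expect_equal(dl$theta, sum(ws * th) / sum(ws), tolerance = 1e-12)
  }

  skip_if_not_installed("metafor")
  set.seed(21)
  th <- rnorm(8, 0.3, 0.4); se <- runif(8, 0.1, 0.5)
  e <- make_effects(th, se)
  fe <- fixed_effect_pool(e)
  rf <- metafor::rma(yi = th, sei = se, method = "FE")
  expect_equal(fe$theta, as.numeric(rf$beta), tolerance = 1e-10)
  expect_equal(fe$se, rf$se, tolerance = 1e-10)
  expect_equal(fe$p, rf$pval, tolerance = 1e-10)
  dl <- dersimonian_laird_pool(e)
  rd <- metafor::rma(yi = th, sei = se, method = "DL")
  expect_equal(dl$tau2, rd$tau2, tolerance = 1e-10)
  expect_equal(dl$theta, as.numeric(rd$beta), tolerance = 1e-10)
  expect_equal(dl$se, rd$se, tolerance = 1e-10)
  hk <- hksj_adjust(e)
  rk <- metafor::rma(yi = th, sei = se, method = "DL", test = "knha")
  expect_equal(hk$se, rk$se, tolerance = 1e-10)
  expect_equal(hk$p, rk$pval, tolerance = 1e-10)
  expect_equal(hk$ci, c(rk$ci.lb, rk$ci.ub), tolerance = 1e-8)
})

test_that("DL recovers tau2 on synthetic data and fixed CI covers under homogeneity", {
  tau2_hat <- numeric(300)
  for (r in seq_len(300)) {
    sim <- simulate_review(sim_spec(k = 50, true_effect = 0.3, tau = 0.3,
                                    data_type = "continuous", control_sd = 1,
                                    size_range = c(150, 150), loss_rate = 0,
                                    seed = 1000 + r))
    eff <- trial_effects(sim$trials, "MD")
    tau2_hat[r] <- dersimonian_laird_pool(eff)$tau2
  }
  expect_lt(abs(mean(tau2_hat) - 0.09) / 0.09, 0.15)

  cover <- 0
  for (r in seq_len(300)) {
    sim <- simulate_review(sim_spec(k = 10, true_effect = 0.3, tau = 0,
                                    data_type = "continuous", control_sd = 1,
                                    size_range = c(100, 100), loss_rate = 0,
                                    seed = 5000 + r))
    ci <- fixed_effect_pool(trial_effects(sim$trials, "MD"))$ci
    if (ci[1] <= 0.3 && 0.3 <= ci[2]) cover <- cover + 1
  }
  expect_gt(cover / 300, 0.92)
  expect_lt(cover / 300, 0.985)
})

test_that("forest data export has one row per trial plus pooled rows", {
  e <- make_effects(c(0.2, 0.4, 0.1), c(0.1, 0.2, 0.15))
  pair <- pool_pair(e)
  fd <- forest_data(e, pair)
  expect_equal(nrow(fd), 5L)
  expect_equal(sum(fd$weight_fixed, na.rm = TRUE), 1, tolerance = 1e-12)
})
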