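test_that("proportion descriptives are unweighted means, invariant to order", {
  r1 <- survey_record("a", 100, 0.5)
  r2 <- survey_record("b", 4000, 0.7)
  d <- rbind(r1, r2)
  s <- describe_proportions(d, "positive_attitude")
  expect_equal(s$mean, 0.6)
  expect_equal(s$sd, sd(c(0.5, 0.7)))
  expect_equal(s$n_surveys, 2)
  expect_equal(describe_proportions(d[2:1, ], "positive_attitude")$mean, 0.6)
})

test_that("success counts reconstruct within bounds and rounding is flagged", {
  r <- survey_record("a", 100, 0.8)
  expect_equal(round(r$proportion * r$n_respondents), 80)
  expect_warning(survey_record("b", 10, 0.234), "not an integer")
  set.seed(4)
  sv <- simulate_surveys(survey_sim_config(n_surveys = 20), seed = 2)
  succ <- round(sv$proportion * sv$n_respondents)
  expect_true(all(succ >= 0 & succ <= sv$n_respondents))
  expect_true(all(abs(sv$proportion * sv$n_respondents - succ) < 1e-8))
})

test_that("with no cluster variance the GLMM matches an ordinary weighted logistic fit", {
  set.seed(10)
  cfg <- survey_sim_config(n_surveys = 40, respondents_range = c(50000, 50000),
                           intercept = 0.4, beta_income_low = 1.2,
                           sd_intercept = 0)
  sv <- simulate_surveys(cfg, seed = 5)
  f <- fit_binomial_mixed(sv, "income")
  succ <- round(sv$proportion * sv$n_respondents)
  glm_fit <- glm(cbind(succ, sv$n_respondents - succ) ~ factor(sv$income),
                 family = binomial())
  expect_equal(unname(f$coefficients$estimate),
               unname(coef(glm_fit)), tolerance = 1e-3)
})

test_that("a logit-scale income effect of 2 is recovered", {
  set.seed(20)
  cfg <- survey_sim_config(n_surveys = 60, beta_income_low = 2,
                           sd_intercept = 0.5)
  errs <- sapply(1:20, function(r) {
    sv <- simulate_surveys(cfg, seed = 1000 + r)
    f <- fit_binomial_mixed(sv, "income")
    f$coefficients["incomelow", "estimate"] - 2
  })
  expect_lt(abs(mean(errs)), 0.3)
})

test_that("AICc has the stated closed form and approaches AIC with many surveys", {
  set.seed(30)
  sv <- simulate_surveys(survey_sim_config(n_surveys = 25), seed = 6)
  f0 <- fit_binomial_mixed(sv)                       # null model: p = 2
  expect_equal(f0$AICc, -2 * f0$loglik + 4 + 12 / (25 - 3), tolerance = 1e-10)
  sv_big <- simulate_surveys(survey_sim_config(n_surveys = 200), seed = 7)
  fb <- fit_binomial_mixed(sv_big)
  aic <- -2 * fb$loglik + 2 * fb$n_par
  expect_lt(fb$AICc - aic, 0.15)
  expect_gt(fb$AICc, aic)                            # correction always > 0
})

test_that("the AICc ranking is coherent and the two-model average is computable by hand", {
  set.seed(40)
  cfg <- survey_sim_config(n_surveys = 45, beta_income_low = 1.5,
                           sd_intercept = 0.4)
  sv <- simulate_surveys(cfg, seed = 8)
  rk <- dredge_and_average(sv, "income", delta = Inf)  # both models averaged
  expect_equal(nrow(rk$table), 2)
  expect_equal(min(rk$table$delta), 0)
  expect_true(all(rk$table$delta >= 0))
  expect_equal(sum(rk$table$weight), 1, tolerance = 1e-12)

  f0 <- fit_binomial_mixed(sv)
  f1 <- fit_binomial_mixed(sv, "income")
  w <- exp(-c(f0$AICc - min(f0$AICc, f1$AICc),
              f1$AICc - min(f0$AICc, f1$AICc)) / 2)
  w <- w / sum(w)
  # full averaging: the income coefficient is zero-substituted in the null model
  b_hand <- w[2] * f1$coefficients["incomelow", "estimate"]
  expect_equal(rk$averaged["incomelow", "estimate"], b_hand, tolerance = 1e-8)
  b_int <- w[1] * f0$coefficients["(Intercept)", "estimate"] +
    w[2] * f1$coefficients["(Intercept)", "estimate"]
  expect_equal(rk$averaged["(Intercept)", "estimate"], b_int, tolerance = 1e-8)
})

test_that("a strong true effect keeps its sign through averaging over null terms", {
  set.seed(50)
  cfg <- survey_sim_config(n_surveys = 45, beta_income_low = 2,
                           sd_intercept = 0.5)
  signs <- sapply(1:15, function(r) {
    sv <- simulate_surveys(cfg, seed = 2000 + r)
    rk <- dredge_and_average(sv, c("income", "climate", "stakeholder"))
    if ("incomelow" %in% rownames(rk$averaged))
      sign(rk$averaged["incomelow", "estimate"]) else 0
  })
  expect_gte(mean(signs == 1), 0.95)
})

test_that("averaged coefficients stay inside the per-model hull under conditional averaging", {
  set.seed(60)
  sv <- simulate_surveys(survey_sim_config(n_surveys = 45,
                                           beta_income_low = 1), seed = 9)
  rk <- dredge_and_average(sv, c("income", "climate"), delta = Inf,
                           method = "conditional")
  bs <- sapply(rk$fits, function(f)
    if ("incomelow" %in% rownames(f$coefficients))
      f$coefficients["incomelow", "estimate"] else NA)
  hull <- range(bs, na.rm = TRUE)
  b_avg <- rk$averaged["incomelow", "estimate"]
  expect_gte(b_avg, hull[1] - 1e-10)
  expect_lte(b_avg, hull[2] + 1e-10)
})

test_that("the Spearman trend test matches the rank formula and flags degenerate input", {
  expect_equal(spearman_trend(c(1, 3, 4, 8, 9, 15))$rho, 1)
  counts <- c(2, 1, 4, 3, 8, 6)                       # handmade, no ties
  st <- spearman_trend(counts)
  dsq <- sum((rank(counts) - 1:6)^2)
  expect_equal(st$rho, 1 - 6 * dsq / (6 * 35), tolerance = 1e-12)
  expect_lt(st$p, 0.2)
  expect_error(spearman_trend(rep(3, 6)), "constant")
  expect_error(spearman_trend(c(1, 2, 3)), "n >= 4")
})
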