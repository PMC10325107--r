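test_that("identical effects give the common value with zero heterogeneity", {
  d <- make_meta_df(c(0.5, 0.5), c(0.1, 0.1))
  f <- fit_multilevel(d)
  expect_equal(unname(f$b[1]), 0.5, tolerance = 1e-8)
  expect_lt(f$tau2_study, 1e-6)
  expect_equal(f$QE, 0, tolerance = 1e-12)
  expect_equal(f$QE_p, 1)
})

test_that("equal sampling variances reduce the pooled mean to the arithmetic mean", {
  set.seed(3)
  g <- rnorm(12, 0.3, 0.4)
  d <- make_meta_df(g, rep(0.05, 12))
  f <- fit_multilevel(d)
  expect_equal(unname(f$b[1]), mean(g), tolerance = 1e-9)
})

test_that("with one comparison per study mu is the closed-form weighted mean at the REML tau2", {
  set.seed(11)
  d <- draw_meta(25, mu = 0.3, tau2_study = 0.05)
  f <- fit_multilevel(d)
  expect_identical(f$random, "study")
  expect_identical(f$tau2_within, 0)
  w <- 1 / (d$v_g + f$tau2_study)
  expect_equal(unname(f$b[1]), sum(w * d$g) / sum(w), tolerance = 1e-9)
})

test_that("the multilevel REML fit matches an independent reference implementation", {
  skip_if_not_installed("metafor")
  set.seed(21)
  recs <- simulate_effects(effect_sim_config(n_studies = 18), seed = 9)
  es <- effect_sizes(recs)
  f <- fit_multilevel(es)
  m <- metafor::rma.mv(g, v_g, random = ~ 1 | study_id / comparison_id,
                       data = es, method = "REML", test = "z")
  expect_equal(unname(f$b[1]), unname(m$b[1, 1]), tolerance = 1e-6)
  expect_equal(unname(f$se[1]), unname(m$se[1]), tolerance = 1e-6)
  expect_equal(sort(c(f$tau2_study, f$tau2_within)), sort(m$sigma2),
               tolerance = 1e-4)
  expect_equal(f$QE, m$QE, tolerance = 1e-8)
  expect_equal(f$loglik_reml, as.numeric(stats::logLik(m)), tolerance = 1e-5)
  expect_equal(unname(f$ci_low[1]), unname(m$ci.lb[1]), tolerance = 1e-6)
})

test_that("QE equals the hand-computed weighted sum of squares and ignores study labels", {
  g <- c(0.1, 0.5, -0.2, 0.8, 0.3)
  v <- c(0.05, 0.1, 0.2, 0.08, 0.12)
  d <- make_meta_df(g, v)
  w <- 1 / v
  mu_fe <- sum(w * g) / sum(w)
  QE_hand <- sum(w * (g - mu_fe)^2)
  q <- q_test(d)
  expect_equal(q$QE, QE_hand, tolerance = 1e-12)
  expect_equal(q$df, 4)
  expect_equal(q$p, pchisq(QE_hand, 4, lower.tail = FALSE))
  # relabeling studies leaves QE unchanged
  d2 <- make_meta_df(g, v, study = c("a", "a", "b", "b", "c"))
  expect_equal(q_test(d2)$QE, QE_hand, tolerance = 1e-12)
})

test_that("the omnibus moderator test is null-calibrated and matches the reference", {
  skip_if_not_installed("metafor")
  # no subgroup difference, no heterogeneity: QM near 0, p near 1
  d0 <- make_meta_df(rep(0.4, 10), rep(0.05, 10),
                     climate = rep(c("tropics", "nontropics"), 5))
  mt0 <- moderator_test(d0, "climate")
  expect_lt(mt0$QM, 1e-8)
  expect_equal(mt0$p, 1, tolerance = 1e-6)

  set.seed(5)
  recs <- simulate_effects(effect_sim_config(
    n_studies = 20,
    moderators = list(climate = list(levels = c("tropics", "nontropics"),
                                     shifts = c(0, 0.5)))), seed = 13)
  es <- effect_sizes(recs)
  mt <- moderator_test(es, "climate")
  m <- metafor::rma.mv(g, v_g, mods = ~ factor(climate),
                       random = ~ 1 | study_id / comparison_id,
                       data = es, method = "REML", test = "z")
  expect_equal(mt$QM, m$QM, tolerance = 1e-4)
  expect_equal(mt$p, m$QMp, tolerance = 1e-4)
})

test_that("moderator power: a 0.8 subgroup difference is detected reliably", {
  set.seed(77)
  rej <- 0
  n_rep <- 100
  for (r in 1:n_rep) {
    d <- draw_meta(40, mu = 0, tau2_study = 0.04)
    grp <- rep(c("a", "b"), length.out = nrow(d))
    d$g <- d$g + ifelse(grp == "b", 0.8, 0)
    d$grp <- grp
    if (moderator_test(d, "grp")$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.8)
})

test_that("subgroup estimates recover level means and collapse to the overall fit", {
  set.seed(9)
  d <- draw_meta(30, mu = 0.2, tau2_study = 0.02)
  d$food <- "coffee"
  sub <- subgroup_estimates(d, "food")
  f <- fit_multilevel(d)
  expect_equal(sub$mu, unname(f$b[1]), tolerance = 1e-7)
  expect_equal(sub$k, nrow(d))

  # two well-separated levels recovered within Monte-Carlo error
  d2 <- draw_meta(60, mu = 0, tau2_study = 0.02)
  lev <- rep(c("apple", "coffee"), length.out = nrow(d2))
  d2$g <- d2$g + ifelse(lev == "apple", 0.7, -0.5)
  d2$food <- lev
  sub2 <- subgroup_estimates(d2, "food")
  expect_identical(sub2$level, c("apple", "coffee"))  # lexicographic
  expect_equal(sub2$mu[sub2$level == "apple"], 0.7, tolerance = 0.25)
  expect_equal(sub2$mu[sub2$level == "coffee"], -0.5, tolerance = 0.25)
})

test_that("the forest table is consistent with the fit and the effects", {
  d <- make_meta_df(c(0.2, 0.6), c(0.04, 0.09))
  f <- fit_multilevel(d)
  tab <- forest_summary(f, d)
  expect_equal(nrow(tab), 3)
  ov <- tab[tab$type == "overall", ]
  expect_equal(ov$g, unname(f$b[1]))
  expect_equal(ov$ci_low, unname(f$b[1] - qnorm(0.975) * f$se[1]))
  expect_equal(tab$ci_high[1], 0.2 + qnorm(0.975) * 0.2)
})

test_that("degenerate designs fail loudly and missing moderators are dropped with a note", {
  d <- make_meta_df(rnorm(8, 0.3, 0.1), rep(0.05, 8),
                    a = rep("x", 8), b = rep(c("p", "q"), 4))
  expect_error(fit_multilevel(d, moderators = c("a")), "rank-deficient")
  d$b[1:2] <- NA
  expect_message(f <- fit_multilevel(d, moderators = "b"), "2 effect")
  expect_equal(f$k, 6)
  expect_error(fit_multilevel(d[1, ]), "k = 2")
})
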