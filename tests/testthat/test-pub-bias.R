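test_that("funnel export is one row per effect with se = sqrt(v)", {
  d <- make_meta_df(c(0.1, 0.4, -0.2), c(0.25, 0.04, 0.09))
  fd <- funnel_data(d)
  expect_equal(nrow(fd), 3)
  expect_equal(fd$se, c(0.5, 0.2, 0.3))
})

test_that("the fail-safe number matches the closed form and its scale invariance", {
  # two effects with Z = 2 each: floor(16 / qnorm(.95)^2 - 2) = 3
  d <- make_meta_df(c(2 * 0.5, 2 * 0.3), c(0.25, 0.09))
  fs <- failsafe_rosenthal(d)
  expect_identical(fs$failsafe_n, 3L)
  expect_identical(fs$threshold, 20L)
  expect_false(fs$robust)

  d0 <- make_meta_df(rep(0, 5), rep(0.1, 5))
  fs0 <- failsafe_rosenthal(d0)
  expect_identical(fs0$failsafe_n, 0L)
  expect_false(fs0$robust)

  # k = 20 effects all with Z about 4 dwarf the 5k + 10 = 110 threshold
  d4 <- make_meta_df(rep(4 * 0.2, 20), rep(0.04, 20))
  fs4 <- failsafe_rosenthal(d4)
  expect_identical(fs4$threshold, 110L)
  expect_gt(fs4$failsafe_n, 10 * fs4$threshold)
  expect_true(fs4$robust)

  # invariant under common rescaling of g and se
  set.seed(2)
  g <- rnorm(12, 0.5, 0.3); v <- runif(12, 0.02, 0.2)
  n1 <- failsafe_rosenthal(make_meta_df(g, v))$failsafe_n
  n2 <- failsafe_rosenthal(make_meta_df(3 * g, 9 * v))$failsafe_n
  expect_identical(n1, n2)
})

test_that("the fail-safe robustness threshold is 5k + 10 for every k", {
  for (k in 2:60) {
    d <- make_meta_df(rnorm(k, 0.2, 0.1), runif(k, 0.01, 0.3))
    expect_identical(failsafe_rosenthal(d)$threshold, 5L * k + 10L)
  }
})

test_that("Kendall tau matches brute-force pair counting and detects monotone funnels", {
  # monotone association between effect and variance
  d <- make_meta_df(c(0.1, 0.2, 0.35, 0.5, 0.8, 1.2),
                    c(0.01, 0.02, 0.04, 0.08, 0.16, 0.32))
  kb <- kendall_bias_test(d)
  expect_equal(kb$tau, 1)

  # handmade table vs exhaustive concordant/discordant enumeration of the
  # exact quantities the test ranks (standardized effects vs variances)
  g <- c(0.3, -0.1, 0.6, 0.2, 0.9)
  v <- c(0.05, 0.2, 0.02, 0.11, 0.08)
  w <- 1 / v; mu <- sum(w * g) / sum(w); s2 <- 1 / sum(w)
  ys <- (g - mu) / sqrt(v - s2)
  conc <- disc <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    s <- sign(ys[i] - ys[j]) * sign(v[i] - v[j])
    if (s > 0) conc <- conc + 1 else disc <- disc + 1
  }
  kb2 <- kendall_bias_test(make_meta_df(g, v))
  expect_equal(kb2$tau, (conc - disc) / 10, tolerance = 1e-12)
  expect_identical(kb2$branch, "exact")

  expect_error(kendall_bias_test(make_meta_df(c(1, 1, 1), rep(0.1, 3))),
               "rank variation")
})

test_that("the exact Kendall p equals full permutation enumeration for small k", {
  set.seed(14)
  for (k in 5:7) {
    x <- rnorm(k); y <- rnorm(k)
    got <- cropbirds:::kendall_test(x, y)
    expect_identical(got$branch, "exact")
    perms <- combinat_perms(k)
    taus <- apply(perms, 1, function(p) cor(x, y[p], method = "kendall"))
    p_enum <- mean(abs(taus) >= abs(got$tau) - 1e-12)
    expect_equal(got$p, p_enum, tolerance = 1e-12)
  }
})

test_that("the regression test matches the reference and rejects degenerate input", {
  skip_if_not_installed("metafor")
  set.seed(31)
  d <- draw_meta(25, mu = 0.3, tau2_study = 0.03)
  eg <- egger_regression_test(d)
  m <- metafor::rma(g, v_g, data = d, method = "REML")
  rt <- metafor::regtest(m, model = "rma", predictor = "sei")
  expect_equal(eg$z, unname(rt$zval), tolerance = 1e-4)
  expect_equal(eg$p, unname(rt$pval), tolerance = 1e-4)
  expect_error(egger_regression_test(make_meta_df(rnorm(5), rep(0.1, 5))),
               "degenerate")
})

test_that("trim-and-fill leaves symmetric funnels alone and is idempotent", {
  set.seed(8)
  v <- runif(10, 0.02, 0.3)
  dev <- abs(rnorm(10, 0, sqrt(v)))
  g <- 0.4 + c(dev, -dev)            # exactly symmetric about 0.4
  d <- make_meta_df(g, rep(v, 2))
  tf <- trim_and_fill(d)
  expect_identical(tf$k0, 0L)
  expect_equal(unname(tf$adjusted_fit$b[1]),
               unname(fit_random_effects(d$g, d$v_g)$b[1]), tolerance = 1e-8)

  # feeding the augmented output back in finds nothing more to fill
  set.seed(15)
  d2 <- draw_meta(20, mu = 0.3, tau2_study = 0.02)
  d2 <- d2[order(d2$g), ]
  d2 <- d2[4:20, ]                    # suppress the 3 most negative
  class(d2) <- c("meta_dataset", "data.frame")
  tf2 <- trim_and_fill(d2, side = "left")
  aug <- make_meta_df(tf2$augmented$g, tf2$augmented$v_g)
  tf3 <- trim_and_fill(aug, side = "left")
  expect_identical(tf3$k0, 0L)
})

test_that("trim-and-fill agrees with the reference estimator on suppressed funnels", {
  skip_if_not_installed("metafor")
  set.seed(23)
  checked <- 0
  for (r in 1:8) {
    d <- draw_meta(20, mu = 0.4, tau2_study = 0.02)
    d <- d[order(d$g), ][4:20, ]      # remove the 3 most negative
    class(d) <- c("meta_dataset", "data.frame")
    m <- tryCatch(metafor::rma(g, v_g, data = d, method = "REML"),
                  error = function(e) NULL)   # reference fit may not converge
    if (is.null(m)) next
    tf <- trim_and_fill(d, side = "left")
    mtf <- metafor::trimfill(m, side = "left", estimator = "L0")
    expect_identical(tf$k0, as.integer(mtf$k0))
    expect_equal(unname(tf$adjusted_fit$b[1]), unname(mtf$b[1, 1]),
                 tolerance = 1e-3)
    checked <- checked + 1
  }
  expect_gte(checked, 3)
})

test_that("the combined bias report assembles all diagnostics coherently", {
  set.seed(40)
  d <- draw_meta(18, mu = 0.5, tau2_study = 0.02)
  br <- publication_bias(d)
  expect_s3_class(br, "bias_report")
  expect_identical(br$failsafe_threshold, 5L * nrow(d) + 10L)
  expect_true(br$trimfill_k0 >= 0 && br$trimfill_k0 <= nrow(d))
  expect_true(br$trimfill_side %in% c("left", "right"))
  expect_equal(nrow(br$funnel), nrow(d))
  expect_output(print(br), "fail-safe")
})
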