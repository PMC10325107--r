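#' Funnel-plot data
#'
#' @param data a `meta_dataset`.
#' @return data frame with one row per effect: `g` and its standard error
#'   `se = sqrt(v_g)`.
#' @export
funnel_data <- function(data) {
  data.frame(g = data$g, se = sqrt(data$v_g))
}

#' Rosenthal's fail-safe number
#'
#' The number of unpublished null-result comparisons that would be needed to
#' bring the combined one-sided evidence down to the significance threshold:
#' `N = max(0, floor((sum Z_i)^2 / z_alpha^2 - k))` with `Z_i = g_i / se_i`.
#' The combined result is conventionally called robust when `N > 5 k + 10`.
#'
#' @param data a `meta_dataset`.
#' @param alpha one-sided significance level (Rosenthal convention 0.05).
#' @return list with `failsafe_n`, `threshold` (= 5k + 10) and `robust`.
#' @export
failsafe_rosenthal <- function(data, alpha = 0.05) {
  k <- nrow(data)
  stopifnot(k >= 2)
  z <- data$g / sqrt(data$v_g)
  zcrit <- stats::qnorm(1 - alpha)
  N <- max(0, floor(sum(z)^2 / zcrit^2 - k))
  list(failsafe_n = as.integer(N), threshold = 5L * k + 10L,
       robust = N > 5L * k + 10L)
}

#' Rank-correlation test for funnel asymmetry
#'
#' Kendall's tau-b between the variance-standardized effects and a rank
#' surrogate for sample size.  Effects are centered at the fixed-effects
#' pooled estimate and standardized by `sqrt(v_i - s^2)` with
#' `s^2 = 1 / sum(1/v_i)` before ranking.  By default the sampling variance
#' itself serves as the (inverse) sample-size surrogate — it is monotone in n
#' and always available; ranking an explicit `n_total` column is exposed as
#' an option.  A significant correlation indicates that small comparisons
#' were published selectively by effect magnitude.
#'
#' The p-value is exact (full permutation-null via the inversion-count
#' distribution) for k <= 10 without ties, otherwise a tie-corrected normal
#' approximation.
#'
#' @param data a `meta_dataset`.
#' @param surrogate `"variance"` (default) or `"sample_size"` (requires an
#'   `n_total` column).
#' @return list with `tau`, `p` and the branch used (`"exact"`/`"normal"`).
#' @export
kendall_bias_test <- function(data, surrogate = c("variance", "sample_size")) {
  surrogate <- match.arg(surrogate)
  k <- nrow(data)
  stopifnot(k >= 3)
  v <- data$v_g
  wsum <- sum(1 / v)
  mu_fe <- sum(data$g / v) / wsum
  s2 <- 1 / wsum
  ystar <- (data$g - mu_fe) / sqrt(v - s2)
  xr <- if (surrogate == "variance") v else {
    if (is.null(data$n_total)) stop("surrogate 'sample_size' needs an n_total column",
                                    call. = FALSE)
    data$n_total
  }
  if (length(unique(xr)) < 2 || length(unique(ystar)) < 2)
    stop("no rank variation in the inputs", call. = FALSE)
  kendall_test(ystar, xr)
}

# Kendall tau-b with exact or tie-corrected-normal p.
#' @keywords internal
kendall_test <- function(x, y) {
  n <- length(x)
  conc <- 0L; disc <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
  }
  S <- conc - disc
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 10) {
    p <- kendall_exact_p(disc, n)
    branch <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(varS)
    p <- 2 * stats::pnorm(-abs(z))
    branch <- "normal"
  }
  list(tau = tau, p = min(1, p), branch = branch, S = S)
}

# Exact two-sided p for Kendall's statistic with d observed discordant pairs
# among n untied observations: P(|tau_null| >= |tau_obs|) under the uniform
# permutation null, from the inversion-count (Mahonian) distribution.
#' @keywords internal
kendall_exact_p <- function(d, n) {
  maxinv <- n * (n - 1) / 2
  f <- c(1, rep(0, maxinv))              # counts for m = 1
  for (m in 2:n) {                       # f_m = f_{m-1} convolved with 0..m-1
    g <- rep(0, maxinv + 1)
    cs <- cumsum(f)
    for (j in 0:(m * (m - 1) / 2)) {
      lo <- j - (m - 1)
      g[j + 1] <- cs[j + 1] - if (lo >= 1) cs[lo] else 0
    }
    f <- g
  }
  probs <- f / factorial(n)
  tau_all <- 1 - 4 * (0:maxinv) / (n * (n - 1))
  tau_obs <- 1 - 4 * d / (n * (n - 1))
  sum(probs[abs(tau_all) >= abs(tau_obs) - 1e-12])
}

#' Regression test for funnel asymmetry
#'
#' Weighted meta-regression of the effects on their standard errors under a
#' single-level random-effects model (the multilevel structure is collapsed
#' for this diagnostic).  The reported p tests the standard-error
#' coefficient; a significant slope indicates small-study effects.
#'
#' @param data a `meta_dataset`.
#' @return list with `slope`, `se`, `z`, `p` and the underlying `fit`.
#' @export
egger_regression_test <- function(data) {
  k <- nrow(data)
  stopifnot(k >= 3)
  se_i <- sqrt(data$v_g)
  if (diff(range(se_i)) < 1e-12)
    stop("degenerate input: all standard errors equal", call. = FALSE)
  fit <- fit_random_effects(data$g, data$v_g, X = matrix(se_i, ncol = 1))
  list(slope = unname(fit$b[2]), se = unname(fit$se[2]),
       z = unname(fit$zval[2]), p = unname(fit$pval[2]), fit = fit)
}

#' Duval-Tweedie trim-and-fill sensitivity analysis
#'
#' Estimates the number `k0` of comparisons suppressed on one side of the
#' funnel with the L0 rank estimator, iteratively trimming the `k0` most
#' extreme effects on the opposite side and re-centering with a single-level
#' random-effects REML fit, then fills the funnel by mirroring the trimmed
#' effects about the final center and refits on the augmented set.
#'
#' @param data a `meta_dataset`.
#' @param side side of the funnel the missing studies are assumed on:
#'   `"auto"` (default; chosen by the sign of the rank-correlation statistic
#'   between standardized effects and variances), `"left"` or `"right"`.
#' @param maxiter maximum trimming iterations.
#' @return list with `k0`, `side`, `augmented` (data frame `g`, `v_g`,
#'   `filled`), `adjusted_fit` (single-level random-effects `meta_fit` on the
#'   augmented set) and the trim iteration trace.
#' @export
trim_and_fill <- function(data, side = c("auto", "left", "right"), maxiter = 50) {
  side <- match.arg(side)
  k <- nrow(data)
  stopifnot(k >= 3)
  if (side == "auto") {
    kb <- tryCatch(kendall_bias_test(data), error = function(e) list(S = 0))
    # positive association (small studies have larger effects) implies the
    # suppressed studies sit on the left of the funnel
    side <- if (kb$S >= 0) "left" else "right"
  }
  flip <- if (side == "left") -1 else 1   # work with missing on the RIGHT
  y <- flip * data$g
  v <- data$v_g
  ord <- order(y)                          # ascending; extremes to trim = smallest
  y <- y[ord]; v <- v[ord]

  k0 <- 0L
  trace <- integer(0)
  for (it in seq_len(maxiter)) {
    keep <- if (k0 > 0) (k0 + 1):k else 1:k
    mu <- fit_random_effects(y[keep], v[keep])$b[1]
    dev <- y - mu
    r <- rank(signif(abs(dev), 12))      # snap float noise so mirrored pairs tie
    Tn <- sum(r[dev < 0])                  # ranks on the trimmed (left) side
    L0 <- (4 * Tn - k * (k + 1)) / (2 * k - 1)
    k0_new <- max(0L, min(k - 2L, as.integer(round(L0))))
    trace <- c(trace, k0_new)
    if (k0_new == k0) break
    k0 <- k0_new
    if (it == maxiter)
      stop("trim-and-fill did not converge after ", maxiter,
           " iterations; k0 trace: ", paste(trace, collapse = ", "),
           call. = FALSE)
  }

  keep <- if (k0 > 0) (k0 + 1):k else 1:k
  mu <- fit_random_effects(y[keep], v[keep])$b[1]
  if (k0 > 0) {
    fill_y <- 2 * mu - y[1:k0]
    fill_v <- v[1:k0]
    aug_g <- flip * c(y, fill_y)
    aug_v <- c(v, fill_v)
    filled <- c(rep(FALSE, k), rep(TRUE, k0))
  } else {
    aug_g <- flip * y; aug_v <- v; filled <- rep(FALSE, k)
  }
  adjusted <- fit_random_effects(aug_g, aug_v)
  list(k0 = as.integer(k0), side = side,
       augmented = data.frame(g = aug_g, v_g = aug_v, filled = filled),
       adjusted_fit = adjusted, trace = trace)
}

#' Full publication-bias report
#'
#' Runs the funnel export, Rosenthal fail-safe number, rank-correlation test,
#' regression test and trim-and-fill on one dataset.
#'
#' @inheritParams trim_and_fill
#' @param alpha one-sided level for the fail-safe number.
#' @return an object of class `bias_report`.
#' @export
publication_bias <- function(data, side = "auto", alpha = 0.05) {
  fs <- failsafe_rosenthal(data, alpha = alpha)
  kd <- kendall_bias_test(data)
  eg <- egger_regression_test(data)
  tf <- trim_and_fill(data, side = side)
  structure(list(
    k = nrow(data),
    failsafe_n = fs$failsafe_n, failsafe_threshold = fs$threshold,
    robust = fs$robust,
    kendall_tau = kd$tau, kendall_p = kd$p,
    egger_slope = eg$slope, egger_p = eg$p,
    trimfill_k0 = tf$k0, trimfill_side = tf$side,
    adjusted_fit = tf$adjusted_fit,
    funnel = funnel_data(data)), class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat("Publication-bias report (k =", x$k, ")\n")
  cat(sprintf("  fail-safe N = %d (threshold %d, robust: %s)\n",
              x$failsafe_n, x$failsafe_threshold, x$robust))
  cat(sprintf("  Kendall tau = %.3f (p = %.4f)\n", x$kendall_tau, x$kendall_p))
  cat(sprintf("  regression slope = %.3f (p = %.4f)\n", x$egger_slope, x$egger_p))
  cat(sprintf("  trim-and-fill: k0 = %d missing on the %s; adjusted mu = %.3f (%.3f, %.3f)\n",
              x$trimfill_k0, x$trimfill_side, x$adjusted_fit$b[1],
              x$adjusted_fit$ci_low[1], x$adjusted_fit$ci_high[1]))
  invisible(x)
}
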