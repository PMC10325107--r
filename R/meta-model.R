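#' Fit a multilevel random-effects meta-analytic model by REML
#'
#' Estimates the pooled standardized effect (or meta-regression coefficients)
#' from a set of effect sizes with known sampling variances, allowing random
#' intercepts for study and for comparison-within-study ("nested groups") to
#' control for the non-independence of multiple comparisons per study.  Each
#' effect is weighted by the inverse of its sampling variance plus the
#' between-study and within-study variance components, which are estimated by
#' restricted maximum likelihood under non-negativity constraints.
#'
#' The marginal covariance is block diagonal by study:
#' `V = diag(v_i + tau2_within) + tau2_study J` within a study (J a matrix of
#' ones), so the likelihood is evaluated with a Sherman–Morrison rank-one
#' update per block.  Confidence intervals are normal (z) Wald intervals.
#'
#' When every study contributes exactly one comparison the within-study
#' component is not identifiable and is dropped automatically (fixed at 0).
#'
#' @param data a `meta_dataset` (see [effect_sizes()] / [as_meta_dataset()]).
#' @param moderators character vector of moderator column names entering the
#'   model as fixed effects (empty for the intercept-only pooled model).
#' @param intercept logical; drop the intercept (e.g. for per-level subgroup
#'   estimation with a single categorical moderator).
#' @param random `"study/comparison"` (default) for nested random intercepts,
#'   or `"study"` for the study level only.
#' @param reltol convergence tolerance on the REML criterion.
#' @return an object of class `meta_fit` with elements `b`, `se`, `zval`,
#'   `pval`, `ci_low`, `ci_high`, `tau2_study`, `tau2_within`, `QE`, `QE_df`,
#'   `QE_p`, `QM`, `QM_df`, `QM_p` (when moderators are present), `k`, `p`,
#'   `loglik_reml`, `vb` (coefficient covariance) and bookkeeping fields.
#' @export
fit_multilevel <- function(data, moderators = character(0), intercept = TRUE,
                           random = c("study/comparison", "study"),
                           reltol = 1e-10) {
  random <- match.arg(random)
  stopifnot(inherits(data, "data.frame"))
  dm <- build_design(data, moderators, intercept)
  y <- dm$y; v <- dm$v; X <- dm$X; study <- dm$study
  k <- length(y); p <- ncol(X)
  if (k < 2) stop("need at least k = 2 effects to fit a model", call. = FALSE)
  if (k <= p) stop("more coefficients than effects (k <= p)", call. = FALSE)

  blocks <- split(seq_len(k), study)
  use_within <- random == "study/comparison" && any(lengths(blocks) > 1)

  obj <- function(par) {
    ts <- par[1]; tw <- if (use_within) par[2] else 0
    -reml_loglik(y, v, X, blocks, ts, tw)
  }
  # moment-style starting value plus boundary / diffuse restarts
  tau0 <- max(0.001, stats::var(y) - mean(v))
  starts <- if (use_within) {
    list(c(tau0 / 2, tau0 / 2), c(1e-4, 1e-4), c(tau0, 1e-4), c(1e-4, tau0))
  } else {
    list(tau0, 1e-4, 1)
  }
  best <- NULL
  for (s in starts) {
    fit <- stats::nlminb(s, obj, lower = rep(0, length(s)),
                         control = list(rel.tol = reltol, iter.max = 500))
    if (is.null(best) || fit$objective < best$objective - 1e-12) best <- fit
  }
  if (!best$convergence %in% c(0, 1) && is.na(best$objective))
    stop("REML optimization did not converge: ", best$message, call. = FALSE)
  ts <- best$par[1]; tw <- if (use_within) best$par[2] else 0

  gl <- gls_at(y, v, X, blocks, ts, tw)
  b <- gl$beta
  vb <- solve(gl$XtVX)
  se <- sqrt(diag(vb))
  zval <- b / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ci_low <- b - stats::qnorm(0.975) * se
  ci_high <- b + stats::qnorm(0.975) * se

  qe <- qe_stat(y, v, X)

  fit <- list(b = b, se = se, zval = zval, pval = pval,
              ci_low = ci_low, ci_high = ci_high, vb = vb,
              tau2_study = ts, tau2_within = tw,
              QE = qe$QE, QE_df = qe$df, QE_p = qe$p,
              k = k, p = p, loglik_reml = -best$objective,
              moderators = moderators, intercept = intercept,
              random = if (use_within) "study/comparison" else "study",
              coef_names = colnames(X), n_dropped = dm$n_dropped)
  if (p > (if (intercept) 1 else 0)) {
    idx <- if (intercept) 2:p else 1:p
    QM <- drop(t(b[idx]) %*% solve(vb[idx, idx, drop = FALSE]) %*% b[idx])
    fit$QM <- QM
    fit$QM_df <- length(idx)
    fit$QM_p <- stats::pchisq(QM, length(idx), lower.tail = FALSE)
  }
  class(fit) <- "meta_fit"
  fit
}

#' @keywords internal
build_design <- function(data, moderators, intercept) {
  need <- c("g", "v_g", "study_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  miss_mod <- setdiff(moderators, names(data))
  if (length(miss_mod)) stop("unknown moderator(s): ",
                             paste(miss_mod, collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, nrow(data))
  for (m in moderators) keep <- keep & !is.na(data[[m]])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " effect(s) dropped for missing moderator values")
  d <- data[keep, , drop = FALSE]
  # explicit dummy coding: the first categorical moderator supplies the full
  # level set when there is no intercept, later ones drop their first level
  cols <- list()
  if (intercept) cols[["intrcpt"]] <- rep(1, nrow(d))
  has_base <- intercept
  for (m in moderators) {
    x <- d[[m]]
    if (is.numeric(x)) {
      cols[[m]] <- x
    } else {
      lev <- sort(unique(as.character(x)))
      use <- if (has_base) lev[-1] else lev
      if (has_base && length(lev) < 2)
        stop("rank-deficient moderator design; aliased column(s): ", m,
             call. = FALSE)
      for (lv in use) cols[[paste0(m, lv)]] <- as.numeric(x == lv)
      has_base <- TRUE
    }
  }
  if (!length(cols)) cols[["intrcpt"]] <- rep(1, nrow(d))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient moderator design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  list(y = d$g, v = d$v_g, X = X, study = as.character(d$study_id),
       data = d, n_dropped = n_dropped)
}

# Restricted log-likelihood at variance components (ts, tw), block-wise.
#' @keywords internal
reml_loglik <- function(y, v, X, blocks, ts, tw) {
  gl <- gls_at(y, v, X, blocks, ts, tw)
  k <- length(y); p <- ncol(X)
  rss <- gl$ytVy - drop(crossprod(gl$beta, gl$XtVy))
  ld_xtvx <- determinant(gl$XtVX, logarithm = TRUE)$modulus
  ld_xtx <- determinant(crossprod(X), logarithm = TRUE)$modulus
  -0.5 * ((k - p) * log(2 * pi) - ld_xtx + gl$logdetV + ld_xtvx + rss)
}

# GLS pieces at given variance components using per-study Sherman-Morrison.
#' @keywords internal
gls_at <- function(y, v, X, blocks, ts, tw) {
  p <- ncol(X)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  logdetV <- 0
  for (idx in blocks) {
    a <- v[idx] + tw
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    ai <- 1 / a
    s <- sum(ai)
    c1 <- ts / (1 + ts * s)
    XtA <- Xb * ai                       # A^-1 X (rows scaled)
    u_x <- colSums(XtA)                  # X' A^-1 1
    u_y <- sum(yb * ai)                  # 1' A^-1 y
    XtVX <- XtVX + crossprod(Xb, XtA) - c1 * tcrossprod(u_x)
    XtVy <- XtVy + colSums(XtA * yb) - c1 * u_x * u_y
    ytVy <- ytVy + sum(yb^2 * ai) - c1 * u_y^2
    logdetV <- logdetV + sum(log(a)) + log1p(ts * s)
  }
  beta <- solve(XtVX, XtVy)
  list(beta = beta, XtVX = XtVX, XtVy = XtVy, ytVy = ytVy, logdetV = logdetV)
}

# Residual heterogeneity Q using fixed-effects weights 1/v at the
# fixed-effects (weighted least squares) projection.
#' @keywords internal
qe_stat <- function(y, v, X) {
  w <- 1 / v
  WX <- X * w
  beta_fe <- solve(crossprod(X, WX), colSums(WX * y))
  res <- y - drop(X %*% beta_fe)
  QE <- sum(w * res^2)
  df <- length(y) - ncol(X)
  list(QE = QE, df = df,
       p = if (df > 0) stats::pchisq(QE, df, lower.tail = FALSE) else NA_real_)
}

#' Residual heterogeneity Q-test
#'
#' `QE = sum w_i (g_i - x_i beta_FE)^2` with fixed-effects weights
#' `w_i = 1/v_i`; under homogeneity QE is chi-square with `k - p` degrees of
#' freedom.
#'
#' @inheritParams fit_multilevel
#' @return list with `QE`, `df`, `p`.
#' @export
q_test <- function(data, moderators = character(0), intercept = TRUE) {
  dm <- build_design(data, moderators, intercept)
  if (length(dm$y) <= ncol(dm$X))
    stop("Q-test needs k > p", call. = FALSE)
  qe_stat(dm$y, dm$v, dm$X)
}

#' Omnibus moderator test
#'
#' Fits the multilevel model with the given moderators and returns the Wald
#' chi-square test of all non-intercept coefficients (QM).
#'
#' @inheritParams fit_multilevel
#' @return list with `QM`, `df`, `p` and the underlying `fit`.
#' @export
moderator_test <- function(data, moderators, random = "study/comparison") {
  if (length(moderators) < 1) stop("at least one moderator required", call. = FALSE)
  fit <- fit_multilevel(data, moderators = moderators, random = random)
  list(QM = fit$QM, df = fit$QM_df, p = fit$QM_p, fit = fit)
}

#' Pooled estimates per level of a categorical moderator
#'
#' Fits one multilevel model with a no-intercept level-indicator design, so
#' every level gets its own pooled estimate sharing the variance components.
#'
#' @param data a `meta_dataset`.
#' @param moderator name of a categorical moderator column.
#' @param random random-effects structure, as in [fit_multilevel()].
#' @return data frame with columns `level`, `mu`, `ci_low`, `ci_high`, `k`,
#'   in lexicographic level order.
#' @export
subgroup_estimates <- function(data, moderator, random = "study/comparison") {
  stopifnot(moderator %in% names(data))
  keep <- !is.na(data[[moderator]])
  if (any(!keep)) warning(sum(!keep), " effect(s) with missing '", moderator,
                          "' omitted")
  d <- data[keep, , drop = FALSE]
  lev <- sort(unique(as.character(d[[moderator]])))
  fit <- fit_multilevel(d, moderators = moderator, intercept = FALSE,
                        random = random)
  ks <- as.integer(table(factor(d[[moderator]], levels = lev)))
  data.frame(level = lev, mu = unname(fit$b), ci_low = unname(fit$ci_low),
             ci_high = unname(fit$ci_high), k = ks,
             stringsAsFactors = FALSE)
}

#' Forest-plot summary table
#'
#' Per-effect rows (g with 95% normal CI from its sampling variance) followed
#' by the pooled overall row of the fit.
#'
#' @param fit a `meta_fit` from an intercept-only model.
#' @param data the `meta_dataset` the fit was computed from.
#' @return data frame with `label`, `g`, `ci_low`, `ci_high`, `type`.
#' @export
forest_summary <- function(fit, data) {
  z <- stats::qnorm(0.975)
  se <- sqrt(data$v_g)
  rows <- data.frame(
    label = paste(data$study_id, data$comparison_id, sep = ":"),
    g = data$g, ci_low = data$g - z * se, ci_high = data$g + z * se,
    type = "effect", stringsAsFactors = FALSE)
  overall <- data.frame(label = "overall", g = unname(fit$b[1]),
                        ci_low = unname(fit$ci_low[1]),
                        ci_high = unname(fit$ci_high[1]),
                        type = "overall", stringsAsFactors = FALSE)
  rbind(rows, overall)
}

#' Single-level random-effects fit
#'
#' Convenience wrapper: the classical random-effects model (one variance
#' component) fitted by REML, used by the publication-bias diagnostics where
#' the multilevel structure is collapsed.
#'
#' @param g,v effect sizes and sampling variances.
#' @param X optional design matrix (default intercept only).
#' @return a `meta_fit`.
#' @export
fit_random_effects <- function(g, v, X = NULL) {
  d <- data.frame(study_id = as.character(seq_along(g)),
                  comparison_id = "1", g = g, v_g = v,
                  stringsAsFactors = FALSE)
  if (is.null(X)) {
    fit_multilevel(as_meta_dataset(d), random = "study")
  } else {
    stopifnot(nrow(X) == length(g))
    for (j in seq_len(ncol(X))) d[[paste0("x", j)]] <- X[, j]
    fit_multilevel(as_meta_dataset(d),
                   moderators = paste0("x", seq_len(ncol(X))),
                   random = "study")
  }
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Multilevel random-effects meta-analysis (REML)\n")
  cat(sprintf("k = %d effects; random: %s\n", x$k, x$random))
  cat(sprintf("tau2 (study) = %.4f; tau2 (within) = %.4f\n",
              x$tau2_study, x$tau2_within))
  tab <- data.frame(estimate = x$b, se = x$se, z = x$zval, p = x$pval,
                    ci.lb = x$ci_low, ci.ub = x$ci_high)
  rownames(tab) <- x$coef_names
  print(round(tab, 4))
  cat(sprintf("QE = %.3f (df = %d, p = %.4f)\n", x$QE, x$QE_df, x$QE_p))
  if (!is.null(x$QM))
    cat(sprintf("QM = %.3f (df = %d, p = %.4f)\n", x$QM, x$QM_df, x$QM_p))
  invisible(x)
}
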