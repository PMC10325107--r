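#' Construct a survey record
#'
#' One independent social survey: the number of respondents, the proportion
#' giving the focal answer (e.g. positive attitude toward birds, perceived
#' crop disservice), and survey-level covariates.
#'
#' @param survey_id opaque label.
#' @param n_respondents integer >= 1.
#' @param proportion proportion of respondents in [0, 1].
#' @param outcome_kind one of `"positive_attitude"`, `"negative_attitude"`,
#'   `"perceived_service"`, `"perceived_disservice"`.
#' @param income `"high"` or `"low"` economic status of the country.
#' @param bird_group focal bird group (free categorical).
#' @param stakeholder `"rural"`, `"urban"` or `"mixed"`.
#' @param climate `"tropics"` or `"nontropics"`.
#' @return a one-row data frame (class `survey_record`).
#' @export
survey_record <- function(survey_id, n_respondents, proportion,
                          outcome_kind = c("positive_attitude", "negative_attitude",
                                           "perceived_service", "perceived_disservice"),
                          income = c("high", "low"),
                          bird_group = "bird",
                          stakeholder = c("rural", "urban", "mixed"),
                          climate = c("tropics", "nontropics")) {
  outcome_kind <- match.arg(outcome_kind)
  income <- match.arg(income)
  stakeholder <- match.arg(stakeholder)
  climate <- match.arg(climate)
  n_respondents <- as.integer(n_respondents)
  stopifnot(n_respondents >= 1, proportion >= 0, proportion <= 1)
  succ <- proportion * n_respondents
  if (abs(succ - round(succ)) > 0.01)
    warning("proportion x n_respondents is ", signif(succ, 5),
            ", not an integer success count; it will be rounded")
  out <- data.frame(survey_id = as.character(survey_id),
                    n_respondents = n_respondents, proportion = proportion,
                    outcome_kind = outcome_kind, income = income,
                    bird_group = tolower(as.character(bird_group)),
                    stakeholder = stakeholder, climate = climate,
                    stringsAsFactors = FALSE)
  class(out) <- c("survey_record", "data.frame")
  out
}

#' Descriptive summary of survey proportions
#'
#' Unweighted arithmetic mean and standard deviation of per-survey
#' proportions for one outcome kind.
#'
#' @param records data frame of survey rows (see [survey_record()]).
#' @param outcome_kind which outcome to summarize.
#' @return list with `mean`, `sd`, `n_surveys`.
#' @export
describe_proportions <- function(records, outcome_kind) {
  p <- records$proportion[records$outcome_kind == outcome_kind]
  stopifnot(length(p) >= 1)
  list(mean = mean(p), sd = stats::sd(p), n_surveys = length(p))
}

#' Binomial random-intercept model for survey proportions
#'
#' Logit model on per-survey success/failure counts (successes reconstructed
#' as `round(proportion * n_respondents)`) with a survey-level normal random
#' intercept, fitted by Laplace-approximated maximum likelihood via
#' `lme4::glmer`.  The small-sample information criterion uses the number of
#' surveys as the sample size:
#' `AICc = -2 l + 2 p + 2 p (p + 1) / (n - p - 1)`.
#'
#' @param records survey data frame (one outcome kind).
#' @param terms character vector of covariate names among `income`,
#'   `bird_group`, `stakeholder`, `climate` (empty = intercept-only).
#' @return list with `coefficients` (estimate, se, z, p), `loglik`, `AICc`,
#'   `n_par`, `n_surveys`, `sigma_intercept` and the `lme4` fit object.
#' @export
fit_binomial_mixed <- function(records, terms = character(0)) {
  stopifnot(all(terms %in% names(records)))
  d <- as.data.frame(records)
  d$successes <- as.integer(round(d$proportion * d$n_respondents))
  d$failures <- d$n_respondents - d$successes
  stopifnot(all(d$successes >= 0), all(d$failures >= 0))
  for (tm in terms)
    if (is.character(d[[tm]])) d[[tm]] <- factor(d[[tm]])
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("cbind(successes, failures) ~", rhs,
                                 "+ (1 | survey_id)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(fml, data = d, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
  fe <- lme4::fixef(fit)
  if (any(abs(fe) > 15))
    stop("apparent complete separation (|coefficient| > 15); ",
         "remove the offending term", call. = FALSE)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ll <- as.numeric(stats::logLik(fit))
  n <- nrow(d)
  p <- length(fe) + 1L                       # fixed effects + intercept variance
  if (n - p - 1 <= 0) stop("too few surveys for AICc with ", p, " parameters",
                           call. = FALSE)
  aicc <- -2 * ll + 2 * p + 2 * p * (p + 1) / (n - p - 1)
  coefs <- data.frame(estimate = fe, se = se, z = fe / se,
                      p = 2 * stats::pnorm(-abs(fe / se)))
  list(coefficients = coefs, loglik = ll, AICc = aicc, n_par = p,
       n_surveys = n,
       sigma_intercept = sqrt(unname(lme4::VarCorr(fit)$survey_id[1])),
       model = fit, terms = terms)
}

#' All-subsets AICc ranking with model averaging
#'
#' Fits every subset of the candidate terms, ranks the models by AICc, and
#' averages coefficients across the models of comparable support
#' (`delta AICc < delta`) using Akaike weights renormalized over that set.
#' The default is full (zero-substituted) averaging: a model not containing a
#' term contributes a 0 coefficient; conditional averaging (over only the
#' models containing the term) is exposed as an option.  Averaged standard
#' errors follow the Burnham-Anderson unconditional form
#' `sqrt(sum w (se^2 + (b - b_avg)^2))` and the reported p-values use a
#' normal approximation on them (approximate by construction).
#'
#' @param records survey data frame (one outcome kind).
#' @param full_terms candidate terms (at most 12).
#' @param delta AICc window for the averaged set (default 2).
#' @param method `"full"` (default) or `"conditional"` averaging.
#' @return an object of class `model_ranking`: list with `table` (term set,
#'   n_par, AICc, delta, weight over the full candidate set), `averaged`
#'   (coefficient, se, z, p per term), `n_averaged`, `fits`.
#' @export
dredge_and_average <- function(records, full_terms, delta = 2,
                               method = c("full", "conditional")) {
  method <- match.arg(method)
  stopifnot(length(full_terms) <= 12)
  m <- length(full_terms)
  subsets <- lapply(0:(2^m - 1), function(mask)
    full_terms[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0])
  fits <- vector("list", length(subsets))
  ok <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(fit_binomial_mixed(records, subsets[[i]]),
                          error = function(e) {
                            warning("model {", paste(subsets[[i]], collapse = ", "),
                                    "} skipped: ", conditionMessage(e))
                            NULL
                          })
    ok[i] <- !is.null(fits[[i]])
  }
  subsets <- subsets[ok]; fits <- fits[ok]
  if (!length(fits)) stop("no candidate model could be fitted", call. = FALSE)
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  d_aicc <- aicc - min(aicc)
  w <- exp(-d_aicc / 2); w <- w / sum(w)
  ord <- order(aicc)
  tab <- data.frame(
    terms = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(intercept)", character(1)),
    n_par = vapply(fits, `[[`, numeric(1), "n_par"),
    AICc = aicc, delta = d_aicc, weight = w, stringsAsFactors = FALSE)[ord, ]
  rownames(tab) <- NULL

  in_set <- which(d_aicc < delta)
  ws <- w[in_set] / sum(w[in_set])
  coef_names <- unique(unlist(lapply(fits[in_set],
                                     function(f) rownames(f$coefficients))))
  avg <- t(vapply(coef_names, function(cn) {
    bs <- ses <- numeric(length(in_set))
    present <- logical(length(in_set))
    for (j in seq_along(in_set)) {
      cf <- fits[[in_set[j]]]$coefficients
      if (cn %in% rownames(cf)) {
        bs[j] <- cf[cn, "estimate"]; ses[j] <- cf[cn, "se"]; present[j] <- TRUE
      }
    }
    if (method == "conditional") {
      wj <- ws[present] / sum(ws[present])
      bsel <- bs[present]; sesel <- ses[present]
    } else {
      wj <- ws; bsel <- bs; sesel <- ses        # absent models contribute 0
    }
    b_avg <- sum(wj * bsel)
    se_avg <- sum(wj * sqrt(sesel^2 + (bsel - b_avg)^2))
    c(estimate = b_avg, se = se_avg, z = b_avg / se_avg,
      p = 2 * stats::pnorm(-abs(b_avg / se_avg)))
  }, numeric(4)))
  structure(list(table = tab, averaged = as.data.frame(avg),
                 n_averaged = length(in_set), delta = delta, method = method,
                 fits = fits, subsets = subsets),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("AICc model ranking (", nrow(x$table), " models; ", x$n_averaged,
      " with delta < ", x$delta, " averaged, ", x$method, " averaging)\n",
      sep = "")
  print(utils::head(transform(x$table, AICc = round(AICc, 2),
                              delta = round(delta, 2),
                              weight = round(weight, 3)), 8))
  cat("\nAveraged coefficients:\n")
  print(round(x$averaged, 4))
  invisible(x)
}

#' Nonparametric trend test for study counts over time
#'
#' Spearman rank correlation between per-period counts and the period index
#' (two-sided; exact p for short untied series via `stats::cor.test`).
#'
#' @param counts_by_period numeric vector of study counts, one per period,
#'   in chronological order.
#' @return list with `rho` and `p`.
#' @export
spearman_trend <- function(counts_by_period) {
  n <- length(counts_by_period)
  stopifnot(n >= 4)
  if (length(unique(counts_by_period)) < 2)
    stop("constant counts: trend correlation undefined", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(counts_by_period, seq_len(n), method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
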