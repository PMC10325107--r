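#' Construct a comparison record
#'
#' A comparison record holds the summary statistics of one experimental
#' treatment/control contrast — the unit of the meta-analyses.  In the
#' exclosure dataset the "treatment" is open access of birds to the crop and
#' the "control" is the exclosure; in the mitigation dataset the treatment is
#' the mitigating measure.
#'
#' @param study_id opaque study label.
#' @param comparison_id opaque comparison label, unique within study.
#' @param mean_treatment,mean_control group means in outcome units.
#' @param sd_treatment,sd_control group standard deviations, strictly positive.
#' @param n_treatment,n_control group sample sizes, integers >= 2.
#' @param outcome_polarity `"gain"` if larger outcome values mean more
#'   production, `"loss"` if larger values mean more damage/loss (e.g. "50%
#'   loss versus 30% loss" outcomes).
#' @param moderators named list of categorical or numeric covariates (crop
#'   stem type, food type, climatic region, pesticide use, focal animal, ...).
#'   Character values are normalized to lowercase tokens.
#' @return an object of class `comparison_record`.
#' @export
comparison_record <- function(study_id, comparison_id,
                              mean_treatment, mean_control,
                              sd_treatment, sd_control,
                              n_treatment, n_control,
                              outcome_polarity = c("gain", "loss"),
                              moderators = list()) {
  outcome_polarity <- match.arg(outcome_polarity)
  n_treatment <- as.integer(n_treatment)
  n_control <- as.integer(n_control)
  if (is.na(n_treatment) || is.na(n_control) || n_treatment < 2L || n_control < 2L)
    stop("sample sizes must be integers >= 2", call. = FALSE)
  for (x in c(mean_treatment, mean_control, sd_treatment, sd_control))
    if (!is.finite(x)) stop("means and SDs must be finite", call. = FALSE)
  if (sd_treatment <= 0 || sd_control <= 0)
    stop("standard deviations must be strictly positive", call. = FALSE)
  moderators <- normalize_moderators(moderators)
  structure(
    list(study_id = as.character(study_id),
         comparison_id = as.character(comparison_id),
         mean_treatment = mean_treatment, mean_control = mean_control,
         sd_treatment = sd_treatment, sd_control = sd_control,
         n_treatment = n_treatment, n_control = n_control,
         outcome_polarity = outcome_polarity,
         moderators = moderators),
    class = "comparison_record")
}

#' @keywords internal
normalize_moderators <- function(moderators) {
  if (length(moderators) == 0) return(list())
  stopifnot(is.list(moderators), !is.null(names(moderators)))
  lapply(moderators, function(v) {
    if (is.character(v) || is.factor(v)) tolower(trimws(as.character(v))) else v
  })
}

#' Cohen's d and its sampling variance from a comparison record
#'
#' The standardized mean difference uses the pooled within-groups standard
#' deviation with (n - 1)-weighted summed squares and divisor
#' `n_t + n_c - 2`.  The sampling variance is the usual large-sample form
#' `(n_c + n_t)/(n_c n_t) + d^2 / (2 (n_c + n_t))`.
#'
#' @param rec a [comparison_record()].
#' @return list with elements `d` and `v_d`.
#' @export
cohen_d <- function(rec) {
  stopifnot(inherits(rec, "comparison_record"))
  nt <- rec$n_treatment; nc <- rec$n_control
  sd_within <- sqrt(((nt - 1) * rec$sd_treatment^2 + (nc - 1) * rec$sd_control^2) /
                      (nt + nc - 2))
  if (sd_within == 0)
    stop("pooled standard deviation is zero: standardized effect undefined ",
         "(study ", rec$study_id, ", comparison ", rec$comparison_id, ")",
         call. = FALSE)
  d <- (rec$mean_treatment - rec$mean_control) / sd_within
  v_d <- (nc + nt) / (nc * nt) + d^2 / (2 * (nc + nt))
  list(d = d, v_d = v_d)
}

#' Hedges' small-sample bias-correction factor J
#'
#' `J = 1 - 3 / (4 df - 1)` with `df = n_t + n_c - 2`.  J lies in (0, 1) and
#' increases towards 1 as the total sample size grows.
#'
#' @param n_treatment,n_control group sample sizes.
#' @return the correction factor, a number in (0, 1).
#' @export
hedges_correction <- function(n_treatment, n_control) {
  df <- n_treatment + n_control - 2
  if (df < 1) stop("degrees of freedom n_t + n_c - 2 must be >= 1", call. = FALSE)
  1 - 3 / (4 * df - 1)
}

#' Bias-corrected Hedges' g for one comparison
#'
#' Applies the J correction to Cohen's d (`g = J d`, `v_g = J^2 v_d`) and then
#' aligns the sign with [align_direction()] so that positive g always means
#' "birds increase production" (exclosure data) or "the measure reduces crop
#' loss" (mitigation data).
#'
#' @param rec a [comparison_record()].
#' @return an `effect_size` object: list with `g`, `v_g`, `study_id`,
#'   `comparison_id` and the record's `moderators`.
#' @export
hedges_g <- function(rec) {
  dd <- cohen_d(rec)
  J <- hedges_correction(rec$n_treatment, rec$n_control)
  es <- effect_size(g = J * dd$d, v_g = J^2 * dd$v_d,
                    study_id = rec$study_id, comparison_id = rec$comparison_id,
                    moderators = rec$moderators)
  align_direction(es, rec$outcome_polarity)
}

#' Construct an effect-size object
#'
#' @param g unitless standardized mean difference.
#' @param v_g its sampling variance, strictly positive.
#' @param study_id,comparison_id labels carried from the source record.
#' @param moderators named list of covariates carried from the source record.
#' @return an object of class `effect_size`.
#' @export
effect_size <- function(g, v_g, study_id, comparison_id, moderators = list()) {
  if (!is.finite(g)) stop("g must be finite", call. = FALSE)
  if (!is.finite(v_g) || v_g <= 0) stop("v_g must be finite and > 0", call. = FALSE)
  structure(list(g = g, v_g = v_g,
                 study_id = as.character(study_id),
                 comparison_id = as.character(comparison_id),
                 moderators = normalize_moderators(moderators)),
            class = "effect_size")
}

#' Align the direction of an effect size with the outcome polarity
#'
#' Outcomes expressed as losses (e.g. "50% loss versus 30% loss") point the
#' opposite way from outcomes expressed as production, so for polarity
#' `"loss"` the effect is multiplied by minus one; the variance is unchanged.
#'
#' @param es an [effect_size()].
#' @param polarity `"gain"` or `"loss"`.
#' @return the effect size, sign-aligned.
#' @export
align_direction <- function(es, polarity = c("gain", "loss")) {
  polarity <- match.arg(polarity)
  if (polarity == "loss") es$g <- -es$g
  es
}

#' Hedges' g from convertible summary statistics
#'
#' Some studies report a two-sample t statistic or means with standard errors
#' instead of full summary data.  For `t_stat`, `d = t * sqrt(1/n_t + 1/n_c)`;
#' for `mean_se`, the standard errors are converted to standard deviations via
#' `SD = SE * sqrt(n)` and the full Hedges computation is applied.
#'
#' @param stat_kind `"t_stat"` or `"mean_se"`.
#' @param values for `t_stat`: list with `t`; for `mean_se`: list with
#'   `mean_treatment`, `mean_control`, `se_treatment`, `se_control`.
#' @param n_treatment,n_control group sample sizes.
#' @param study_id,comparison_id labels for the resulting effect size.
#' @param outcome_polarity,moderators as in [comparison_record()].
#' @return an `effect_size`.
#' @export
g_from_convertible <- function(stat_kind, values, n_treatment, n_control,
                               study_id = "conv", comparison_id = "1",
                               outcome_polarity = "gain", moderators = list()) {
  if (!stat_kind %in% c("t_stat", "mean_se"))
    stop("unsupported stat_kind '", stat_kind,
         "'; supported kinds: t_stat, mean_se", call. = FALSE)
  if (stat_kind == "mean_se") {
    rec <- comparison_record(
      study_id, comparison_id,
      mean_treatment = values$mean_treatment, mean_control = values$mean_control,
      sd_treatment = values$se_treatment * sqrt(n_treatment),
      sd_control = values$se_control * sqrt(n_control),
      n_treatment = n_treatment, n_control = n_control,
      outcome_polarity = outcome_polarity, moderators = moderators)
    return(hedges_g(rec))
  }
  nt <- n_treatment; nc <- n_control
  if (nt < 2 || nc < 2) stop("sample sizes must be >= 2", call. = FALSE)
  d <- values$t * sqrt(1 / nt + 1 / nc)
  v_d <- (nc + nt) / (nc * nt) + d^2 / (2 * (nc + nt))
  J <- hedges_correction(nt, nc)
  es <- effect_size(g = J * d, v_g = J^2 * v_d, study_id = study_id,
                    comparison_id = comparison_id, moderators = moderators)
  align_direction(es, outcome_polarity)
}

#' Compute effect sizes for a list of comparison records
#'
#' @param records list of [comparison_record()] objects.
#' @return a `meta_dataset`: data frame with one row per comparison holding
#'   `study_id`, `comparison_id`, `g`, `v_g` and one column per moderator.
#' @export
effect_sizes <- function(records) {
  stopifnot(length(records) >= 1)
  es <- lapply(records, hedges_g)
  effects_to_dataset(es)
}

#' @keywords internal
effects_to_dataset <- function(es_list) {
  mod_names <- unique(unlist(lapply(es_list, function(e) names(e$moderators))))
  base <- data.frame(
    study_id = vapply(es_list, `[[`, character(1), "study_id"),
    comparison_id = vapply(es_list, `[[`, character(1), "comparison_id"),
    g = vapply(es_list, `[[`, numeric(1), "g"),
    v_g = vapply(es_list, `[[`, numeric(1), "v_g"),
    stringsAsFactors = FALSE)
  for (m in mod_names) {
    vals <- lapply(es_list, function(e) {
      v <- e$moderators[[m]]
      if (is.null(v) || length(v) != 1) NA else v
    })
    base[[m]] <- unlist(vals)
  }
  if (anyDuplicated(base[c("study_id", "comparison_id")]))
    stop("(study_id, comparison_id) pairs must be unique in a dataset", call. = FALSE)
  class(base) <- c("meta_dataset", "data.frame")
  base
}

#' Coerce a data frame of precomputed effects to a meta-analysis dataset
#'
#' @param df data frame with at least `study_id`, `comparison_id`, `g`, `v_g`;
#'   additional columns are treated as moderators.
#' @return a `meta_dataset`.
#' @export
as_meta_dataset <- function(df) {
  need <- c("study_id", "comparison_id", "g", "v_g")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$g)) || any(!is.finite(df$v_g)) || any(df$v_g <= 0))
    stop("g must be finite and v_g finite and > 0 for every effect", call. = FALSE)
  df$study_id <- as.character(df$study_id)
  df$comparison_id <- as.character(df$comparison_id)
  if (anyDuplicated(df[c("study_id", "comparison_id")]))
    stop("(study_id, comparison_id) pairs must be unique in a dataset", call. = FALSE)
  for (m in setdiff(names(df), need))
    if (is.character(df[[m]]) || is.factor(df[[m]]))
      df[[m]] <- tolower(trimws(as.character(df[[m]])))
  class(df) <- c("meta_dataset", "data.frame")
  df
}
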