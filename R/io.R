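#' Read a table of experimental comparisons
#'
#' Reads a CSV (or XLSX, via readxl) file with one row per comparison and
#' validates every row.  A column map adapts arbitrary source headers to the
#' canonical schema without editing the file.  Rows may carry either raw
#' summaries (`mean_treatment`, `mean_control`, `sd_treatment`, `sd_control`,
#' `n_treatment`, `n_control`) or a precomputed effect (`g`, `v_g`); every
#' remaining column is kept as a moderator (character moderators are
#' lowercased).  Rejected rows are reported per row, never dropped silently.
#'
#' @param path CSV or XLSX file.
#' @param colmap optional named character vector mapping canonical field
#'   names to source column names, e.g. `c(mean_treatment = "Mean.T")`.
#' @return object of class `comparison_input`: list with `records` (list of
#'   [comparison_record()]), `precomputed` (list of [effect_size()]) and
#'   `rejects` (data frame of row, reason).
#' @export
read_comparisons <- function(path, colmap = NULL) {
  df <- read_table_file(path)
  df <- apply_colmap(df, colmap)
  raw_cols <- c("mean_treatment", "mean_control", "sd_treatment", "sd_control",
                "n_treatment", "n_control")
  id_cols <- c("study_id", "comparison_id")
  miss_id <- setdiff(id_cols, names(df))
  if (length(miss_id))
    stop("missing mapped column(s): ", paste(miss_id, collapse = ", "),
         call. = FALSE)
  has_raw <- all(raw_cols %in% names(df))
  has_pre <- all(c("g", "v_g") %in% names(df))
  if (!has_raw && !has_pre)
    stop("missing mapped column(s): need either ",
         paste(raw_cols, collapse = ", "), " or g, v_g", call. = FALSE)
  mod_cols <- setdiff(names(df), c(id_cols, raw_cols, "g", "v_g",
                                   "outcome_polarity"))
  records <- list(); precomputed <- list(); rejects <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    mods <- as.list(row[mod_cols])
    pol <- if ("outcome_polarity" %in% names(df) &&
               !is.na(row$outcome_polarity))
      tolower(row$outcome_polarity) else "gain"
    row_raw_ok <- has_raw && !anyNA(row[raw_cols])
    if (row_raw_ok) {
      reason <- validate_raw_row(row)
      if (is.null(reason)) {
        records[[length(records) + 1]] <- comparison_record(
          row$study_id, row$comparison_id,
          row$mean_treatment, row$mean_control,
          row$sd_treatment, row$sd_control,
          row$n_treatment, row$n_control,
          outcome_polarity = pol, moderators = mods)
        next
      }
    } else if (has_pre && !is.na(row$g) && !is.na(row$v_g)) {
      if (is.finite(row$g) && is.finite(row$v_g) && row$v_g > 0) {
        precomputed[[length(precomputed) + 1]] <-
          effect_size(row$g, row$v_g, row$study_id, row$comparison_id,
                      moderators = mods)
        next
      }
      reason <- "g not finite or v_g <= 0"
    } else {
      reason <- "incomplete row: neither raw summaries nor (g, v_g)"
    }
    rejects[[length(rejects) + 1]] <- data.frame(row = i, reason = reason,
                                                 stringsAsFactors = FALSE)
  }
  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(row = integer(0), reason = character(0))
  if (nrow(rejects) > 0)
    message(nrow(rejects), " row(s) rejected; see $rejects for reasons")
  if (length(records) + length(precomputed) == 0)
    stop("zero valid rows in ", path, call. = FALSE)
  structure(list(records = records, precomputed = precomputed,
                 rejects = rejects), class = "comparison_input")
}

#' @keywords internal
validate_raw_row <- function(row) {
  if (row$n_treatment < 2) return("n_treatment < 2")
  if (row$n_control < 2) return("n_control < 2")
  if (row$sd_treatment <= 0) return("sd_treatment <= 0")
  if (row$sd_control <= 0) return("sd_control <= 0")
  NULL
}

#' @keywords internal
read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' @keywords internal
apply_colmap <- function(df, colmap) {
  if (is.null(colmap)) return(df)
  stopifnot(!is.null(names(colmap)), !anyDuplicated(names(colmap)))
  for (canon in names(colmap)) {
    src <- colmap[[canon]]
    if (!src %in% names(df))
      stop("missing mapped column(s): ", src, " (for ", canon, ")",
           call. = FALSE)
    names(df)[names(df) == src] <- canon
  }
  df
}

#' Effect sizes from a comparison input (raw rows computed, precomputed kept)
#'
#' @param input a `comparison_input` from [read_comparisons()].
#' @return a `meta_dataset`.
#' @export
effect_sizes_from_input <- function(input) {
  stopifnot(inherits(input, "comparison_input"))
  es <- c(lapply(input$records, hedges_g), input$precomputed)
  effects_to_dataset(es)
}

#' Write an effect-size dataset as CSV
#'
#' @param dataset a `meta_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_sizes <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Write comparison records as a canonical CSV
#'
#' @param records list of [comparison_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(records, path) {
  mod_names <- unique(unlist(lapply(records, function(r) names(r$moderators))))
  rows <- lapply(records, function(r) {
    base <- data.frame(
      study_id = r$study_id, comparison_id = r$comparison_id,
      mean_treatment = r$mean_treatment, mean_control = r$mean_control,
      sd_treatment = r$sd_treatment, sd_control = r$sd_control,
      n_treatment = r$n_treatment, n_control = r$n_control,
      outcome_polarity = r$outcome_polarity, stringsAsFactors = FALSE)
    for (m in mod_names) {
      v <- r$moderators[[m]]
      base[[m]] <- if (is.null(v)) NA else v
    }
    base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read survey records
#'
#' @param path CSV or XLSX with columns `survey_id`, `n_respondents`,
#'   `proportion`, `outcome_kind`, `income`, `bird_group`, `stakeholder`,
#'   `climate` (or a `colmap` to them).
#' @param colmap optional canonical-to-source column map.
#' @return survey data frame; rejected rows (proportion outside [0, 1],
#'   n < 1) in the `rejects` attribute.
#' @export
read_surveys <- function(path, colmap = NULL) {
  df <- apply_colmap(read_table_file(path), colmap)
  need <- c("survey_id", "n_respondents", "proportion", "outcome_kind",
            "income", "bird_group", "stakeholder", "climate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing mapped column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad_p <- is.na(df$proportion) | df$proportion < 0 | df$proportion > 1
  bad_n <- is.na(df$n_respondents) | df$n_respondents < 1
  rejects <- data.frame(row = which(bad_p | bad_n),
                        reason = ifelse(bad_p[bad_p | bad_n],
                                        "proportion outside [0, 1]",
                                        "n_respondents < 1"))
  if (nrow(rejects)) message(nrow(rejects), " survey row(s) rejected")
  out <- df[!(bad_p | bad_n), need]
  if (nrow(out) == 0) stop("zero valid rows in ", path, call. = FALSE)
  for (cc in c("income", "bird_group", "stakeholder", "climate", "outcome_kind"))
    out[[cc]] <- tolower(trimws(out[[cc]]))
  attr(out, "rejects") <- rejects
  out
}

#' Read decade-level study counts
#'
#' @param path CSV or XLSX with columns `period` and one count column per
#'   study topic (or a single `count` column).
#' @return data frame ordered by period.
#' @export
read_counts <- function(path) {
  df <- read_table_file(path)
  if (!"period" %in% names(df))
    stop("missing mapped column(s): period", call. = FALSE)
  df[order(df$period), , drop = FALSE]
}

#' Run the full coexistence synthesis pipeline
#'
#' Chains every analysis stage on supplied dataset files: effect sizes and
#' multilevel pooled fits for the exclosure data (overall and per stem type,
#' with moderator tests, subgroup estimates, the direction tree and the
#' publication-bias suite including trim-and-fill), the mitigation dataset
#' (overall, per stage, per category), survey descriptives with AICc-averaged
#' binomial mixed models, and the study-count trend tests.  Writes a
#' machine-readable JSON report plus CSV tables.
#'
#' @param exclosure_path,mitigation_path comparison CSV/XLSX files.
#' @param survey_path survey CSV/XLSX file.
#' @param counts_path decade-count CSV file (optional).
#' @param out_dir output directory (created if needed).
#' @param colmaps optional named list of column maps per dataset
#'   (`exclosure`, `mitigation`, `survey`).
#' @return the report, invisibly (also written to `out_dir/report.json`).
#' @export
reproduce <- function(exclosure_path, mitigation_path = NULL,
                      survey_path = NULL, counts_path = NULL,
                      out_dir = ".", colmaps = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()

  excl <- effect_sizes_from_input(
    read_comparisons(exclosure_path, colmaps$exclosure))
  report$exclosure <- analyse_effect_dataset(excl, split_by = "stem_type")
  write_effect_sizes(excl, file.path(out_dir, "exclosure_effects.csv"))

  if (!is.null(mitigation_path)) {
    mit <- effect_sizes_from_input(
      read_comparisons(mitigation_path, colmaps$mitigation))
    report$mitigation <- analyse_effect_dataset(mit, split_by = "stage")
    write_effect_sizes(mit, file.path(out_dir, "mitigation_effects.csv"))
  }

  if (!is.null(survey_path)) {
    sv <- read_surveys(survey_path, colmaps$survey)
    terms <- intersect(c("income", "bird_group", "stakeholder", "climate"),
                       names(sv))
    report$surveys <- list()
    for (kind in unique(sv$outcome_kind)) {
      sub <- sv[sv$outcome_kind == kind, ]
      entry <- list(descriptive = describe_proportions(sv, kind))
      if (nrow(sub) >= 10) {
        rk <- tryCatch(dredge_and_average(sub, terms),
                       error = function(e) NULL)
        if (!is.null(rk))
          entry$averaged <- cbind(term = rownames(rk$averaged), rk$averaged)
      }
      report$surveys[[kind]] <- entry
    }
  }

  if (!is.null(counts_path)) {
    cnt <- read_counts(counts_path)
    topics <- setdiff(names(cnt), "period")
    report$trends <- lapply(stats::setNames(topics, topics), function(tp)
      tryCatch(spearman_trend(cnt[[tp]]), error = function(e)
        list(rho = NA, p = NA)))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}

# Overall fit, bias suite, direction tree and per-level splits for one
# effect-size dataset.
#' @keywords internal
analyse_effect_dataset <- function(es, split_by = NULL) {
  out <- list(overall = fit_summary(fit_multilevel(es)))
  out$q_test <- q_test(es)
  out$bias <- bias_summary(publication_bias(es))
  mod_cols <- setdiff(names(es), c("study_id", "comparison_id", "g", "v_g"))
  cat_cols <- mod_cols[vapply(mod_cols, function(m)
    is.character(es[[m]]) && length(unique(stats::na.omit(es[[m]]))) >= 2,
    logical(1))]
  if (length(cat_cols)) {
    cov <- es[cat_cols]
    out$direction_tree <- tryCatch({
      root <- fit_ctree(es$g > 0, cov)
      list(split_variable = root$split_variable,
           p = if (!is.null(root$split_variable))
             unname(root$p_values[[root$split_variable]]) else NA,
           n_positive = unname(root$class_counts[1]),
           n_negative = unname(root$class_counts[2]))
    }, error = function(e) NULL)
    out$moderator_tests <- lapply(stats::setNames(cat_cols, cat_cols),
      function(m) tryCatch({
        mt <- moderator_test(es, m)
        list(QM = mt$QM, df = mt$df, p = mt$p)
      }, error = function(e) list(QM = NA, df = NA, p = NA)))
  }
  if (!is.null(split_by) && split_by %in% names(es)) {
    out$by_level <- lapply(
      stats::setNames(nm = sort(unique(stats::na.omit(es[[split_by]])))),
      function(lv) {
        sub <- es[!is.na(es[[split_by]]) & es[[split_by]] == lv, ]
        class(sub) <- class(es)
        res <- list(overall = fit_summary(fit_multilevel(sub)))
        res$bias <- tryCatch(bias_summary(publication_bias(sub)),
                             error = function(e) NULL)
        res$direction_positive <- mean(sub$g > 0)
        res
      })
  }
  out
}

#' @keywords internal
fit_summary <- function(fit) {
  list(mu = unname(fit$b[1]), ci_low = unname(fit$ci_low[1]),
       ci_high = unname(fit$ci_high[1]), p = unname(fit$pval[1]),
       tau2_study = fit$tau2_study, tau2_within = fit$tau2_within,
       k = fit$k, QE = fit$QE, QE_p = fit$QE_p)
}

#' @keywords internal
bias_summary <- function(br) {
  list(failsafe_n = br$failsafe_n, failsafe_threshold = br$failsafe_threshold,
       robust = br$robust, kendall_tau = br$kendall_tau,
       kendall_p = br$kendall_p, egger_slope = br$egger_slope,
       egger_p = br$egger_p, trimfill_k0 = br$trimfill_k0,
       trimfill_side = br$trimfill_side,
       adjusted_mu = unname(br$adjusted_fit$b[1]),
       adjusted_ci_low = unname(br$adjusted_fit$ci_low[1]),
       adjusted_ci_high = unname(br$adjusted_fit$ci_high[1]))
}
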