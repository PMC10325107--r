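#' Configuration for the experimental-comparison generator
#'
#' Defaults mirror the structure of the exclosure dataset: 40 studies
#' contributing 1-6 comparisons each, a true pooled standardized effect of
#' 0.4 with between-study variance 0.04 and a smaller within-study component,
#' and heterogeneous replication (4-30 plots per arm).  Group standard
#' deviations are drawn log-normal around 1 so sampling variances vary
#' realistically across comparisons.
#'
#' @param n_studies number of studies.
#' @param comparisons_per_study integer range `c(min, max)` of comparisons
#'   drawn per study.
#' @param mu true pooled effect on the standardized (g) scale.
#' @param tau2_study between-study variance of true effects.
#' @param tau2_within between-comparison-within-study variance.
#' @param n_range integer range of per-group sample sizes.
#' @param sdlog log-scale SD of the log-normal group standard deviations.
#' @param moderators optional named list; each element is a list with
#'   `levels` (character), `shifts` (numeric, same length, added to the true
#'   effect) and optionally `assign = "study"` (default) or `"comparison"`.
#' @param loss_fraction fraction of comparisons whose outcome is expressed as
#'   a loss (larger = more damage), exercising direction alignment.
#' @param censor optional publication-censoring rule: list with
#'   `z_threshold` (default 1.6449), `severity` (>= 0) and `se_scale`;
#'   a comparison with one-sided `z = g/se` below the threshold is suppressed
#'   with probability `1 - exp(-severity (z_threshold - z) se / (se + se_scale))`,
#'   i.e. small studies are published mainly when they show large effects.
#' @return a list of class `effect_sim_config`.
#' @export
effect_sim_config <- function(n_studies = 40, comparisons_per_study = c(1, 6),
                              mu = 0.4, tau2_study = 0.04, tau2_within = 0.02,
                              n_range = c(4, 30), sdlog = 0.25,
                              moderators = NULL, loss_fraction = 0,
                              censor = NULL) {
  stopifnot(n_studies >= 1, tau2_study >= 0, tau2_within >= 0,
            loss_fraction >= 0, loss_fraction <= 1,
            comparisons_per_study[1] >= 1, n_range[1] >= 2)
  structure(as.list(environment()), class = "effect_sim_config")
}

#' Simulate experimental comparison records
#'
#' Draws a true standardized effect per comparison
#' (`theta = mu + moderator shift + study effect + within-study effect`),
#' then draws raw group means, SDs and sample sizes whose population
#' standardized difference equals `theta`, so the effect-size computation is
#' exercised end to end.  Output is deterministic given `(cfg, seed)`.
#'
#' @param cfg an [effect_sim_config()].
#' @param seed integer seed.
#' @return list of [comparison_record()]s with a `truth` attribute (data
#'   frame of the per-comparison true effects and publication flags).
#' @export
simulate_effects <- function(cfg, seed) {
  stopifnot(inherits(cfg, "effect_sim_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  records <- list()
  truth <- list()
  for (s in seq_len(cfg$n_studies)) {
    b_study <- stats::rnorm(1, 0, sqrt(cfg$tau2_study))
    n_comp <- sample(cfg$comparisons_per_study[1]:cfg$comparisons_per_study[2], 1)
    study_mods <- lapply(cfg$moderators, function(m) {
      if (is.null(m$assign) || m$assign == "study")
        sample(seq_along(m$levels), 1) else NA_integer_
    })
    for (cpt in seq_len(n_comp)) {
      b_within <- stats::rnorm(1, 0, sqrt(cfg$tau2_within))
      shift <- 0
      mods <- list()
      for (mn in names(cfg$moderators)) {
        m <- cfg$moderators[[mn]]
        li <- study_mods[[mn]]
        if (is.na(li)) li <- sample(seq_along(m$levels), 1)
        mods[[mn]] <- m$levels[li]
        shift <- shift + m$shifts[li]
      }
      theta <- cfg$mu + shift + b_study + b_within
      nt <- sample(cfg$n_range[1]:cfg$n_range[2], 1)
      nc <- sample(cfg$n_range[1]:cfg$n_range[2], 1)
      St <- stats::rlnorm(1, 0, cfg$sdlog)
      Sc <- stats::rlnorm(1, 0, cfg$sdlog)
      spool <- sqrt((St^2 + Sc^2) / 2)
      is_loss <- stats::runif(1) < cfg$loss_fraction
      base <- if (is_loss) 50 else 10
      delta <- theta * spool * if (is_loss) -1 else 1
      mt <- stats::rnorm(1, base + delta, St / sqrt(nt))
      mc <- stats::rnorm(1, base, Sc / sqrt(nc))
      sdt <- St * sqrt(stats::rchisq(1, nt - 1) / (nt - 1))
      sdc <- Sc * sqrt(stats::rchisq(1, nc - 1) / (nc - 1))
      rec <- comparison_record(
        study_id = sprintf("s%03d", s), comparison_id = sprintf("c%d", cpt),
        mean_treatment = mt, mean_control = mc,
        sd_treatment = max(sdt, 1e-6), sd_control = max(sdc, 1e-6),
        n_treatment = nt, n_control = nc,
        outcome_polarity = if (is_loss) "loss" else "gain",
        moderators = mods)
      published <- TRUE
      if (!is.null(cfg$censor)) {
        es <- hedges_g(rec)
        se <- sqrt(es$v_g)
        z <- es$g / se
        zc <- if (is.null(cfg$censor$z_threshold)) stats::qnorm(0.95) else cfg$censor$z_threshold
        sev <- cfg$censor$severity
        ssc <- if (is.null(cfg$censor$se_scale)) 0.2 else cfg$censor$se_scale
        if (z < zc) {
          p_pub <- exp(-sev * (zc - z) * se / (se + ssc))
          published <- stats::runif(1) < p_pub
        }
      }
      truth[[length(truth) + 1]] <- data.frame(
        study_id = rec$study_id, comparison_id = rec$comparison_id,
        theta = theta, published = published, stringsAsFactors = FALSE)
      if (published) records[[length(records) + 1]] <- rec
    }
  }
  attr(records, "truth") <- do.call(rbind, truth)
  records
}

#' Configuration for the survey generator
#'
#' Defaults mirror the attitude dataset: 39 independent surveys with 50-1,500
#' respondents each, and a wide survey-level random intercept
#' (`sd_intercept = 1.5` on the logit scale) so that with an intercept of 0.9
#' and no covariate effects the per-survey proportions average about 0.66
#' with a standard deviation near 0.28 — the spread reported for positive
#' attitudes across real surveys.
#'
#' @param n_surveys number of surveys.
#' @param respondents_range integer range of respondents per survey.
#' @param intercept logit-scale intercept.
#' @param beta_income_low logit effect of low (vs high) national income.
#' @param beta_bird_group named numeric vector of logit shifts for bird
#'   groups other than the reference `"bird"`.
#' @param beta_stakeholder named numeric vector of shifts for `"urban"` and
#'   `"mixed"` stakeholders (reference `"rural"`).
#' @param beta_climate_tropics logit effect of tropics (vs nontropics).
#' @param sd_intercept SD of the survey-level normal random intercept.
#' @param outcome_kind label for the generated outcome.
#' @return a list of class `survey_sim_config`.
#' @export
survey_sim_config <- function(n_surveys = 39, respondents_range = c(50, 1500),
                              intercept = 0.9, beta_income_low = 0,
                              beta_bird_group = c(waterfowl = 0, parrot = 0),
                              beta_stakeholder = c(urban = 0, mixed = 0),
                              beta_climate_tropics = 0, sd_intercept = 1.5,
                              outcome_kind = "positive_attitude") {
  stopifnot(n_surveys >= 1, respondents_range[1] >= 1, sd_intercept >= 0)
  structure(as.list(environment()), class = "survey_sim_config")
}

#' Simulate survey records
#'
#' Per survey: covariates drawn uniformly over their levels, a normal random
#' intercept added to the logit-scale linear predictor, and the success count
#' drawn binomial; the stored proportion is the realized successes over
#' respondents, so reconstruction of integer counts is exact.
#'
#' @param cfg a [survey_sim_config()].
#' @param seed integer seed.
#' @return data frame of survey rows (columns as in [survey_record()]).
#' @export
simulate_surveys <- function(cfg, seed) {
  stopifnot(inherits(cfg, "survey_sim_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  rows <- lapply(seq_len(cfg$n_surveys), function(i) {
    n <- sample(cfg$respondents_range[1]:cfg$respondents_range[2], 1)
    income <- sample(c("high", "low"), 1)
    bird_group <- sample(c("bird", names(cfg$beta_bird_group)), 1)
    stakeholder <- sample(c("rural", names(cfg$beta_stakeholder)), 1)
    climate <- sample(c("tropics", "nontropics"), 1)
    eta <- cfg$intercept +
      (income == "low") * cfg$beta_income_low +
      (if (bird_group != "bird") cfg$beta_bird_group[[bird_group]] else 0) +
      (if (stakeholder != "rural") cfg$beta_stakeholder[[stakeholder]] else 0) +
      (climate == "tropics") * cfg$beta_climate_tropics +
      stats::rnorm(1, 0, cfg$sd_intercept)
    succ <- stats::rbinom(1, n, stats::plogis(eta))
    survey_record(sprintf("sv%03d", i), n, succ / n,
                  outcome_kind = cfg$outcome_kind, income = income,
                  bird_group = bird_group, stakeholder = stakeholder,
                  climate = climate)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration for the grid generator
#'
#' @param shape `c(nrows, ncols)`, at least 3x3.
#' @param smoothness Gaussian-blur scale (cells) for spatial autocorrelation.
#' @param hot_corner optional planted priority cluster: list with `rows` and
#'   `cols` (index vectors).  When planted, the benefit share and the
#'   richness fields outside the corner follow opposing spatial gradients so
#'   the joint top tercile is exactly the planted block — a validation
#'   construction, not a model of real geography.
#' @param nodata_fraction fraction of cells masked as missing (e.g. ocean).
#' @return a list of class `grid_sim_config`.
#' @export
grid_sim_config <- function(shape = c(40, 60), smoothness = 2,
                            hot_corner = NULL, nodata_fraction = 0.1) {
  stopifnot(all(shape >= 3), smoothness >= 0,
            nodata_fraction >= 0, nodata_fraction < 1)
  structure(as.list(environment()), class = "grid_sim_config")
}

# Separable Gaussian blur with edge renormalization.
#' @keywords internal
smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  blur1 <- function(mat) {                      # along rows (vertical shifts)
    acc <- matrix(0, nrow(mat), ncol(mat))
    wgt <- matrix(0, nrow(mat), ncol(mat))
    for (o in -half:half) {
      w <- kern[o + half + 1]
      src <- pmin(pmax(seq_len(nrow(mat)) + o, 1L), nrow(mat))
      acc <- acc + w * mat[src, , drop = FALSE]
      wgt <- wgt + w
    }
    acc / wgt
  }
  t(blur1(t(blur1(m))))
}

#' Simulate co-registered production and richness grids
#'
#' Produces four non-negative, spatially autocorrelated layers — woody crop
#' production, total crop production (woody <= total everywhere), threatened
#' bird richness and total bird richness — sharing one nodata mask.
#'
#' @param cfg a [grid_sim_config()].
#' @param seed integer seed.
#' @return named list of `grid_layer`s: `woody`, `total`, `threatened`,
#'   `richness`.
#' @export
simulate_grids <- function(cfg, seed) {
  stopifnot(inherits(cfg, "grid_sim_config"))
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  noise <- function() smooth2d(matrix(stats::rnorm(nr * nc), nr, nc),
                               cfg$smoothness)
  total <- exp(noise() + 2)                       # log-normal-ish production
  if (is.null(cfg$hot_corner)) {
    share <- stats::plogis(2 * noise())
    threatened <- exp(noise())
    richness <- exp(noise() + 1)
  } else {
    # opposing gradients so the joint top tercile is exactly the planted block
    colg <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
    share <- 0.05 + 0.5 * colg + 0.02 * noise()
    richv <- 0.5 + 50 * (1 - colg) + 0.5 * noise()
    threatened <- pmax(richv * 0.2, 0.01)
    richness <- pmax(richv, 0.01)
    hc_r <- cfg$hot_corner$rows; hc_c <- cfg$hot_corner$cols
    share[hc_r, hc_c] <- 0.99
    threatened[hc_r, hc_c] <- max(threatened) * 3
    richness[hc_r, hc_c] <- max(richness) * 3
  }
  share <- pmin(pmax(share, 0), 1)
  woody <- share * total
  mask <- matrix(stats::runif(nr * nc) < cfg$nodata_fraction, nr, nc)
  if (!is.null(cfg$hot_corner)) mask[cfg$hot_corner$rows, cfg$hot_corner$cols] <- FALSE
  apply_mask <- function(m) { m[mask] <- NA; grid_layer(m) }
  list(woody = apply_mask(woody), total = apply_mask(total),
       threatened = apply_mask(threatened), richness = apply_mask(richness))
}
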