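# Term-by-term arithmetic oracle for the standardized-mean-difference
# formulas, written independently of the package implementation.
oracle_hedges <- function(mt, mc, st, sc, nt, nc, polarity = "gain") {
  sd_within <- sqrt(((nt - 1) * st * st + (nc - 1) * sc * sc) / (nt + nc - 2))
  d <- (mt - mc) / sd_within
  v_d <- (nc + nt) / (nc * nt) + (d * d) / (2 * (nc + nt))
  J <- 1 - 3 / (4 * (nt + nc - 2) - 1)
  g <- J * d
  v_g <- J * J * v_d
  if (polarity == "loss") g <- -g
  list(d = d, v_d = v_d, J = J, g = g, v_g = v_g)
}

# Random valid comparison record plus its oracle values.
random_record <- function(i) {
  nt <- sample(2:40, 1); nc <- sample(2:40, 1)
  mt <- runif(1, -10, 10); mc <- runif(1, -10, 10)
  st <- runif(1, 0.1, 5); sc <- runif(1, 0.1, 5)
  pol <- sample(c("gain", "loss"), 1)
  list(rec = comparison_record(paste0("s", i), "c1", mt, mc, st, sc, nt, nc,
                               outcome_polarity = pol),
       oracle = oracle_hedges(mt, mc, st, sc, nt, nc, pol))
}

# Quick effect-size dataset construction from bare vectors.
make_meta_df <- function(g, v, study = as.character(seq_along(g)),
                         comparison = NULL, ...) {
  if (is.null(comparison)) {
    comparison <- stats::ave(seq_along(g), study, FUN = seq_along)
  }
  df <- data.frame(study_id = study, comparison_id = as.character(comparison),
                   g = g, v_g = v, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  as_meta_dataset(df)
}

# All permutations of 1:n as rows of a matrix (for exhaustive null
# distributions at tiny n).
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in 1:n) {
    rest <- setdiff(1:n, i)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1
    }
  }
  out
}

# Draw a nested meta-analytic dataset directly on the g scale (normal
# sampling model) for model-level simulations.
draw_meta <- function(n_studies, comp_range = c(1, 1), mu = 0.4,
                      tau2_study = 0.04, tau2_within = 0,
                      v_range = c(0.02, 0.3)) {
  g <- numeric(0); v <- numeric(0); study <- character(0)
  for (s in seq_len(n_studies)) {
    m <- sample(comp_range[1]:comp_range[2], 1)
    bs <- rnorm(1, 0, sqrt(tau2_study))
    vi <- runif(m, v_range[1], v_range[2])
    gi <- mu + bs + rnorm(m, 0, sqrt(tau2_within)) + rnorm(m, 0, sqrt(vi))
    g <- c(g, gi); v <- c(v, vi); study <- c(study, rep(sprintf("s%03d", s), m))
  }
  make_meta_df(g, v, study = study)
}
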