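#' Conditional inference tree for effect-size direction
#'
#' Recursive binary partitioning in the conditional-inference style: at each
#' node the global null of independence between the binary response (is the
#' effect positive?) and each covariate is tested with a permutation test,
#' the p-values are Bonferroni-adjusted across covariates, and the node is
#' split on the most significant covariate only if its adjusted p-value is
#' below `alpha` — so the stopping rule is an internal multiplicity-adjusted
#' significance test, not pruning.
#'
#' Test flavours: 2x2 tables use Fisher's exact test; larger categorical
#' tables use the Pearson chi-square statistic with a Monte-Carlo permutation
#' null; numeric covariates use maximally selected two-sample statistics over
#' observed cutpoints, again with a permutation null.  Categorical splits
#' search all two-set partitions of the observed levels for the largest
#' collapsed 2x2 chi-square; numeric splits use the best cutpoint.
#'
#' @param responses logical or 0/1 vector: effect direction (positive = TRUE).
#'   An effect of exactly 0 is classed as non-positive.
#' @param covariates data frame of categorical (character/factor) and numeric
#'   covariates, same length as `responses`.
#' @param alpha significance level for the adjusted split tests.
#' @param minsplit minimum node size to attempt a split.
#' @param minbucket minimum size of a child node.
#' @param n_perm Monte-Carlo permutations for non-exact tests.
#' @param seed seed for the Monte-Carlo permutation draws.
#' @return a `ctree_node` (nested list) with fields `node_id`, `n`,
#'   `class_counts` (n_positive, n_negative), `p_values` (Bonferroni-adjusted,
#'   per covariate), `split_variable`, `split` (level set or cutpoint) and
#'   `children`.
#' @export
fit_ctree <- function(responses, covariates, alpha = 0.05,
                      minsplit = 20, minbucket = 7,
                      n_perm = 9999, seed = 20230706) {
  y <- as.logical(responses)
  stopifnot(length(y) >= 2, is.data.frame(covariates),
            nrow(covariates) == length(y))
  cov <- as.data.frame(covariates, stringsAsFactors = FALSE)
  for (j in names(cov))
    if (is.factor(cov[[j]])) cov[[j]] <- as.character(cov[[j]])
  env <- new.env()
  env$next_id <- 1L
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  grow_node(y, cov, alpha, minsplit, minbucket, n_perm, env)
}

#' @keywords internal
get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

#' @keywords internal
restore_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, globalenv())
}

#' @keywords internal
grow_node <- function(y, cov, alpha, minsplit, minbucket, n_perm, env) {
  id <- env$next_id
  env$next_id <- env$next_id + 1L
  node <- list(node_id = id, n = length(y),
               class_counts = c(n_positive = sum(y), n_negative = sum(!y)),
               p_values = NULL, split_variable = NULL, split = NULL,
               children = NULL)
  class(node) <- "ctree_node"
  if (length(unique(y)) < 2 || length(y) < minsplit) return(node)

  m <- ncol(cov)
  pvals <- vapply(names(cov), function(nm) {
    node_test_p(y, cov[[nm]], n_perm)
  }, numeric(1))
  padj <- stats::setNames(pmin(1, pvals * m), names(cov))  # Bonferroni across covariates
  node$p_values <- padj
  if (all(is.na(padj)) || min(padj, na.rm = TRUE) >= alpha) return(node)

  best_var <- names(cov)[which.min(padj)]
  sp <- best_split(y, cov[[best_var]], minbucket)
  if (is.null(sp)) return(node)
  node$split_variable <- best_var
  node$split <- sp$split
  left <- sp$left
  node$children <- list(
    grow_node(y[left], cov[left, , drop = FALSE], alpha, minsplit,
              minbucket, n_perm, env),
    grow_node(y[!left], cov[!left, , drop = FALSE], alpha, minsplit,
              minbucket, n_perm, env))
  node
}

# Permutation-based independence test p-value between binary y and one covariate.
#' @keywords internal
node_test_p <- function(y, x, n_perm) {
  ok <- !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 2 || length(unique(y)) < 2) return(NA_real_)
  if (is.numeric(x)) {
    if (length(unique(x)) < 2) return(NA_real_)
    return(maxsel_perm_p(y, x, n_perm))
  }
  if (length(unique(x)) < 2) return(NA_real_)
  tab <- table(x, y)
  if (nrow(tab) == 2)
    return(stats::fisher.test(tab)$p.value)
  obs <- chisq_stat(tab)
  perm <- replicate(n_perm, chisq_stat(table(x, sample(y))))
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

#' @keywords internal
chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Maximally selected standardized two-sample statistic over observed
# cutpoints, p via Monte-Carlo permutation of the response.
#' @keywords internal
maxsel_perm_p <- function(y, x, n_perm) {
  stat <- function(yy) maxsel_stat(yy, x)
  obs <- stat(y)
  perm <- replicate(n_perm, stat(sample(y)))
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

#' @keywords internal
maxsel_stat <- function(y, x) {
  n <- length(y); ybar <- mean(y); yvar <- stats::var(y)
  if (yvar == 0) return(0)
  cuts <- sort(unique(x))
  cuts <- cuts[-length(cuts)]
  best <- 0
  for (cc in cuts) {
    inl <- x <= cc
    nl <- sum(inl)
    if (nl == 0 || nl == n) next
    # standardized difference of the left-child response sum from expectation
    s <- sum(y[inl])
    mu <- nl * ybar
    sd2 <- yvar * nl * (n - nl) / n
    z <- abs(s - mu) / sqrt(sd2)
    if (z > best) best <- z
  }
  best
}

# Best binary partition for the chosen covariate honouring minbucket.
#' @keywords internal
best_split <- function(y, x, minbucket) {
  ok <- !is.na(x)
  if (is.numeric(x)) {
    cuts <- sort(unique(x[ok]))
    if (length(cuts) < 2) return(NULL)
    cuts <- cuts[-length(cuts)]
    best <- NULL; best_stat <- -Inf
    for (cc in cuts) {
      left <- !is.na(x) & x <= cc
      if (sum(left) < minbucket || sum(!left) < minbucket) next
      st <- split_stat(y, left)
      if (st > best_stat) { best_stat <- st; best <- cc }
    }
    if (is.null(best)) return(NULL)
    return(list(split = list(type = "numeric", cutpoint = best),
                left = !is.na(x) & x <= best))
  }
  lev <- sort(unique(x[ok]))
  L <- length(lev)
  if (L < 2) return(NULL)
  if (L > 12) stop("categorical covariate with more than 12 levels", call. = FALSE)
  best <- NULL; best_stat <- -Inf
  for (mask in 1:(2^(L - 1) - 1)) {        # level 1 fixed to the right set
    inset <- lev[bitwAnd(mask, 2^(seq_len(L) - 1)) > 0]
    left <- !is.na(x) & x %in% inset
    if (sum(left) < minbucket || sum(!left) < minbucket) next
    st <- split_stat(y, left)
    if (st > best_stat) { best_stat <- st; best <- inset }
  }
  if (is.null(best)) return(NULL)
  list(split = list(type = "categorical", levels_left = best,
                    levels_right = setdiff(lev, best)),
       left = !is.na(x) & x %in% best)
}

#' @keywords internal
split_stat <- function(y, left) {
  tab <- table(left, y)
  if (any(dim(tab) < 2)) return(-Inf)
  chisq_stat(tab)
}

#' Proportion of positive effects per group
#'
#' @param responses logical (or 0/1) direction per effect; g exactly 0 counts
#'   as non-positive.
#' @param grouping grouping vector (e.g. crop stem type), same length.
#' @return named numeric vector: proportion positive per group level.
#' @export
direction_proportions <- function(responses, grouping) {
  y <- as.logical(responses)
  stopifnot(length(y) == length(grouping))
  out <- tapply(y, as.character(grouping), mean)
  stats::setNames(as.vector(out), names(out))
}

#' @export
print.ctree_node <- function(x, indent = "", ...) {
  lab <- sprintf("node %d: n=%d (+%d/-%d)", x$node_id, x$n,
                 x$class_counts[1], x$class_counts[2])
  if (!is.null(x$split_variable)) {
    pv <- x$p_values[[x$split_variable]]
    if (x$split$type == "categorical") {
      cat(indent, lab, sprintf(" split on %s (adj p = %.4g): {%s} | {%s}\n",
                               x$split_variable, pv,
                               paste(x$split$levels_left, collapse = ","),
                               paste(x$split$levels_right, collapse = ",")),
          sep = "")
    } else {
      cat(indent, lab, sprintf(" split on %s (adj p = %.4g): <= %g | > %g\n",
                               x$split_variable, pv,
                               x$split$cutpoint, x$split$cutpoint), sep = "")
    }
    for (ch in x$children) print(ch, indent = paste0(indent, "  "))
  } else {
    cat(indent, lab, " [leaf]\n", sep = "")
  }
  invisible(x)
}
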