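test_that("the benefit index is the cellwise woody share with proper missingness", {
  w <- grid_layer(matrix(c(30, 120, 0, NA), 2, 2))
  t <- grid_layer(matrix(c(120, 120, 0, 5), 2, 2))
  b <- benefit_index(w, t)
  expect_equal(b$values[1, 1], 0.25)
  expect_equal(b$values[2, 1], 1)          # all-woody cell
  expect_true(is.na(b$values[1, 2]))       # zero total -> missing
  expect_true(is.na(b$values[2, 2]))       # missing woody -> missing
  w2 <- grid_layer(matrix(10, 2, 2)); t2 <- grid_layer(matrix(5, 2, 2))
  expect_error(benefit_index(w2, t2), "exceeds")
  expect_error(benefit_index(w, grid_layer(matrix(1, 3, 3))),
               "co-registered")
  # random grids against a cell-by-cell loop oracle
  set.seed(3)
  tv <- matrix(runif(30, 1, 5), 5, 6)
  wv <- tv * matrix(runif(30), 5, 6)
  bi <- benefit_index(grid_layer(wv), grid_layer(tv))
  for (i in 1:5) for (j in 1:6)
    expect_equal(bi$values[i, j], wv[i, j] / tv[i, j])
})

test_that("min-max standardization hits the endpoints and degrades gracefully", {
  l <- grid_layer(matrix(c(2, 4, 6, NA), 2, 2))
  s <- standardize_minmax(l)
  expect_equal(sort(as.vector(s$values[!is.na(s$values)])), c(0, 0.5, 1))
  expect_true(is.na(s$values[2, 2]))
  expect_warning(sc <- standardize_minmax(grid_layer(matrix(7, 2, 2))),
                 "constant")
  expect_true(all(sc$values == 0))
})

test_that("the integrative index is a symmetric product of standardized layers", {
  set.seed(4)
  a <- grid_layer(matrix(runif(20, 0, 9), 4, 5))
  b <- grid_layer(matrix(runif(20, 0, 3), 4, 5))
  ii <- integrative_index(a, b)
  ii_swap <- integrative_index(b, a)
  expect_equal(ii$values, ii_swap$values)
  # loop oracle
  sa <- (a$values - min(a$values)) / diff(range(a$values))
  sb <- (b$values - min(b$values)) / diff(range(b$values))
  for (i in 1:4) for (j in 1:5)
    expect_equal(ii$values[i, j], sa[i, j] * sb[i, j])
  # a cell at the maximum of both inputs scores exactly 1; minima annihilate
  a1 <- a; b1 <- b
  a1$values[3, 3] <- max(a$values) + 1
  b1$values[3, 3] <- max(b$values) + 1
  expect_equal(integrative_index(a1, b1)$values[3, 3], 1)
  expect_equal(integrative_index(a1, b1)$values[which.min(a1$values)], 0)
})

test_that("tercile classification cuts at the 1/3 and 2/3 quantiles", {
  l <- grid_layer(matrix(c(9, 1, 5, 3, 7, 2, 8, 4, 6), 3, 3))
  tc <- tercile_classify(l)
  expect_equal(sum(tc == 1), 3)
  expect_equal(sum(tc == 2), 3)
  expect_equal(sum(tc == 3), 3)
  expect_equal(tc[l$values <= 3], rep(1L, 3))
  expect_warning(t1 <- tercile_classify(grid_layer(matrix(5, 3, 3))),
                 "tercile 1")
  expect_true(all(t1 == 1))
  # near-balanced counts on random grids with distinct values
  set.seed(6)
  for (r in 1:5) {
    x <- grid_layer(matrix(sample(seq(0.1, 99, by = 0.7), 126), 9, 14))
    tt <- tercile_classify(x)
    n <- sum(!is.na(tt))
    expect_true(all(abs(table(tt) - n / 3) <= 1))
  }
})

test_that("the bivariate class grid and priority mask behave as a 3x3 cross", {
  b <- grid_layer(matrix(rep(1:9, each = 1), 3, 3))
  c_ <- grid_layer(matrix(rep(1:9, each = 1), 3, 3))
  pm <- priority_mask(b, c_)
  expect_equal(pm$class[b$values <= 3], rep(1L, 3))      # bottom in both
  expect_equal(pm$class[b$values >= 7], rep(9L, 3))      # top in both
  expect_identical(pm$priority, pm$class == 9L)
  expect_equal(nrow(pm$legend), 9)
  expect_identical(pm$legend$priority, pm$legend$class == 9L)
  # missing in either input is missing everywhere
  b2 <- b; b2$values[1, 1] <- NA
  pm2 <- priority_mask(b2, c_)
  expect_true(is.na(pm2$class[1, 1]) && !pm2$priority[1, 1])
})

test_that("the priority mask recovers a planted hot corner exactly and is rank-invariant", {
  g <- simulate_grids(grid_sim_config(shape = c(30, 45),
                                      hot_corner = list(rows = 1:5, cols = 1:5)),
                      seed = 11)
  ben <- benefit_index(g$woody, g$total)
  cons <- integrative_index(g$threatened, g$richness)
  pm <- priority_mask(ben, cons)
  planted <- matrix(FALSE, 30, 45); planted[1:5, 1:5] <- TRUE
  expect_identical(pm$priority, planted)
  # strictly monotone transforms of the inputs leave the mask unchanged
  ben3 <- grid_layer(ben$values^3)
  cons3 <- grid_layer(exp(cons$values))
  pm3 <- priority_mask(ben3, cons3)
  expect_identical(pm3$priority, pm$priority)
  expect_identical(pm3$class, pm$class)
})

test_that("ESRI ASCII grids round-trip through write and read", {
  set.seed(12)
  m <- matrix(round(runif(24, 0, 50), 3), 4, 6)
  m[2, 3] <- NA
  l <- grid_layer(m, xll = -180, yll = -60, cellsize = 0.5)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(l, path)
  l2 <- read_ascii_grid(path)
  expect_equal(l2$values, l$values)
  expect_equal(l2$xll, -180)
  expect_equal(l2$cellsize, 0.5)
  expect_error(read_ascii_grid(tempfile()), "file not found")
})
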