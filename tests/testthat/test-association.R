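test_that("pearson_matrix is symmetric with unit diagonal and exact limits", {
  d <- make_dataset(fe = c(0.1, 0.2, 0.3, 0.4))
  d$as_conc <- d$fe          # identical -> 1
  d$tds <- 1000 - 500 * d$fe # affine decreasing -> -1
  M <- pearson_matrix(d, vars = c("fe", "as_conc", "tds"))
  expect_equal(M["fe", "as_conc"], 1)
  expect_equal(M["fe", "tds"], -1)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 1))
})

test_that("pearson_matrix agrees with a naive two-pass oracle", {
  set.seed(42)
  d <- random_dataset(1, n = 100)
  d$ec[sample(100, 10)] <- NA  # exercise pairwise-complete deletion
  M <- pearson_matrix(d, vars = c("fe", "as_conc", "ec", "tds", "depth"))
  for (a in rownames(M)) {
    for (b in colnames(M)) {
      expect_equal(M[a, b], oracle_pearson(d[[a]], d[[b]]),
                   tolerance = 1e-12, label = paste(a, b))
    }
  }
  np <- attr(M, "n_pairs")
  expect_equal(np["fe", "ec"], sum(!is.na(d$ec)))
})

test_that("zero-variance variables yield NA entries with a warning", {
  d <- make_dataset(fe = c(0.5, 0.5, 0.5), as_conc = c(0.01, 0.02, 0.03))
  expect_warning(M <- pearson_matrix(d, vars = c("fe", "as_conc")), "zero-variance")
  expect_true(is.na(M["fe", "as_conc"]))
  expect_equal(diag(M), c(fe = 1, as_conc = 1))
})

test_that("depth regression recovers closed-form least squares", {
  d1 <- make_dataset(fe = c(1, 2, 3), depth = c(1, 2, 3))
  f1 <- fit_depth_regression(d1, "fe")
  expect_equal(f1$w0, 0, tolerance = 1e-12)
  expect_equal(f1$w, 1, tolerance = 1e-12)
  expect_equal(f1$r2, 1, tolerance = 1e-12)

  d2 <- make_dataset(fe = c(1, 0, 1), depth = c(0, 1, 2))
  f2 <- fit_depth_regression(d2, "fe")
  expect_equal(f2$w, 0, tolerance = 1e-12)
  expect_equal(f2$r, 0, tolerance = 1e-12)
  expect_equal(f2$r2, f2$r^2, tolerance = 1e-12)

  d3 <- random_dataset(17, n = 25)
  f3 <- fit_depth_regression(d3, "fe")
  expect_equal(sign(f3$r), sign(f3$w))
  expect_equal(f3$r2, f3$r^2, tolerance = 1e-12)

  expect_error(fit_depth_regression(make_dataset(fe = c(1, 2, 3), depth = 300), "fe"),
               "constant")
})

test_that("regression residuals are orthogonal to the predictor", {
  d <- random_dataset(3, n = 50)
  f <- fit_depth_regression(d, "as")
  res <- d$as_conc - (f$w0 + f$w * d$depth)
  expect_lt(abs(sum(res * d$depth)), 1e-8 * sum(abs(res * d$depth) + 1))
})

test_that("PCA handles perfectly correlated and independent variables", {
  d <- make_dataset(fe = seq(0.1, 2, length.out = 20))
  d$as_conc <- d$fe * 0.05
  p <- run_pca(d, vars = c("fe", "as_conc"))
  expect_equal(p$explained_pct[1], 100, tolerance = 1e-9)

  set.seed(9)
  n <- 5000
  di <- make_dataset(fe = exp(rnorm(n)), tds = exp(rnorm(n)))
  pi <- run_pca(di, vars = c("fe", "tds"))
  expect_equal(pi$explained_pct, c(50, 50), tolerance = 2)
})

test_that("PCA matches an independent eigen-solver oracle on a 3-variable toy", {
  set.seed(4)
  n <- 60
  d <- make_dataset(fe = exp(rnorm(n)), tds = exp(rnorm(n, 6, 0.3)),
                    ec = exp(rnorm(n, 6.8, 0.3)))
  d$ec <- d$ec * (1 + 0.5 * scale(d$tds)[, 1])^2  # induce correlation
  vars <- c("fe", "tds", "ec")
  p <- run_pca(d, vars = vars)

  # oracle: prcomp on the same transformed, scaled data
  eps <- vapply(vars, function(v) 0.5 * min(d[[v]][d[[v]] > 0]), 0)
  L <- log10(sweep(as.matrix(d[, vars]), 2, -eps))
  pr <- prcomp(L, center = TRUE, scale. = TRUE)
  expect_equal(abs(unclass(p$loadings)), abs(t(unclass(pr$rotation))),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(p$explained_pct, 100 * pr$sdev^2 / sum(pr$sdev^2),
               tolerance = 1e-8)
})

test_that("PCA output satisfies its structural invariants", {
  d <- generate_dataset(synthetic_config(n = 75, seed = 2))
  p <- run_pca(d)
  expect_true(all(diff(p$explained_pct) <= 1e-9))
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-9)
  expect_equal(p$loadings %*% t(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: dominant loading of each component is positive
  for (k in seq_len(nrow(p$loadings))) {
    expect_gte(p$loadings[k, which.max(abs(p$loadings[k, ]))], 0)
  }
  # reconstruction of the transformed data from all components
  Zs <- p$scores %*% p$loadings
  L <- log10(sweep(as.matrix(d[, p$preprocessing$variable]), 2,
                   -p$preprocessing$eps))
  Zref <- scale(L, center = p$preprocessing$center, scale = p$preprocessing$scale)
  expect_equal(unclass(Zs), unclass(Zref), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("PCA refuses an all-zero variable by name", {
  d <- make_dataset(fe = rep(0, 20), tds = exp(rnorm(20)))
  expect_error(run_pca(d, vars = c("fe", "tds")), "fe")
})
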