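test_that("feature encoding applies thresholds and a reversible codebook", {
  d <- make_dataset(fe = 0.94, as_conc = 0.02)
  f <- encode_features(d)
  expect_equal(f$fe_who, 1L)
  expect_equal(f$as_who, 1L)
  expect_equal(f$as_bdws, 0L)
  expect_equal(f$fe_bdws, 0L)

  z <- encode_features(make_dataset(fe = 0, as_conc = 0))
  expect_true(all(z[, c("fe_who", "fe_bdws", "as_who", "as_bdws")] == 0))

  expect_equal(decode_union(encode_union(union_levels())), union_levels())
  expect_error(encode_union("Nowhere"), "unknown union")
  expect_error(encode_features(make_dataset(fe = NA_real_)), "fe")
})

test_that("the regularized update with alpha = 0 is a plain gradient step", {
  set.seed(2)
  X <- matrix(rnorm(40), 8, 5)
  y <- matrix(rnorm(8), ncol = 1)
  net0 <- tubewellrisk:::init_weights(c(5, 4, 1))
  act <- tubewellrisk:::activation_fun("relu")
  eta <- 0.05
  alpha <- 0.7
  plain <- tubewellrisk:::mlp_step(net0, X, y, act, eta, 0)
  penal <- tubewellrisk:::mlp_step(net0, X, y, act, eta, alpha)
  for (l in seq_along(net0$W)) {
    # penalty shifts each weight by exactly -eta * alpha * w
    expect_lt(max(abs(penal$W[[l]] - (plain$W[[l]] - eta * alpha * net0$W[[l]]))),
              1e-10)
    expect_equal(penal$b[[l]], plain$b[[l]], tolerance = 1e-12)
  }
})

test_that("the surrogate learns a representable noiseless function", {
  d <- generate_dataset(synthetic_config(n = 500, seed = 7))
  f <- encode_features(d)
  y <- 2 * scale(f$depth)[, 1] - 1.5 * scale(f$fe)[, 1] + 0.5 * scale(f$ec)[, 1] + 3
  m <- train_surrogate(f, y, surrogate_config(seed = 1))
  expect_gte(m$report$test_r2, 0.99)
})

test_that("training is seed-deterministic and degrades gracefully on a constant target", {
  d <- generate_dataset(synthetic_config(n = 80, seed = 4))
  f <- encode_features(d)
  y <- log1p(f$fe) + 0.1 * scale(f$depth)[, 1]
  cfg <- surrogate_config(epochs = 30, seed = 9)
  m1 <- train_surrogate(f, y, cfg)
  m2 <- train_surrogate(f, y, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, f), predict(m2, f))

  mc <- train_surrogate(f, rep(2, nrow(f)), surrogate_config(epochs = 5, seed = 1))
  expect_true(is.na(mc$report$train_r2))
  expect_equal(unname(predict(mc, f)), rep(2, nrow(f)), tolerance = 0.2)

  expect_error(
    train_surrogate(f, y, surrogate_config(eta = 1e6, epochs = 5, seed = 1)),
    "eta")
  expect_error(train_surrogate(f[1:10, ], y[1:10]), "at least 20")
})

test_that("cross-validation is deterministic, exhaustive, and over-regularization hurts", {
  d <- generate_dataset(synthetic_config(n = 100, seed = 10))
  f <- encode_features(d)
  y <- 2 * scale(f$depth)[, 1] + scale(f$tds)[, 1]  # low-noise target
  cfg <- surrogate_config(epochs = 60, cv_folds = 5, seed = 3,
                          alpha_sweep = c(0.1, 1, 10))
  cv1 <- cross_validate(f, y, cfg)
  cv2 <- cross_validate(f, y, cfg)
  expect_identical(cv1$summary, cv2$summary)
  # every row validated exactly once per alpha
  expect_equal(sort(unique(table(cv1$fold_id))), 20)
  expect_equal(sum(cv1$folds$n_test), 3 * 100)
  expect_true(all(is.finite(cv1$summary$mean_r2)))
  expect_lt(cv1$summary$mean_r2[cv1$summary$alpha == 10],
            cv1$summary$mean_r2[cv1$summary$alpha == 0.1])
})

test_that("ten folds on ten rows is leave-one-out", {
  f <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  y <- f$a + f$b
  cfg <- surrogate_config(hidden_layers = 4, epochs = 10, cv_folds = 10,
                          alpha_sweep = 0.1, seed = 2)
  cv <- cross_validate(f, y, cfg)
  expect_equal(nrow(cv$folds), 10)
  expect_true(all(cv$folds$n_test == 1))
  expect_error(cross_validate(f[1:5, ], y[1:5],
                              surrogate_config(cv_folds = 10)), "folds")
})

test_that("exact Shapley values satisfy efficiency and the linear closed form", {
  w <- c(2, -1, 0.5, 3)
  model <- linear_region_surrogate(w)
  set.seed(8)
  bg <- tibble::as_tibble(setNames(as.data.frame(matrix(runif(40 * 4, 1, 5), 40)),
                                   model$feature_names))
  x <- setNames(as.list(c(2, 3, 4, 1.5)), model$feature_names)
  att <- shapley_attribution(model, x, bg)
  expect_equal(att$baseline + sum(att$shap), att$prediction, tolerance = 1e-6)
  closed <- w * (unlist(x) - colMeans(bg))
  expect_equal(unname(att$shap), unname(closed), tolerance = 1e-8)
  expect_equal(att$baseline, mean(predict(model, bg)), tolerance = 1e-10)

  # single feature: the attribution is the full gap to baseline
  m1 <- linear_region_surrogate(2.5)
  bg1 <- tibble::tibble(f1 = runif(20, 1, 4))
  a1 <- shapley_attribution(m1, list(f1 = 3), bg1)
  expect_equal(unname(a1$shap), a1$prediction - a1$baseline, tolerance = 1e-10)
})

test_that("efficiency holds for a trained nonlinear surrogate", {
  d <- generate_dataset(synthetic_config(n = 120, seed = 6))
  f <- encode_features(d)
  p <- exposure_params("table-consistent")
  y <- log(fir_combined(d$fe, d$as_conc, p))
  ok <- is.finite(y)
  m <- train_surrogate(f[ok, ], y[ok], surrogate_config(epochs = 60, seed = 1))
  att <- shapley_attribution(m, f[ok, ][3, ], f[ok, ][1:40, ])
  expect_equal(att$baseline + sum(att$shap), att$prediction, tolerance = 1e-6)
  expect_equal(att$prediction, unname(predict(m, f[ok, ][3, ])), tolerance = 1e-10)
})

test_that("duplicated symmetric features receive equal attributions", {
  w <- c(1.5, 1.5, -2)
  model <- linear_region_surrogate(w)
  set.seed(3)
  base <- runif(30, 1, 5)
  bg <- tibble::tibble(f1 = base, f2 = base, f3 = runif(30, 1, 5))
  x <- list(f1 = 2.5, f2 = 2.5, f3 = 4)
  att <- shapley_attribution(model, x, bg)
  expect_lt(abs(att$shap[["f1"]] - att$shap[["f2"]]), 1e-8)
})

test_that("sampling mode agrees with exact enumeration within Monte-Carlo error", {
  w <- c(1, -2, 0.5, 2, -1, 0.3, 1.2, -0.7)
  model <- linear_region_surrogate(w)
  set.seed(11)
  bg <- tibble::as_tibble(setNames(as.data.frame(matrix(runif(30 * 8, 1, 5), 30)),
                                   model$feature_names))
  x <- setNames(as.list(runif(8, 1, 5)), model$feature_names)
  exact <- shapley_attribution(model, x, bg, mode = "exact")
  runs <- sapply(1:5, function(s) {
    shapley_attribution(model, x, bg, mode = "sampling", n_perm = 150,
                        seed = s)$shap
  })
  mc_se <- apply(runs, 1, sd)
  expect_true(all(abs(rowMeans(runs) - exact$shap) <= 3 * pmax(mc_se, 1e-6)))
})

test_that("a persisted surrogate reloads with identical predictions", {
  d <- generate_dataset(synthetic_config(n = 60, seed = 14))
  f <- encode_features(d)
  y <- log1p(f$fe)
  m <- train_surrogate(f, y, surrogate_config(epochs = 20, seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_surrogate(m, path)
  m2 <- read_surrogate(path)
  expect_equal(predict(m2, f), predict(m, f), tolerance = 1e-12)
})

test_that("the two-group diagnostic separates blobs and flags degeneracy", {
  set.seed(20)
  blob <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  preds <- dplyr::bind_rows(
    tibble::tibble(alpha = 0.1, prediction = blob, actual = blob + rnorm(40, 0, 0.05)),
    tibble::tibble(alpha = 1, prediction = blob, actual = blob + rnorm(40, 0, 0.05))
  )
  rep <- alpha_cluster_report(preds, seed = 1)
  expect_true(all(rep$summary$agreement_pct == 100))
  expect_equal(rep$summary$n1 + rep$summary$n2, c(40, 40))

  # agreement equals a brute-force co-assignment recount
  a1 <- rep$assignments[, 1]
  a2 <- rep$assignments[, 2]
  brute <- 100 * max(mean(a1 == a2), mean(a1 == (3L - a2)))
  expect_equal(rep$summary$agreement_pct[2], brute)

  ident <- dplyr::bind_rows(
    tibble::tibble(alpha = 0.1, prediction = rep(1, 10), actual = rep(1, 10)),
    tibble::tibble(alpha = 1, prediction = rep(1, 10), actual = rep(1, 10))
  )
  repd <- alpha_cluster_report(ident, seed = 1)
  expect_true(all(repd$summary$degenerate))

  expect_error(alpha_cluster_report(preds[c(1, 41), ]), "4 samples|2 alpha")
})
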