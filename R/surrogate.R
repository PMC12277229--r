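#' Union integer codebook
#'
#' Fixed encoding of the four unions used in the numeric feature table.
#'
#' @return Named integer vector (union name -> code).
#' @export
union_codebook <- function() {
  setNames(seq_along(UNION_LEVELS), UNION_LEVELS)
}

#' @rdname union_codebook
#' @param union_name Character vector of union names.
#' @export
encode_union <- function(union_name) {
  code <- union_codebook()[union_name]
  if (any(is.na(code))) {
    stop("unknown union: ", paste(unique(union_name[is.na(code)]), collapse = ", "))
  }
  unname(code)
}

#' @rdname union_codebook
#' @param code Integer vector of union codes.
#' @export
decode_union <- function(code) {
  if (any(is.na(code)) || any(!code %in% union_codebook())) {
    stop("unknown union code")
  }
  UNION_LEVELS[code]
}

#' Encode a sample table into the numeric feature matrix
#'
#' Builds the fixed-order feature table used by the surrogate model: the
#' union as an integer code (see [union_codebook()]), depth, the two
#' analyte concentrations, pH, EC and TDS, plus binary guideline-exceedance
#' flags for iron (WHO, BDWS) and arsenic (WHO, BDWS).
#'
#' @param d A validated sample table.
#' @param registry A [guideline_registry()].
#' @return A tibble with columns `union_code, depth, fe, as_conc, ph, ec,
#'   tds, fe_who, fe_bdws, as_who, as_bdws`; the codebook is attached as
#'   attribute `"codebook"`.
#' @export
encode_features <- function(d, registry = guideline_registry()) {
  validate_registry(registry)
  needed <- c("union_name", "depth", "fe", "as_conc", "ph", "ec", "tds")
  for (col in needed) {
    if (!col %in% names(d)) stop("missing mandatory feature: ", col)
    if (any(is.na(d[[col]]))) stop("missing values in mandatory feature: ", col)
  }
  flag_for <- function(parameter, authority) {
    rule <- registry[registry$parameter == parameter & registry$authority == authority, ]
    if (nrow(rule) != 1) stop("no registry rule for ", authority, " ", parameter)
    as.integer(rule_exceeds(d[[param_column(parameter)]], rule))
  }
  out <- tibble::tibble(
    union_code = encode_union(d$union_name),
    depth = d$depth, fe = d$fe, as_conc = d$as_conc,
    ph = d$ph, ec = d$ec, tds = d$tds,
    fe_who = flag_for("fe", "WHO"),
    fe_bdws = flag_for("fe", "BDWS"),
    as_who = flag_for("as", "WHO"),
    as_bdws = flag_for("as", "BDWS")
  )
  attr(out, "codebook") <- union_codebook()
  out
}

#' Surrogate model configuration
#'
#' Hyperparameters for the feed-forward surrogate of the safe-intake limit.
#' The weight update follows the regularized gradient rule
#' `w <- w - eta * (alpha * dR/dw + dLoss/dw)` with `R(w) = 0.5 * ||w||^2`
#' over the connection weights and a half mean-squared-error loss over each
#' mini-batch.
#'
#' @param hidden_layers Integer vector of hidden-layer sizes.
#' @param activation `"relu"` or `"tanh"`.
#' @param eta Learning rate (> 0).
#' @param alpha L2 regularization strength (>= 0).
#' @param alpha_sweep Regularization grid for [cross_validate()]; defaults
#'   to the half-decade grid 10^(-1, -0.5, 0, 0.5, 1).
#' @param epochs Number of passes over the training data.
#' @param batch_size Mini-batch size.
#' @param split_fraction Fraction of rows used for training (rest held
#'   out), in (0, 1).
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed controlling split, initialization and batch
#'   order.
#' @return A list of class `tw_surrogate_config`.
#' @export
surrogate_config <- function(hidden_layers = c(16, 8),
                             activation = c("relu", "tanh"),
                             eta = 0.02,
                             alpha = 1e-4,
                             alpha_sweep = 10^seq(-1, 1, by = 0.5),
                             epochs = 400L,
                             batch_size = 32L,
                             split_fraction = 0.9,
                             cv_folds = 10L,
                             seed = 1L) {
  activation <- match.arg(activation)
  stopifnot(eta > 0, alpha >= 0, all(alpha_sweep >= 0),
            split_fraction > 0, split_fraction < 1,
            epochs >= 1, batch_size >= 1, cv_folds >= 2,
            all(hidden_layers >= 1))
  cfg <- list(
    hidden_layers = as.integer(hidden_layers), activation = activation,
    eta = eta, alpha = alpha, alpha_sweep = alpha_sweep,
    loss = "squared_error",
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    split_fraction = split_fraction, cv_folds = as.integer(cv_folds),
    seed = as.integer(seed)
  )
  class(cfg) <- "tw_surrogate_config"
  cfg
}

activation_fun <- function(name) {
  switch(name,
    relu = list(f = function(x) pmax(x, 0), df = function(x) (x > 0) * 1),
    tanh = list(f = tanh, df = function(x) 1 - tanh(x)^2)
  )
}

# He-style initialization, drawn from the current RNG stream.
init_weights <- function(sizes) {
  W <- list()
  b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(2 / sizes[l])),
                     nrow = sizes[l])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  list(W = W, b = b)
}

# Forward pass on already-scaled inputs; returns activations per layer.
mlp_forward <- function(net, X, act) {
  L <- length(net$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Zl <- A[[l]] %*% net$W[[l]] + matrix(net$b[[l]], nrow(A[[l]]),
                                         length(net$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < L) act$f(Zl) else Zl
  }
  A
}

# One regularized gradient step on a mini-batch:
# w <- w - eta * (alpha * w + dLoss/dw), Loss = mean((pred - y)^2) / 2.
# Biases carry no penalty.
mlp_step <- function(net, X, y, act, eta, alpha) {
  L <- length(net$W)
  A <- mlp_forward(net, X, act)
  m <- nrow(X)
  delta <- (A[[L + 1]] - y) / m
  for (l in rev(seq_len(L))) {
    gW <- crossprod(A[[l]], delta)
    gb <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) * act$df(A[[l]])
    }
    net$W[[l]] <- net$W[[l]] - eta * (alpha * net$W[[l]] + gW)
    net$b[[l]] <- net$b[[l]] - eta * gb
  }
  net
}

r_squared <- function(actual, predicted) {
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((actual - predicted)^2) / ss_tot
}

# Stratified train/holdout split: within each stratum a seeded fraction
# goes to training (drawn from the current RNG stream).
split_indices <- function(n, fraction, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, n)
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- max(1L, round(fraction * length(idx)))
    train <- c(train, sort(sample(idx, k)))
  }
  sort(train)
}

#' Train the feed-forward surrogate
#'
#' Fits a small fully connected network to a numeric target by mini-batch
#' gradient descent with an L2 penalty, following the update
#' `w <- w - eta * (alpha * dR/dw + dLoss/dw)`. Features and target are
#' centered and unit-scaled using training rows only; the split is seeded
#' and, when a `union_code` column is present, stratified by union. A fixed
#' seed yields identical weights.
#'
#' @param features Numeric feature table (e.g. from [encode_features()]).
#' @param target Numeric target vector (same length as `nrow(features)`).
#' @param cfg A [surrogate_config()].
#' @param holdout If `FALSE`, all rows train and no test metrics are
#'   computed (used by [cross_validate()]).
#' @return A list of class `tw_surrogate`: config, `weights`,
#'   `feature_names`, `feature_scaling`, `target_scaling`, `fitted`, and a
#'   `report` tibble with train/test R-squared (`NA` when undefined, e.g. a
#'   constant target).
#' @export
train_surrogate <- function(features, target, cfg = surrogate_config(),
                            holdout = TRUE) {
  stopifnot(inherits(cfg, "tw_surrogate_config"))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  # the holdout path needs enough rows for a meaningful split; internal
  # cross-validation folds may train on fewer
  if (holdout && nrow(X) < 20) stop("train_surrogate needs at least 20 rows")
  if (nrow(X) < 2) stop("train_surrogate needs at least 2 rows")
  if (length(target) != nrow(X)) stop("target length must match feature rows")
  if (any(!is.finite(target))) stop("target must be finite")
  if (any(!is.finite(X))) stop("features must be finite")
  act <- activation_fun(cfg$activation)

  with_seed(cfg$seed, {
    strata <- if ("union_code" %in% colnames(X)) X[, "union_code"] else NULL
    train_idx <- if (holdout) {
      split_indices(nrow(X), cfg$split_fraction, strata)
    } else {
      seq_len(nrow(X))
    }
    test_idx <- setdiff(seq_len(nrow(X)), train_idx)

    ctr <- colMeans(X[train_idx, , drop = FALSE])
    scl <- apply(X[train_idx, , drop = FALSE], 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    y_ctr <- mean(target[train_idx])
    y_scl <- sd(target[train_idx])
    if (!is.finite(y_scl) || y_scl == 0) y_scl <- 1

    Xs <- scale(X, center = ctr, scale = scl)
    ys <- (target - y_ctr) / y_scl

    sizes <- c(ncol(X), cfg$hidden_layers, 1L)
    net <- init_weights(sizes)
    ntr <- length(train_idx)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(ntr)
      starts <- seq(1, ntr, by = cfg$batch_size)
      for (s in starts) {
        rows <- train_idx[ord[s:min(s + cfg$batch_size - 1, ntr)]]
        net <- mlp_step(net, Xs[rows, , drop = FALSE],
                        matrix(ys[rows], ncol = 1), act, cfg$eta, cfg$alpha)
      }
      if (any(!vapply(net$W, function(w) all(is.finite(w)), TRUE))) {
        stop("training diverged (non-finite weights); reduce eta")
      }
    }

    pred_s <- mlp_forward(net, Xs, act)[[length(net$W) + 1]][, 1]
    if (any(!is.finite(pred_s))) {
      stop("training diverged (non-finite loss); reduce eta")
    }
    pred <- pred_s * y_scl + y_ctr
    report <- tibble::tibble(
      n_train = length(train_idx),
      n_test = length(test_idx),
      train_r2 = r_squared(target[train_idx], pred[train_idx]),
      test_r2 = if (length(test_idx) >= 2) {
        r_squared(target[test_idx], pred[test_idx])
      } else NA_real_,
      train_rmse = sqrt(mean((target[train_idx] - pred[train_idx])^2))
    )

    model <- list(
      config = cfg,
      weights = net,
      feature_names = colnames(X),
      feature_scaling = list(center = ctr, scale = scl),
      target_scaling = list(center = y_ctr, scale = y_scl),
      fitted = TRUE,
      train_idx = train_idx,
      test_idx = test_idx,
      report = report
    )
    class(model) <- "tw_surrogate"
    model
  })
}

#' @export
print.tw_surrogate <- function(x, ...) {
  cat(sprintf("Feed-forward surrogate (%s, layers %s)\n",
              x$config$activation,
              paste(c(length(x$feature_names), x$config$hidden_layers, 1),
                    collapse = "-")))
  print(x$report)
  invisible(x)
}

#' Predict from a fitted surrogate
#'
#' @param object A fitted `tw_surrogate`.
#' @param newdata Feature table or matrix with the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of predictions on the target's original scale.
#' @export
predict.tw_surrogate <- function(object, newdata, ...) {
  stopifnot(isTRUE(object$fitted))
  X <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  storage.mode(X) <- "double"
  Xs <- scale(X, center = object$feature_scaling$center,
              scale = object$feature_scaling$scale)
  act <- activation_fun(object$config$activation)
  pred_s <- mlp_forward(object$weights, Xs, act)[[length(object$weights$W) + 1]][, 1]
  pred_s * object$target_scaling$scale + object$target_scaling$center
}

#' k-fold cross-validation over the regularization sweep
#'
#' Deterministic (seeded) fold assignment; every row is validated exactly
#' once per `alpha` in `cfg$alpha_sweep`.
#'
#' @inheritParams train_surrogate
#' @return A list of class `tw_cv`: `folds` (tibble `alpha, fold, n_test,
#'   r2`) and `summary` (tibble `alpha, mean_r2, sd_r2`).
#' @export
cross_validate <- function(features, target, cfg = surrogate_config()) {
  stopifnot(inherits(cfg, "tw_surrogate_config"))
  X <- as.data.frame(features)
  n <- nrow(X)
  k <- cfg$cv_folds
  if (k > n) stop("more folds than rows")
  fold_id <- with_seed(cfg$seed, sample(rep(seq_len(k), length.out = n)))
  rows <- list()
  for (alpha in cfg$alpha_sweep) {
    cfg_a <- cfg
    cfg_a$alpha <- alpha
    for (f in seq_len(k)) {
      test <- which(fold_id == f)
      train <- setdiff(seq_len(n), test)
      model <- train_surrogate(X[train, , drop = FALSE], target[train],
                               cfg_a, holdout = FALSE)
      pred <- predict(model, X[test, , drop = FALSE])
      rows[[length(rows) + 1]] <- tibble::tibble(
        alpha = alpha, fold = f, n_test = length(test),
        r2 = if (length(test) >= 2) r_squared(target[test], pred) else NA_real_,
        rmse = sqrt(mean((target[test] - pred)^2))
      )
    }
  }
  folds <- dplyr::bind_rows(rows)
  summary <- folds |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(mean_r2 = mean(.data$r2, na.rm = TRUE),
                     sd_r2 = sd(.data$r2, na.rm = TRUE),
                     mean_rmse = mean(.data$rmse),
                     .groups = "drop")
  out <- list(folds = folds, summary = summary, fold_id = fold_id)
  class(out) <- "tw_cv"
  out
}

#' @export
print.tw_cv <- function(x, ...) {
  cat("Cross-validation over the regularization sweep\n")
  print(x$summary)
  invisible(x)
}

#' Shapley attribution of a surrogate prediction
#'
#' Exact Shapley values by enumeration over all feature coalitions for up
#' to 12 features; above that a seeded Monte-Carlo permutation estimator is
#' used. Absent features are integrated out over the background table
#' (interventional convention: the coalition value is the mean model
#' prediction with absent columns taken from background rows), so the
#' efficiency axiom `baseline + sum(shap) = prediction` holds exactly.
#'
#' @param model A fitted `tw_surrogate`.
#' @param x A one-row feature table (or named vector) to explain.
#' @param background Feature table of background rows (non-empty).
#' @param mode `"auto"` (exact up to 12 features), `"exact"` or
#'   `"sampling"`.
#' @param n_perm Number of permutations in sampling mode.
#' @param seed Seed for sampling mode.
#' @return A list of class `tw_attribution`: `baseline` (mean background
#'   prediction), `shap` (named vector), `prediction`.
#' @export
shapley_attribution <- function(model, x, background,
                                mode = c("auto", "exact", "sampling"),
                                n_perm = 200L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "tw_surrogate"), isTRUE(model$fitted))
  background <- as.data.frame(background)
  if (nrow(background) == 0) stop("background set must be non-empty")
  feats <- model$feature_names
  xv <- unlist(as.data.frame(as.list(x))[1, feats])
  bg <- as.matrix(background[, feats, drop = FALSE])
  storage.mode(bg) <- "double"
  p <- length(feats)
  if (mode == "auto") mode <- if (p <= 12) "exact" else "sampling"
  if (mode == "exact" && p > 20) stop("too many features for exact mode")

  value_of <- function(mask_cols) {
    M <- bg
    if (length(mask_cols) > 0) {
      M[, mask_cols] <- matrix(xv[mask_cols], nrow(bg), length(mask_cols),
                               byrow = TRUE)
    }
    mean(predict(model, M))
  }

  if (mode == "exact") {
    nmask <- 2^p
    masks <- 0:(nmask - 1)
    popcount <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(p - 1))) > 0), 0)
    v <- vapply(masks, function(m) {
      value_of(which(bitwAnd(m, 2^(0:(p - 1))) > 0))
    }, 0)
    wts <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) - lfactorial(p))
    shap <- setNames(numeric(p), feats)
    for (i in seq_len(p)) {
      bit <- 2^(i - 1)
      without <- masks[bitwAnd(masks, bit) == 0]
      shap[i] <- sum(wts[popcount[without + 1] + 1] *
                       (v[without + bit + 1] - v[without + 1]))
    }
    baseline <- v[1]
    prediction <- v[nmask]
  } else {
    shap <- setNames(numeric(p), feats)
    baseline <- value_of(integer(0))
    prediction <- value_of(seq_len(p))
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(p)
        prev <- baseline
        cols <- integer(0)
        for (i in perm) {
          cols <- c(cols, i)
          cur <- value_of(cols)
          shap[i] <- shap[i] + (cur - prev)
          prev <- cur
        }
      }
    })
    shap <- shap / n_perm
  }
  out <- list(baseline = baseline, shap = shap, prediction = prediction,
              mode = mode)
  class(out) <- "tw_attribution"
  out
}

#' @export
print.tw_attribution <- function(x, ...) {
  cat(sprintf("Shapley attribution (%s mode): baseline %.4g, prediction %.4g\n",
              x$mode, x$baseline, x$prediction))
  print(round(x$shap, 5))
  invisible(x)
}

#' Two-group diagnostic over the regularization sweep
#'
#' Descriptive companion to [cross_validate()]: for each regularization
#' strength, samples are partitioned into two groups by a seeded two-means
#' clustering of (prediction, residual), and the partition is compared with
#' the partition at the first (reference) alpha by co-assignment agreement.
#'
#' @param predictions A tibble with columns `alpha`, `prediction`,
#'   `actual`; rows for different alphas must be aligned (same samples in
#'   the same order).
#' @param seed Seed for the clustering initialization.
#' @return A list of class `tw_alpha_clusters`: `summary` (tibble `alpha,
#'   n1, n2, agreement_pct, degenerate`) and `assignments` (matrix samples
#'   x alphas).
#' @export
alpha_cluster_report <- function(predictions, seed = 1L) {
  predictions <- tibble::as_tibble(predictions)
  stopifnot(all(c("alpha", "prediction", "actual") %in% names(predictions)))
  alphas <- sort(unique(predictions$alpha))
  if (length(alphas) < 2) stop("need cross-validation results for >= 2 alpha values")
  n <- sum(predictions$alpha == alphas[1])
  if (n < 4) stop("need at least 4 samples per alpha")

  cluster_one <- function(sub) {
    feat <- cbind(sub$prediction, sub$actual - sub$prediction)
    if (nrow(unique(feat)) < 2) {
      return(list(assign = rep(1L, nrow(feat)), degenerate = TRUE))
    }
    km <- with_seed(seed, kmeans(scale(feat), centers = 2, nstart = 10))
    assign <- km$cluster
    # canonical labels: group 1 has the lower mean prediction
    if (mean(sub$prediction[assign == 1]) > mean(sub$prediction[assign == 2])) {
      assign <- 3L - assign
    }
    list(assign = assign, degenerate = FALSE)
  }

  assigns <- matrix(NA_integer_, n, length(alphas),
                    dimnames = list(NULL, paste0("alpha_", signif(alphas, 4))))
  degenerate <- logical(length(alphas))
  for (j in seq_along(alphas)) {
    sub <- predictions[predictions$alpha == alphas[j], ]
    if (nrow(sub) != n) stop("all alphas must carry the same number of samples")
    res <- cluster_one(sub)
    assigns[, j] <- res$assign
    degenerate[j] <- res$degenerate
  }
  ref <- assigns[, 1]
  agreement <- vapply(seq_along(alphas), function(j) {
    a <- assigns[, j]
    100 * max(mean(a == ref), mean((3L - a) == ref))
  }, 0)
  summary <- tibble::tibble(
    alpha = alphas,
    n1 = unname(colSums(assigns == 1L)),
    n2 = unname(colSums(assigns == 2L)),
    agreement_pct = agreement,
    degenerate = degenerate
  )
  out <- list(summary = summary, assignments = assigns)
  class(out) <- "tw_alpha_clusters"
  out
}

#' @export
print.tw_alpha_clusters <- function(x, ...) {
  cat("Two-group diagnostic over the regularization sweep\n")
  print(x$summary)
  invisible(x)
}

#' Persist / reload a fitted surrogate as structured text
#'
#' Writes the architecture, weights, scaling and feature names as JSON so a
#' model reloads bit-exactly.
#'
#' @param model A fitted `tw_surrogate`.
#' @param path Output path.
#' @return `path` (write) / the model (read).
#' @export
write_surrogate <- function(model, path) {
  stopifnot(inherits(model, "tw_surrogate"))
  payload <- list(
    config = unclass(model$config),
    weights = list(W = lapply(model$weights$W, identity),
                   b = model$weights$b),
    feature_names = model$feature_names,
    feature_scaling = model$feature_scaling,
    target_scaling = model$target_scaling,
    report = model$report
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- payload$config
  class(cfg) <- "tw_surrogate_config"
  model <- list(
    config = cfg,
    weights = list(W = lapply(payload$weights$W, as.matrix),
                   b = lapply(payload$weights$b, as.numeric)),
    feature_names = payload$feature_names,
    feature_scaling = list(
      center = setNames(as.numeric(payload$feature_scaling$center),
                        payload$feature_names),
      scale = setNames(as.numeric(payload$feature_scaling$scale),
                       payload$feature_names)
    ),
    target_scaling = payload$target_scaling,
    fitted = TRUE,
    report = tibble::as_tibble(payload$report)
  )
  class(model) <- "tw_surrogate"
  model
}
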