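#' Pearson correlation matrix of water-quality parameters
#'
#' Sample Pearson coefficients over pairwise-complete observations. A
#' zero-variance variable produces missing entries (off-diagonal) with a
#' warning rather than an error.
#'
#' @param d A sample table with at least 3 rows.
#' @param vars Columns to correlate.
#' @return Symmetric numeric matrix with unit diagonal; the number of
#'   complete pairs per entry is attached as attribute `"n_pairs"`.
#' @export
pearson_matrix <- function(d, vars = c("ph", "ec", "tds", "temperature",
                                       "salinity", "fe", "as_conc")) {
  if (nrow(d) < 3) stop("pearson_matrix needs at least 3 samples")
  bad <- setdiff(vars, names(d))
  if (length(bad) > 0) stop("unknown variable: ", paste(bad, collapse = ", "))
  X <- as.matrix(d[, vars])
  storage.mode(X) <- "double"
  zero_var <- vars[apply(X, 2, function(x) {
    x <- x[!is.na(x)]
    length(x) >= 2 && sd(x) == 0
  })]
  if (length(zero_var) > 0) {
    warning("zero-variance variable(s): ", paste(zero_var, collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  }
  M <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  diag(M) <- 1
  npairs <- crossprod(!is.na(X))
  attr(M, "n_pairs") <- npairs
  M
}

#' Ordinary least-squares regression of an analyte on tubewell depth
#'
#' Fits `concentration ~ depth` and reports the slope, intercept, Pearson
#' correlation and coefficient of determination, the diagnostics used to
#' describe how iron and arsenic decline with well depth.
#'
#' @param d A sample table with at least 3 complete (depth, analyte) pairs.
#' @param analyte `"fe"` or `"as"`.
#' @return A list of class `tw_linfit`: `w0` (intercept), `w` (slope),
#'   `r`, `r2`, `n`, plus the underlying `lm` fit.
#' @export
fit_depth_regression <- function(d, analyte = c("fe", "as")) {
  analyte <- match.arg(analyte)
  col <- param_column(analyte)
  ok <- complete.cases(d$depth, d[[col]])
  x <- d$depth[ok]
  y <- d[[col]][ok]
  if (length(x) < 3) stop("need at least 3 complete (depth, analyte) pairs")
  if (sd(x) == 0) stop("depth is constant; regression undefined")
  fit <- lm(y ~ x)
  r <- if (sd(y) == 0) 0 else cor(x, y)
  out <- list(
    analyte = analyte,
    w0 = unname(coef(fit)[1]),
    w = unname(coef(fit)[2]),
    r = r,
    r2 = r^2,
    n = length(x),
    fit = fit
  )
  class(out) <- "tw_linfit"
  out
}

#' @export
print.tw_linfit <- function(x, ...) {
  cat(sprintf("OLS %s ~ depth (n = %d)\n", x$analyte, x$n))
  cat(sprintf("  intercept %.6g, slope %.6g, r = %.3f, R^2 = %.3f\n",
              x$w0, x$w, x$r, x$r2))
  invisible(x)
}

#' Principal component analysis on log10-scaled indicators
#'
#' Variables are transformed as `log10(x + eps)` with `eps` equal to half
#' the smallest positive observed value of that variable (a zero-handling
#' rule needed because Fe and As readings of exactly 0 occur), then
#' centered and unit-scaled; components come from the eigendecomposition of
#' the correlation matrix. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making the output deterministic.
#'
#' @param d A sample table with more rows than `vars`.
#' @param vars Numeric columns to include.
#' @return A list of class `tw_pca`: `loadings` (components x variables,
#'   rows orthonormal), `explained_pct` (non-increasing, sums to 100),
#'   `scores` (samples x components, of the transformed scaled data),
#'   `preprocessing` (per-variable eps, center, scale).
#' @export
run_pca <- function(d, vars = c("ph", "ec", "tds", "temperature",
                                "salinity", "fe", "as_conc", "depth")) {
  bad <- setdiff(vars, names(d))
  if (length(bad) > 0) stop("unknown variable: ", paste(bad, collapse = ", "))
  X <- as.matrix(d[, vars])
  storage.mode(X) <- "double"
  keep <- complete.cases(X)
  X <- X[keep, , drop = FALSE]
  if (nrow(X) <= length(vars)) {
    stop("run_pca needs more complete rows than variables")
  }
  eps <- vapply(seq_along(vars), function(j) {
    pos <- X[, j][X[, j] > 0]
    if (length(pos) == 0) stop("variable all zero (cannot log-scale): ", vars[j])
    0.5 * min(pos)
  }, 0)
  L <- log10(sweep(X, 2, -eps))
  ctr <- colMeans(L)
  scl <- apply(L, 2, sd)
  if (any(scl == 0)) {
    stop("variable constant after log scaling: ",
         paste(vars[scl == 0], collapse = ", "))
  }
  Zs <- scale(L, center = ctr, scale = scl)
  R <- cor(Zs)
  ev <- eigen(R, symmetric = TRUE)
  loadings <- t(ev$vectors)  # components x variables
  # deterministic sign: largest-|loading| entry of each component positive
  for (k in seq_len(nrow(loadings))) {
    j <- which.max(abs(loadings[k, ]))
    if (loadings[k, j] < 0) loadings[k, ] <- -loadings[k, ]
  }
  dimnames(loadings) <- list(paste0("PC", seq_along(vars)), vars)
  scores <- Zs %*% t(loadings)
  colnames(scores) <- rownames(loadings)
  out <- list(
    loadings = loadings,
    explained_pct = 100 * ev$values / sum(ev$values),
    scores = scores,
    preprocessing = tibble::tibble(variable = vars, eps = eps,
                                   center = ctr, scale = scl),
    n = nrow(X)
  )
  class(out) <- "tw_pca"
  out
}

#' @export
print.tw_pca <- function(x, ...) {
  cat(sprintf("PCA on log10-scaled indicators (n = %d, %d variables)\n",
              x$n, ncol(x$loadings)))
  cat("explained variance (%):",
      paste(sprintf("%.2f", x$explained_pct), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}
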