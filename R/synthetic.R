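#' Configuration for the synthetic tubewell cohort generator
#'
#' Builds the parameter set that [generate_dataset()] consumes. Defaults
#' reproduce the study conditions of a 75-school tubewell survey: per-union
#' sample counts 29/14/17/15 (Bagoan/Dariapur/Mohajanpur/Monakhali), the
#' published marginal moments of pH, EC, TDS, Fe, As and depth, the
#' published pairwise correlations (TDS-EC 0.92, TDS-salinity 0.7,
#' As-depth -0.71, Fe-depth -0.34, Fe-As 0.22), and the quantization of the
#' iron colorimeter (0.01 mg/L steps) and the arsenic field-kit read-out
#' grid.
#'
#' If `n` differs from the sum of the default `union_counts`, counts are
#' re-allocated proportionally (largest-remainder rounding).
#'
#' @param n Number of samples.
#' @param union_counts Named integer vector of per-union sample counts;
#'   must sum to `n`.
#' @param depth_range Tubewell depth range in feet.
#' @param target_moments Named list of `c(mean, sd)` per parameter
#'   (`ph`, `ec`, `tds`, `fe`, `as`, `depth`, `salinity`, `temperature`).
#' @param target_correlations Named vector of output Pearson targets for
#'   the pairs `tds_ec`, `tds_salinity`, `as_depth`, `fe_depth`, `fe_as`.
#' @param as_grid Ordered arsenic kit read-out levels (mg/L), starting at 0.
#' @param fe_resolution Iron colorimeter display resolution (mg/L).
#' @param ph_range Truncation range for pH.
#' @param bbox Bounding box `c(lon_min, lon_max, lat_min, lat_max)` for the
#'   uniform placeholder coordinates.
#' @param include_outliers If `TRUE`, overwrite one sample with the
#'   physically implausible EC/TDS minima seen in some field records
#'   (EC 2.72 uS/cm, TDS 1.37 mg/L); off by default.
#' @param seed Integer seed; the full generation is reproducible from it.
#' @return A list of class `tw_synth_config`.
#' @export
synthetic_config <- function(
    n = 75L,
    union_counts = NULL,
    depth_range = c(100, 560),
    target_moments = list(
      ph = c(6.85, 0.24), ec = c(900.27, 290.48), tds = c(460.50, 144.30),
      fe = c(0.94, 0.92), as = c(0.03, 0.05), depth = c(311.20, 126.14),
      salinity = c(0.45, 0.15), temperature = c(26.5, 0.8)
    ),
    target_correlations = c(
      tds_ec = 0.92, tds_salinity = 0.7, as_depth = -0.71,
      fe_depth = -0.34, fe_as = 0.22
    ),
    as_grid = c(0, 0.005, 0.01, 0.025, 0.035, 0.05, 0.075, 0.1, 0.175, 0.25, 0.5),
    fe_resolution = 0.01,
    ph_range = c(6.12, 7.8),
    bbox = c(lon_min = 88.57, lon_max = 88.72, lat_min = 23.60, lat_max = 23.75),
    include_outliers = FALSE,
    seed = 1L) {
  n <- as.integer(n)
  if (n < 0) stop("n must be >= 0")
  default_counts <- c(Bagoan = 29L, Dariapur = 14L, Mohajanpur = 17L, Monakhali = 15L)
  if (is.null(union_counts)) {
    union_counts <- allocate_counts(n, default_counts)
  }
  if (sum(union_counts) != n) {
    stop("union_counts must sum to n")
  }
  if (!all(names(union_counts) %in% UNION_LEVELS)) {
    stop("unknown union in union_counts")
  }
  defaults <- eval(formals(synthetic_config)$target_moments)
  target_moments <- modifyList(defaults, target_moments)
  if (any(abs(target_correlations) >= 1)) {
    stop("correlation targets must lie in (-1, 1)")
  }
  if (is.unsorted(as_grid, strictly = TRUE) || as_grid[1] != 0) {
    stop("as_grid must be strictly increasing and start at 0")
  }
  stopifnot(fe_resolution > 0, depth_range[1] > 0, depth_range[1] < depth_range[2])
  cfg <- list(
    n = n, union_counts = union_counts, depth_range = depth_range,
    target_moments = target_moments, target_correlations = target_correlations,
    as_grid = as_grid, fe_resolution = fe_resolution, ph_range = ph_range,
    bbox = bbox, include_outliers = include_outliers, seed = as.integer(seed)
  )
  class(cfg) <- "tw_synth_config"
  cfg
}

# Largest-remainder allocation of n over the reference proportions.
allocate_counts <- function(n, ref) {
  if (n == 0) return(setNames(integer(length(ref)), names(ref)))
  quota <- n * ref / sum(ref)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(ref))
}

# Lognormal parameters matching a given arithmetic mean and sd.
lnorm_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# Parameters (mu, sigma) of a normal censored below at zero whose censored
# mean and sd match the targets. Solved numerically; deterministic.
censored_normal_params <- function(mean, sd) {
  moments <- function(mu, sigma) {
    a <- mu / sigma
    m1 <- mu * pnorm(a) + sigma * dnorm(a)
    m2 <- (mu^2 + sigma^2) * pnorm(a) + mu * sigma * dnorm(a)
    c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
  }
  obj <- function(par) {
    got <- moments(par[1], exp(par[2]))
    (got[1] - mean)^2 / mean^2 + (got[2] - sd)^2 / sd^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Pearson correlation between a monotone transform g(Z) of a standard
# normal and Z itself, by numeric integration (used for the truncated
# normal depth transform).
transform_linearity <- function(g) {
  z <- seq(-8, 8, length.out = 4001)
  w <- dnorm(z)
  w <- w / sum(w)
  gz <- g(z)
  m <- sum(w * gz)
  v <- sum(w * (gz - m)^2)
  sum(w * (gz - m) * z) / sqrt(v)
}

# Latent correlation between two lognormal margins that yields the target
# Pearson correlation on the observed scale (exact bivariate-lognormal
# inversion).
latent_lnorm_pair <- function(target, s1, s2) {
  v <- target * sqrt((exp(s1^2) - 1) * (exp(s2^2) - 1))
  if (v <= -1) return(NA_real_)
  log(1 + v) / (s1 * s2)
}

# Inverse-CDF transform of a standard normal into a truncated normal.
qtrunc_normal <- function(z, mean, sd, lower, upper) {
  pa <- pnorm(lower, mean, sd)
  pb <- pnorm(upper, mean, sd)
  qnorm(pa + pnorm(z) * (pb - pa), mean, sd)
}

# Snap values to an ordered grid; exact midpoints snap to the lower level.
snap_to_grid <- function(x, grid) {
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  grid[findInterval(x, mids, left.open = TRUE) + 1]
}

# Build the calibrated latent model from a config: the latent Gaussian
# correlations are de-attenuated analytically (first-order Hermite
# expansion for the mixed margins; exact inversion for lognormal pairs) so
# the post-transform Pearson correlations hit the configured targets in
# expectation.
latent_model <- function(cfg) {
  tm <- cfg$target_moments
  tc <- cfg$target_correlations
  p_ec <- lnorm_params(tm$ec[1], tm$ec[2])
  p_tds <- lnorm_params(tm$tds[1], tm$tds[2])
  p_sal <- lnorm_params(tm$salinity[1], tm$salinity[2])
  p_fe <- lnorm_params(tm$fe[1], tm$fe[2])
  p_as <- censored_normal_params(tm$as[1], tm$as[2])

  # attenuation of a latent correlation through each margin's transform
  att_fe <- p_fe$sigma * tm$fe[1] / tm$fe[2]
  att_as <- p_as$sigma * pnorm(p_as$mu / p_as$sigma) / tm$as[2]
  att_depth <- transform_linearity(function(z) {
    qtrunc_normal(z, tm$depth[1], tm$depth[2], cfg$depth_range[1], cfg$depth_range[2])
  })

  need <- function(val, pair) {
    if (is.na(val) || abs(val) >= 1) {
      stop(sprintf("correlation target for (%s) is infeasible after de-attenuation", pair))
    }
    val
  }
  r_ec_tds <- need(latent_lnorm_pair(tc[["tds_ec"]], p_ec$sigma, p_tds$sigma), "tds, ec")
  r_tds_sal <- need(latent_lnorm_pair(tc[["tds_salinity"]], p_tds$sigma, p_sal$sigma), "tds, salinity")
  r_fe_depth <- need(tc[["fe_depth"]] / (att_fe * att_depth), "fe, depth")
  r_as_depth <- need(tc[["as_depth"]] / (att_as * att_depth), "as, depth")
  r_fe_as_lat <- need(tc[["fe_as"]] / (att_fe * att_as), "fe, as")
  r_fe_res <- need((r_fe_as_lat - r_fe_depth * r_as_depth) / sqrt(1 - r_as_depth^2),
                   "fe, as")

  # latent order: depth, ph, ec, tds, salinity, temperature, fe, as-residual
  vars <- c("depth", "ph", "ec", "tds", "salinity", "temperature", "fe", "asres")
  S <- diag(length(vars))
  dimnames(S) <- list(vars, vars)
  set <- function(a, b, v) {
    S[a, b] <<- v
    S[b, a] <<- v
  }
  set("ec", "tds", r_ec_tds)
  set("tds", "salinity", r_tds_sal)
  set("ec", "salinity", r_ec_tds * r_tds_sal)  # implied, keeps S well-conditioned
  set("depth", "fe", r_fe_depth)
  set("fe", "asres", r_fe_res)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    stop("correlation targets are jointly infeasible (latent covariance not positive definite)")
  }
  list(S = S, chol = ch, r_as_depth = r_as_depth,
       p_ec = p_ec, p_tds = p_tds, p_sal = p_sal, p_fe = p_fe, p_as = p_as)
}

#' Generate a synthetic tubewell cohort
#'
#' Draws a seeded sample table with the statistical structure described by
#' the config: a latent multivariate Gaussian is transformed to the target
#' marginals (lognormal EC/TDS/salinity/Fe, censored-normal As with a
#' negative linear dependence on depth, truncated-normal depth and pH),
#' clipped to the instrument ranges and quantized to the field-kit
#' read-out levels. The same seed yields a bit-identical table.
#'
#' @param cfg A [synthetic_config()].
#' @return A sample table; provenance records the seed.
#' @export
#' @examples
#' d <- generate_dataset(synthetic_config(n = 75, seed = 42))
#' nrow(d)
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "tw_synth_config"))
  model <- latent_model(cfg)
  tm <- cfg$target_moments
  n <- cfg$n
  prov <- sprintf("synthetic(seed=%d)", cfg$seed)
  if (n == 0) {
    return(new_dataset(tibble::tibble(sample_id = character()), provenance = prov))
  }
  with_seed(cfg$seed, {
    Z <- matrix(rnorm(n * ncol(model$S)), nrow = n) %*% model$chol
    colnames(Z) <- colnames(model$S)

    depth <- qtrunc_normal(Z[, "depth"], tm$depth[1], tm$depth[2],
                           cfg$depth_range[1], cfg$depth_range[2])
    ph <- qtrunc_normal(Z[, "ph"], tm$ph[1], tm$ph[2],
                        cfg$ph_range[1], cfg$ph_range[2])
    ec <- exp(model$p_ec$mu + model$p_ec$sigma * Z[, "ec"])
    tds <- exp(model$p_tds$mu + model$p_tds$sigma * Z[, "tds"])
    salinity <- exp(model$p_sal$mu + model$p_sal$sigma * Z[, "salinity"])
    temperature <- tm$temperature[1] + tm$temperature[2] * Z[, "temperature"]

    fe <- exp(model$p_fe$mu + model$p_fe$sigma * Z[, "fe"])
    fe <- pmin(pmax(fe, FE_RANGE[1]), FE_RANGE[2])
    fe <- round_half_up(fe / cfg$fe_resolution) * cfg$fe_resolution

    r_ad <- model$r_as_depth
    w_as <- r_ad * Z[, "depth"] + sqrt(1 - r_ad^2) * Z[, "asres"]
    as_raw <- model$p_as$mu + model$p_as$sigma * w_as
    as_conc <- pmin(pmax(as_raw, AS_RANGE[1]), AS_RANGE[2])
    as_conc <- snap_to_grid(as_conc, cfg$as_grid)

    lon <- runif(n, cfg$bbox[["lon_min"]], cfg$bbox[["lon_max"]])
    lat <- runif(n, cfg$bbox[["lat_min"]], cfg$bbox[["lat_max"]])

    union_name <- rep(names(cfg$union_counts), times = cfg$union_counts)
    d <- tibble::tibble(
      sample_id = sprintf("S%04d", seq_len(n)),
      school = sprintf("School %04d", seq_len(n)),
      union_name = union_name,
      longitude = lon, latitude = lat,
      depth = depth, ph = ph, ec = ec, tds = tds,
      temperature = temperature, salinity = salinity,
      fe = fe, as_conc = as_conc
    )
    if (cfg$include_outliers && n >= 1) {
      d$ec[1] <- 2.72
      d$tds[1] <- 1.37
    }
    new_dataset(d, provenance = prov)
  })
}

#' Summarize a cohort against the generator targets
#'
#' Per-parameter min/max/mean/sd plus the pairwise Pearson correlations the
#' generator calibrates, in a form that can be diffed against a
#' [synthetic_config()]'s `target_moments` / `target_correlations`.
#'
#' @param d A sample table with at least two rows.
#' @return A list of class `tw_cohort_report` with tibbles `stats` and
#'   `correlations`.
#' @export
cohort_report <- function(d) {
  if (nrow(d) < 2) stop("cohort_report needs at least 2 samples")
  params <- c("depth", "ph", "ec", "tds", "temperature", "salinity", "fe", "as_conc")
  stats <- dplyr::bind_rows(lapply(params, function(p) {
    x <- d[[p]][!is.na(d[[p]])]
    tibble::tibble(
      parameter = p,
      min = if (length(x)) min(x) else NA_real_,
      max = if (length(x)) max(x) else NA_real_,
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) >= 2) sd(x) else NA_real_
    )
  }))
  pairs <- list(
    c("tds", "ec"), c("tds", "salinity"), c("as_conc", "depth"),
    c("fe", "depth"), c("fe", "as_conc")
  )
  correlations <- dplyr::bind_rows(lapply(pairs, function(pr) {
    ok <- complete.cases(d[[pr[1]]], d[[pr[2]]])
    r <- if (sum(ok) >= 3 && sd(d[[pr[1]]][ok]) > 0 && sd(d[[pr[2]]][ok]) > 0) {
      cor(d[[pr[1]]][ok], d[[pr[2]]][ok])
    } else NA_real_
    tibble::tibble(var1 = pr[1], var2 = pr[2], r = r, n = sum(ok))
  }))
  out <- list(stats = stats, correlations = correlations)
  class(out) <- "tw_cohort_report"
  out
}

#' @export
print.tw_cohort_report <- function(x, ...) {
  cat("Cohort summary\n")
  print(x$stats)
  cat("\nPairwise correlations\n")
  print(x$correlations)
  invisible(x)
}
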