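# Small programmatic fixtures and independent oracles shared across tests.

make_dataset <- function(fe = 0.5, as_conc = 0.02, union_name = "Bagoan",
                         depth = 300, ph = 7, ec = 800, tds = 450,
                         temperature = 26, salinity = 0.4,
                         longitude = 88.6, latitude = 23.7) {
  n <- max(lengths(list(fe, as_conc, union_name, depth, ph, ec, tds)))
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    school = sprintf("School %03d", seq_len(n)),
    union_name = rep_len(union_name, n),
    longitude = rep_len(longitude, n),
    latitude = rep_len(latitude, n),
    depth = rep_len(depth, n),
    ph = rep_len(ph, n),
    ec = rep_len(ec, n),
    tds = rep_len(tds, n),
    temperature = rep_len(temperature, n),
    salinity = rep_len(salinity, n),
    fe = rep_len(fe, n),
    as_conc = rep_len(as_conc, n)
  )
}

# Random legal dataset, for property tests.
random_dataset <- function(seed, n = 30) {
  set.seed(seed)
  make_dataset(
    fe = round(runif(n, 0, 5), 2),
    as_conc = round(runif(n, 0, 0.5), 3),
    union_name = sample(union_levels(), n, replace = TRUE),
    depth = runif(n, 100, 560),
    ph = runif(n, 6, 8.6),
    ec = runif(n, 100, 1800),
    tds = runif(n, 50, 1200)
  )
}

# Brute-force per-sample recount of the compliance table.
oracle_compliance_counts <- function(d, registry, strict_ph = FALSE) {
  sapply(seq_len(nrow(registry)), function(i) {
    rule <- registry[i, ]
    col <- if (rule$parameter == "as") "as_conc" else rule$parameter
    sum(vapply(seq_len(nrow(d)), function(r) {
      v <- d[[col]][r]
      if (is.na(v)) return(FALSE)
      if (rule$exceed_mode == "above_upper") return(v > rule$upper)
      above <- !is.na(rule$upper) && v > rule$upper
      below <- !is.na(rule$lower) && v < rule$lower
      if (rule$parameter == "ph" && !strict_ph) above else above || below
    }, TRUE))
  })
}

# Naive two-pass Pearson coefficient.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A hand-built surrogate whose response is exactly linear on positive
# inputs: one relu hidden layer with identity-like weights and a large
# positive bias keeps every unit active, so f(x) = sum(w * x) + const.
linear_region_surrogate <- function(w, bias_shift = 1000) {
  p <- length(w)
  net <- list(
    W = list(diag(p), matrix(w, ncol = 1)),
    b = list(rep(bias_shift, p), -bias_shift * sum(w))
  )
  model <- list(
    config = surrogate_config(hidden_layers = p, activation = "relu"),
    weights = net,
    feature_names = paste0("f", seq_len(p)),
    feature_scaling = list(center = rep(0, p), scale = rep(1, p)),
    target_scaling = list(center = 0, scale = 1),
    fitted = TRUE,
    report = tibble::tibble()
  )
  class(model) <- "tw_surrogate"
  model
}
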