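#' @section Sample tables:
#' A sample table ("dataset") is a tibble with one row per tubewell water
#' record and columns `sample_id`, `school`, `union_name`, `longitude`,
#' `latitude`, `depth` (feet), `ph`, `ec` (uS/cm), `tds` (mg/L),
#' `temperature` (deg C), `salinity` (practical units), `fe` (mg/L) and
#' `as_conc` (mg/L). `longitude`, `latitude`, `temperature` and `salinity`
#' are optional and may be `NA`; concentrations of zero are meaningful and
#' are never used as missing markers.
#' @name tubewellrisk-data
NULL

DATASET_COLUMNS <- c(
  "sample_id", "school", "union_name", "longitude", "latitude", "depth",
  "ph", "ec", "tds", "temperature", "salinity", "fe", "as_conc"
)
OPTIONAL_COLUMNS <- c("longitude", "latitude", "temperature", "salinity")
NUMERIC_COLUMNS <- setdiff(DATASET_COLUMNS, c("sample_id", "school", "union_name"))

# Header aliases accepted on input (lower-cased header -> canonical name).
DEFAULT_COL_ALIASES <- c(
  union = "union_name", lon = "longitude", lat = "latitude",
  "as" = "as_conc", arsenic = "as_conc", iron = "fe", temp = "temperature",
  id = "sample_id"
)

new_dataset <- function(samples, provenance = NA_character_) {
  samples <- tibble::as_tibble(samples)
  missing_cols <- setdiff(DATASET_COLUMNS, names(samples))
  for (col in missing_cols) {
    samples[[col]] <- if (col %in% NUMERIC_COLUMNS) NA_real_ else NA_character_
  }
  samples <- samples[, DATASET_COLUMNS]
  attr(samples, "provenance") <- provenance
  samples
}

#' Provenance of a sample table
#'
#' @param d A sample table created by [read_samples()] or
#'   [generate_dataset()].
#' @return The provenance string (source path or generator seed), or `NA`.
#' @export
dataset_provenance <- function(d) {
  p <- attr(d, "provenance", exact = TRUE)
  if (is.null(p)) NA_character_ else p
}

# Per-row invariant check. Returns tibble(row, field, rule, value).
invariant_violations <- function(d) {
  viol <- list()
  add <- function(rows, field, rule, values) {
    if (length(rows) > 0) {
      viol[[length(viol) + 1]] <<- tibble::tibble(
        row = rows, field = field, rule = rule, value = as.character(values)
      )
    }
  }
  chk <- function(field, bad, rule) {
    rows <- which(!is.na(d[[field]]) & bad)
    add(rows, field, rule, d[[field]][rows])
  }
  chk("fe", d$fe < FE_RANGE[1] | d$fe > FE_RANGE[2],
      sprintf("fe out of colorimeter range [%g, %g] mg/L", FE_RANGE[1], FE_RANGE[2]))
  chk("as_conc", d$as_conc < AS_RANGE[1] | d$as_conc > AS_FLAG_MAX,
      sprintf("as_conc out of [%g, %g] mg/L", AS_RANGE[1], AS_FLAG_MAX))
  chk("depth", d$depth <= 0, "depth must be > 0 feet")
  chk("ph", d$ph < 0 | d$ph > 14, "ph out of [0, 14]")
  chk("ec", d$ec < 0, "ec must be >= 0")
  chk("tds", d$tds < 0, "tds must be >= 0")
  rows <- which(!is.na(d$union_name) & !(d$union_name %in% UNION_LEVELS))
  add(rows, "union_name", "unknown union", d$union_name[rows])
  if (length(viol) == 0) {
    tibble::tibble(row = integer(), field = character(),
                   rule = character(), value = character())
  } else {
    dplyr::bind_rows(viol)
  }
}

# Values above the arsenic kit's nominal 0.5 mg/L detection limit but within
# its extended 5 mg/L read-out are flagged, not rejected.
as_kit_flags <- function(d) {
  which(!is.na(d$as_conc) & d$as_conc > AS_RANGE[2] & d$as_conc <= AS_FLAG_MAX)
}

#' Read a tubewell sample table from delimited text
#'
#' Parses a delimited text file into a validated sample table. Header names
#' are matched case-insensitively and common aliases (`union`, `as`, `lon`,
#' `lat`, ...) are accepted; union spellings are canonicalized through an
#' alias map. Rows that violate a type invariant (e.g. an iron reading
#' beyond the 5.00 mg/L colorimeter range) are rejected with row-indexed
#' diagnostics; empty cells in optional columns become `NA`, never zero.
#'
#' @param path Path to the file.
#' @param delim Field delimiter (default comma).
#' @param aliases Named character vector of union-spelling aliases
#'   (variant -> canonical); defaults to [union_aliases()].
#' @param col_aliases Extra header aliases (lower-cased header -> canonical
#'   column name), merged over the built-in ones.
#' @return A sample table (tibble); rejected rows are reported via warning
#'   and attached as the `"rejected"` attribute.
#' @export
read_samples <- function(path, delim = ",", aliases = union_aliases(),
                         col_aliases = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
  amap <- DEFAULT_COL_ALIASES
  if (!is.null(col_aliases)) amap[names(col_aliases)] <- col_aliases
  nm <- tolower(names(raw))
  nm <- ifelse(nm %in% names(amap), amap[nm], nm)
  names(raw) <- nm

  required <- setdiff(DATASET_COLUMNS, OPTIONAL_COLUMNS)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("header is missing required fields: ",
         paste(missing_cols, collapse = ", "))
  }

  d <- tibble::tibble(
    sample_id = raw$sample_id,
    school = raw$school,
    union_name = canonical_union(raw$union_name, aliases)
  )
  for (col in NUMERIC_COLUMNS) {
    x <- if (col %in% names(raw)) raw[[col]] else NA_character_
    x[!is.na(x) & x == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(num))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value %s in column '%s', row %d",
                   dQuote(x[bad[1]]), col, bad[1]))
    }
    d[[col]] <- num
  }

  viol <- invariant_violations(d)
  if (nrow(viol) > 0) {
    keep <- setdiff(seq_len(nrow(d)), unique(viol$row))
    warning(sprintf(
      "rejected %d row(s) violating sample invariants: %s",
      length(unique(viol$row)),
      paste(sprintf("row %d (%s: %s)", viol$row, viol$field, viol$rule),
            collapse = "; ")
    ), call. = FALSE)
    d <- d[keep, ]
  }
  flag <- as_kit_flags(d)
  if (length(flag) > 0) {
    warning(sprintf(
      "%d arsenic reading(s) above the 0.5 mg/L kit detection limit (rows %s); kept but flagged",
      length(flag), paste(flag, collapse = ", ")
    ), call. = FALSE)
  }
  out <- new_dataset(d, provenance = path)
  attr(out, "rejected") <- viol
  out
}

canonical_union <- function(x, aliases = union_aliases()) {
  hit <- x %in% names(aliases)
  x[hit] <- aliases[x[hit]]
  x
}

#' Write a sample table to CSV
#'
#' Round-trip companion of [read_samples()]: writes the canonical header
#' and empty cells for missing values.
#'
#' @param d A sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(d, path) {
  readr::write_csv(d[, DATASET_COLUMNS], path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a sample table
#'
#' Pure check of the per-field invariants, duplicate sample ids and missing
#' values. Returns a report; never raises on invalid data.
#'
#' @param d A sample table.
#' @return A list of class `tw_validation` with elements `n` (row count),
#'   `violations` (tibble: row, field, rule, value), `duplicate_ids`
#'   (character), `flagged_as_rows` (rows where the arsenic reading is above
#'   the nominal kit limit but below 5 mg/L) and `missing` (tibble: field,
#'   n_missing).
#' @export
validate_dataset <- function(d) {
  stopifnot(is.data.frame(d))
  d <- new_dataset(d, provenance = dataset_provenance(d))
  ids <- d$sample_id[!is.na(d$sample_id)]
  dup <- unique(ids[duplicated(ids)])
  missing <- tibble::tibble(
    field = DATASET_COLUMNS,
    n_missing = vapply(DATASET_COLUMNS, function(col) sum(is.na(d[[col]])), 0L)
  )
  out <- list(
    n = nrow(d),
    violations = invariant_violations(d),
    duplicate_ids = dup,
    flagged_as_rows = as_kit_flags(d),
    missing = missing
  )
  class(out) <- "tw_validation"
  out
}

#' @export
print.tw_validation <- function(x, ...) {
  cat(sprintf("Sample-table validation: n = %d\n", x$n))
  if (x$n == 0) cat("  (empty dataset)\n")
  cat(sprintf("  invariant violations: %d\n", nrow(x$violations)))
  if (nrow(x$violations) > 0) {
    msg <- sprintf("    row %d: %s (%s = %s)", x$violations$row,
                   x$violations$rule, x$violations$field, x$violations$value)
    cat(paste(msg, collapse = "\n"), "\n")
  }
  cat(sprintf("  duplicate sample ids: %d\n", length(x$duplicate_ids)))
  if (length(x$duplicate_ids) > 0)
    cat("    ", paste(x$duplicate_ids, collapse = ", "), "\n")
  if (length(x$flagged_as_rows) > 0)
    cat(sprintf("  arsenic readings above kit limit (flagged): rows %s\n",
                paste(x$flagged_as_rows, collapse = ", ")))
  cat(sprintf("  missing values: %d\n", sum(x$missing$n_missing)))
  invisible(x)
}
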