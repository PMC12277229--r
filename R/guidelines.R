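#' Drinking-water guideline registry
#'
#' Loads the registry of (authority, parameter) limits used for exceedance
#' accounting. The shipped registry covers pH, electrical conductivity,
#' total dissolved solids, iron and arsenic limits of the WHO, the US EPA
#' and the Bangladesh Drinking Water Standard (BDWS / Environmental
#' Conservation Rules).
#'
#' Each rule carries an `exceed_mode`:
#' * `above_upper` - a sample exceeds when its value is strictly greater
#'   than `upper`;
#' * `outside_range` - a sample exceeds when its value falls outside
#'   `[lower, upper]`.
#'
#' The BDWS iron rule is stored with its full 0.3-1.0 mg/L band but counts
#' exceedances only above 1.0 mg/L, and the WHO TDS rule (600-1000 mg/L)
#' counts only above 1000 mg/L: both choices reproduce the published
#' per-standard exceedance accounting for this study area.
#'
#' @param path Optional path to a registry CSV with columns
#'   `authority, parameter, lower, upper, exceed_mode`. Defaults to the
#'   registry shipped with the package.
#' @return A tibble with one row per (authority, parameter) rule.
#' @export
#' @examples
#' guideline_registry()
guideline_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "guidelines.csv",
                        package = "tubewellrisk", mustWork = TRUE)
  }
  reg <- readr::read_csv(path, col_types = readr::cols(
    authority = readr::col_character(),
    parameter = readr::col_character(),
    lower = readr::col_double(),
    upper = readr::col_double(),
    exceed_mode = readr::col_character()
  ), progress = FALSE)
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  needed <- c("authority", "parameter", "lower", "upper", "exceed_mode")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad_auth <- setdiff(unique(reg$authority), c("WHO", "USEPA", "BDWS"))
  if (length(bad_auth) > 0) {
    stop("unknown authority in registry: ", paste(bad_auth, collapse = ", "))
  }
  bad_par <- setdiff(unique(reg$parameter), c("ph", "ec", "tds", "fe", "as"))
  if (length(bad_par) > 0) {
    stop("unknown parameter in registry: ", paste(bad_par, collapse = ", "))
  }
  bad_mode <- setdiff(unique(reg$exceed_mode), c("above_upper", "outside_range"))
  if (length(bad_mode) > 0) {
    stop("unknown exceed_mode in registry: ", paste(bad_mode, collapse = ", "))
  }
  if (any(is.na(reg$lower) & is.na(reg$upper))) {
    stop("every registry rule needs at least one of lower/upper")
  }
  both <- !is.na(reg$lower) & !is.na(reg$upper)
  if (any(reg$lower[both] > reg$upper[both])) {
    stop("registry rule has lower > upper")
  }
  if (anyDuplicated(reg[, c("authority", "parameter")]) > 0) {
    stop("duplicate (authority, parameter) rule in registry")
  }
  invisible(reg)
}
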