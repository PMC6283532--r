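#' Indicator life stages, polarities and income classes
#'
#' The controlled vocabularies used throughout the package. Life stages
#' order a country profile from socioeconomic context through gestation,
#' infancy, water/sanitation access and adult lifestyle to NCD mortality.
#' Polarity records whether a higher raw value is desirable (literacy),
#' undesirable (stunting) or merely descriptive (total population).
#'
#' @return Character vector of allowed labels, in display order.
#' @export
life_stages <- function() {
  c("socioeconomic", "gestation_birth", "infancy_under5", "wash",
    "adult_lifestyle", "adult_biomarker", "ncd_mortality")
}

#' @rdname life_stages
#' @export
polarities <- function() {
  c("higher_desirable", "lower_desirable", "neutral")
}

#' @rdname life_stages
#' @export
income_classes <- function() {
  c("high", "upper_middle", "lower_middle", "low")
}

#' Read an indicator registry
#'
#' The registry is a CSV with one row per indicator and columns
#' `id,name,life_stage,polarity,ceiling,units`. It declares, for every
#' column of the country table, which life stage the indicator belongs to,
#' whether a higher raw value is desirable, and whether the indicator is
#' compressed against a ceiling (near-100% rates) and should therefore be
#' scored by rank-percentile rather than Box-Cox + T-score.
#'
#' @param path Path to the registry CSV.
#' @return A tibble with one validated row per indicator.
#' @seealso [example_registry()] for the packaged 53-indicator registry.
#' @export
read_indicator_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file not found: ", path, call. = FALSE)
  }
  reg <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character(),
                                                 ceiling = readr::col_logical()))
  validate_registry(reg)
}

validate_registry <- function(reg) {
  reg <- tibble::as_tibble(reg)
  needed <- c("id", "name", "life_stage", "polarity", "ceiling", "units")
  missing_cols <- setdiff(needed, names(reg))
  if (length(missing_cols) > 0) {
    stop("registry is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(reg$id)) {
    dup <- unique(reg$id[duplicated(reg$id)])
    stop("duplicate indicator id(s) in registry: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad_stage <- setdiff(unique(reg$life_stage), life_stages())
  if (length(bad_stage) > 0) {
    stop("unknown life stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  bad_pol <- setdiff(unique(reg$polarity), polarities())
  if (length(bad_pol) > 0) {
    stop("unknown polarity label(s): ", paste(bad_pol, collapse = ", "),
         call. = FALSE)
  }
  reg$ceiling <- as.logical(reg$ceiling)
  if (anyNA(reg$ceiling)) {
    stop("registry column 'ceiling' must be TRUE/FALSE", call. = FALSE)
  }
  reg[needed]
}

#' Path to the packaged example indicator registry
#'
#' A best-effort transcription of the 53 nutrition-related variables the
#' method was designed around — socioeconomic context, gestation and birth,
#' under-5 nutrition, WASH access, adult lifestyle and biomarkers, and NCD
#' mortality — with the polarity and ceiling flags the scoring rules need.
#' The original variable list was never published as a single enumerated
#' table, so ids and groupings here are a reconstruction, suitable as a
#' template for real runs and as a realistic fixture.
#'
#' @return Path to the installed registry CSV.
#' @export
example_registry <- function() {
  system.file("extdata", "indicator_registry.csv", package = "devgraph",
              mustWork = TRUE)
}
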