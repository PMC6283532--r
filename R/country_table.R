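#' Construct a validated country table
#'
#' A country table couples a countries-by-indicators numeric tibble with the
#' indicator registry describing its columns. Validation enforces the
#' contracts the scoring pipeline relies on: unique country ids, income
#' classes drawn from the four World Bank levels, a registry entry for every
#' indicator column, and at least 3 non-missing values per indicator (the
#' minimum for a defined sample SD; indicators below that are dropped with a
#' warning rather than failing the run, since sparsely reported variables
#' such as vitamin A supplementation are expected in practice).
#'
#' @param data Tibble/data frame with columns `country` (unique ids, ISO3
#'   recommended), `income` (one of [income_classes()]) and one numeric
#'   column per indicator. Missing cells are `NA`.
#' @param registry Indicator registry tibble (see [read_indicator_registry()]).
#' @return An object of class `country_table`: a list with elements `data`
#'   (indicator columns reordered to registry order) and `registry`.
#' @export
country_table <- function(data, registry) {
  data <- tibble::as_tibble(data)
  registry <- validate_registry(registry)
  if (!all(c("country", "income") %in% names(data))) {
    stop("country table needs 'country' and 'income' columns", call. = FALSE)
  }
  if (anyDuplicated(data$country)) {
    dup <- unique(data$country[duplicated(data$country)])
    stop("duplicate country id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(data$income %in% income_classes())
  if (any(bad)) {
    stop("unknown income class ", paste(unique(data$income[bad]), collapse = ", "),
         " in row(s) ", paste(which(bad), collapse = ", "),
         " (country ", paste(data$country[bad], collapse = ", "), ")",
         call. = FALSE)
  }

  ind_cols <- setdiff(names(data), c("country", "income"))
  orphan <- setdiff(ind_cols, registry$id)
  if (length(orphan) > 0) {
    stop("indicator column(s) with no registry entry: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  unused <- setdiff(registry$id, ind_cols)
  if (length(unused) > 0) {
    warning("registry indicator(s) absent from data, dropped from registry: ",
            paste(unused, collapse = ", "), call. = FALSE)
    registry <- registry[registry$id %in% ind_cols, ]
  }

  # registry order is the display order everywhere downstream
  data <- data[c("country", "income", registry$id)]
  for (id in registry$id) {
    data[[id]] <- as.numeric(data[[id]])
  }

  too_sparse <- registry$id[vapply(registry$id,
                                   function(id) sum(!is.na(data[[id]])) < 3,
                                   logical(1))]
  if (length(too_sparse) > 0) {
    warning("indicator(s) with fewer than 3 reported values dropped: ",
            paste(too_sparse, collapse = ", "), call. = FALSE)
    registry <- registry[!registry$id %in% too_sparse, ]
    data <- data[c("country", "income", registry$id)]
  }

  new_country_table(data, registry, dropped = too_sparse)
}

# internal constructor: no revalidation (used by stratify_by_income so that
# subsetting never re-triggers the sparsity rule or re-standardization)
new_country_table <- function(data, registry, dropped = character(0)) {
  structure(list(data = data, registry = registry, dropped = dropped),
            class = "country_table")
}

#' @export
print.country_table <- function(x, ...) {
  cat("<country_table> ", nrow(x$data), " countries x ",
      nrow(x$registry), " indicators\n", sep = "")
  tab <- table(factor(x$data$income, levels = income_classes()))
  cat("income classes: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  n_miss <- sum(is.na(as.matrix(x$data[x$registry$id])))
  cat("missing cells: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' Read a country table and its indicator registry from CSV
#'
#' The data file must have a header row with `country`, `income`, then one
#' column per indicator; missing cells may be empty or `NA`. Column order in
#' the returned table follows the registry.
#'
#' @param data_path Path to the countries-by-indicators CSV.
#' @param registry_path Path to the indicator registry CSV.
#' @return A validated [country_table()].
#' @export
read_country_table <- function(data_path, registry_path) {
  if (!file.exists(data_path)) {
    stop("data file not found: ", data_path, call. = FALSE)
  }
  registry <- read_indicator_registry(registry_path)
  data <- readr::read_csv(data_path, na = c("", "NA"), show_col_types = FALSE,
                          col_types = readr::cols(
                            country = readr::col_character(),
                            income = readr::col_character(),
                            .default = readr::col_double()))
  country_table(data, registry)
}

#' Write a country table (and optionally its registry) to CSV
#'
#' Missing cells are written as empty strings; [read_country_table()] on the
#' written files round-trips values, missingness pattern and registry.
#'
#' @param table A [country_table()].
#' @param data_path Output path for the data CSV.
#' @param registry_path Optional output path for the registry CSV.
#' @return `data_path`, invisibly.
#' @export
write_country_table <- function(table, data_path, registry_path = NULL) {
  stopifnot(inherits(table, "country_table"))
  readr::write_csv(table$data, data_path, na = "")
  if (!is.null(registry_path)) {
    readr::write_csv(table$registry, registry_path, na = "")
  }
  invisible(data_path)
}

#' Subset a country table to one income class
#'
#' Used for display and grouping only: deviation values are always computed
#' against the full international reference, then grouped by income class,
#' so stratifying never re-standardizes.
#'
#' @param table A [country_table()].
#' @param class One of [income_classes()].
#' @return A `country_table` containing only the requested class.
#' @export
stratify_by_income <- function(table, class) {
  stopifnot(inherits(table, "country_table"))
  class <- match.arg(class, income_classes())
  keep <- table$data$income == class
  if (!any(keep)) {
    stop("no countries in income class '", class, "'", call. = FALSE)
  }
  new_country_table(table$data[keep, ], table$registry, table$dropped)
}
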