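#' Deviation values (T-scores)
#'
#' The deviation value of a country on an indicator is the classical
#' T-score of its (transformed) value against all countries reporting that
#' indicator:
#' \deqn{T = 50 + 10 \, (x - \bar x) / s}
#' with \eqn{\bar x} the mean and \eqn{s} the sample standard deviation
#' (n - 1 denominator) over non-missing values. 50 is the international
#' reference; 60 means one standard deviation better-reported than average,
#' 40 one standard deviation worse. Missing entries stay missing and never
#' influence other countries' scores on other indicators — though removing
#' a country that does report shifts the reference for everyone else, an
#' inherent property of relative scores.
#'
#' @param values Numeric vector (typically Box-Cox transformed), `NA`s
#'   preserved. At least 3 non-missing values and nonzero SD required.
#' @return Deviation-value vector, same length and missingness.
#' @examples
#' tscore(c(1, 2, 3))  # 40 50 60
#' @export
tscore <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 3) {
    stop("need at least 3 non-missing values for a deviation value",
         call. = FALSE)
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate indicator: zero standard deviation", call. = FALSE)
  }
  50 + 10 * (values - mean(x)) / s
}

#' Percentile-based deviation values for ceiling indicators
#'
#' Indicators compressed against a ceiling (near-100% primary school
#' participation, literacy, vitamin A supplementation) carry almost no
#' usable spread for a location-scale standardization: most countries pile
#' up at the top and a power transform cannot unpile them. For these, each
#' country's deviation value reflects its rank: with midranks for ties,
#' \eqn{p = (\mathrm{rank} - 0.5)/n} and \eqn{T = 50 + 10\,\Phi^{-1}(p)}.
#' A country at the median gets 50; a country at the 25th percentile gets
#' \eqn{50 - 6.745 \approx 43.3}. The plotting position \eqn{(r-0.5)/n}
#' keeps \eqn{p} strictly inside (0, 1) so quantiles stay finite.
#'
#' @param values Numeric vector, `NA`s preserved; at least 3 non-missing.
#' @return Deviation-value vector.
#' @export
percentile_tscore <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) {
    stop("need at least 3 non-missing values for a deviation value",
         call. = FALSE)
  }
  r <- rank(values, na.last = "keep", ties.method = "average")
  p <- (r - 0.5) / sum(ok)
  50 + 10 * stats::qnorm(p)
}

#' Orient deviation values so that higher is always desirable
#'
#' For indicators where a lower raw value is desirable (stunting, tobacco
#' smoking, NCD mortality) the deviation value is reflected about the
#' reference: \eqn{T \mapsto 100 - T}, equivalent to negating the raw
#' variable before standardization. Higher-desirable and neutral indicators
#' pass through unchanged. Reflection is an involution and preserves the
#' mean-50 / SD-10 calibration.
#'
#' @param values Deviation-value vector.
#' @param polarity One of [polarities()].
#' @return Oriented deviation-value vector.
#' @export
orient <- function(values, polarity) {
  polarity <- match.arg(polarity, polarities())
  if (polarity == "lower_desirable") 100 - values else values
}

#' Score a country table into a deviation matrix
#'
#' Runs the full per-indicator pipeline: ceiling indicators (registry flag,
#' or `overrides`) are scored by [percentile_tscore()]; all others by
#' [estimate_lambda()] + [boxcox_apply()] + [tscore()]. Every indicator is
#' then oriented by its registry polarity so higher means better. Degenerate
#' indicators (constant values) are collected into `issues` and excluded
#' rather than aborting the run. Percent-scaled indicators that look
#' ceiling-compressed (at least 25% of reported values within 1% of the
#' attainable maximum of 100) but are not flagged trigger a warning —
#' never a silent method switch.
#'
#' @param table A [country_table()].
#' @param fits Optional named list of `boxcox_fit`s to reuse (e.g. replayed
#'   from [write_boxcox_fits()] output); missing entries are estimated.
#' @param overrides Optional named character vector mapping indicator id to
#'   `"percentile"` or `"boxcox_tscore"`, overriding the registry flag.
#' @param reference `"global"` (default): standardize against all countries
#'   reporting the indicator, then group by income class only for display.
#'   `"within_income"`: exploratory option standardizing within each income
#'   class separately.
#' @return A `deviation_matrix`: list with `values` (tibble `country`,
#'   `income`, one column per scored indicator), `methods` (named character,
#'   `"boxcox_tscore"` or `"percentile"`), `oriented` (named logical, TRUE
#'   where the indicator was reflected), `fits`, `registry`, and `issues`
#'   (tibble of skipped indicators with reasons).
#' @export
score_table <- function(table, fits = NULL, overrides = NULL,
                        reference = c("global", "within_income")) {
  stopifnot(inherits(table, "country_table"))
  reference <- match.arg(reference)
  if (reference == "within_income") {
    return(score_within_income(table, fits, overrides))
  }
  reg <- table$registry
  values <- table$data[c("country", "income")]
  methods <- character(0)
  oriented <- logical(0)
  out_fits <- list()
  issues <- list()

  for (i in seq_len(nrow(reg))) {
    id <- reg$id[i]
    x <- table$data[[id]]
    use_percentile <- if (!is.null(overrides) && id %in% names(overrides)) {
      match.arg(overrides[[id]], c("percentile", "boxcox_tscore")) == "percentile"
    } else {
      isTRUE(reg$ceiling[i])
    }
    if (!use_percentile) warn_if_ceiling_like(x, id)

    d <- tryCatch({
      if (use_percentile) {
        percentile_tscore(x)
      } else {
        fit <- if (!is.null(fits) && id %in% names(fits)) fits[[id]] else
          estimate_lambda(x)
        out_fits[[id]] <- fit
        tscore(boxcox_apply(x, fit))
      }
    }, error = function(e) e)
    if (inherits(d, "error")) {
      issues[[id]] <- conditionMessage(d)
      next
    }
    values[[id]] <- orient(d, reg$polarity[i])
    methods[id] <- if (use_percentile) "percentile" else "boxcox_tscore"
    oriented[id] <- reg$polarity[i] == "lower_desirable"
  }

  structure(list(
    values = values,
    methods = methods,
    oriented = oriented,
    fits = out_fits,
    registry = reg[reg$id %in% names(methods), ],
    issues = tibble::tibble(indicator = names(issues),
                            issue = unlist(issues, use.names = FALSE))),
    class = "deviation_matrix")
}

score_within_income <- function(table, fits, overrides) {
  parts <- lapply(income_classes(), function(cl) {
    if (!any(table$data$income == cl)) return(NULL)
    score_table(stratify_by_income(table, cl), fits, overrides,
                reference = "global")
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- parts[[1]]
  out$values <- dplyr::bind_rows(lapply(parts, function(p) p$values))
  # restore original country order
  out$values <- out$values[match(table$data$country, out$values$country), ]
  out$fits <- lapply(parts, function(p) p$fits)
  names(out$fits) <- vapply(parts, function(p) p$values$income[1], character(1))
  out$issues <- dplyr::distinct(dplyr::bind_rows(lapply(parts, `[[`, "issues")))
  out
}

warn_if_ceiling_like <- function(x, id) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(invisible())
  # the attainable maximum is only knowable for percentage-like scales
  if (min(x) < 0 || max(x) > 100) return(invisible())
  if (mean(x >= 99) >= 0.25) {
    warning("indicator '", id, "' looks ceiling-compressed (>=25% of values ",
            "within 1% of the maximum) but is scored by boxcox_tscore; ",
            "consider setting its ceiling flag", call. = FALSE)
  }
  invisible()
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat("<deviation_matrix> ", nrow(x$values), " countries x ",
      length(x$methods), " indicators\n", sep = "")
  cat("methods: ", sum(x$methods == "boxcox_tscore"), " boxcox_tscore, ",
      sum(x$methods == "percentile"), " percentile; ",
      sum(x$oriented), " reflected (lower-desirable)\n", sep = "")
  if (nrow(x$issues) > 0) {
    cat("skipped: ", paste(x$issues$indicator, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Export a deviation matrix to CSV
#'
#' Writes the countries-by-indicators deviation values preceded by two
#' bookkeeping rows (`.method` and `.oriented` in the country column) so
#' the scoring method and orientation of every column travel with the
#' numbers.
#'
#' @param matrix A `deviation_matrix` from [score_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_deviation_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "deviation_matrix"))
  ids <- names(matrix$methods)
  meta <- tibble::tibble(country = c(".method", ".oriented"),
                         income = c("", ""))
  for (id in ids) {
    meta[[id]] <- c(matrix$methods[[id]],
                    ifelse(matrix$oriented[[id]], "TRUE", "FALSE"))
  }
  body <- matrix$values
  body[ids] <- lapply(body[ids], function(v)
    ifelse(is.na(v), NA_character_, formatC(v, format = "g", digits = 15)))
  readr::write_csv(dplyr::bind_rows(meta, body), path, na = "")
  invisible(path)
}
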