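#' Qualitative bands for deviation values
#'
#' Verbal banding turns a profile into the language used to narrate country
#' diagnoses: a sanitation score of 25 reads "very low", literacy at 60
#' "high", GNI at 53 "middle". Default cutpoints: below 35 `very_low`,
#' 35 to <45 `low`, 45 to 55 `middle`, above 55 to <72 `high`, 72 and up
#' `very_high`. The cuts are a package convention reconstructed from how
#' practitioners describe T-scores (the boundaries near 45/55 bracket half
#' a standard deviation around the reference); override them per run if a
#' different reading convention is wanted.
#'
#' @param values Numeric deviation values (NA allowed).
#' @param cutpoints Increasing numeric vector of the four band boundaries
#'   `c(very_low_upper, low_upper, middle_upper, high_upper)`.
#' @return Character vector of band labels (`NA` where the value is `NA`).
#'   Every finite value receives exactly one band.
#' @export
assign_band <- function(values, cutpoints = deviation_bands()) {
  stopifnot(length(cutpoints) == 4, !is.unsorted(cutpoints, strictly = TRUE))
  vapply(values, function(t) {
    if (is.na(t)) return(NA_character_)
    if (t < cutpoints[1]) "very_low"
    else if (t < cutpoints[2]) "low"
    else if (t <= cutpoints[3]) "middle"
    else if (t < cutpoints[4]) "high"
    else "very_high"
  }, character(1))
}

#' @rdname assign_band
#' @export
deviation_bands <- function() {
  c(very_low_upper = 35, low_upper = 45, middle_upper = 55, high_upper = 72)
}

band_levels <- function() {
  c("very_low", "low", "middle", "high", "very_high")
}

#' Build a country's deviation profile
#'
#' Assembles one country's deviation values into an ordered profile: one
#' entry per indicator, grouped by life stage (in [life_stages()] order)
#' and registry order within a stage, with qualitative bands. Entries carry
#' both the oriented value (`value`, higher = better) and the raw-direction
#' reading (`raw_reading`, the score before polarity reflection) so that,
#' e.g., a reflected blood-pressure score of 27 is still recognizable as
#' "raised blood pressure very high at 73". Neutral indicators (total
#' population) are descriptive only: they are profiled unoriented and
#' excluded from strength/weakness flagging.
#'
#' @param matrix A `deviation_matrix` from [score_table()].
#' @param table The [country_table()] that was scored.
#' @param country Country id present in the table.
#' @param cutpoints Banding cutpoints, see [assign_band()].
#' @return A `country_profile`: tibble of entries (`indicator`, `name`,
#'   `life_stage`, `polarity`, `method`, `value`, `raw_reading`, `band`)
#'   with attributes `country` and `income`.
#' @export
build_profile <- function(matrix, table, country,
                          cutpoints = deviation_bands()) {
  stopifnot(inherits(matrix, "deviation_matrix"),
            inherits(table, "country_table"))
  row <- which(matrix$values$country == country)
  if (length(row) != 1) {
    stop("unknown country id: ", country, call. = FALSE)
  }
  reg <- matrix$registry
  vals <- vapply(reg$id, function(id) matrix$values[[id]][row], numeric(1))
  entries <- tibble::tibble(
    indicator = reg$id,
    name = reg$name,
    life_stage = factor(reg$life_stage, levels = life_stages()),
    polarity = reg$polarity,
    method = unname(matrix$methods[reg$id]),
    value = unname(vals),
    raw_reading = ifelse(reg$polarity == "lower_desirable",
                         100 - unname(vals), unname(vals)),
    band = assign_band(unname(vals), cutpoints))
  entries <- entries[order(entries$life_stage), ]
  structure(entries, class = c("country_profile", class(entries)),
            country = country,
            income = matrix$values$income[row],
            cutpoints = cutpoints)
}

#' @export
print.country_profile <- function(x, ...) {
  cat("<country_profile> ", attr(x, "country"),
      " (", attr(x, "income"), " income), ", nrow(x), " indicators\n",
      sep = "")
  NextMethod()
}

#' Flag a profile's strengths and weaknesses
#'
#' Mechanizes the verbal reading of a deviation graph: oriented values at
#' least `k` points above the reference 50 are strengths, at least `k`
#' below are weaknesses (default `k = 10`, i.e. one standard deviation).
#' Neutral indicators are skipped. Results are sorted by distance from the
#' reference, most extreme first.
#'
#' @param profile A `country_profile`.
#' @param k Half-width on the T-score scale (default 10).
#' @return Tibble `indicator`, `direction` (`"strength"`/`"weakness"`),
#'   `value`, `raw_reading`.
#' @export
flag_extremes <- function(profile, k = 10) {
  stopifnot(inherits(profile, "country_profile"), k > 0)
  p <- tibble::as_tibble(profile)
  p <- p[!is.na(p$value) & p$polarity != "neutral", ]
  p <- p[abs(p$value - 50) >= k, ]
  p$direction <- ifelse(p$value >= 50, "strength", "weakness")
  p <- p[order(-abs(p$value - 50)), ]
  p[c("indicator", "direction", "value", "raw_reading")]
}

#' Summarize one income class's deviation values
#'
#' Per-indicator mean, min, max and member count over the countries of one
#' income class, using each country's globally referenced scores (scores
#' are computed against all countries, then grouped by income class).
#'
#' @param matrix A `deviation_matrix` from [score_table()].
#' @param table The scored [country_table()].
#' @param class One of [income_classes()].
#' @return A tibble `indicator`, `mean`, `min`, `max`, `n_with_data`, with
#'   attribute `income_class`.
#' @export
summarize_group <- function(matrix, table, class) {
  stopifnot(inherits(matrix, "deviation_matrix"))
  class <- match.arg(class, income_classes())
  keep <- matrix$values$income == class
  if (!any(keep)) {
    stop("no countries in income class '", class, "'", call. = FALSE)
  }
  ids <- names(matrix$methods)
  rows <- lapply(ids, function(id) {
    v <- matrix$values[[id]][keep]
    v <- v[!is.na(v)]
    tibble::tibble(indicator = id,
                   mean = if (length(v)) mean(v) else NA_real_,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_,
                   n_with_data = length(v))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "income_class") <- class
  out
}

#' Render a country's deviation graph
#'
#' Draws the profile as a horizontal bar chart — one bar per indicator,
#' grouped and colour-coded by life stage, a solid reference line at 50 and
#' dashed guides at the banding cutpoints — and writes the exact plotted
#' numbers to a sidecar CSV (`<out>_values.csv`) so every figure is
#' auditable; the sidecar keeps rows for missing indicators with an empty
#' value cell. Image format follows the file extension (`.png`, `.pdf`, or
#' `.svg`).
#'
#' @param profile A `country_profile`.
#' @param out_path Output image path.
#' @param width,height Device size in inches.
#' @return Invisibly, a list with `image` and `sidecar` paths.
#' @export
render_deviation_graph <- function(profile, out_path, width = 8, height = 10) {
  stopifnot(inherits(profile, "country_profile"), nrow(profile) > 0)
  dir <- dirname(out_path)
  if (!dir.exists(dir)) {
    stop("output directory does not exist: ", dir, call. = FALSE)
  }
  cuts <- attr(profile, "cutpoints")
  p <- tibble::as_tibble(profile)
  p$label <- factor(p$name, levels = rev(p$name))
  plot_data <- p[!is.na(p$value), ]

  g <- ggplot2::ggplot(plot_data,
                       ggplot2::aes(x = .data$value, y = .data$label,
                                    fill = .data$life_stage)) +
    ggplot2::geom_col(orientation = "y") +
    ggplot2::geom_vline(xintercept = 50, linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = cuts, linetype = "dashed",
                        linewidth = 0.3, colour = "grey40") +
    ggplot2::labs(
      title = paste0("Deviation graph: ", attr(profile, "country"),
                     " (", attr(profile, "income"), " income)"),
      x = "deviation value (oriented: higher = more desirable)",
      y = NULL, fill = "life stage") +
    ggplot2::theme_minimal(base_size = 9)

  ggplot2::ggsave(out_path, g, width = width, height = height, dpi = 150)

  sidecar <- paste0(tools::file_path_sans_ext(out_path), "_values.csv")
  readr::write_csv(
    p[c("indicator", "name", "life_stage", "polarity", "method",
        "value", "raw_reading", "band")],
    sidecar, na = "")
  invisible(list(image = out_path, sidecar = sidecar))
}
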