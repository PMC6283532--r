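test_that("banding matches the narrative reading of deviation values", {
  # spot values as narrated in country diagnoses
  expect_equal(assign_band(25), "very_low")
  expect_equal(assign_band(34), "very_low")
  expect_equal(assign_band(c(36, 39, 42, 43, 44)), rep("low", 5))
  expect_equal(assign_band(c(45, 50, 53, 55)), rep("middle", 4))
  expect_equal(assign_band(c(58, 60, 64, 69, 71)), rep("high", 5))
  expect_equal(assign_band(c(72, 73, 75, 79, 82)), rep("very_high", 5))
  expect_identical(assign_band(NA_real_), NA_character_)
})

test_that("banding is total and exclusive over the whole scale", {
  grid <- seq(-20, 120, by = 0.25)
  bands <- assign_band(grid)
  expect_false(anyNA(bands))
  expect_true(all(bands %in% c("very_low", "low", "middle", "high",
                               "very_high")))
  # monotone: band index never decreases as the value increases
  idx <- match(bands, c("very_low", "low", "middle", "high", "very_high"))
  expect_true(all(diff(idx) >= 0))
})

make_profile_fixture <- function() {
  set.seed(20)
  n <- 40
  data <- tibble::tibble(
    country = sprintf("X%02d", 1:n),
    income = rep_len(income_classes(), n),
    literacy = rnorm(n, 70, 12),
    raised_bp = rnorm(n, 25, 6),
    pop = rlnorm(n, 9, 1))
  reg <- mini_registry(c("literacy", "raised_bp", "pop"),
                       polarity = c("higher_desirable", "lower_desirable",
                                    "neutral"),
                       life_stage = c("socioeconomic", "adult_biomarker",
                                      "socioeconomic"))
  tab <- country_table(data, reg)
  list(tab = tab, dm = score_table(tab))
}

test_that("profiles order by life stage and carry both readings", {
  fx <- make_profile_fixture()
  pr <- build_profile(fx$dm, fx$tab, "X07")
  expect_s3_class(pr, "country_profile")
  expect_equal(attr(pr, "country"), "X07")
  expect_false(is.unsorted(as.integer(pr$life_stage)))
  # oriented value and raw-direction reading are mirror images for
  # lower-desirable indicators, identical otherwise
  bp <- pr[pr$indicator == "raised_bp", ]
  expect_equal(bp$raw_reading, 100 - bp$value)
  lit <- pr[pr$indicator == "literacy", ]
  expect_equal(lit$raw_reading, lit$value)
  expect_error(build_profile(fx$dm, fx$tab, "nowhere"), "unknown country")
})

test_that("a reference-level profile bands everything middle", {
  fx <- make_profile_fixture()
  pr <- build_profile(fx$dm, fx$tab, "X01")
  pr$value <- 50
  pr$band <- assign_band(pr$value)
  expect_true(all(pr$band == "middle"))
  expect_equal(nrow(flag_extremes(pr)), 0)
})

test_that("extreme flags mechanize the strengths/weaknesses reading", {
  fx <- make_profile_fixture()
  pr <- build_profile(fx$dm, fx$tab, "X02")
  # force a recognizable picture: blood pressure very high in raw terms
  # (73/75-style) means a low oriented score, i.e. a weakness
  pr$value[pr$indicator == "raised_bp"] <- 27
  pr$raw_reading[pr$indicator == "raised_bp"] <- 73
  pr$value[pr$indicator == "literacy"] <- 62
  pr$raw_reading[pr$indicator == "literacy"] <- 62
  pr$value[pr$indicator == "pop"] <- 90  # neutral: must never be flagged

  fl <- flag_extremes(pr, k = 10)
  expect_equal(fl$indicator, c("raised_bp", "literacy"))  # sorted by |t-50|
  expect_equal(fl$direction, c("weakness", "strength"))
  expect_equal(fl$raw_reading[1], 73)
  expect_false("pop" %in% fl$indicator)
  # larger k keeps only the more extreme flags
  expect_lte(nrow(flag_extremes(pr, k = 30)), nrow(fl))
  expect_equal(flag_extremes(pr, k = 20)$indicator, "raised_bp")
})

test_that("group summaries aggregate member countries only", {
  fx <- make_profile_fixture()
  gs <- summarize_group(fx$dm, fx$tab, "low")
  members <- fx$dm$values$income == "low"
  lit <- fx$dm$values$literacy[members]
  row <- gs[gs$indicator == "literacy", ]
  expect_equal(row$mean, mean(lit))
  expect_equal(row$min, min(lit))
  expect_equal(row$max, max(lit))
  expect_equal(row$n_with_data, sum(!is.na(lit)))
  expect_error(summarize_group(fx$dm, fx$tab, "median"))
})

test_that("a one-member class collapses mean, min and max", {
  set.seed(21)
  data <- tibble::tibble(country = c("S", "T", "U", "V"),
                         income = c("low", "high", "high", "high"),
                         a = rnorm(4), b = rnorm(4))
  tab <- country_table(data, mini_registry(c("a", "b")))
  dm <- score_table(tab)
  gs <- summarize_group(dm, tab, "low")
  expect_equal(gs$mean, gs$min)
  expect_equal(gs$min, gs$max)
  expect_equal(gs$mean, c(dm$values$a[1], dm$values$b[1]))
})

test_that("the full-population group mean sits at the reference 50", {
  tab <- full_size_table(seed = 5)
  dm <- score_table(tab)
  ids <- names(dm$methods)[dm$methods == "boxcox_tscore"]
  full <- sapply(ids, function(id) mean(dm$values[[id]], na.rm = TRUE))
  expect_equal(unname(full), rep(50, length(ids)), tolerance = 1e-9)
})

test_that("a narrow band in a group is reflected in its summary", {
  # lower-middle education scores confined to [40, 60] by construction
  set.seed(22)
  data <- tibble::tibble(
    country = sprintf("X%02d", 1:40),
    income = rep(c("lower_middle", "low"), each = 20),
    education = c(runif(20, 45, 55), runif(20, 10, 90)))
  tab <- country_table(data, mini_registry("education"))
  dm <- score_table(tab, overrides = c(education = "percentile"))
  # build a summary from already-scored values restricted to the group
  gs <- summarize_group(dm, tab, "lower_middle")
  lm_scores <- dm$values$education[dm$values$income == "lower_middle"]
  expect_equal(gs$min, min(lm_scores))
  expect_equal(gs$max, max(lm_scores))
})

test_that("the deviation graph writes an image and a faithful sidecar", {
  fx <- make_profile_fixture()
  tab2 <- fx$tab
  tab2$data$literacy[3] <- NA
  dm2 <- score_table(tab2)
  pr <- build_profile(dm2, tab2, "X03")
  dir <- withr::local_tempdir()
  out <- file.path(dir, "x03.png")
  paths <- render_deviation_graph(pr, out)
  expect_true(file.exists(paths$image))
  expect_gt(file.info(paths$image)$size, 0)

  side <- readr::read_csv(paths$sidecar, show_col_types = FALSE)
  expect_equal(nrow(side), nrow(pr))              # missing rows kept
  expect_identical(side$value, pr$value)          # bit-identical values
  expect_true(is.na(side$value[side$indicator == "literacy"]))
  expect_error(render_deviation_graph(pr, file.path(dir, "no/such/dir.png")),
               "directory")
})
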