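test_that("tscore reproduces the T-score anchors", {
  expect_equal(tscore(c(1, 2, 3)), c(40, 50, 60))

  set.seed(1)
  x <- rnorm(100, 7, 3)
  d <- tscore(x)
  expect_equal(d[which.min(abs(x - mean(x)))],
               50 + 10 * (x[which.min(abs(x - mean(x)))] - mean(x)) / sd(x))
  # a value exactly at the mean scores 50, one SD out scores 40/60
  y <- c(x, mean(x), mean(x) + sd(x), mean(x) - sd(x))
  # appending changes the reference, so score against the original stats:
  d2 <- 50 + 10 * (y - mean(x)) / sd(x)
  expect_equal(d2[101:103], c(50, 60, 40))
})

test_that("tscore conserves mean 50 and sample SD 10 with missing data", {
  set.seed(2)
  x <- rgamma(80, 2)
  x[sample(80, 15)] <- NA
  d <- tscore(x)
  expect_identical(is.na(d), is.na(x))
  expect_equal(mean(d, na.rm = TRUE), 50, tolerance = 1e-12)
  expect_equal(sd(d, na.rm = TRUE), 10, tolerance = 1e-12)
})

test_that("tscore rejects degenerate input", {
  expect_error(tscore(c(5, 5, 5, NA)), "degenerate")
  expect_error(tscore(c(1, 2, NA, NA)), "at least 3")
})

test_that("percentile scores follow the normal-quantile ladder", {
  # median of an odd-length vector sits at p = 0.5 -> exactly 50
  expect_equal(percentile_tscore(c(10, 20, 30))[2], 50)

  # rank 2 of 6 gives p = (2 - 0.5)/6 = 0.25 -> 50 + 10 * qnorm(0.25)
  d <- percentile_tscore(c(4, 8, 15, 16, 23, 42))
  expect_equal(d[2], 43.2551, tolerance = 0.01)

  # strict monotonicity in rank, ties share a midrank score
  set.seed(3)
  for (i in 1:10) {
    x <- sample(100, 25)
    d <- percentile_tscore(x)
    expect_true(all(diff(d[order(x)]) > 0))
  }
  dt <- percentile_tscore(c(1, 2, 2, 9))
  expect_equal(dt[2], dt[3])
  expect_lt(dt[1], dt[2])
})

test_that("orientation reflects about 50 and is an involution", {
  t <- c(40, 50, 60, NA, 73)
  expect_equal(orient(t, "lower_desirable"), c(60, 50, 40, NA, 27))
  expect_equal(orient(orient(t, "lower_desirable"), "lower_desirable"), t)
  expect_identical(orient(t, "higher_desirable"), t)
  expect_identical(orient(t, "neutral"), t)

  set.seed(4)
  d <- tscore(rnorm(60))
  o <- orient(d, "lower_desirable")
  expect_equal(mean(o), 50, tolerance = 1e-12)
  expect_equal(sd(o), 10, tolerance = 1e-12)
})

test_that("score_table scores, orients and labels a mixed table", {
  set.seed(5)
  n <- 60
  data <- tibble::tibble(
    country = sprintf("X%02d", 1:n),
    income = rep_len(income_classes(), n),
    good = rnorm(n, 50, 8),
    bad = rgamma(n, 2) * 10,
    lit = 100 * rbeta(n, 30, 1))
  reg <- mini_registry(c("good", "bad", "lit"),
                       polarity = c("higher_desirable", "lower_desirable",
                                    "higher_desirable"),
                       ceiling = c(FALSE, FALSE, TRUE))
  tab <- country_table(data, reg)
  dm <- score_table(tab)

  expect_equal(unname(dm$methods), c("boxcox_tscore", "boxcox_tscore",
                                     "percentile"))
  expect_equal(unname(dm$oriented), c(FALSE, TRUE, FALSE))
  for (id in c("good", "bad")) {
    expect_equal(mean(dm$values[[id]]), 50, tolerance = 1e-9)
    expect_equal(sd(dm$values[[id]]), 10, tolerance = 1e-9)
  }
  # orientation: the worst raw 'bad' country gets the best oriented score
  expect_equal(which.max(dm$values$bad), which.min(data$bad))
  # fits exported for the boxcox-scored indicators only
  expect_setequal(names(dm$fits), c("good", "bad"))
})

test_that("a degenerate indicator is flagged without sinking the run", {
  set.seed(6)
  data <- tibble::tibble(country = sprintf("X%02d", 1:10),
                         income = rep("low", 10),
                         ok = rnorm(10), flat = rep(4, 10))
  tab <- country_table(data, mini_registry(c("ok", "flat")))
  dm <- score_table(tab)
  expect_equal(dm$issues$indicator, "flat")
  expect_match(dm$issues$issue, "degenerate")
  expect_false("flat" %in% names(dm$values))
  expect_equal(mean(dm$values$ok), 50, tolerance = 1e-9)
})

test_that("an unflagged ceiling-like indicator triggers a warning, not a switch", {
  set.seed(7)
  x <- c(runif(30, 99.2, 100), runif(30, 40, 95))
  data <- tibble::tibble(country = sprintf("X%02d", 1:60),
                         income = rep("high", 60), lit = x)
  tab <- country_table(data, mini_registry("lit"))
  expect_warning(dm <- score_table(tab), "ceiling-compressed")
  expect_equal(unname(dm$methods["lit"]), "boxcox_tscore")
})

test_that("method overrides beat the registry flag", {
  tab <- mini_table(n = 30, ids = c("a", "b"))
  dm <- score_table(tab, overrides = c(a = "percentile"))
  expect_equal(unname(dm$methods["a"]), "percentile")
  expect_equal(unname(dm$methods["b"]), "boxcox_tscore")
})

test_that("missing cells never leak across indicators", {
  tab <- mini_table(n = 40, ids = c("a", "b"))
  dm1 <- score_table(tab)
  tab2 <- tab
  tab2$data$a[5] <- NA  # drop one country's value on indicator a
  dm2 <- score_table(tab2)
  # indicator b untouched for everyone
  expect_equal(dm2$values$b, dm1$values$b)
  # indicator a re-referenced: other countries' scores legitimately move
  expect_false(isTRUE(all.equal(dm2$values$a[-5], dm1$values$a[-5])))
})

test_that("deviation matrices export with method and orientation rows", {
  tab <- mini_table(n = 20, ids = c("a", "b"),
                    polarity = c("higher_desirable", "lower_desirable"))
  dm <- score_table(tab)
  path <- withr::local_tempfile(fileext = ".csv")
  write_deviation_matrix(dm, path)
  got <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  expect_equal(got$country[1:2], c(".method", ".oriented"))
  expect_equal(got$a[1:2], c("boxcox_tscore", "FALSE"))
  expect_equal(got$b[2], "TRUE")
  vals <- as.numeric(got$a[-(1:2)])
  expect_equal(vals, dm$values$a, tolerance = 1e-12)
})
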