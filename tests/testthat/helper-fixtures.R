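# fixture builders shared across test files; everything is generated in code

mini_registry <- function(ids = c("a", "b", "c"),
                          polarity = rep("higher_desirable", length(ids)),
                          ceiling = rep(FALSE, length(ids)),
                          life_stage = rep("socioeconomic", length(ids))) {
  tibble::tibble(id = ids, name = toupper(ids), life_stage = life_stage,
                 polarity = polarity, ceiling = ceiling,
                 units = rep("u", length(ids)))
}

mini_table <- function(n = 5, ids = c("a", "b", "c"), seed = 42, ...) {
  set.seed(seed)
  data <- tibble::tibble(
    country = sprintf("X%02d", seq_len(n)),
    income = rep_len(income_classes(), n))
  for (id in ids) data[[id]] <- rnorm(n, 50, 10)
  country_table(data, mini_registry(ids, ...))
}

# a 194-row table with the reference income-class partition 55/57/48/34
full_size_table <- function(seed = 7) {
  generate_table(generator_config(seed = seed))
}

write_fixture_csvs <- function(table, dir = withr::local_tempdir(
                                 .local_envir = parent.frame())) {
  data_path <- file.path(dir, "table.csv")
  registry_path <- file.path(dir, "registry.csv")
  write_country_table(table, data_path, registry_path)
  list(data = data_path, registry = registry_path)
}

# family draws at the generator's default parameters (for modality checks)
family_draw <- function(family, n = 194) {
  switch(family,
    gaussian = rnorm(n, 50, 10),
    skewed   = 10 * rgamma(n, 2),
    bimodal  = {
      k <- sample(1:2, n, replace = TRUE)
      rnorm(n, c(42.5, 57.5)[k], 5)
    },
    trimodal = {
      k <- sample(1:3, n, replace = TRUE)
      rnorm(n, c(35, 50, 65)[k], 5)
    },
    ceiling  = 100 * rbeta(n, 45, 1))
}
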