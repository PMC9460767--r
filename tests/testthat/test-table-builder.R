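test_that("retinol activity equivalents combine components at 12 and 24", {
  expect_equal(compute_rae(100, 0, 0), 100)
  expect_equal(compute_rae(0, 1200, 0), 100)
  expect_equal(compute_rae(50, 600, 240), 110)
  # missing components contribute nothing when any component is present
  expect_equal(compute_rae(NA, 1200, NA), 100)
  expect_true(is.na(compute_rae(NA, NA, NA)))
  expect_error(compute_rae(-1, 0, 0), "non-negative")
})

test_that("standardization rescales to 100 g of edible portion", {
  i <- make_item("f1", "A001", portion_mass_g = 50, energy_kcal = 80)
  expect_equal(standardize_to_100g(i)$energy_kcal, 160)

  i <- make_item("f2", "A001", portion_mass_g = 100, iron_mg = 3.3)
  expect_equal(standardize_to_100g(i)$fe_mg, 3.3)

  i <- make_item("f3", "A001", portion_mass_g = 250, iron_mg = 5)
  expect_equal(standardize_to_100g(i)$fe_mg, 2)

  i <- make_item("f4", "A001", vitamin_c_mg = NA)
  expect_true(is.na(standardize_to_100g(i)$vitc_mg))
})

test_that("densities are invariant to the reported portion size", {
  base <- make_item("f1", "A001", portion_mass_g = 120, energy_kcal = 180,
                    protein_g = 7, retinol_ug = 12, beta_carotene_ug = 60,
                    vitamin_c_mg = 4, iron_mg = 1.1, zinc_mg = 0.4)
  s0 <- standardize_to_100g(base)
  for (c_scale in c(0.5, 3, 10)) {
    scaled <- base
    amount_cols <- c("portion_mass_g", "energy_kcal", "protein_g",
                     "retinol_ug", "beta_carotene_ug",
                     "other_provitamin_a_ug", "vitamin_c_mg", "iron_mg",
                     "zinc_mg")
    scaled[amount_cols] <- scaled[amount_cols] * c_scale
    expect_equal(standardize_to_100g(scaled), s0)
  }
})

test_that("Tukey fences match the interpolated-quartile formula", {
  f <- tukey_fence(c(10, 10, 20, 20))
  expect_equal(f$q1, 10)
  expect_equal(f$q3, 20)
  expect_equal(c(f$lower, f$upper), c(-5, 35))

  f <- tukey_fence(c(7, 7, 7))
  expect_equal(f$iqr, 0)
  expect_equal(c(f$lower, f$upper), c(7, 7))

  v <- c(1, 2, 3, 4, 100)
  f <- tukey_fence(v)
  expect_equal(c(f$lower, f$upper), unname(brute_fence(v)))

  expect_error(tukey_fence(c(NA_real_, NA_real_)), "missing")
})

test_that("outlier flags are strict, per category, and spare boundaries", {
  std <- standardize_to_100g(make_energy_category(c(1, 2, 3, 4, 100)))
  fl <- flag_outliers(std)
  en <- fl[fl$nutrient == "energy_kcal", ]
  expect_identical(en$food_id[en$outlier], "A001_5")

  # all equal: degenerate interval contains everything
  std <- standardize_to_100g(make_energy_category(rep(5, 4)))
  fl <- flag_outliers(std)
  expect_false(any(fl$outlier))

  # a value exactly on the upper fence is not an outlier:
  # {0,10,20,30,60} has Q1=10, Q3=30, upper fence 60
  std <- standardize_to_100g(make_energy_category(c(0, 10, 20, 30, 60)))
  fl <- flag_outliers(std)
  expect_false(any(fl$outlier[fl$nutrient == "energy_kcal"]))
  std <- standardize_to_100g(make_energy_category(c(0, 10, 20, 30, 60.001)))
  fl <- flag_outliers(std)
  expect_true(any(fl$outlier[fl$nutrient == "energy_kcal"]))

  # single-item categories produce no flags
  std <- standardize_to_100g(make_item("solo", "A009"))
  expect_false(any(flag_outliers(std)$outlier))
})

test_that("flags equal the brute-force oracle on random small categories", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    v <- round(rlnorm(n, log(50), 1), 3)
    std <- standardize_to_100g(make_energy_category(v))
    fl <- flag_outliers(std)
    fl <- fl[fl$nutrient == "energy_kcal", ]
    fl <- fl[order(match(fl$food_id, std$food_id)), ]
    expect_identical(fl$outlier, brute_flags(v))
  }
})

test_that("items with two or more flagged nutrients are eliminated", {
  # f5 is extreme in energy and iron, f6 only in vitamin C
  items <- dplyr::bind_rows(
    make_item("f1", "A001", energy_kcal = 100, iron_mg = 2, vitamin_c_mg = 10),
    make_item("f2", "A001", energy_kcal = 110, iron_mg = 2.1, vitamin_c_mg = 11),
    make_item("f3", "A001", energy_kcal = 95, iron_mg = 1.9, vitamin_c_mg = 9),
    make_item("f4", "A001", energy_kcal = 105, iron_mg = 2.2, vitamin_c_mg = 10.5),
    make_item("f5", "A001", energy_kcal = 2000, iron_mg = 40, vitamin_c_mg = 10.2),
    make_item("f6", "A001", energy_kcal = 102, iron_mg = 2.05, vitamin_c_mg = 300)
  )
  std <- standardize_to_100g(items)
  fl <- flag_outliers(std)
  res <- drop_multi_outlier_items(std, fl)
  expect_identical(res$drop_log$food_id, "f5")
  expect_match(res$drop_log$flagged_nutrients, "energy_kcal")
  expect_match(res$drop_log$flagged_nutrients, "fe_mg")
  expect_true("f6" %in% res$retained$food_id)

  # f6's flagged vitamin C value is excluded from aggregation only, and
  # the eliminated f5 contributes nothing anywhere
  prof <- aggregate_category(res$retained, fl, method = "mean",
                             drop_log = res$drop_log)
  expect_equal(prof$vitc_mg, mean(c(10, 11, 9, 10.5)))
  expect_equal(prof$n_items_retained, 5)
  expect_equal(prof$n_items_dropped, 1)

  # no flags anywhere: everything retained, empty log
  clean <- standardize_to_100g(make_energy_category(c(10, 11, 12)))
  res2 <- drop_multi_outlier_items(clean, flag_outliers(clean))
  expect_equal(nrow(res2$drop_log), 0)
  expect_equal(nrow(res2$retained), 3)

  # a category losing every item is an error naming the category
  fake_flags <- tidyr::expand_grid(
    category_key = "A001", food_id = c("A001_1", "A001_2", "A001_3"),
    nutrient = c("energy_kcal", "fe_mg")
  )
  fake_flags$value <- 1
  fake_flags$outlier <- TRUE
  std3 <- standardize_to_100g(make_energy_category(c(1, 2, 3)))
  expect_error(drop_multi_outlier_items(std3, fake_flags), "A001")
})

test_that("aggregation honours method, exclusions and missingness", {
  std <- standardize_to_100g(make_energy_category(c(2, 4, 6)))
  fl <- flag_outliers(std)
  expect_equal(aggregate_category(std, fl, "mean")$energy_kcal, 4)

  std <- standardize_to_100g(make_energy_category(c(1, 2, 3, 4)))
  fl <- flag_outliers(std)
  expect_equal(aggregate_category(std, fl, "median")$energy_kcal, 2.5)

  # flagged value excluded from the mean: {2,4,100} with 100 flagged
  std <- standardize_to_100g(make_energy_category(c(2, 4, 100)))
  fl <- flag_outliers(std)
  fl$outlier[fl$nutrient == "energy_kcal" & fl$value == 100] <- TRUE
  expect_equal(aggregate_category(std, fl, "mean")$energy_kcal, 3)

  # a nutrient with no usable values is emitted missing, with a warning
  items <- dplyr::bind_rows(
    make_item("g1", "A002", vitamin_c_mg = NA),
    make_item("g2", "A002", vitamin_c_mg = NA)
  )
  std <- standardize_to_100g(items)
  expect_warning(prof <- aggregate_category(std, flag_outliers(std), "mean"),
                 "A002")
  expect_true(is.na(prof$vitc_mg))
})

test_that("conversion-table construction is deterministic and complete", {
  set.seed(41)
  cfg <- sim_config(seed = 5, n_categories = 40, n_non_nutritive = 3)
  gen <- suppressMessages(generate_catalog_and_foods(cfg))
  t1 <- build_conversion_table(gen$catalog, gen$items)
  t2 <- build_conversion_table(gen$catalog, gen$items)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 37)
  expect_true(all(t1$n_items_retained >= 1))

  # each density lies within [min, max] of its category's item densities
  std <- standardize_to_100g(gen$items)
  for (nut in sample(heis_nutrients(), 2)) {
    rng <- std |>
      dplyr::group_by(category_key) |>
      dplyr::summarise(lo = min(.data[[nut]]), hi = max(.data[[nut]]))
    m <- merge(t1, rng, by = "category_key")
    expect_true(all(m[[nut]] >= m$lo & m[[nut]] <= m$hi))
  }

  # single-item categories reproduce the standardized item
  solo <- make_item("s1", "A001", portion_mass_g = 200, energy_kcal = 500)
  tbl <- build_conversion_table(make_catalog(1), solo)
  expect_equal(tbl$energy_kcal, 250)
  expect_equal(tbl$n_items_retained, 1)

  # empty nutritive categories are reported collectively
  expect_warning(
    tbl <- build_conversion_table(make_catalog(3), solo),
    "no paired food"
  )
  expect_setequal(attr(tbl, "empty_categories"), c("A002", "A003"))
})

test_that("mean and median agree on symmetric item sets", {
  # three items per category with densities truth * {0.9, 1, 1.1}
  set.seed(51)
  items <- dplyr::bind_rows(lapply(1:6, function(k) {
    key <- sprintf("A%03d", k)
    e <- runif(1, 50, 400)
    dplyr::bind_rows(lapply(seq_along(c(0.9, 1, 1.1)), function(i) {
      f <- c(0.9, 1, 1.1)[i]
      make_item(paste0(key, "_", i), key, energy_kcal = e * f,
                protein_g = 5 * f, iron_mg = 2 * f, zinc_mg = f,
                vitamin_c_mg = 10 * f, retinol_ug = 40 * f)
    }))
  }))
  catalog <- make_catalog(6)
  tm <- build_conversion_table(catalog, items, method = "mean")
  td <- build_conversion_table(catalog, items, method = "median")
  for (nut in heis_nutrients()) {
    expect_equal(tm[[nut]], td[[nut]], tolerance = 1e-9)
  }
})

test_that("a gross contaminant is dropped and the table matches the clean one", {
  clean <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_item(paste0("c", i), "A001", energy_kcal = 95 + 2 * i,
              iron_mg = 1.9 + 0.05 * i, vitamin_c_mg = 9 + 0.4 * i)
  }))
  poisoned <- dplyr::bind_rows(
    clean,
    make_item("bad", "A001",
              energy_kcal = 10 * max(clean$energy_kcal),
              iron_mg = 12 * max(clean$iron_mg))
  )
  catalog <- make_catalog(1)
  t_clean <- build_conversion_table(catalog, clean)
  t_pois <- build_conversion_table(catalog, poisoned)
  expect_identical(attr(t_pois, "drop_log")$food_id, "bad")
  for (nut in heis_nutrients()) {
    expect_equal(t_pois[[nut]], t_clean[[nut]], tolerance = 1e-12)
  }
  # far smaller than the contaminant's naive effect on the mean
  naive_energy <- mean(standardize_to_100g(poisoned)$energy_kcal)
  expect_gt(abs(naive_energy - t_clean$energy_kcal),
            abs(t_pois$energy_kcal - t_clean$energy_kcal))
})

test_that("conversion tables round-trip through their CSV layout", {
  cfg <- sim_config(seed = 9, n_categories = 12, n_non_nutritive = 1)
  gen <- suppressMessages(generate_catalog_and_foods(cfg))
  tbl <- build_conversion_table(gen$catalog, gen$items)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "table.csv")
  write_conversion_table(tbl, path)
  back <- read_conversion_table(path)
  expect_equal(back$energy_kcal, tbl$energy_kcal)
  expect_equal(back$category_key, tbl$category_key)
})
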