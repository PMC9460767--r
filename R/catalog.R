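#' Read an expenditure-category catalog
#'
#' A catalog lists every food/beverage expenditure category of a HEIS, keyed
#' by a short opaque code, with a flag marking whether the category has
#' nutritional value (tobacco, animal feed and similar categories do not).
#'
#' @param path Path to a UTF-8, comma-separated file with header
#'   `key,label,nutritive`. `nutritive` accepts logical (`TRUE`/`FALSE`) or
#'   0/1 encodings.
#' @return A tibble with columns `key` (character), `label` (character),
#'   `nutritive` (logical), one row per category, in file order.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("key,label,nutritive", "A001,maize tortilla,TRUE",
#'              "A900,tobacco,FALSE"), path)
#' read_category_catalog(path)
read_category_catalog <- function(path) {
  df <- read_checked_csv(path, c("key", "label", "nutritive"))
  df$key <- as.character(df$key)
  df$label <- as.character(df$label)
  df$nutritive <- coerce_logical(df$nutritive, "nutritive")
  if (anyNA(df$key) || any(!nzchar(df$key))) {
    abort("catalog contains empty category keys")
  }
  dup <- unique(df$key[duplicated(df$key)])
  if (length(dup) > 0) {
    abort(paste0("duplicate category keys: ", paste(dup, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn(paste0("catalog at '", path, "' is empty"))
  }
  inform(paste0("loaded ", nrow(df), " categories from '", path, "'"))
  as_tibble(df[c("key", "label", "nutritive")])
}

#' Write a category catalog to CSV
#'
#' @param catalog Tibble as returned by [read_category_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_category_catalog <- function(catalog, path) {
  readr::write_csv(catalog[c("key", "label", "nutritive")], path)
  invisible(path)
}

#' Keep only categories with nutritional value
#'
#' Non-nutritive categories (tobacco, animal feed, food-preparation services,
#' ...) are excluded from all nutrient accounting; the remainder are the
#' analyzable categories.
#'
#' @param catalog Category tibble.
#' @return The nutritive subset, input order preserved.
#' @export
filter_nutritive <- function(catalog) {
  stopifnot(is.data.frame(catalog), "nutritive" %in% names(catalog))
  catalog[catalog$nutritive, , drop = FALSE]
}

#' Read a food-composition item file
#'
#' Each row is one food from one composition source, already paired to an
#' expenditure category, with the edible fraction and the analytical nutrient
#' amounts referring to `portion_mass_g` grams of edible portion. Blank
#' nutrient cells are read as missing (`NA`), never as zero: the workflow
#' distinguishes unmeasured content from measured-zero content.
#'
#' @param path CSV with header `food_id,source,category_key,edible_fraction,`
#'   `portion_mass_g,energy_kcal,protein_g,retinol_ug,beta_carotene_ug,`
#'   `other_provitamin_a_ug,vitamin_c_mg,iron_mg,zinc_mg`.
#' @return Tibble of typed food items.
#' @export
read_food_items <- function(path) {
  req <- c(
    "food_id", "source", "category_key", "edible_fraction", "portion_mass_g",
    food_nutrient_cols()
  )
  df <- read_checked_csv(path, req)
  df$food_id <- as.character(df$food_id)
  df$source <- as.character(df$source)
  df$category_key <- as.character(df$category_key)
  for (col in c("edible_fraction", "portion_mass_g", food_nutrient_cols())) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_food_items(df)
  as_tibble(df[req])
}

#' Write food items to CSV
#'
#' @param items Food-item tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_food_items <- function(items, path) {
  req <- c(
    "food_id", "source", "category_key", "edible_fraction", "portion_mass_g",
    food_nutrient_cols()
  )
  readr::write_csv(items[req], path)
  invisible(path)
}

validate_food_items <- function(items) {
  dup <- unique(items$food_id[duplicated(items$food_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate food_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  bad_ef <- !is.na(items$edible_fraction) &
    (items$edible_fraction <= 0 | items$edible_fraction > 1)
  if (any(bad_ef) || anyNA(items$edible_fraction)) {
    abort(paste0(
      "edible_fraction must lie in (0, 1]; offending food_id: ",
      paste(head(items$food_id[bad_ef | is.na(items$edible_fraction)], 5),
            collapse = ", ")
    ))
  }
  bad_pm <- is.na(items$portion_mass_g) | items$portion_mass_g <= 0
  if (any(bad_pm)) {
    abort(paste0(
      "portion_mass_g must be positive; offending food_id: ",
      paste(head(items$food_id[bad_pm], 5), collapse = ", ")
    ))
  }
  for (col in food_nutrient_cols()) {
    neg <- !is.na(items[[col]]) & items[[col]] < 0
    if (any(neg)) {
      abort(paste0(
        "negative ", col, " for food_id: ",
        paste(head(items$food_id[neg], 5), collapse = ", ")
      ))
    }
  }
  invisible(items)
}

# items must reference known, nutritive keys
validate_pairing <- function(catalog, items) {
  unknown <- setdiff(unique(items$category_key), catalog$key)
  if (length(unknown) > 0) {
    abort(paste0(
      "food items paired to unknown category keys: ",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  non_nutritive <- catalog$key[!catalog$nutritive]
  bad <- intersect(unique(items$category_key), non_nutritive)
  if (length(bad) > 0) {
    abort(paste0(
      "food items paired to non-nutritive categories: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Coverage accounting for a food-to-category pairing
#'
#' Reports, per composition source, how many foods are paired and how many
#' distinct categories they cover; totals count a category once even when two
#' sources serve it. Nutritive categories left without any paired food are
#' enumerated — they are the trigger for another pairing iteration with
#' additional composition sources.
#'
#' @param catalog Category tibble.
#' @param items Food-item tibble; every `category_key` must exist in the
#'   catalog and be nutritive.
#' @return An object of class `heis_coverage`: a list with `per_source`
#'   (tibble: source, n_foods, n_categories), `n_foods`, `n_categories`
#'   (distinct), `empty_categories` (nutritive keys with no items) and
#'   `multi_source_categories` (keys served by more than one source).
#' @export
coverage_report <- function(catalog, items) {
  validate_pairing(catalog, items)
  nutritive_keys <- catalog$key[catalog$nutritive]
  lv <- source_priority_levels()
  src <- ifelse(items$source %in% lv, items$source, "other")
  per_source <- tibble(source = src, category_key = items$category_key) |>
    group_by(.data$source) |>
    summarise(
      n_foods = n(),
      n_categories = n_distinct(.data$category_key),
      .groups = "drop"
    ) |>
    arrange(match(.data$source, lv))
  by_cat <- tapply(src, items$category_key, function(s) length(unique(s)))
  out <- structure(
    list(
      per_source = per_source,
      n_foods = nrow(items),
      n_categories = length(unique(items$category_key)),
      empty_categories = setdiff(nutritive_keys, items$category_key),
      multi_source_categories = names(by_cat)[by_cat > 1]
    ),
    class = "heis_coverage"
  )
  out
}

#' @export
print.heis_coverage <- function(x, ...) {
  cat("Pairing coverage\n")
  cat("  foods paired:      ", x$n_foods, "\n")
  cat("  categories paired: ", x$n_categories, "\n")
  cat("  empty nutritive categories: ", length(x$empty_categories), "\n")
  cat("  categories served by >1 source: ",
      length(x$multi_source_categories), "\n")
  print(x$per_source)
  invisible(x)
}

#' Serialize a coverage report as a tidy CSV
#'
#' One row per source plus a `total` row; the total category count removes
#' double-counting of categories served by several sources.
#'
#' @param report A `heis_coverage` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  tbl <- bind_rows(
    report$per_source,
    tibble(
      source = "total",
      n_foods = report$n_foods,
      n_categories = report$n_categories
    )
  )
  readr::write_csv(tbl, path)
  invisible(path)
}

# ---- internal helpers ------------------------------------------------------

read_checked_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: '", path, "'"))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      "'", path, "' is missing required columns: ",
      paste(missing, collapse = ", ")
    ))
  }
  df
}

coerce_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1), na.rm = TRUE)) {
      abort(paste0(what, " must be logical or 0/1"))
    }
    return(x == 1)
  }
  y <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(y))
  out[y %in% c("true", "t", "1", "yes")] <- TRUE
  out[y %in% c("false", "f", "0", "no")] <- FALSE
  if (anyNA(out) && !anyNA(x)) {
    abort(paste0(what, " contains values not interpretable as logical"))
  }
  out
}
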