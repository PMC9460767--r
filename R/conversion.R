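#' Define an adult-equivalence scale
#'
#' Age bands partition `[0, Inf)`; each band carries a dimensionless weight
#' with the reference adult at 1.0. The official Mexican (CONEVAL) scale can
#' be supplied here; the packaged default ([default_equivalence_scale()]) is
#' an illustrative scale, not the official coefficients.
#'
#' @param age_min Non-negative, strictly increasing band lower bounds; the
#'   first must be 0.
#' @param weight Positive per-band weights.
#' @return Tibble with columns `age_min`, `weight`, class
#'   `heis_equivalence_scale`.
#' @export
#' @examples
#' equivalence_scale(age_min = c(0, 12, 18), weight = c(0.7, 0.8, 1.0))
equivalence_scale <- function(age_min, weight) {
  age_min <- as.numeric(age_min)
  weight <- as.numeric(weight)
  if (length(age_min) != length(weight) || length(age_min) == 0) {
    abort("age_min and weight must be non-empty and of equal length")
  }
  if (age_min[1] != 0 || is.unsorted(age_min, strictly = TRUE)) {
    abort("age_min must start at 0 and be strictly increasing")
  }
  if (any(is.na(weight)) || any(weight <= 0)) {
    abort("equivalence-scale weights must be positive")
  }
  structure(tibble(age_min = age_min, weight = weight),
            class = c("heis_equivalence_scale", class(tibble())))
}

#' Illustrative default adult-equivalence scale
#'
#' Four age bands with weights 0.70 (< 4 y), 0.75 (4-11 y), 0.80 (12-17 y)
#' and 1.00 (adults). These are plausible round values for demonstration and
#' testing only; substantive analyses should pass the official scale for
#' their setting via [equivalence_scale()].
#'
#' @return A `heis_equivalence_scale`.
#' @export
default_equivalence_scale <- function() {
  equivalence_scale(age_min = c(0, 4, 12, 18),
                    weight = c(0.70, 0.75, 0.80, 1.00))
}

#' Number of equivalent adults in a household
#'
#' Sum of the per-member scale weights.
#'
#' @param ages Numeric vector of member ages in years (one household).
#' @param scale A `heis_equivalence_scale`
#'   (default [default_equivalence_scale()]).
#' @return A single non-negative number; 1.0 for one reference adult.
#' @export
#' @examples
#' equivalent_adults(c(35, 33, 6))
equivalent_adults <- function(ages, scale = default_equivalence_scale()) {
  ages <- as.numeric(ages)
  if (length(ages) == 0) abort("a household must have at least one member")
  if (anyNA(ages) || any(ages < 0)) {
    abort("member ages must be non-negative")
  }
  sum(scale$weight[findInterval(ages, scale$age_min)])
}

#' Parse pipe-delimited member-age strings
#'
#' Household rosters serialize member ages as e.g. `"35|33|6"`.
#'
#' @param x Character vector.
#' @return List of numeric age vectors.
#' @export
parse_member_ages <- function(x) {
  lapply(strsplit(as.character(x), "|", fixed = TRUE), as.numeric)
}

#' Read household roster / survey-design file
#'
#' @param path CSV with header
#'   `household_id,stratum,psu,weight,income,member_ages` where `member_ages`
#'   is a pipe-delimited age list.
#' @return Tibble with typed columns plus `n_members`.
#' @export
read_households <- function(path) {
  df <- read_checked_csv(
    path,
    c("household_id", "stratum", "psu", "weight", "income", "member_ages")
  )
  df$household_id <- as.character(df$household_id)
  df$weight <- as.numeric(df$weight)
  df$income <- as.numeric(df$income)
  if (any(is.na(df$weight) | df$weight <= 0)) {
    abort("expansion factors (weight) must be positive")
  }
  ages <- parse_member_ages(df$member_ages)
  if (any(lengths(ages) == 0)) abort("every household needs >= 1 member")
  df$n_members <- lengths(ages)
  as_tibble(df)
}

#' Read purchase microdata
#'
#' @param path CSV with header
#'   `household_id,category_key,quantity_g,expenditure,is_fafh`. Food away
#'   from home (FAFH) records carry expenditure only; their `quantity_g` must
#'   be empty.
#' @return Typed purchase tibble.
#' @export
read_purchases <- function(path) {
  df <- read_checked_csv(
    path,
    c("household_id", "category_key", "quantity_g", "expenditure", "is_fafh")
  )
  df$household_id <- as.character(df$household_id)
  df$category_key <- as.character(df$category_key)
  df$quantity_g <- as.numeric(df$quantity_g)
  df$expenditure <- as.numeric(df$expenditure)
  df$is_fafh <- coerce_logical(df$is_fafh, "is_fafh")
  if (any(!df$is_fafh & (is.na(df$quantity_g) | df$quantity_g < 0))) {
    abort("food-at-home purchases need a non-negative quantity_g")
  }
  if (any(df$is_fafh & !is.na(df$quantity_g))) {
    abort("FAFH records must not carry a quantity_g")
  }
  if (any(!is.na(df$expenditure) & df$expenditure < 0)) {
    abort("expenditure must be non-negative")
  }
  as_tibble(df)
}

#' Nutrients delivered by purchases over the reference period
#'
#' For each purchase record, multiplies the quantity acquired by the
#' category's edible fraction and nutrient density per 100 g of edible
#' portion: `quantity_g * edible_fraction * density / 100`. FAFH records are
#' a contract violation here — they carry no quantity and are excluded from
#' nutrient conversion by design.
#'
#' @param purchases Purchase tibble with no FAFH rows.
#' @param table Conversion table covering every purchased category.
#' @return Tibble `household_id`, `category_key` plus the six nutrient
#'   amounts for the whole reference period.
#' @export
#' @examples
#' tbl <- tibble::tibble(category_key = "A001", edible_fraction = 1,
#'   energy_kcal = 100, protein_g = 2, vita_ug_rae = 0, vitc_mg = 0,
#'   fe_mg = 0.5, zn_mg = 0.3)
#' p <- tibble::tibble(household_id = "h1", category_key = "A001",
#'   quantity_g = 700, expenditure = 20, is_fafh = FALSE)
#' purchase_to_nutrients(p, tbl)
purchase_to_nutrients <- function(purchases, table) {
  if (any(purchases$is_fafh)) {
    abort("purchase_to_nutrients received FAFH records; exclude them first")
  }
  uncovered <- setdiff(unique(purchases$category_key), table$category_key)
  if (length(uncovered) > 0) {
    abort(paste0(
      "purchased categories missing from the conversion table: ",
      paste(head(uncovered, 5), collapse = ", ")
    ))
  }
  joined <- left_join(
    purchases, table[c("category_key", "edible_fraction", heis_nutrients())],
    by = "category_key"
  )
  out <- joined[c("household_id", "category_key")]
  for (nut in heis_nutrients()) {
    out[[nut]] <- joined$quantity_g * joined$edible_fraction *
      joined[[nut]] / 100
  }
  as_tibble(out)
}

#' Daily per-equivalent-adult nutrient availability by household
#'
#' Sums the nutrients delivered by each household's food-at-home purchases
#' over the reference period, divides by the number of days in the period
#' (default 7) and by the household's equivalent adults. FAFH records are
#' ignored with a message stating how many were skipped. Households with no
#' food-at-home purchases are retained with zero availability.
#'
#' @param purchases Purchase tibble (FAFH rows allowed; they are skipped).
#' @param table Conversion table.
#' @param households Household tibble with `household_id` and `member_ages`.
#' @param scale Equivalence scale.
#' @param reference_days Length of the recall period in days (default 7).
#' @return Tibble `household_id` plus six daily per-equivalent-adult nutrient
#'   columns, one row per household in `households`.
#' @export
household_daily_availability <- function(purchases, table, households,
                                         scale = default_equivalence_scale(),
                                         reference_days = 7) {
  stopifnot(reference_days > 0)
  n_fafh <- sum(purchases$is_fafh)
  if (n_fafh > 0) {
    inform(paste0(
      "ignoring ", n_fafh,
      " FAFH records (expenditure only, no nutrient conversion)"
    ))
  }
  home <- purchases[!purchases$is_fafh, , drop = FALSE]
  totals <- if (nrow(home) > 0) {
    purchase_to_nutrients(home, table) |>
      group_by(.data$household_id) |>
      summarise(across(dplyr::all_of(heis_nutrients()), sum), .groups = "drop")
  } else {
    tibble(household_id = character())
  }
  ae <- vapply(parse_member_ages(households$member_ages),
               equivalent_adults, numeric(1), scale = scale)
  out <- left_join(households["household_id"], totals, by = "household_id")
  for (nut in heis_nutrients()) {
    if (!nut %in% names(out)) out[[nut]] <- NA_real_
    out[[nut]][is.na(out[[nut]]) &
                 !out$household_id %in% totals$household_id] <- 0
    out[[nut]] <- out[[nut]] / reference_days / ae
  }
  as_tibble(out)
}

#' Deflate expenditure to constant base-year prices
#'
#' @param expenditure Current-price amount(s).
#' @param year_index CPI for the observation year.
#' @param base_index CPI for the base year.
#' @return `expenditure * base_index / year_index`.
#' @export
#' @examples
#' deflate(110, year_index = 110, base_index = 100)  # 100
deflate <- function(expenditure, year_index, base_index) {
  if (any(c(year_index, base_index) <= 0, na.rm = TRUE) ||
      anyNA(c(year_index, base_index))) {
    abort("CPI indices must be positive")
  }
  expenditure * base_index / year_index
}
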