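#' Vitamin A as retinol activity equivalents (RAE)
#'
#' Combines preformed retinol with provitamin-A carotenoids at the standard
#' IOM divisors: 1 ug RAE = 1 ug retinol = 12 ug beta-carotene = 24 ug of
#' other provitamin-A carotenoids. A component recorded as missing
#' contributes nothing provided at least one component is present; if all
#' three are missing the result is missing.
#'
#' @param retinol,beta_carotene,other_provitamin_a Amounts in ug; vectors are
#'   recycled to a common length. Must be non-negative where present.
#' @param divisors Named numeric vector with elements `beta_carotene` and
#'   `other_provitamin_a`; override only for sensitivity analyses.
#' @return Numeric vector of ug RAE.
#' @export
#' @examples
#' compute_rae(100, 0, 0)     # 100
#' compute_rae(0, 1200, 0)    # 100
#' compute_rae(50, 600, 240)  # 110
compute_rae <- function(retinol, beta_carotene, other_provitamin_a,
                        divisors = c(beta_carotene = 12,
                                     other_provitamin_a = 24)) {
  n <- max(length(retinol), length(beta_carotene), length(other_provitamin_a))
  r <- rep_len(as.numeric(retinol), n)
  b <- rep_len(as.numeric(beta_carotene), n)
  o <- rep_len(as.numeric(other_provitamin_a), n)
  if (any(c(r, b, o) < 0, na.rm = TRUE)) {
    abort("vitamin A components must be non-negative")
  }
  all_missing <- is.na(r) & is.na(b) & is.na(o)
  out <- ifelse(is.na(r), 0, r) +
    ifelse(is.na(b), 0, b) / divisors[["beta_carotene"]] +
    ifelse(is.na(o), 0, o) / divisors[["other_provitamin_a"]]
  out[all_missing] <- NA_real_
  out
}

#' Standardize food items to densities per 100 g of edible portion
#'
#' Rescales each analytical nutrient amount from the recorded portion mass to
#' a common basis of 100 g of edible portion, and collapses the three
#' vitamin A components into a single ug RAE density. The result is invariant
#' to the portion size the source table happened to report.
#'
#' @param items Food-item tibble (see [read_food_items()]).
#' @param rae_divisors Passed to [compute_rae()].
#' @return Tibble with `food_id`, `source`, `category_key`,
#'   `edible_fraction` and the six density columns of [heis_nutrients()];
#'   missing inputs stay missing.
#' @export
standardize_to_100g <- function(items,
                                rae_divisors = c(beta_carotene = 12,
                                                 other_provitamin_a = 24)) {
  if (any(is.na(items$portion_mass_g) | items$portion_mass_g <= 0)) {
    abort("portion_mass_g must be positive for every item")
  }
  rae <- compute_rae(items$retinol_ug, items$beta_carotene_ug,
                     items$other_provitamin_a_ug, divisors = rae_divisors)
  k <- 100 / items$portion_mass_g
  tibble(
    food_id = items$food_id,
    source = items$source,
    category_key = items$category_key,
    edible_fraction = items$edible_fraction,
    energy_kcal = items$energy_kcal * k,
    protein_g = items$protein_g * k,
    vita_ug_rae = rae * k,
    vitc_mg = items$vitamin_c_mg * k,
    fe_mg = items$iron_mg * k,
    zn_mg = items$zinc_mg * k
  )
}

#' Tukey's fences for a set of nutrient densities
#'
#' Quartiles are estimated by linear interpolation between order statistics
#' at positions \eqn{1 + (n-1)p} (base R quantile type 7); the fences are
#' \eqn{[Q_1 - 1.5\,IQR,\; Q_3 + 1.5\,IQR]}. Missing values are ignored.
#'
#' @param values Numeric vector with at least one non-missing value.
#' @return One-row tibble: `q1`, `q3`, `iqr`, `lower`, `upper`.
#' @export
#' @examples
#' tukey_fence(c(1, 2, 3, 4, 100))
tukey_fence <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) {
    abort("cannot build a fence: all values are missing")
  }
  q <- quantile(v, probs = c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  tibble(
    q1 = q[1], q3 = q[2], iqr = iqr,
    lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr
  )
}

#' Flag per-nutrient outliers within each category
#'
#' For every category and nutrient, values strictly outside the Tukey fences
#' built from that category's non-missing values are flagged. The interval is
#' closed: a value exactly on a fence is not an outlier, and fence
#' comparisons carry a relative numerical tolerance (1e-10 of the category
#' maximum) so that ties split only by floating-point rounding are never
#' flagged. Missing values are never flagged, and a category with a single
#' item produces no flags (its fences collapse onto the value itself).
#'
#' @param std_items Standardized items ([standardize_to_100g()]), any number
#'   of categories.
#' @return Long tibble: `category_key`, `food_id`, `nutrient`, `value`,
#'   `outlier` (logical), one row per non-missing item-nutrient value.
#' @export
flag_outliers <- function(std_items) {
  long <- tidyr::pivot_longer(
    std_items[c("category_key", "food_id", heis_nutrients())],
    cols = dplyr::all_of(heis_nutrients()),
    names_to = "nutrient", values_to = "value"
  )
  long <- long[!is.na(long$value), , drop = FALSE]
  long |>
    group_by(.data$category_key, .data$nutrient) |>
    mutate(
      q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
      q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
      tol = 1e-10 * max(abs(.data$value)),
      outlier = .data$value <
        .data$q1 - 1.5 * (.data$q3 - .data$q1) - .data$tol |
        .data$value > .data$q3 + 1.5 * (.data$q3 - .data$q1) + .data$tol
    ) |>
    ungroup() |>
    select("category_key", "food_id", "nutrient", "value", "outlier")
}

#' Eliminate food items with outliers in two or more nutrients
#'
#' An item flagged in `threshold` or more nutrients is judged incompatible
#' with its category and removed entirely; an item with a single flagged
#' nutrient is retained (the flagged value is still excluded from that
#' nutrient's aggregation downstream).
#'
#' @param std_items Standardized items.
#' @param flags Output of [flag_outliers()] on the same items.
#' @param threshold Minimum number of flagged nutrients that eliminates an
#'   item (default 2).
#' @return List with `retained` (standardized items kept) and `drop_log`
#'   (tibble: `food_id`, `category_key`, `n_flagged`, `flagged_nutrients`
#'   comma-separated).
#' @export
drop_multi_outlier_items <- function(std_items, flags, threshold = 2) {
  counts <- flags |>
    filter(.data$outlier) |>
    group_by(.data$food_id, .data$category_key) |>
    summarise(
      n_flagged = n(),
      flagged_nutrients = paste(sort(.data$nutrient), collapse = ","),
      .groups = "drop"
    )
  drop_log <- counts[counts$n_flagged >= threshold, , drop = FALSE]
  retained <- std_items[!(std_items$food_id %in% drop_log$food_id), ,
                        drop = FALSE]
  emptied <- setdiff(std_items$category_key, retained$category_key)
  if (length(emptied) > 0) {
    abort(paste0(
      "outlier elimination removed every item in categor",
      if (length(emptied) > 1) "ies: " else "y: ",
      paste(emptied, collapse = ", ")
    ))
  }
  list(retained = retained, drop_log = drop_log)
}

#' Aggregate retained items into category nutrient profiles
#'
#' Per category and nutrient, aggregates the non-missing, non-flagged values
#' of the retained items with the chosen method; the edible fraction is
#' aggregated with the same method. A nutrient with no usable value in a
#' category is emitted as missing with a warning — such categories need
#' another pairing iteration.
#'
#' @param retained Standardized items that survived
#'   [drop_multi_outlier_items()].
#' @param flags Flags from [flag_outliers()] (computed before the drops;
#'   fences are not recomputed).
#' @param method `"mean"` or `"median"`.
#' @param drop_log Optional drop log used to fill `n_items_dropped`.
#' @return Tibble: `category_key`, `edible_fraction`, the six nutrient
#'   densities, `n_items_retained`, `n_items_dropped`, `method`.
#' @export
aggregate_category <- function(retained, flags, method = c("mean", "median"),
                               drop_log = NULL) {
  method <- match.arg(method)
  agg <- if (method == "mean") mean else median
  if (nrow(retained) == 0) abort("no retained items to aggregate")

  usable <- flags |>
    filter(!.data$outlier, .data$food_id %in% retained$food_id)
  dens <- usable |>
    group_by(.data$category_key, .data$nutrient) |>
    summarise(value = agg(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "nutrient", values_from = "value")
  base <- retained |>
    group_by(.data$category_key) |>
    summarise(
      edible_fraction = agg(.data$edible_fraction),
      n_items_retained = n(),
      .groups = "drop"
    )
  out <- left_join(base, dens, by = "category_key")
  for (col in setdiff(heis_nutrients(), names(out))) out[[col]] <- NA_real_

  n_drop <- if (is.null(drop_log) || nrow(drop_log) == 0) {
    tibble(category_key = character(), n_items_dropped = integer())
  } else {
    drop_log |> count(.data$category_key, name = "n_items_dropped")
  }
  out <- left_join(out, n_drop, by = "category_key")
  out$n_items_dropped[is.na(out$n_items_dropped)] <- 0L
  out$method <- method

  gap <- vapply(
    seq_len(nrow(out)),
    function(i) anyNA(unlist(out[i, heis_nutrients()])), logical(1)
  )
  if (any(gap)) {
    warn(paste0(
      "categories with a nutrient left without usable values ",
      "(candidates for re-pairing): ",
      paste(out$category_key[gap], collapse = ", ")
    ))
  }
  out[c("category_key", "edible_fraction", heis_nutrients(),
        "n_items_retained", "n_items_dropped", "method")]
}

#' Build the category-level nutrient conversion table
#'
#' Full table-construction pipeline: validate the pairing, standardize items
#' to 100 g of edible portion, flag per-nutrient Tukey-fence outliers,
#' eliminate items flagged in two or more nutrients, and aggregate the rest
#' by mean or median. Deterministic given its inputs.
#'
#' @param catalog Category tibble.
#' @param items Food-item tibble.
#' @param method `"mean"` (default) or `"median"`.
#' @param threshold Item-elimination threshold (flagged nutrients), default 2.
#' @param rae_divisors Passed to [compute_rae()].
#' @return Conversion-table tibble (one row per covered nutritive category)
#'   with attributes `drop_log` (eliminated items) and `empty_categories`
#'   (nutritive categories with no paired food, also raised as a warning).
#' @export
build_conversion_table <- function(catalog, items, method = c("mean", "median"),
                                   threshold = 2,
                                   rae_divisors = c(beta_carotene = 12,
                                                    other_provitamin_a = 24)) {
  method <- match.arg(method)
  validate_pairing(catalog, items)
  empty <- setdiff(catalog$key[catalog$nutritive], items$category_key)
  if (length(empty) > 0) {
    warn(paste0(
      length(empty), " nutritive categories have no paired food: ",
      paste(head(empty, 10), collapse = ", "),
      if (length(empty) > 10) ", ..." else ""
    ))
  }
  std <- standardize_to_100g(items, rae_divisors = rae_divisors)
  flags <- flag_outliers(std)
  dropped <- drop_multi_outlier_items(std, flags, threshold = threshold)
  tbl <- aggregate_category(dropped$retained, flags, method = method,
                            drop_log = dropped$drop_log)
  tbl <- tbl[order(match(tbl$category_key, catalog$key)), , drop = FALSE]
  attr(tbl, "drop_log") <- dropped$drop_log
  attr(tbl, "empty_categories") <- empty
  tbl
}

#' Write / read a conversion table in its interchange CSV layout
#'
#' Density columns gain a `_100g` suffix on disk to make the basis explicit.
#'
#' @param table Conversion table from [build_conversion_table()].
#' @param path CSV path.
#' @return `path` (write) or the conversion-table tibble (read).
#' @export
write_conversion_table <- function(table, path) {
  out <- table
  names(out) <- sub(
    paste0("^(", paste(heis_nutrients(), collapse = "|"), ")$"), "\\1_100g",
    names(out)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_conversion_table
#' @export
read_conversion_table <- function(path) {
  req <- c("category_key", "edible_fraction",
           paste0(heis_nutrients(), "_100g"))
  df <- read_checked_csv(path, req)
  names(df) <- sub("_100g$", "", names(df))
  as_tibble(df)
}
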