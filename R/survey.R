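#' Design-based weighted mean with Taylor-linearized confidence interval
#'
#' Estimates a population mean from a stratified two-stage sample as the
#' ratio `sum(w*y) / sum(w)`. The variance treats the first stage as drawn
#' with replacement: linearized residuals `w*(y - est)/sum(w)` are totalled
#' per PSU and their between-PSU variance accumulated within strata with the
#' factor `n_h / (n_h - 1)`. The 95% interval uses a t critical value with
#' `#PSUs - #strata` degrees of freedom.
#'
#' Subpopulation (domain) estimates keep the full design: households outside
#' the domain contribute zero residuals but their PSUs still count, which is
#' the standard way to avoid understating domain variance.
#'
#' A stratum holding a single PSU cannot contribute a within-stratum
#' variance; its squared deviation is taken around the grand mean of all PSU
#' totals, with a warning.
#'
#' @param values Numeric vector, one value per household (may be `NA` outside
#'   the domain).
#' @param design Data frame aligned with `values`, columns `stratum`, `psu`,
#'   `weight` (positive expansion factors).
#' @param domain Optional logical vector marking the subpopulation.
#' @param conf_level Confidence level, default 0.95.
#' @return One-row tibble: `estimate`, `se`, `ci_lower`, `ci_upper`, `n`
#'   (households in the domain), `df`.
#' @export
#' @examples
#' des <- tibble::tibble(stratum = 1, psu = 1:10, weight = 1)
#' svy_mean(rnorm(10), des)  # matches mean() and the classical t-interval
svy_mean <- function(values, design, domain = NULL, conf_level = 0.95) {
  y <- as.numeric(values)
  if (nrow(design) != length(y)) {
    abort("design must have one row per value")
  }
  w <- as.numeric(design$weight)
  if (anyNA(w) || any(w <= 0)) abort("weights must be positive")
  d <- if (is.null(domain)) rep(TRUE, length(y)) else as.logical(domain)
  if (anyNA(d)) abort("domain indicator must not contain NA")
  if (!any(d)) abort("empty estimation domain")
  if (anyNA(y[d])) abort("missing values inside the estimation domain")

  y0 <- ifelse(d, y, 0)
  wd <- w * d
  est <- sum(wd * y0) / sum(wd)
  z <- wd * (y0 - est) / sum(wd)

  psu_key <- paste(design$stratum, design$psu, sep = "\r")
  z_psu <- tapply(z, psu_key, sum)
  stratum_psu <- tapply(as.character(design$stratum), psu_key, `[`, 1)
  n_psu <- length(z_psu)
  strata <- unique(stratum_psu)
  grand <- mean(z_psu)

  v <- 0
  lonely <- character()
  for (h in strata) {
    zh <- z_psu[stratum_psu == h]
    nh <- length(zh)
    if (nh == 1) {
      lonely <- c(lonely, h)
      v <- v + (zh - grand)^2
    } else {
      v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
    }
  }
  if (length(lonely) > 0) {
    warn(paste0(
      "lonely PSU in strat", if (length(lonely) > 1) "a: " else "um: ",
      paste(lonely, collapse = ", "),
      "; contribution centered at the grand mean"
    ))
  }
  se <- sqrt(as.numeric(v))
  df <- max(1L, n_psu - length(strata))
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  tibble(
    estimate = est, se = se,
    ci_lower = est - tcrit * se, ci_upper = est + tcrit * se,
    n = sum(d), df = df
  )
}

#' Weighted quantiles by interpolation on the cumulative weight scale
#'
#' Sorted values receive plotting positions `S_k / (S_n + mean(w))` where
#' `S_k` is the cumulative weight; with equal weights this reduces to the
#' familiar `k / (n + 1)` positions, and quantiles are linear interpolations
#' between adjacent order statistics. Outside the first/last position the
#' extreme value is returned.
#'
#' @param x Numeric values.
#' @param w Positive weights, same length.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
#' @examples
#' weighted_quantile(1:100, rep(1, 100), c(0.2, 0.4, 0.6, 0.8))
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), !anyNA(x))
  ord <- order(x)
  xs <- x[ord]
  S <- cumsum(w[ord])
  n <- length(xs)
  pk <- S / (S[n] + mean(w))
  vapply(probs, function(p) {
    if (p <= pk[1]) return(xs[1])
    if (p >= pk[n]) return(xs[n])
    i <- findInterval(p, pk)
    xs[i] + (p - pk[i]) / (pk[i + 1] - pk[i]) * (xs[i + 1] - xs[i])
  }, numeric(1))
}

#' Assign households to weighted income quintiles
#'
#' Cut points are weighted quantiles at p = 0.2, 0.4, 0.6, 0.8 of the
#' person-weighted income distribution (weight multiplied by household
#' size), so each quintile holds 20% of the represented population. A
#' household whose income falls exactly on a cut point goes to the lower
#' quintile.
#'
#' @param income Income per equivalent adult, one value per household.
#' @param weight Expansion factors.
#' @param size Household sizes (default 1 = household-weighted quintiles).
#' @return List with `quintile` (factor, levels `I`..`V`) and `cut_points`
#'   (the four nondecreasing cut points).
#' @export
assign_income_quintiles <- function(income, weight, size = 1) {
  income <- as.numeric(income)
  if (anyNA(income)) abort("incomes must be present for every household")
  if (any(weight <= 0)) abort("weights must be positive")
  size <- rep_len(size, length(income))
  lv <- c("I", "II", "III", "IV", "V")
  if (length(unique(income)) == 1) {
    warn("all incomes equal: degenerate quintile assignment (all in I)")
    return(list(
      quintile = factor(rep("I", length(income)), levels = lv),
      cut_points = rep(income[1], 4)
    ))
  }
  cuts <- weighted_quantile(income, weight * size, c(0.2, 0.4, 0.6, 0.8))
  idx <- rowSums(outer(income, cuts, FUN = ">")) + 1
  list(quintile = factor(lv[idx], levels = lv), cut_points = cuts)
}

#' Per-quintile survey estimates of nutrient availability
#'
#' A 5 x 6 grid of design-based estimates: for each income quintile and
#' nutrient, the weighted mean restricted to the quintile as a subpopulation
#' of the full design (out-of-domain households contribute zero residuals).
#'
#' @param availability Output of [household_daily_availability()].
#' @param quintile Factor from [assign_income_quintiles()], aligned with the
#'   rows of `households`.
#' @param households Household tibble with `household_id`, `stratum`, `psu`,
#'   `weight`.
#' @return Tidy tibble: `quintile`, `nutrient`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `n`, `df`.
#' @export
quintile_nutrient_table <- function(availability, quintile, households) {
  stopifnot(length(quintile) == nrow(households))
  av <- left_join(households["household_id"], availability,
                  by = "household_id")
  if (anyNA(av[heis_nutrients()])) {
    abort("availability missing for some households in the design")
  }
  design <- households[c("stratum", "psu", "weight")]
  rows <- list()
  for (q in levels(quintile)) {
    dom <- quintile == q
    if (!any(dom)) abort(paste0("quintile ", q, " is empty"))
    for (nut in heis_nutrients()) {
      est <- svy_mean(av[[nut]], design, domain = dom)
      rows[[length(rows) + 1]] <- mutate(est, quintile = q, nutrient = nut,
                                         .before = 1)
    }
  }
  bind_rows(rows)
}

#' Percent excess of the richest over the poorest quintile
#'
#' The income-gradient headline: for each nutrient,
#' `round(100 * (mean_V / mean_I - 1))`, the integer percentage by which the
#' top quintile's availability exceeds the bottom quintile's.
#'
#' @param x Either a tidy table from [quintile_nutrient_table()] (columns
#'   `quintile`, `nutrient`, `estimate`) or a wide table with a `quintile`
#'   column plus one column per nutrient of mean availabilities.
#' @return Named integer vector, one element per nutrient.
#' @export
quintile_excess <- function(x) {
  if (all(c("quintile", "nutrient", "estimate") %in% names(x))) {
    wide <- tidyr::pivot_wider(x[c("quintile", "nutrient", "estimate")],
                               names_from = "nutrient",
                               values_from = "estimate")
  } else if ("quintile" %in% names(x)) {
    wide <- x
  } else {
    abort("unrecognized quintile-table layout")
  }
  nuts <- intersect(heis_nutrients(), names(wide))
  lo <- wide[wide$quintile %in% c("I", "1"), nuts, drop = FALSE]
  hi <- wide[wide$quintile %in% c("V", "5"), nuts, drop = FALSE]
  if (nrow(lo) != 1 || nrow(hi) != 1) {
    abort("table must contain exactly one row for quintiles I and V")
  }
  out <- round(100 * (unlist(hi) / unlist(lo) - 1))
  setNames(as.integer(out), nuts)
}

#' Food-away-from-home expenditure diagnostics
#'
#' Four design-based estimates describing the FAFH bias of
#' purchase-based nutrient accounting: the percentage of households with any
#' FAFH spending; daily per-equivalent-adult constant-price expenditure on
#' food at home and on all food; and the mean household-level share of food
#' spending going to FAFH (households with zero total food spending are
#' excluded from the share, with a message).
#'
#' @param purchases Purchase tibble including FAFH records.
#' @param households Household tibble (`household_id`, `stratum`, `psu`,
#'   `weight`, `member_ages`).
#' @param scale Equivalence scale for the per-adult expenditure measures.
#' @param reference_days Recall-period length in days (default 7).
#' @param year_index,base_index CPI values used to deflate expenditures to
#'   constant base-year prices (defaults 1, i.e. no deflation).
#' @return Tibble with rows `pct_households_fafh`,
#'   `daily_home_food_exp_per_ea`, `daily_total_food_exp_per_ea`,
#'   `fafh_share_pct` and the [svy_mean()] columns.
#' @export
fafh_summary <- function(purchases, households,
                         scale = default_equivalence_scale(),
                         reference_days = 7,
                         year_index = 1, base_index = 1) {
  per_hh <- purchases |>
    group_by(.data$household_id) |>
    summarise(
      fafh_exp = sum(.data$expenditure[.data$is_fafh]),
      home_exp = sum(.data$expenditure[!.data$is_fafh]),
      .groups = "drop"
    )
  hh <- left_join(households, per_hh, by = "household_id")
  hh$fafh_exp[is.na(hh$fafh_exp)] <- 0
  hh$home_exp[is.na(hh$home_exp)] <- 0
  hh$fafh_exp <- deflate(hh$fafh_exp, year_index, base_index)
  hh$home_exp <- deflate(hh$home_exp, year_index, base_index)
  hh$total_exp <- hh$fafh_exp + hh$home_exp
  ae <- vapply(parse_member_ages(hh$member_ages),
               equivalent_adults, numeric(1), scale = scale)
  design <- hh[c("stratum", "psu", "weight")]

  with_total <- hh$total_exp > 0
  n_excluded <- sum(!with_total)
  if (n_excluded > 0) {
    inform(paste0(
      n_excluded, " households with zero food expenditure excluded ",
      "from the FAFH share estimate"
    ))
  }
  share <- ifelse(with_total, 100 * hh$fafh_exp / hh$total_exp, NA_real_)

  bind_rows(
    mutate(svy_mean(100 * (hh$fafh_exp > 0), design),
           measure = "pct_households_fafh", .before = 1),
    mutate(svy_mean(hh$home_exp / reference_days / ae, design),
           measure = "daily_home_food_exp_per_ea", .before = 1),
    mutate(svy_mean(hh$total_exp / reference_days / ae, design),
           measure = "daily_total_food_exp_per_ea", .before = 1),
    mutate(svy_mean(share, design, domain = with_total),
           measure = "fafh_share_pct", .before = 1)
  )
}

#' Year-by-year nutrient availability estimates
#'
#' One design-based estimate per nutrient per year, ready for a trend plot.
#'
#' @param availability Household availability tibble with a `year` column.
#' @param households Household tibble with a matching `year` column plus
#'   `household_id`, `stratum`, `psu`, `weight`.
#' @return Tidy tibble: `year`, `nutrient`, [svy_mean()] columns.
#' @export
trend_series <- function(availability, households) {
  stopifnot("year" %in% names(availability), "year" %in% names(households))
  rows <- list()
  for (yr in sort(unique(households$year))) {
    hh <- households[households$year == yr, , drop = FALSE]
    av <- left_join(hh["household_id"],
                    availability[availability$year == yr, , drop = FALSE],
                    by = "household_id")
    for (nut in heis_nutrients()) {
      est <- svy_mean(av[[nut]], hh[c("stratum", "psu", "weight")])
      rows[[length(rows) + 1]] <- mutate(est, year = yr, nutrient = nut,
                                         .before = 1)
    }
  }
  bind_rows(rows)
}
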