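#' Configuration for the synthetic ENIGH-like generator
#'
#' Bundles and validates every knob of the fixture generator. Defaults
#' emulate the structure of the Mexican income-expenditure survey workflow:
#' 245 expenditure categories of which 9 are non-nutritive, a 7-day recall
#' period, a stratified two-stage weighted design, an income gradient in
#' purchases (default top/bottom-quintile availability ratios mirror the
#' published Mexico 2020 gradients: protein 1.24, vitamin A 1.46, vitamin C
#' 1.83, energy and iron 1.07, zinc 1.10), and food away from home recorded
#' as expenditure only.
#'
#' Density noise is deliberately small (`density_noise_sdlog = 0.005`):
#' synthetic items within a category are near-replicates of the category's
#' typical food, sized so that a category mean over as few as three retained
#' items recovers the truth to well under 2%. Real composition tables show
#' far larger cross-food spread; see the methods vignette.
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @param n_categories,n_non_nutritive Catalog size and its non-nutritive
#'   subset.
#' @param items_per_category Length-2 integer range of foods per category.
#' @param density_noise_sdlog Log-sd of multiplicative item noise around the
#'   category truth (mean-one lognormal).
#' @param missing_rate Probability a clean item-nutrient cell is missing.
#' @param outlier_rate Marginal probability an item is contaminated; at most
#'   one item per category is hit (isolated data-entry errors — coincident
#'   contaminants in a small group mask each other under any quartile fence).
#' @param outlier_magnitude Multiplier applied to 2-3 nutrients of a
#'   contaminated item.
#' @param n_strata,psus_per_stratum,households_per_psu Design dimensions.
#' @param weight_range Range of expansion factors (uniform).
#' @param income_meanlog,income_sdlog Log-normal income per equivalent adult.
#' @param gradient_ratios Named per-nutrient target ratios of expected
#'   quintile-V to quintile-I availability (1 = no gradient), realized
#'   through category-mix shifts: categories dominated by a nutrient are
#'   bought more by richer households.
#' @param quantity_noise_sdlog Log-sd of mean-one lognormal noise on
#'   purchase quantities.
#' @param fafh_participation Probability a household spends on food away
#'   from home.
#' @param fafh_share_mean,fafh_share_conc Beta distribution (mean,
#'   concentration) of the FAFH share of total food spending among
#'   participants.
#' @param total_grams_per_ae_day Expected total purchased mass per
#'   equivalent adult per day, split across categories.
#' @param reference_days Recall-period length.
#' @param market_seed Seed for the purchase-pattern "market" (per-category
#'   base quantities and prices). Defaults to `seed`; fix it across configs
#'   to simulate repeated survey years drawn from the same population truth.
#' @return Validated list of class `heis_sim_config`.
#' @export
sim_config <- function(seed,
                       n_categories = 245,
                       n_non_nutritive = 9,
                       items_per_category = c(4, 8),
                       density_noise_sdlog = 0.005,
                       missing_rate = 0,
                       outlier_rate = 0.05,
                       outlier_magnitude = 10,
                       n_strata = 8,
                       psus_per_stratum = 4,
                       households_per_psu = 10,
                       weight_range = c(50, 500),
                       income_meanlog = log(8000),
                       income_sdlog = 0.7,
                       gradient_ratios = c(
                         energy_kcal = 1.07, protein_g = 1.24,
                         vita_ug_rae = 1.46, vitc_mg = 1.83,
                         fe_mg = 1.07, zn_mg = 1.10
                       ),
                       quantity_noise_sdlog = 0.30,
                       fafh_participation = 0.6,
                       fafh_share_mean = 0.22,
                       fafh_share_conc = 20,
                       total_grams_per_ae_day = 2000,
                       reference_days = 7,
                       market_seed = NULL) {
  if (missing(seed) || is.na(seed)) abort("a seed is mandatory")
  cfg <- list(
    market_seed = as.integer(market_seed %||% seed),
    seed = as.integer(seed), n_categories = n_categories,
    n_non_nutritive = n_non_nutritive,
    items_per_category = as.integer(items_per_category),
    density_noise_sdlog = density_noise_sdlog, missing_rate = missing_rate,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    n_strata = n_strata, psus_per_stratum = psus_per_stratum,
    households_per_psu = households_per_psu, weight_range = weight_range,
    income_meanlog = income_meanlog, income_sdlog = income_sdlog,
    gradient_ratios = gradient_ratios,
    quantity_noise_sdlog = quantity_noise_sdlog,
    fafh_participation = fafh_participation,
    fafh_share_mean = fafh_share_mean, fafh_share_conc = fafh_share_conc,
    total_grams_per_ae_day = total_grams_per_ae_day,
    reference_days = reference_days
  )
  stopifnot(
    cfg$n_categories >= 1, cfg$n_non_nutritive >= 0,
    cfg$n_non_nutritive < cfg$n_categories,
    length(cfg$items_per_category) == 2,
    cfg$items_per_category[1] >= 1,
    diff(cfg$items_per_category) >= 0,
    cfg$density_noise_sdlog >= 0, cfg$quantity_noise_sdlog >= 0,
    cfg$missing_rate >= 0, cfg$missing_rate < 1,
    cfg$outlier_rate >= 0, cfg$outlier_rate <= 1,
    cfg$outlier_magnitude > 1,
    cfg$n_strata >= 1, cfg$psus_per_stratum >= 1,
    cfg$households_per_psu >= 1,
    all(cfg$weight_range > 0), diff(cfg$weight_range) >= 0,
    all(sort(names(cfg$gradient_ratios)) == sort(heis_nutrients())),
    all(cfg$gradient_ratios > 0),
    cfg$fafh_participation >= 0, cfg$fafh_participation <= 1,
    cfg$fafh_share_mean > 0, cfg$fafh_share_mean < 1,
    cfg$total_grams_per_ae_day > 0, cfg$reference_days > 0
  )
  structure(cfg, class = "heis_sim_config")
}

# mean-one multiplicative lognormal noise
lognoise <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic catalog and multi-source food-composition table
#'
#' Nutritive categories receive a true nutrient-density profile (per 100 g
#' of edible portion) drawn from plausible food-composition ranges; items
#' are the truth times small mean-one lognormal noise, reported at random
#' portion masses and attributed to composition sources with realistic
#' priority shares. With probability `1 - (1 - outlier_rate)^n_items` a
#' category gets one contaminated item: 2-3 of its nutrients multiplied by
#' `outlier_magnitude`. Fully deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return List: `catalog` (category tibble), `items` (food-item tibble
#'   validating under [read_food_items()] conventions), and `truth` with
#'   `categories` (true per-category edible fraction and densities) and
#'   `contaminated` (food_id, category_key, contaminated nutrients).
#' @export
generate_catalog_and_foods <- function(config) {
  stopifnot(inherits(config, "heis_sim_config"))
  set.seed(config$seed)
  n <- config$n_categories
  keys <- sprintf("A%03d", seq_len(n))
  nutritive <- rep(TRUE, n)
  nutritive[sample.int(n, config$n_non_nutritive)] <- FALSE
  catalog <- tibble(
    key = keys,
    label = paste("synthetic category", keys),
    nutritive = nutritive
  )

  nk <- keys[nutritive]
  m <- length(nk)
  truth <- tibble(
    category_key = nk,
    edible_fraction = runif(m, 0.5, 1),
    energy_kcal = rlnorm(m, log(150), 0.9),
    protein_g = rlnorm(m, log(7), 0.9),
    vita_ug_rae = rlnorm(m, log(60), 1.2),
    vitc_mg = rlnorm(m, log(10), 1.2),
    fe_mg = rlnorm(m, log(2), 0.8),
    zn_mg = rlnorm(m, log(1.5), 0.8)
  )

  n_items <- sample(seq(config$items_per_category[1],
                        config$items_per_category[2]), m, replace = TRUE)
  idx <- rep(seq_len(m), n_items)
  total <- length(idx)
  within <- sequence(n_items)
  sdlog <- config$density_noise_sdlog

  dens <- vapply(heis_nutrients(), function(nut) {
    truth[[nut]][idx] * lognoise(total, sdlog)
  }, numeric(total))
  dens <- matrix(dens, nrow = total,
                 dimnames = list(NULL, heis_nutrients()))

  # at most one contaminated item per category (isolated anomalies)
  hit <- runif(m) < 1 - (1 - config$outlier_rate)^n_items
  contaminated <- tibble(food_id = character(), category_key = character(),
                         nutrients = character())
  row_offset <- c(0, cumsum(n_items))
  food_id <- paste0(truth$category_key[idx], "_", within)
  for (j in which(hit)) {
    pick <- row_offset[j] + sample.int(n_items[j], 1)
    nuts <- sample(heis_nutrients(), sample(2:3, 1))
    dens[pick, nuts] <- dens[pick, nuts] * config$outlier_magnitude
    contaminated <- bind_rows(contaminated, tibble(
      food_id = food_id[pick], category_key = truth$category_key[j],
      nutrients = paste(sort(nuts), collapse = ",")
    ))
  }

  if (config$missing_rate > 0) {
    for (nut in heis_nutrients()) {
      miss <- runif(total) < config$missing_rate
      # keep the truth recoverable: never blank a contaminated cell, and
      # keep at least one value per category and nutrient
      miss[food_id %in% contaminated$food_id] <- FALSE
      keep_one <- !duplicated(idx)
      miss[keep_one] <- FALSE
      dens[miss, nut] <- NA_real_
    }
  }

  portion <- round(runif(total, 30, 500), 1)
  rae <- dens[, "vita_ug_rae"]
  s_ret <- runif(total, 0.2, 0.8)
  s_bc <- (1 - s_ret) * runif(total, 0.3, 0.9)
  s_other <- 1 - s_ret - s_bc
  amt <- function(v) v * portion / 100
  items <- tibble(
    food_id = food_id,
    source = sample(source_priority_levels(), total, replace = TRUE,
                    prob = c(0.80, 0.08, 0.05, 0.03, 0.02, 0.02)),
    category_key = truth$category_key[idx],
    edible_fraction = truth$edible_fraction[idx],
    portion_mass_g = portion,
    energy_kcal = amt(dens[, "energy_kcal"]),
    protein_g = amt(dens[, "protein_g"]),
    retinol_ug = amt(rae * s_ret),
    beta_carotene_ug = amt(rae * s_bc * 12),
    other_provitamin_a_ug = amt(rae * s_other * 24),
    vitamin_c_mg = amt(dens[, "vitc_mg"]),
    iron_mg = amt(dens[, "fe_mg"]),
    zinc_mg = amt(dens[, "zn_mg"])
  )
  list(catalog = catalog, items = items,
       truth = list(categories = truth, contaminated = contaminated))
}

#' Generate a synthetic stratified weighted survey with purchases
#'
#' Builds a stratified two-stage frame (strata of PSUs of households) with
#' uniform expansion factors, log-normal income per equivalent adult, and
#' purchase quantities whose expectation delivers a per-equivalent-adult
#' availability following the configured income gradient. The gradient works
#' through the category mix: each category is assigned the nutrient it is
#' most dense in (relative to the catalog average), and its purchased
#' quantity scales linearly in the household's person-weighted income rank so
#' that the expected quintile-V/quintile-I ratio for that nutrient matches
#' `gradient_ratios`. FAFH spending is attached as expenditure-only records.
#'
#' @param config A [sim_config()].
#' @param profiles Category nutrient profiles used as truth: tibble with
#'   `category_key`, `edible_fraction` and the six density columns (e.g. the
#'   `truth$categories` of [generate_catalog_and_foods()] or a built
#'   conversion table).
#' @return List: `households`, `purchases` (CSV-schema tibbles) and `truth`
#'   with `mean_availability` (expected population mean per nutrient),
#'   `quintile_ratio` (expected V/I ratio per nutrient),
#'   `household_expected` (per-household expected availability),
#'   `fafh_participation` and `fafh_share_mean`.
#' @export
generate_survey <- function(config, profiles) {
  stopifnot(inherits(config, "heis_sim_config"))
  need <- c("category_key", "edible_fraction", heis_nutrients())
  stopifnot(all(need %in% names(profiles)))
  if (anyNA(profiles[need])) abort("profiles must be complete (no NA)")

  # the "market": how total purchases split across categories, and prices;
  # seeded separately so repeated survey years can share one truth
  set.seed(config$market_seed + 2000003L)
  C <- nrow(profiles)
  u <- rlnorm(C, 0, 1)
  base <- config$total_grams_per_ae_day * u / sum(u)  # g/day per eq. adult
  price <- rlnorm(C, log(0.08), 0.5)                  # currency per gram

  set.seed(config$seed + 1000003L)

  D <- as.matrix(profiles[heis_nutrients()])
  rel <- sweep(D, 2, colMeans(D), "/")
  dominant <- heis_nutrients()[max.col(rel, ties.method = "first")]
  ratio <- config$gradient_ratios[dominant]
  slope <- (ratio - 1) / (0.8 * (ratio + 1))  # quintile-mean multiplier 1±0.8s

  H <- config$n_strata * config$psus_per_stratum * config$households_per_psu
  stratum <- rep(seq_len(config$n_strata),
                 each = config$psus_per_stratum * config$households_per_psu)
  psu <- rep(seq_len(config$n_strata * config$psus_per_stratum),
             each = config$households_per_psu)
  weight <- runif(H, config$weight_range[1], config$weight_range[2])
  n_members <- 1 + rpois(H, 1.5)
  ages <- lapply(n_members, function(k) sample(0:79, k, replace = TRUE))
  ae <- vapply(ages, equivalent_adults, numeric(1))
  income_per_ea <- rlnorm(H, config$income_meanlog, config$income_sdlog)

  # person-weighted income rank in (0, 1)
  pw <- weight * n_members
  ord <- order(income_per_ea)
  r <- numeric(H)
  r[ord] <- (cumsum(pw[ord]) - 0.5 * pw[ord]) / sum(pw)

  households <- tibble(
    household_id = sprintf("H%05d", seq_len(H)),
    stratum = stratum, psu = psu, weight = weight,
    income = income_per_ea * ae,
    member_ages = vapply(ages, paste, character(1), collapse = "|"),
    n_members = n_members
  )

  hh_idx <- rep(seq_len(H), each = C)
  cat_idx <- rep(seq_len(C), times = H)
  mix <- 1 + slope[cat_idx] * (2 * r[hh_idx] - 1)
  q <- base[cat_idx] * ae[hh_idx] * config$reference_days * mix *
    lognoise(H * C, config$quantity_noise_sdlog)
  purchases <- tibble(
    household_id = households$household_id[hh_idx],
    category_key = profiles$category_key[cat_idx],
    quantity_g = q,
    expenditure = q * price[cat_idx],
    is_fafh = FALSE
  )

  if (config$fafh_participation > 0) {
    takes <- runif(H) < config$fafh_participation
    if (any(takes)) {
      a <- config$fafh_share_mean * config$fafh_share_conc
      b <- (1 - config$fafh_share_mean) * config$fafh_share_conc
      share <- rbeta(sum(takes), a, b)
      home_exp <- tapply(purchases$expenditure, purchases$household_id, sum)
      home_exp <- home_exp[households$household_id[takes]]
      purchases <- bind_rows(purchases, tibble(
        household_id = households$household_id[takes],
        category_key = "FAFH",
        quantity_g = NA_real_,
        expenditure = as.numeric(home_exp) * share / (1 - share),
        is_fafh = TRUE
      ))
    }
  }

  # per-nutrient expected daily availability per equivalent adult
  t_ck <- base * profiles$edible_fraction * D / 100   # C x 6
  mean_avail <- colSums(t_ck)
  qI <- colSums(t_ck * (1 - 0.8 * slope))
  qV <- colSums(t_ck * (1 + 0.8 * slope))
  expected <- outer(rep(1, H), mean_avail) +
    (2 * r - 1) * matrix(rep(colSums(t_ck * slope), each = H), nrow = H)
  colnames(expected) <- heis_nutrients()
  household_expected <- bind_cols(
    tibble(household_id = households$household_id),
    as_tibble(expected)
  )

  list(
    households = households, purchases = purchases,
    truth = list(
      mean_availability = mean_avail,
      quintile_ratio = qV / qI,
      household_expected = household_expected,
      fafh_participation = config$fafh_participation,
      fafh_share_mean = config$fafh_share_mean
    )
  )
}

#' Emit a complete synthetic fixture set to a directory
#'
#' Writes `categories.csv`, `food_items.csv`, `households.csv`,
#' `purchases.csv` (the exact schemas the readers expect) and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory, created if needed.
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_to_dir <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_catalog_and_foods(config)
  svy <- generate_survey(config, gen$truth$categories)
  paths <- c(
    categories = file.path(outdir, "categories.csv"),
    food_items = file.path(outdir, "food_items.csv"),
    households = file.path(outdir, "households.csv"),
    purchases = file.path(outdir, "purchases.csv"),
    truth = file.path(outdir, "truth.json")
  )
  write_category_catalog(gen$catalog, paths[["categories"]])
  write_food_items(gen$items, paths[["food_items"]])
  readr::write_csv(
    svy$households[c("household_id", "stratum", "psu", "weight", "income",
                     "member_ages")],
    paths[["households"]]
  )
  readr::write_csv(svy$purchases, paths[["purchases"]])
  jsonlite::write_json(
    list(
      categories = gen$truth$categories,
      contaminated = gen$truth$contaminated,
      mean_availability = as.list(svy$truth$mean_availability),
      quintile_ratio = as.list(svy$truth$quintile_ratio),
      fafh_participation = svy$truth$fafh_participation,
      fafh_share_mean = svy$truth$fafh_share_mean
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
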