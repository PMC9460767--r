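# In-code fixture builders shared across test files.

nuts <- heis_nutrients()

make_catalog <- function(n = 5, non_nutritive = integer(0)) {
  keys <- sprintf("A%03d", seq_len(n))
  tibble::tibble(
    key = keys,
    label = paste("cat", keys),
    nutritive = !(seq_len(n) %in% non_nutritive)
  )
}

# one food item row with sensible defaults; nutrient amounts refer to
# portion_mass_g grams
make_item <- function(food_id, category_key, portion_mass_g = 100,
                      edible_fraction = 1, energy_kcal = 100, protein_g = 5,
                      retinol_ug = 50, beta_carotene_ug = 0,
                      other_provitamin_a_ug = 0, vitamin_c_mg = 10,
                      iron_mg = 2, zinc_mg = 1, source = "SZ") {
  tibble::tibble(
    food_id = food_id, source = source, category_key = category_key,
    edible_fraction = edible_fraction, portion_mass_g = portion_mass_g,
    energy_kcal = energy_kcal, protein_g = protein_g,
    retinol_ug = retinol_ug, beta_carotene_ug = beta_carotene_ug,
    other_provitamin_a_ug = other_provitamin_a_ug,
    vitamin_c_mg = vitamin_c_mg, iron_mg = iron_mg, zinc_mg = zinc_mg
  )
}

# a category of items whose energy densities are `values` (per 100 g),
# everything else constant
make_energy_category <- function(values, key = "A001") {
  dplyr::bind_rows(lapply(seq_along(values), function(i) {
    make_item(paste0(key, "_", i), key, energy_kcal = values[i])
  }))
}

# minimal one-category conversion table
tiny_table <- function(key = "A001", edible_fraction = 1, energy_kcal = 100,
                       protein_g = 0, vita_ug_rae = 0, vitc_mg = 0,
                       fe_mg = 0, zn_mg = 0) {
  tibble::tibble(
    category_key = key, edible_fraction = edible_fraction,
    energy_kcal = energy_kcal, protein_g = protein_g,
    vita_ug_rae = vita_ug_rae, vitc_mg = vitc_mg, fe_mg = fe_mg,
    zn_mg = zn_mg
  )
}

one_adult_household <- function(id = "h1", stratum = 1, psu = 1,
                                weight = 1, income = 100) {
  tibble::tibble(
    household_id = id, stratum = stratum, psu = psu, weight = weight,
    income = income, member_ages = "30", n_members = 1L
  )
}

# independent-households design: every household its own PSU in one stratum
srs_design <- function(n, weight = 1) {
  tibble::tibble(stratum = 1L, psu = seq_len(n), weight = weight)
}
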