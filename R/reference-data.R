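#' Published quintile mean availability, Mexico 2020
#'
#' Point estimates of average daily nutrient availability per capita
#' (adjusted by equivalence scales) by income quintile, as published for
#' Mexico in 2020 from the national income-expenditure survey. Bundled so
#' the income-gradient utilities can be demonstrated and checked without
#' microdata access; the headline gradients are recovered as
#' `quintile_excess(published_quintile_means())`.
#'
#' @return Wide tibble: `quintile` (`I`..`V`) plus the six nutrient columns
#'   of [heis_nutrients()].
#' @export
#' @examples
#' quintile_excess(published_quintile_means())
published_quintile_means <- function() {
  path <- system.file("extdata", "quintile_means_mx2020.csv",
                      package = "heisnutr", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
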