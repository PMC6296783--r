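#' The 16-species experimental pool
#'
#' Returns the species pool of the grassland diversity experiment the
#' simulator emulates: 16 perennial herbaceous species, four from each of
#' four functional groups (C3 grasses, C4 grasses, legumes, and
#' non-leguminous forbs).
#'
#' @return A data frame with columns `species` (character, Latin binomial)
#'   and `functional_group` (factor with levels `"C3 grass"`, `"C4 grass"`,
#'   `"legume"`, `"forb"`), 16 rows, ordered alphabetically by species
#'   within functional group.
#' @examples
#' pool <- build_species_pool()
#' table(pool$functional_group)
#' @export
build_species_pool <- function() {
  pool <- data.frame(
    species = c(
      # C3 grasses
      "Agropyron repens", "Bromus inermis", "Koeleria cristata",
      "Poa pratensis",
      # C4 grasses
      "Andropogon gerardii", "Bouteloua gracilis",
      "Schizachyrium scoparium", "Sorghastrum nutans",
      # legumes
      "Amorpha canescens", "Lespedeza capitata", "Lupinus perennis",
      "Petalostemum villosum",
      # non-leguminous forbs
      "Achillea millefolium", "Anemone cylindrica", "Asclepias tuberosa",
      "Solidago rigida"
    ),
    functional_group = factor(
      rep(c("C3 grass", "C4 grass", "legume", "forb"), each = 4L),
      levels = c("C3 grass", "C4 grass", "legume", "forb")
    ),
    stringsAsFactors = FALSE
  )
  pool
}
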