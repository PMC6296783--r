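#' Top-performing monoculture per function and environment
#'
#' For every soil function and every CO2 x N cell, identifies the species
#' whose monoculture plots have the highest mean value. Ties (within
#' numerical tolerance) are broken lexicographically by species name and
#' flagged.
#'
#' @param functions Data frame with `plot_id` plus function columns.
#' @param design Design table with `plot_id`, `co2`, `n`,
#'   `sown_richness`, `sown_species`.
#' @return A data frame with columns `function_name`, `co2`, `n`,
#'   `species`, `mean_value`, `n_plots`, `tie` (logical). Cells with no
#'   monoculture data for a function carry `NA` species and values.
#' @export
top_monoculture <- function(functions, design) {
  stopifnot(all(c("plot_id", "co2", "n", "sown_richness", "sown_species")
                %in% names(design)))
  mono <- design[design$sown_richness == 1L,
                 c("plot_id", "co2", "n", "sown_species")]
  names(mono)[4L] <- "species"
  d <- merge(mono, functions, by = "plot_id")
  fn_cols <- setdiff(names(functions), "plot_id")
  cells <- expand.grid(co2 = unique(design$co2), n = unique(design$n),
                       stringsAsFactors = FALSE)
  rows <- list()
  for (f in fn_cols) {
    for (i in seq_len(nrow(cells))) {
      sub <- d[d$co2 == cells$co2[i] & d$n == cells$n[i] &
               is.finite(d[[f]]), ]
      if (nrow(sub) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          function_name = f, co2 = cells$co2[i], n = cells$n[i],
          species = NA_character_, mean_value = NA_real_, n_plots = 0L,
          tie = NA, stringsAsFactors = FALSE)
        next
      }
      means <- tapply(sub[[f]], sub$species, mean)
      best <- max(means)
      winners <- sort(names(means)[means >= best - 1e-12 * max(1, abs(best))])
      rows[[length(rows) + 1L]] <- data.frame(
        function_name = f, co2 = cells$co2[i], n = cells$n[i],
        species = winners[1L], mean_value = unname(means[winners[1L]]),
        n_plots = sum(sub$species == winners[1L]),
        tie = length(winners) > 1L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
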