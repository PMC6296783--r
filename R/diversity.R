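#' Taxonomic diversity and evenness of a plot
#'
#' Indices computed from a single plot's cover vector. Covers may be on
#' any nonnegative scale (percent ground cover or relative proportions);
#' all indices are scale-invariant because they work on relative
#' abundances `p_i = cover_i / sum(cover)`.
#'
#' `realized_richness()` counts species with cover above a detection
#' threshold (default 0, i.e. any positive cover). `shannon_diversity()`
#' is `H = -sum(p_i * log(p_i))` in nats. `shannon_evenness()` is Pielou's
#' `J = H / log(S)`, undefined (`NA`) for fewer than two species.
#' `simpson_evenness()` is the inverse Simpson concentration divided by
#' realized richness, `E = (1 / sum(p_i^2)) / S`, equal to 1 for any
#' perfectly even community including monocultures.
#'
#' @param covers Numeric vector of nonnegative covers, one entry per
#'   species.
#' @param detect_threshold Covers strictly greater than this count as
#'   present (default 0).
#' @param base Logarithm base for the Shannon family (default `exp(1)`,
#'   i.e. nats).
#' @return A single numeric value (`NA_real_` where the index is
#'   undefined, see Details).
#' @examples
#' shannon_diversity(c(0.5, 0.3, 0.2))
#' simpson_evenness(c(0.25, 0.25, 0.25, 0.25))  # 1
#' @name plot_diversity
NULL

.check_covers <- function(covers) {
  if (!is.numeric(covers) || any(!is.finite(covers)))
    stop("covers must be finite numeric values", call. = FALSE)
  if (any(covers < 0))
    stop("covers must be nonnegative", call. = FALSE)
  invisible(covers)
}

#' @rdname plot_diversity
#' @export
realized_richness <- function(covers, detect_threshold = 0) {
  .check_covers(covers)
  sum(covers > detect_threshold)
}

#' @rdname plot_diversity
#' @export
shannon_diversity <- function(covers, base = exp(1)) {
  .check_covers(covers)
  if (sum(covers) <= 0)
    stop("Shannon diversity is undefined for an all-zero community",
         call. = FALSE)
  as.numeric(vegan::diversity(covers, index = "shannon", base = base))
}

#' @rdname plot_diversity
#' @export
shannon_evenness <- function(covers, base = exp(1)) {
  .check_covers(covers)
  s <- realized_richness(covers)
  if (s < 2L) return(NA_real_)
  shannon_diversity(covers, base = base) / log(s, base = base)
}

#' @rdname plot_diversity
#' @export
simpson_evenness <- function(covers) {
  .check_covers(covers)
  if (sum(covers) <= 0)
    stop("Simpson evenness is undefined for an all-zero community",
         call. = FALSE)
  s <- realized_richness(covers)
  as.numeric(vegan::diversity(covers, index = "invsimpson")) / s
}

#' Per-plot diversity table
#'
#' Applies the taxonomic indices to every row of a cover table. Plots in
#' which every sown species went extinct (all covers zero) receive 0 for
#' every index, following the convention of the analysis this package
#' implements; the Shannon evenness of surviving monocultures is reported
#' as `NA` (the index is undefined at one species) so such plots drop out
#' of evenness analyses rather than biasing them.
#'
#' @param covers A data frame with a `plot_id` column plus one numeric
#'   cover column per species (as produced by [generate_covers()]).
#' @param detect_threshold Passed to [realized_richness()].
#' @return A data frame with columns `plot_id`, `realized_richness`,
#'   `shannon_H`, `shannon_evenness`, `simpson_evenness`.
#' @export
community_diversity <- function(covers, detect_threshold = 0) {
  stopifnot("plot_id" %in% names(covers))
  mat <- as.matrix(covers[, setdiff(names(covers), "plot_id"), drop = FALSE])
  .check_covers(as.numeric(mat))
  out <- data.frame(plot_id = covers$plot_id,
                    realized_richness = 0L, shannon_H = 0,
                    shannon_evenness = 0, simpson_evenness = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (sum(x) <= 0) next  # all sown species extinct: indices stay 0
    out$realized_richness[i] <- realized_richness(x, detect_threshold)
    out$shannon_H[i] <- shannon_diversity(x)
    out$shannon_evenness[i] <- shannon_evenness(x)
    out$simpson_evenness[i] <- simpson_evenness(x)
  }
  out
}
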