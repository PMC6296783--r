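#' Pairwise Pearson correlations among soil functions
#'
#' Pearson r, r^2, and a two-sided p value (t transform) for every pair
#' of function columns, using pairwise-complete observations.
#'
#' @param functions Data frame with `plot_id` plus numeric function
#'   columns.
#' @return A data frame with one row per unordered pair: `var1`, `var2`,
#'   `n` (complete pairs), `r`, `r2`, `p`. A zero-variance column yields
#'   `NA` for its pairs, with a warning.
#' @export
pearson_matrix <- function(functions) {
  stopifnot("plot_id" %in% names(functions))
  vars <- setdiff(names(functions), "plot_id")
  pairs <- utils::combn(vars, 2L)
  out <- data.frame(var1 = pairs[1L, ], var2 = pairs[2L, ],
                    n = NA_integer_, r = NA_real_, r2 = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    x <- functions[[pairs[1L, k]]]
    y <- functions[[pairs[2L, k]]]
    ok <- is.finite(x) & is.finite(y)
    out$n[k] <- sum(ok)
    if (sum(ok) < 3L) {
      warning("fewer than 3 complete pairs for ", pairs[1L, k], " ~ ",
              pairs[2L, k], call. = FALSE)
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("zero-variance column in pair ", pairs[1L, k], " ~ ",
              pairs[2L, k], "; correlation undefined", call. = FALSE)
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    out$r[k] <- unname(ct$estimate)
    out$r2[k] <- unname(ct$estimate)^2
    out$p[k] <- ct$p.value
  }
  out
}
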