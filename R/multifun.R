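#' Standardize soil functions to the unit interval
#'
#' Linear min-max rescaling of each function over the analysed plot set:
#' `(x - min) / (max - min)`, computed once across all plots (not per
#' treatment), so the plot attaining a function's minimum maps to 0 and
#' the maximum to 1. Missing cells are preserved as `NA`.
#'
#' @param functions Data frame with `plot_id` plus one numeric column per
#'   soil function.
#' @return A data frame of the same shape with each function rescaled to
#'   \[0, 1\].
#' @export
standardize_functions <- function(functions) {
  stopifnot("plot_id" %in% names(functions))
  out <- functions
  for (f in setdiff(names(functions), "plot_id")) {
    x <- functions[[f]]
    rng <- range(x, na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) <= 0)
      stop("function '", f, "' is constant (or all missing); ",
           "cannot standardize", call. = FALSE)
    out[[f]] <- (x - rng[1L]) / diff(rng)
  }
  out
}

#' Average ecosystem multifunctionality
#'
#' The averaging approach: the mean of the standardized function values of
#' each plot. Plots with any missing function are excluded (with a
#' message) rather than averaged over fewer functions.
#'
#' @param std Standardized functions from [standardize_functions()].
#' @return A data frame with columns `plot_id` and `multifunctionality`
#'   (in \[0, 1\]), complete-case plots only.
#' @export
average_multifunctionality <- function(std) {
  stopifnot("plot_id" %in% names(std))
  vals <- as.matrix(std[, setdiff(names(std), "plot_id"), drop = FALSE])
  complete <- stats::complete.cases(vals)
  if (any(!complete))
    message(sum(!complete), " plot(s) excluded from average ",
            "multifunctionality (missing function values)")
  data.frame(plot_id = std$plot_id[complete],
             multifunctionality = rowMeans(vals[complete, , drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Number of functions at or above a threshold
#'
#' The multiple-threshold approach's per-plot count: the number of
#' functions whose raw value is at or above `t` percent of that
#' function's maximum observed value across the analysed plots.
#'
#' @param functions Raw (unstandardized) function table with `plot_id`.
#' @param t Threshold in percent, in (0, 100\].
#' @param na_action `"complete"` (default) restricts counting to
#'   complete-case plots; `"available"` counts over non-missing functions.
#' @return A data frame with columns `plot_id` and `n_functions`
#'   (0..number of functions).
#' @export
threshold_counts <- function(functions, t, na_action = c("complete", "available")) {
  na_action <- match.arg(na_action)
  stopifnot("plot_id" %in% names(functions))
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t > 100)
    stop("threshold t must be a single percent value in (0, 100]",
         call. = FALSE)
  vals <- as.matrix(functions[, setdiff(names(functions), "plot_id"),
                              drop = FALSE])
  keep <- if (na_action == "complete") stats::complete.cases(vals)
          else rep(TRUE, nrow(vals))
  vals <- vals[keep, , drop = FALSE]
  maxima <- apply(vals, 2L, max, na.rm = TRUE)
  hit <- sweep(vals, 2L, (t / 100) * maxima, ">=")
  data.frame(plot_id = functions$plot_id[keep],
             n_functions = as.integer(rowSums(hit, na.rm = TRUE)),
             stringsAsFactors = FALSE)
}

#' Diversity-multifunctionality slope across thresholds
#'
#' For every threshold in `t_range`, regresses the per-plot number of
#' functions at or above the threshold on (by default, the natural log
#' of) sown species richness by ordinary least squares, and records the
#' slope and its standard error. The full 1-99% profile summarizes how
#' the diversity effect on simultaneous functioning changes with the
#' stringency of the performance criterion.
#'
#' @param functions Raw function table with `plot_id`.
#' @param design Design table with `plot_id` and `sown_richness`.
#' @param t_range Integer vector of thresholds in percent (default
#'   `1:99`).
#' @param regressor `"log_richness"` (default) or `"richness"`.
#' @return A data frame with columns `t`, `slope`, `se`.
#' @export
threshold_slope_profile <- function(functions, design, t_range = 1:99,
                                    regressor = c("log_richness", "richness")) {
  regressor <- match.arg(regressor)
  stopifnot(all(c("plot_id", "sown_richness") %in% names(design)))
  if (length(unique(design$sown_richness)) < 2L)
    stop("need at least two distinct richness levels to estimate a slope",
         call. = FALSE)
  out <- data.frame(t = t_range, slope = NA_real_, se = NA_real_)
  for (k in seq_along(t_range)) {
    counts <- threshold_counts(functions, t_range[k])
    d <- merge(counts, design[, c("plot_id", "sown_richness")], by = "plot_id")
    x <- if (regressor == "log_richness") log(d$sown_richness)
         else d$sown_richness
    # direct least squares; a constant count gives slope 0 with SE 0
    X <- cbind(1, x)
    qx <- qr(X)
    beta <- qr.coef(qx, d$n_functions)
    sigma2 <- sum(qr.resid(qx, d$n_functions)^2) / (nrow(d) - 2L)
    out$slope[k] <- beta[2L]
    out$se[k] <- sqrt(sigma2 * chol2inv(qr.R(qx))[2L, 2L])
  }
  out
}

#' Shannon diversity and evenness of multiple functions
#'
#' Treats the four standardized function values of a plot like species
#' abundances: with `q_f = std_f / sum(std)`,
#' `H_func = -sum(q_f * log(q_f))` and `evenness = H_func / log(F)` for F
#' functions. A plot whose standardized values are all zero receives 0
#' for both quantities (the convention for empty communities).
#'
#' @param std Standardized functions from [standardize_functions()].
#' @return A data frame with columns `plot_id`, `shannon_H_functions`,
#'   `evenness_functions`, complete-case plots only.
#' @export
function_evenness <- function(std) {
  stopifnot("plot_id" %in% names(std))
  vals <- as.matrix(std[, setdiff(names(std), "plot_id"), drop = FALSE])
  complete <- stats::complete.cases(vals)
  vals <- vals[complete, , drop = FALSE]
  nf <- ncol(vals)
  H <- apply(vals, 1L, function(v) {
    tot <- sum(v)
    if (tot <= 0) return(0)
    q <- v[v > 0] / tot
    -sum(q * log(q))
  })
  data.frame(plot_id = std$plot_id[complete],
             shannon_H_functions = H,
             evenness_functions = H / log(nf),
             stringsAsFactors = FALSE)
}
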