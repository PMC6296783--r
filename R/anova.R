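#' Split-plot Type III ANOVA for the factorial diversity experiment
#'
#' Fits the study's general linear model to one response: CO2, N, the
#' natural log of species richness (PSR), all their interactions, and a
#' ring-within-CO2 block term, with Type III sums of squares (each term
#' adjusted for all others, sum-to-zero factor coding, centred richness
#' covariate). CO2 is the whole-plot factor and is tested against the
#' ring-within-CO2 mean square; every other term is tested against the
#' residual.
#'
#' Degrees-of-freedom bookkeeping is reported two ways: the conventional
#' nested accounting (ring within CO2 carries 4 df, so the full model has
#' 11 non-intercept df) drives all F and p values, while the attribute
#' `df_residual_caption` carries the alternative accounting that counts
#' the ring block with 6 df (13 model df, residual `n - 14`), which some
#' software reports for this design.
#'
#' @param data Data frame with the response column plus `co2`, `n`,
#'   `ring`, `sown_richness` (and `realized_richness` if
#'   `richness = "realized"`).
#' @param response Name of the response column.
#' @param richness `"sown"` (default) or `"realized"`: which richness
#'   enters as the log-linear regressor.
#' @param exclude_monocultures If `TRUE`, refit using only richness
#'   levels > 1 (sensitivity analysis).
#' @param co2_test `"classical"` (default) tests CO2 against the ring
#'   mean square with its conventional df; `"satterthwaite"` builds a
#'   linear combination of the ring and residual mean squares whose
#'   expectation matches the CO2 numerator's under the null (relevant for
#'   unbalanced ring sizes) and uses Satterthwaite's approximate df.
#' @param center_richness Centre the log-richness covariate (default
#'   `TRUE`); with sum-to-zero factor coding this makes Type III and
#'   sequential sums of squares agree on balanced designs.
#' @return A data frame of class `anova_table` with one row per term
#'   (`CO2`, `Ring(CO2)`, `N`, `PSR`, `CO2:N`, `CO2:PSR`, `N:PSR`,
#'   `CO2:N:PSR`) and columns `term`, `df`, `SS`, `MS`, `F`, `p`,
#'   `den_stratum`, `den_df`. Attributes: `n`, `model_df`,
#'   `model_df_caption`, `df_residual`, `df_residual_caption`,
#'   `ss_residual`, `response`.
#' @export
type3_anova <- function(data, response,
                        richness = c("sown", "realized"),
                        exclude_monocultures = FALSE,
                        co2_test = c("classical", "satterthwaite"),
                        center_richness = TRUE) {
  richness <- match.arg(richness)
  co2_test <- match.arg(co2_test)
  rich_col <- if (richness == "sown") "sown_richness" else "realized_richness"
  need <- unique(c(response, "co2", "n", "ring", "sown_richness", rich_col))
  if (!all(need %in% names(data)))
    stop("missing column(s): ", paste(setdiff(need, names(data)),
                                      collapse = ", "), call. = FALSE)
  d <- data[stats::complete.cases(data[, need]), need]
  if (exclude_monocultures) d <- d[d$sown_richness > 1L, , drop = FALSE]
  d <- d[d[[rich_col]] > 0, , drop = FALSE]
  n <- nrow(d)
  y <- d[[response]]

  co2f <- factor(d$co2)
  nf <- factor(d$n)
  if (nlevels(co2f) != 2L || nlevels(nf) != 2L)
    stop("co2 and n must each have two levels in the analysed data",
         call. = FALSE)
  x <- log(d[[rich_col]])
  if (center_richness) x <- x - mean(x)
  C <- stats::contr.sum(2L)[co2f, 1L]
  N <- stats::contr.sum(2L)[nf, 1L]

  # ring nested within CO2: sum-to-zero contrasts among each CO2 level's rings
  ring_cols <- NULL
  for (lev in levels(co2f)) {
    rl <- factor(d$ring[co2f == lev])
    if (nlevels(rl) < 2L) next
    cc <- stats::contr.sum(nlevels(rl))
    block <- matrix(0, n, ncol(cc))
    block[co2f == lev, ] <- cc[rl, , drop = FALSE]
    ring_cols <- cbind(ring_cols, block)
  }
  if (is.null(ring_cols))
    stop("need at least two rings per CO2 level", call. = FALSE)

  terms <- list(
    "CO2"        = cbind(C),
    "Ring(CO2)"  = ring_cols,
    "N"          = cbind(N),
    "PSR"        = cbind(x),
    "CO2:N"      = cbind(C * N),
    "CO2:PSR"    = cbind(C * x),
    "N:PSR"      = cbind(N * x),
    "CO2:N:PSR"  = cbind(C * N * x)
  )
  X <- cbind("(Intercept)" = rep(1, n), do.call(cbind, terms))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("rank-deficient design: aliasing among terms ",
         "(check ring/CO2 assignment and richness levels)", call. = FALSE)
  }
  rss_full <- sum(qr.resid(qrX, y)^2)
  df_resid <- n - qrX$rank
  ms_resid <- rss_full / df_resid

  col_of <- split(seq_len(ncol(X) - 1L) + 1L,
                  rep(seq_along(terms), vapply(terms, ncol, 1L)))
  names(col_of) <- names(terms)
  ss <- df <- stats::setNames(numeric(length(terms)), names(terms))
  for (tn in names(terms)) {
    Xr <- X[, -col_of[[tn]], drop = FALSE]
    ss[tn] <- sum(qr.resid(qr(Xr), y)^2) - rss_full
    df[tn] <- length(col_of[[tn]])
  }
  ms <- ss / df
  ms_ring <- ms[["Ring(CO2)"]]
  df_ring <- df[["Ring(CO2)"]]

  out <- data.frame(term = names(terms), df = as.integer(df), SS = ss,
                    MS = ms, F = NA_real_, p = NA_real_,
                    den_stratum = "residual", den_df = df_resid,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    tn <- out$term[i]
    if (tn == "CO2") {
      if (co2_test == "classical") {
        out$F[i] <- out$MS[i] / ms_ring
        out$den_stratum[i] <- "Ring(CO2)"
        out$den_df[i] <- df_ring
      } else {
        sw <- .satterthwaite_co2(X, col_of, ms_ring, df_ring, ms_resid,
                                 df_resid, d$ring)
        out$F[i] <- out$MS[i] / sw$denominator
        out$den_stratum[i] <- "Satterthwaite(Ring(CO2), residual)"
        out$den_df[i] <- sw$df
      }
    } else {
      out$F[i] <- out$MS[i] / ms_resid
    }
    out$p[i] <- stats::pf(out$F[i], out$df[i], out$den_df[i],
                          lower.tail = FALSE)
  }
  structure(out,
            class = c("anova_table", "data.frame"),
            n = n,
            model_df = qrX$rank - 1L,
            model_df_caption = 13L,
            df_residual = df_resid,
            df_residual_caption = n - 1L - 13L,
            ss_residual = rss_full,
            response = response)
}

# Expected-mean-square matching for the CO2 test on unbalanced designs:
# SS_term = y' A y with A the Type III projection difference, so under the
# null E[MS_term] = sigma^2 + tr(A Z Z') / df * sigma^2_ring for the ring
# incidence matrix Z. The denominator c * MS_ring + (1 - c) * MS_resid with
# c = tr(A_co2 G)/df_co2 / (tr(A_ring G)/df_ring) matches E[MS_CO2], and
# Satterthwaite's formula gives its approximate df.
.satterthwaite_co2 <- function(X, col_of, ms_ring, df_ring, ms_resid,
                               df_resid, ring) {
  Z <- stats::model.matrix(~ 0 + factor(ring))
  tr_pg <- function(cols_dropped) {
    Xr <- if (is.null(cols_dropped)) X else X[, -cols_dropped, drop = FALSE]
    qrr <- qr(Xr)
    PZ <- qr.fitted(qrr, Z)
    sum(Z * PZ)
  }
  tr_full <- tr_pg(NULL)
  c1 <- (tr_full - tr_pg(col_of[["CO2"]])) / length(col_of[["CO2"]])
  c2 <- (tr_full - tr_pg(col_of[["Ring(CO2)"]])) / length(col_of[["Ring(CO2)"]])
  cc <- min(max(c1 / c2, 0), 1)
  denom <- cc * ms_ring + (1 - cc) * ms_resid
  df <- denom^2 / ((cc * ms_ring)^2 / df_ring +
                   ((1 - cc) * ms_resid)^2 / df_resid)
  list(denominator = denom, df = df)
}

#' @export
print.anova_table <- function(x, ...) {
  cat(sprintf("Split-plot Type III ANOVA for '%s' (n = %d)\n",
              attr(x, "response"), attr(x, "n")))
  print.data.frame(x, digits = 4, ...)
  cat(sprintf("Residual: df = %d (conventional), %d (13-model-df accounting), SS = %.4g\n",
              attr(x, "df_residual"), attr(x, "df_residual_caption"),
              attr(x, "ss_residual")))
  invisible(x)
}
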