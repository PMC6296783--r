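# Independent oracles and small fixtures used across the suite.

# Brute-force minimum spanning tree: enumerate every (n-1)-subset of edges,
# keep those forming a spanning tree, return the edge matrix of the
# minimum-total-weight tree.
brute_force_mst <- function(coords) {
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  edges <- t(combn(n, 2L))
  subsets <- combn(nrow(edges), n - 1L)
  best_w <- Inf
  best <- NULL
  for (k in seq_len(ncol(subsets))) {
    es <- edges[subsets[, k], , drop = FALSE]
    # spanning + acyclic <=> connects all n vertices with n-1 edges
    comp <- seq_len(n)
    for (e in seq_len(nrow(es))) {
      a <- comp[es[e, 1L]]; b <- comp[es[e, 2L]]
      comp[comp == b] <- a
    }
    if (length(unique(comp)) != 1L) next
    w <- sum(dm[es])
    if (w < best_w) {
      best_w <- w
      best <- es
    }
  }
  list(edges = best, weight = best_w)
}

# FEve computed directly from a given tree's edges (Villeger's formula)
feve_from_tree <- function(edges, coords, p) {
  dm <- as.matrix(dist(coords))
  s <- nrow(coords)
  ew <- dm[edges] / (p[edges[, 1L]] + p[edges[, 2L]])
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1L)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# Balanced split-plot toy design: 2 CO2 levels x 2 rings each x 2 N levels
# x richness {1, 4} x `reps` replicates, fully crossed within ring.
balanced_design <- function(reps = 2L) {
  g <- expand.grid(ring_in_co2 = 1:2, n = c("ambient", "enriched"),
                   sown_richness = c(1L, 4L), rep = seq_len(reps),
                   co2 = c("ambient", "elevated"),
                   stringsAsFactors = FALSE)
  g$ring <- g$ring_in_co2 + ifelse(g$co2 == "elevated", 2L, 0L)
  g$plot_id <- sprintf("p%03d", seq_len(nrow(g)))
  g[, c("plot_id", "ring", "co2", "n", "sown_richness")]
}

# Sequential (Type I) sums of squares for the same column blocks the
# package uses, via successive QR fits.
sequential_ss <- function(X_blocks, y) {
  X <- cbind(rep(1, length(y)))
  rss_prev <- sum(qr.resid(qr(X), y)^2)
  ss <- numeric(length(X_blocks))
  for (i in seq_along(X_blocks)) {
    X <- cbind(X, X_blocks[[i]])
    rss <- sum(qr.resid(qr(X), y)^2)
    ss[i] <- rss_prev - rss
    rss_prev <- rss
  }
  names(ss) <- names(X_blocks)
  ss
}

# The ANOVA design columns exactly as type3_anova builds them, for use in
# independent reduced-model refits.
anova_design_blocks <- function(d, center = TRUE) {
  co2f <- factor(d$co2); nf <- factor(d$n)
  x <- log(d$sown_richness)
  if (center) x <- x - mean(x)
  C <- contr.sum(2L)[co2f, 1L]
  N <- contr.sum(2L)[nf, 1L]
  ring_cols <- NULL
  for (lev in levels(co2f)) {
    rl <- factor(d$ring[co2f == lev])
    cc <- contr.sum(nlevels(rl))
    block <- matrix(0, nrow(d), ncol(cc))
    block[co2f == lev, ] <- cc[rl, , drop = FALSE]
    ring_cols <- cbind(ring_cols, block)
  }
  list("CO2" = cbind(C), "Ring(CO2)" = ring_cols, "N" = cbind(N),
       "PSR" = cbind(x), "CO2:N" = cbind(C * N), "CO2:PSR" = cbind(C * x),
       "N:PSR" = cbind(N * x), "CO2:N:PSR" = cbind(C * N * x))
}

# Draw a sample of size n whose sample moments match `sigma` exactly
# (empirically whitened then recoloured), so chi-square against the
# saturated model is exactly zero for the generating structure.
exact_moment_sample <- function(n, sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(sigma)
  z <- matrix(rnorm(n * p), n, p)
  z <- scale(z, center = TRUE, scale = FALSE)
  z <- z %*% solve(chol(cov(z) * (n - 1) / n))
  x <- z %*% chol(sigma)
  colnames(x) <- colnames(sigma)
  as.data.frame(x)
}

# Hand-checked 4-plot worked fixture for the multifunctionality module.
worked_functions <- function() {
  data.frame(plot_id = c("p1", "p2", "p3", "p4"),
             root_biomass = c(100, 200, 300, 500),
             respiration = c(2, 10, 6, 4),
             microbial_biomass = c(100, 300, 500, 200),
             wsa = c(0.2, 0.4, 0.8, 0.5),
             stringsAsFactors = FALSE)
}
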