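toy_traits <- data.frame(species = c("a", "b", "c"),
                         x = c(0, 1, 2), y = c(0, 0, 4))

test_that("Gower distances match the hand-computed toy and field packages", {
  d <- gower_distances(toy_traits)
  # ranges: x -> 2, y -> 4; mean of per-trait normalized differences
  expect_equal(d["a", "b"], (0.5 + 0) / 2)
  expect_equal(d["b", "c"], (0.5 + 1) / 2)
  expect_equal(d["a", "c"], (1 + 1) / 2)
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))

  # identical rows -> 0; opposite extremes on every trait -> 1
  tr <- data.frame(species = c("p", "q", "r"),
                   t1 = c(1, 1, 5), t2 = c(2, 2, 9))
  dd <- gower_distances(tr)
  expect_equal(dd["p", "q"], 0)
  expect_equal(dd["p", "r"], 1)

  set.seed(10)
  m <- matrix(runif(40), 8, 5, dimnames = list(letters[1:8], paste0("t", 1:5)))
  expect_equal(gower_distances(m),
               as.matrix(vegan::vegdist(m, method = "gower")),
               ignore_attr = TRUE, tolerance = 1e-12)

  # affine rescaling of one trait column leaves distances unchanged
  m2 <- m
  m2[, 3] <- 7 + 3.5 * m2[, 3]
  expect_equal(gower_distances(m2), gower_distances(m), tolerance = 1e-12)

  m3 <- m
  m3[, 2] <- 1
  expect_error(gower_distances(m3), "t2")
})

test_that("PCoA embedding reproduces distances and corrects non-Euclidean input", {
  set.seed(11)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(letters[1:6], NULL))
  d <- as.matrix(dist(pts))
  sp <- pcoa_embed(d, correction = "none")
  expect_lt(max(abs(as.matrix(dist(sp$coords)) - d)), 1e-8)

  # two species: one axis, separation equals the distance
  d2 <- matrix(c(0, 0.7, 0.7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  sp2 <- pcoa_embed(d2)
  expect_equal(ncol(sp2$coords), 1L)
  expect_equal(abs(diff(sp2$coords[, 1])), 0.7, ignore_attr = TRUE)

  # non-Euclidean 4-point configuration: raw double-centred matrix has a
  # negative eigenvalue; the correction activates and removes it
  D <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 1.9
  J <- diag(4) - 1 / 4
  raw_eig <- eigen(-0.5 * J %*% D^2 %*% J, symmetric = TRUE)$values
  expect_lt(min(raw_eig), -1e-6)
  spc <- pcoa_embed(D, correction = "cailliez")
  expect_equal(spc$correction, "cailliez")
  expect_true(all(spc$eig > 0))
})

test_that("functional dispersion follows the weighted-centroid formula", {
  coords1 <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c")))
  expect_equal(functional_dispersion(coords1, c(a = 1, b = 0, c = 0)), 0)
  expect_equal(functional_dispersion(coords1[1:2, , drop = FALSE],
                                     c(a = 1, b = 1)), 0.5)
  # direct computation: centroid 0.9, weighted distances 0.45+0.03+0.42
  expect_equal(functional_dispersion(coords1, c(a = 0.5, b = 0.3, c = 0.2)),
               0.9)

  # rigid rotation invariance
  set.seed(12)
  z <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  a <- runif(5)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(functional_dispersion(z %*% R, a),
               functional_dispersion(z, a))
  expect_error(functional_dispersion(z, rep(0, 5)), "all-zero")
})

test_that("hull volumes are exact on known solids and match brute force", {
  expect_equal(convhull_volume(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(convhull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1))), 1)
  expect_equal(convhull_volume(rbind(c(0, 0, 0), diag(3))), 1 / 6)
  expect_equal(convhull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))), 1)
  # interior points change nothing
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(1, 1), c(0.5, 0.3))
  expect_equal(convhull_volume(sq), 4)
  expect_equal(convhull_vertices(sq), 1:4)
  # degenerate (collinear in 2-D) set has zero area
  expect_equal(convhull_volume(cbind(0:3, 0:3)), 0)
})

test_that("hull volume agrees with an external qhull implementation", {
  py <- Sys.which("python")
  set.seed(13)
  x <- matrix(rnorm(3 * 12), 12, 3)
  f <- tempfile(fileext = ".csv")
  write.table(x, f, row.names = FALSE, col.names = FALSE, sep = ",")
  out <- tryCatch(
    system2(py, c("-c", shQuote(paste0(
      "import numpy as np; from scipy.spatial import ConvexHull; ",
      "x = np.loadtxt('", f, "', delimiter=','); ",
      "print(repr(ConvexHull(x).volume))"))), stdout = TRUE),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(out) || length(out) == 0) succeed("qhull oracle unavailable")
  else expect_equal(convhull_volume(x), as.numeric(out[length(out)]),
                    tolerance = 1e-10)
})

test_that("functional richness is the normalized hull fraction", {
  # right triangle with legs 1,1 inside a pool of hull area 2
  coords <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1),
                  d = c(2, 0), e = c(0, 2))
  expect_equal(convhull_volume(coords), 2)
  expect_equal(functional_richness(coords, c("a", "b", "c"), axes = 2), 0.25)
  expect_equal(functional_richness(coords, rownames(coords), axes = 2), 1)
  # undefined when species count does not exceed axis count
  expect_true(is.na(functional_richness(coords, c("a", "b"), axes = 2)))

  # 4-species subset of a toy pool against direct hull-volume computation
  set.seed(14)
  pool <- matrix(rnorm(16), 8, 2, dimnames = list(letters[1:8], NULL))
  sub <- c("a", "c", "e", "g")
  expect_equal(functional_richness(pool, sub, axes = 2),
               convhull_volume(pool[sub, ]) / convhull_volume(pool))
})

test_that("FRic is monotone under adding species", {
  set.seed(15)
  pool <- matrix(rnorm(20), 10, 2, dimnames = list(letters[1:10], NULL))
  for (i in 1:20) {
    k <- sample(3:8, 1)
    sub <- sample(rownames(pool), k)
    extra <- sample(setdiff(rownames(pool), sub), 1)
    f1 <- functional_richness(pool, sub, axes = 2)
    f2 <- functional_richness(pool, c(sub, extra), axes = 2)
    expect_gte(f2, f1 - 1e-12)
  }
})

test_that("functional evenness matches a brute-force spanning-tree oracle", {
  # equidistant collinear points, equal abundances: perfectly even tree
  line <- matrix(c(0, 1, 2, 3), ncol = 1, dimnames = list(letters[1:4]))
  expect_equal(functional_evenness(line, rep(1, 4)), 1)
  # one branch carrying nearly all weighted evenness drives FEve toward 0
  skew <- matrix(c(0, 1e-4, 2e-4, 1), ncol = 1, dimnames = list(letters[1:4]))
  expect_lt(functional_evenness(skew, rep(0.25, 4)), 0.05)
  expect_true(is.na(functional_evenness(line[1:2, , drop = FALSE], c(1, 1))))

  coords <- rbind(a = c(0, 0), b = c(0.2, 0), c = c(1, 0.1), d = c(1.1, 1))
  p <- c(a = 0.1, b = 0.4, c = 0.3, d = 0.2)
  oracle <- brute_force_mst(coords)
  mst <- soilmultifun:::.mst_edges(coords)
  expect_equal(sum(as.matrix(dist(coords))[mst]), oracle$weight)
  expect_equal(functional_evenness(coords, p),
               feve_from_tree(oracle$edges, coords, p))
})

test_that("functional divergence matches direct formula evaluation", {
  # equal abundances at hull vertices equidistant from the centre
  square <- rbind(a = c(0, 0), b = c(1, 0), c = c(1, 1), d = c(0, 1))
  expect_equal(functional_divergence(square, rep(0.25, 4), axes = 2), 1)
  # all abundance near the species farthest from the centre of gravity
  stretched <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), d = c(2, 1))
  far <- c(a = 1e-6, b = 1e-6, c = 1e-6, d = 1)
  expect_gt(functional_divergence(stretched, far, axes = 2), 0.99)
  # asymmetric toy, hand-computed frozen value
  p <- c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  expect_equal(functional_divergence(stretched, p, axes = 2), 0.7702057,
               tolerance = 1e-6)
  expect_true(is.na(functional_divergence(stretched[1:2, ], c(a = 1, b = 1),
                                          axes = 1)))
})

test_that("FEve and FDiv stay in [0, 1] over random communities", {
  set.seed(16)
  coords <- matrix(rnorm(24), 12, 2, dimnames = list(letters[1:12], NULL))
  for (i in 1:2000) {
    k <- sample(3:12, 1)
    sub <- sample(rownames(coords), k)
    a <- setNames(rgamma(k, shape = 0.5) + 1e-9, sub)
    fe <- functional_evenness(coords[sub, , drop = FALSE], a)
    fdv <- functional_divergence(coords[sub, , drop = FALSE], a)
    expect_true(fe >= -1e-10 && fe <= 1 + 1e-10)
    expect_true(fdv >= -1e-10 && fdv <= 1 + 1e-10)
  }
})

test_that("FDis on 1-trait Gower equals the direct standardized-trait oracle", {
  set.seed(17)
  tr <- data.frame(species = letters[1:6], H = runif(6, 10, 120))
  a <- setNames(runif(6), letters[1:6])
  space <- pcoa_embed(gower_distances(tr))
  z <- tr$H / diff(range(tr$H))
  centroid <- sum(a / sum(a) * z)
  expect_equal(functional_dispersion(space, a),
               sum(a / sum(a) * abs(z - centroid)), tolerance = 1e-8)
})

test_that("community_fd applies the zero and undefined conventions per plot", {
  pool <- build_species_pool()
  p <- sim_params(seed = 18)
  traits <- generate_traits(p, pool)
  cv <- data.frame(plot_id = c("dead", "mono", "pair", "full"),
                   matrix(0, 4, 16, dimnames = list(NULL, pool$species)),
                   check.names = FALSE)
  cv[cv$plot_id == "mono", pool$species[1]] <- 1
  cv[cv$plot_id == "pair", pool$species[2:3]] <- 0.5
  cv[cv$plot_id == "full", pool$species] <- 1 / 16
  fd <- community_fd(cv, traits)
  expect_equal(unlist(fd[fd$plot_id == "dead", -1]),
               c(FRic = 0, FEve = 0, FDiv = 0, FDis = 0))
  expect_equal(fd$FDis[fd$plot_id == "mono"], 0)
  expect_true(all(is.na(unlist(fd[fd$plot_id == "mono",
                                  c("FRic", "FEve", "FDiv")]))))
  expect_true(all(is.na(unlist(fd[fd$plot_id == "pair",
                                  c("FRic", "FEve", "FDiv")]))))
  expect_gt(fd$FDis[fd$plot_id == "pair"], 0)
  expect_equal(fd$FRic[fd$plot_id == "full"], 1)

  cv_bad <- cv
  names(cv_bad)[2] <- "Unknown species"
  expect_error(community_fd(cv_bad, traits), "absent from traits")
})
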