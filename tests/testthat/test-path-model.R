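# implied covariance of the study's 4-variable recursive structure:
# x -> m1, x -> m2, m1 -> y, m2 -> y (uncorrelated errors)
implied_sigma <- function(a, b, c, d, var_x, psi1, psi2, psiy,
                          vars = c("log_richness", "FDis",
                                   "evenness_functions", "multifunctionality")) {
  B <- matrix(0, 4, 4, dimnames = list(vars, vars))
  B["FDis", "log_richness"] <- a
  B["evenness_functions", "log_richness"] <- b
  B["multifunctionality", "FDis"] <- c
  B["multifunctionality", "evenness_functions"] <- d
  psi <- diag(c(var_x, psi1, psi2, psiy))
  A <- solve(diag(4) - B)
  s <- A %*% psi %*% t(A)
  dimnames(s) <- list(vars, vars)
  s
}

test_that("exact-moment data recover the generating model with chi-square 0", {
  sigma <- implied_sigma(0.8, 0.3, 0.5, 0.4, 1.2, 0.4, 0.6, 0.25)
  d <- exact_moment_sample(200, sigma, seed = 50)
  fit <- fit_path_model(d)
  expect_equal(fit$df, 2L)
  expect_equal(fit$chisq, 0, tolerance = 1e-8)
  est <- setNames(fit$coefficients$estimate,
                  paste(fit$coefficients$from, fit$coefficients$to))
  expect_equal(est[["log_richness FDis"]], 0.8, tolerance = 1e-8)
  expect_equal(est[["log_richness evenness_functions"]], 0.3,
               tolerance = 1e-8)
  expect_equal(est[["FDis multifunctionality"]], 0.5, tolerance = 1e-8)
  expect_equal(est[["evenness_functions multifunctionality"]], 0.4,
               tolerance = 1e-8)
  expect_equal(fit$aic, 2 * fit$n_parameters, tolerance = 1e-6)
})

test_that("model df equals moments minus free parameters", {
  # 10 moments of 4 variables - (4 paths + 3 residual + 1 exogenous) = 2
  sigma <- implied_sigma(0.5, 0.5, 0.5, 0.5, 1, 1, 1, 1)
  d <- exact_moment_sample(100, sigma, seed = 51)
  fit <- fit_path_model(d)
  expect_equal(fit$n_parameters, 8L)
  expect_equal(fit$df, 2L)
})

test_that("equation-wise OLS attains the covariance-likelihood optimum", {
  set.seed(52)
  x <- rnorm(150)
  d <- data.frame(log_richness = x,
                  FDis = 0.7 * x + rnorm(150, 0, 0.5),
                  evenness_functions = 0.2 * x + rnorm(150, 0, 0.8))
  d$multifunctionality <- 0.4 * d$FDis + 0.5 * d$evenness_functions +
    rnorm(150, 0, 0.3)
  fit <- fit_path_model(d)
  S <- fit$sample_cov
  vars <- fit$variables
  fml <- function(theta) {
    s <- implied_sigma(theta[1], theta[2], theta[3], theta[4],
                       exp(theta[5]), exp(theta[6]), exp(theta[7]),
                       exp(theta[8]), vars = vars)
    as.numeric(determinant(s)$modulus) + sum(diag(S %*% solve(s))) -
      as.numeric(determinant(S)$modulus) - 4
  }
  opt <- optim(c(0.5, 0.5, 0.5, 0.5, 0, -1, -1, -1), fml,
               method = "BFGS", control = list(reltol = 1e-14))
  # the numerical optimum cannot beat the closed-form ML solution
  expect_gte(opt$value, fit$F_ml - 1e-6)
  expect_equal(fit$F_ml, opt$value, tolerance = 1e-4)
})

test_that("chi-square and standardized coefficients are scale-free", {
  set.seed(53)
  x <- rnorm(120)
  d <- data.frame(log_richness = x,
                  FDis = 0.7 * x + rnorm(120, 0, 0.5),
                  evenness_functions = 0.2 * x + rnorm(120, 0, 0.8))
  d$multifunctionality <- 0.4 * d$FDis + 0.5 * d$evenness_functions +
    rnorm(120, 0, 0.3)
  f1 <- fit_path_model(d)
  d2 <- d
  d2$FDis <- d2$FDis * 37
  d2$multifunctionality <- d2$multifunctionality / 5
  f2 <- fit_path_model(d2)
  expect_equal(f2$chisq, f1$chisq, tolerance = 1e-8)
  expect_equal(f2$coefficients$std_estimate, f1$coefficients$std_estimate,
               tolerance = 1e-8)
})

test_that("indirect effects sum to the implied richness-multifunctionality link", {
  set.seed(54)
  x <- rnorm(200)
  d <- data.frame(log_richness = x,
                  FDis = 0.9 * x + rnorm(200, 0, 0.4),
                  evenness_functions = 0.3 * x + rnorm(200, 0, 0.9))
  d$multifunctionality <- 0.5 * d$FDis + 0.3 * d$evenness_functions +
    rnorm(200, 0, 0.3)
  fit <- fit_path_model(d)
  std <- setNames(fit$coefficients$std_estimate,
                  paste(fit$coefficients$from, fit$coefficients$to))
  indirect <- std[["log_richness FDis"]] * std[["FDis multifunctionality"]] +
    std[["log_richness evenness_functions"]] *
    std[["evenness_functions multifunctionality"]]
  implied_r <- fit$implied_cov["log_richness", "multifunctionality"] /
    sqrt(fit$implied_cov["log_richness", "log_richness"] *
         fit$implied_cov["multifunctionality", "multifunctionality"])
  expect_equal(indirect, implied_r, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("path coefficients are recovered across replicates at n = 364", {
  true_std <- local({
    s <- implied_sigma(0.8, 0.3, 0.5, 0.4, 1.2, 0.4, 0.6, 0.25)
    sds <- sqrt(diag(s))
    c(a = 0.8 * sds[1] / sds[2], b = 0.3 * sds[1] / sds[3],
      cc = 0.5 * sds[2] / sds[4], d = 0.4 * sds[3] / sds[4])
  })
  sigma <- implied_sigma(0.8, 0.3, 0.5, 0.4, 1.2, 0.4, 0.6, 0.25)
  ch <- chol(sigma)
  n_rep <- 500L
  est <- matrix(NA_real_, n_rep, 4)
  set.seed(55)
  for (r in seq_len(n_rep)) {
    z <- matrix(rnorm(364 * 4), 364, 4) %*% ch
    colnames(z) <- colnames(sigma)
    fit <- fit_path_model(as.data.frame(z))
    est[r, ] <- fit$coefficients$std_estimate
  }
  means <- colMeans(est)
  mc_se <- apply(est, 2, sd) / sqrt(n_rep)
  for (j in 1:4) {
    expect_lt(abs(means[j] - true_std[j]), 4 * mc_se[j] + 0.005)
  }
})

test_that("AIC comparison penalizes useless paths and rewards real ones", {
  sigma <- implied_sigma(0.8, 0.3, 0.5, 0.4, 1.2, 0.4, 0.6, 0.25)
  d <- exact_moment_sample(300, sigma, seed = 56)
  # a truly-zero path on exact-moment data costs exactly +2
  delta <- compare_paths(d, default_paths(),
                         "log_richness -> multifunctionality")
  expect_equal(as.numeric(delta), 2, tolerance = 1e-6)

  # simulate with a real direct path: adding it helps, dropping it hurts
  set.seed(57)
  x <- rnorm(364)
  d2 <- data.frame(log_richness = x,
                   FDis = 0.8 * x + rnorm(364, 0, 0.6),
                   evenness_functions = 0.3 * x + rnorm(364, 0, 0.8))
  d2$multifunctionality <- 0.5 * d2$FDis + 0.4 * d2$evenness_functions +
    0.4 * x + rnorm(364, 0, 0.3)
  expect_lt(as.numeric(compare_paths(d2, default_paths(),
                                     "log_richness -> multifunctionality")), 0)
  # removing a generating path worsens the penalized fit
  pruned <- fit_path_model(d2, setdiff(default_paths(),
                                       "FDis -> multifunctionality"))
  expect_gt(pruned$aic, fit_path_model(d2, default_paths())$aic)
})

test_that("degenerate path-model inputs raise informative errors", {
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  expect_error(fit_path_model(d, c("a -> b", "b -> a")), "not recursive")
  d2 <- data.frame(a = rnorm(5), b = rnorm(5), c = rnorm(5), d = rnorm(5))
  names(d2) <- c("log_richness", "FDis", "evenness_functions",
                 "multifunctionality")
  expect_error(fit_path_model(d2[1:4, ]), "insufficient data|positive definite")
  d3 <- data.frame(x = rnorm(50))
  d3$y <- 2 * d3$x  # exactly collinear: singular covariance
  expect_error(fit_path_model(d3, "x -> y"), "positive definite")
})
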