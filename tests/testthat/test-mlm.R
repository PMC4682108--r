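test_that("restricted likelihood collapses correctly at sigma2_g = 0", {
  fx <- sim_mlm_fixture(25, 10, 5, 0.4, seed = 31)
  y <- fx$data$y; X <- fx$data$X
  s2e <- 0.8
  ll <- restricted_loglik(c(0, s2e), fx$data)
  n <- length(y); cc <- ncol(X)
  rss <- sum(lm.fit(X, y)$residuals^2)
  direct <- -0.5 * ((n - cc) * log(s2e) + rss / s2e +
                      determinant(crossprod(X))$modulus[1])
  expect_equal(ll, direct, tolerance = 1e-10)
})

test_that("restricted likelihood is invariant to phenotype translation", {
  fx <- sim_mlm_fixture(30, 15, 5, 0.5, seed = 32)
  th <- c(0.4, 0.7)
  l1 <- restricted_loglik(th, fx$data)
  d2 <- mlm_data(fx$data$y + 100, grm = fx$grm)
  expect_equal(restricted_loglik(th, d2), l1, tolerance = 1e-8)
})

test_that("restricted likelihood agrees with a direct determinant oracle", {
  fx <- sim_mlm_fixture(6, 4, 2, 0.5, seed = 33)
  for (th in list(c(0.2, 0.9), c(1.4, 0.3), c(0.01, 1.2))) {
    expect_equal(restricted_loglik(th, fx$data),
                 oracle_loglik(fx$grm$G, fx$data$y, fx$data$X,
                               th[1], th[2]),
                 tolerance = 1e-10)
  }
})

test_that("AI-REML estimates vanishing heritability on a pure-noise trait", {
  set.seed(77)
  g <- simulate_genotypes(500, 200, seed = 41)
  y <- rnorm(500)
  dat <- mlm_data(y, z = standardize(g))
  fit <- airml_fit(dat)
  expect_lte(fit$h2, 0.05)
})

test_that("a genetic-variance optimum at zero is clamped and flagged", {
  # phenotype built from the GRM's smallest eigen-directions: the
  # restricted likelihood is decreasing in sigma2_g, so the optimum sits
  # at the lower constraint
  fx <- sim_mlm_fixture(60, 80, 20, 0.5, seed = 44)
  eig <- eigendecompose_grm(fx$grm)
  n <- fx$data$n
  y <- drop(eig$vectors[, (n - 9):n] %*% rep(1, 10))
  dat <- mlm_data(y, grm = fx$grm)
  fit <- airml_fit(dat, list(backend = "dense"))
  expect_true(fit$boundary)
  expect_lt(fit$h2, 1e-3)
  fite <- reml_fit_eigen(dat)
  expect_true(fite$boundary)
  expect_lt(fite$h2, 1e-3)
})

test_that("AI-REML matches a 2-D grid search of the restricted likelihood", {
  fx <- sim_mlm_fixture(12, 4, 3, 0.5, seed = 35)
  fit <- airml_fit(fx$data, list(backend = "dense"))
  grid <- oracle_grid_fit(fx$grm$G, fx$data$y, fx$data$X)
  expect_lt(abs(fit$sigma2_g - grid$theta[1]), grid$res)
  expect_lt(abs(fit$sigma2_e - grid$theta[2]), grid$res)
})

test_that("dense and eigen-rotated AI-REML backends produce identical fits", {
  for (seed in c(51, 52, 53)) {
    fx <- sim_mlm_fixture(80, 40, 10, 0.5, seed = seed)
    f1 <- airml_fit(fx$data, list(backend = "dense", keep_trace = TRUE))
    f2 <- airml_fit(fx$data, list(backend = "eigen", keep_trace = TRUE))
    expect_equal(f1$sigma2_g, f2$sigma2_g, tolerance = 1e-8)
    expect_equal(f1$sigma2_e, f2$sigma2_e, tolerance = 1e-8)
    expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
    expect_identical(f1$n_iter, f2$n_iter)
  }
})

test_that("accepted AI-REML iterations never decrease the likelihood", {
  for (seed in c(61, 62)) {
    fx <- sim_mlm_fixture(100, 50, 10, 0.4, seed = seed)
    fit <- airml_fit(fx$data, list(keep_trace = TRUE))
    expect_true(all(diff(fit$trace) >= -1e-9))
  }
})

test_that("AI-REML and the eigen-rotation path agree across random instances", {
  set.seed(99)
  for (k in 1:20) {
    n <- sample(30:300, 1)
    m <- sample(15:80, 1)
    h2 <- runif(1, 0.15, 0.8)
    fx <- sim_mlm_fixture(n, m, max(3, m %/% 4), h2, seed = 200 + k)
    f1 <- airml_fit(fx$data, list(backend = "dense"))
    f2 <- reml_fit_eigen(fx$data)
    if (f1$boundary || f2$boundary) next  # ratio comparison undefined at 0
    expect_equal(f2$sigma2_g, f1$sigma2_g,
                 tolerance = 1e-4 * max(f1$sigma2_g, 1e-8))
    expect_equal(f2$sigma2_e, f1$sigma2_e, tolerance = 1e-4 * f1$sigma2_e)
    # both maximize the same function
    expect_gte(f2$loglik, f1$loglik - 1e-6)
  }
})

test_that("eigen-path reports a boundary fit when delta hits the bracket", {
  set.seed(7)
  g <- simulate_genotypes(150, 60, seed = 71)
  y <- rnorm(150)
  dat <- mlm_data(y, z = standardize(g))
  fit <- reml_fit_eigen(dat)
  if (fit$h2 < 1e-4) expect_true(fit$boundary)
  expect_lt(fit$h2, 0.15)
})

test_that("REML fits are scale-equivariant", {
  fx <- sim_mlm_fixture(120, 60, 15, 0.5, seed = 81)
  f1 <- airml_fit(fx$data)
  d2 <- mlm_data(3 * fx$data$y, grm = fx$grm, z = fx$z)
  f2 <- airml_fit(d2)
  expect_equal(f2$sigma2_g, 9 * f1$sigma2_g, tolerance = 1e-5)
  expect_equal(f2$sigma2_e, 9 * f1$sigma2_e, tolerance = 1e-5)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-8)
})

test_that("GLS fixed effects match closed forms and the dense oracle", {
  fx <- sim_mlm_fixture(40, 20, 5, 0.5, seed = 91)
  y <- fx$data$y

  # sigma2_g = 0 reduces to OLS; intercept-only V = I gives the mean
  vc0 <- list(sigma2_g = 0, sigma2_e = 1)
  gls0 <- gls_fixed_effects(fx$data, vc0)
  expect_equal(gls0$beta, unname(coef(lm(y ~ 1))), tolerance = 1e-10)
  expect_equal(gls0$beta, mean(y), tolerance = 1e-12)

  fx6 <- sim_mlm_fixture(6, 3, 2, 0.5, seed = 92)
  X <- cbind(1, rnorm(6))
  d6 <- mlm_data(fx6$data$y, X = X, grm = fx6$grm)
  vc <- list(sigma2_g = 0.5, sigma2_e = 0.7)
  gls <- gls_fixed_effects(d6, vc)
  orc <- oracle_gls(fx6$grm$G, fx6$data$y, X, 0.5, 0.7)
  expect_equal(gls$beta, orc$beta, tolerance = 1e-10)
  expect_equal(gls$se, sqrt(diag(orc$cov)), tolerance = 1e-10)

  # eigen fast path agrees with the dense path
  glse <- gls_fixed_effects(d6, vc, grm_eigen = eigendecompose_grm(fx6$grm))
  expect_equal(glse$beta, gls$beta, tolerance = 1e-10)
})

test_that("heritability is recovered across the simulated h2 settings", {
  # 30 replicates at each generating h2; mean estimate within
  # 2 Monte-Carlo standard errors of the truth
  for (h2 in c(0.2, 0.5, 0.7)) {
    est <- vapply(1:30, function(i) {
      g <- simulate_genotypes(2000, 1000, seed = 3000 + i)
      tr <- simulate_trait(g, 100, h2, seed = 4000 + round(1e4 * h2) + i)
      z <- standardize(g)
      reml_fit_eigen(mlm_data(tr$y, z = z),
                     grm_eigen_from_genotypes(z))$h2
    }, 0)
    mc_se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - h2), 2 * mc_se + 1e-12)
  }
})

test_that("the .hsq variance table is written in GCTA-like layout", {
  fx <- sim_mlm_fixture(60, 30, 8, 0.5, seed = 95)
  fit <- airml_fit(fx$data)
  tmp <- withr::local_tempfile()
  write_hsq(fit, 60, tmp)
  lines <- readLines(tmp)
  expect_match(lines[2], "^V\\(G\\)\t")
  expect_match(lines[5], "^V\\(G\\)/Vp\t")
  got <- as.numeric(strsplit(lines[5], "\t")[[1]][2])
  expect_equal(got, fit$h2, tolerance = 1e-5)
})
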