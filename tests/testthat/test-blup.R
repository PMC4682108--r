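test_that("BLUP genetic values: degenerate cases, shrinkage, dense oracle", {
  fx <- sim_mlm_fixture(40, 20, 8, 0.5, seed = 301)
  fit <- airml_fit(fx$data)

  vc0 <- list(sigma2_g = 0, sigma2_e = 1, beta = fit$beta)
  expect_equal(blup_genetic_values(fx$data, vc0, fit$beta), rep(0, 40))

  gh <- blup_genetic_values(fx$data, fit)
  expect_lte(var(gh), var(fx$data$y))

  # direct dense-solve oracle on a small fixture
  fx6 <- sim_mlm_fixture(6, 3, 2, 0.5, seed = 302)
  vc <- list(sigma2_g = 0.6, sigma2_e = 0.5)
  beta <- oracle_gls(fx6$grm$G, fx6$data$y, fx6$data$X, 0.6, 0.5)$beta
  V <- 0.6 * fx6$grm$G + 0.5 * diag(6)
  r <- fx6$data$y - drop(fx6$data$X %*% beta)
  expect_equal(blup_genetic_values(fx6$data, vc, beta),
               0.6 * drop(fx6$grm$G %*% solve(V) %*% r),
               tolerance = 1e-10)
})

test_that("g_hat = Z a_hat holds to machine precision, incl. eigen path", {
  for (case in list(c(30, 12), c(150, 60), c(500, 120))) {
    fx <- sim_mlm_fixture(case[1], case[2], max(4, case[2] %/% 4), 0.5,
                          seed = 310 + case[1])
    fit <- airml_fit(fx$data)
    gh <- blup_genetic_values(fx$data, fit)
    eff <- blup_snp_effects(fx$z, fx$data, fit)
    expect_lt(max(abs(gh - drop(fx$z$Z %*% eff$effect))), 1e-10)

    eig <- grm_eigen_from_genotypes(fx$z)
    gh2 <- blup_genetic_values(fx$data, fit, grm_eigen = eig)
    eff2 <- blup_snp_effects(fx$z, fx$data, fit, grm_eigen = eig)
    expect_lt(max(abs(gh - gh2)), 1e-8)
    expect_lt(max(abs(eff$effect - eff2$effect)), 1e-8)
  }
})

test_that("SNP-effect BLUP: zero at sigma2_g = 0 and single-SNP arithmetic", {
  fx <- sim_mlm_fixture(20, 8, 4, 0.5, seed = 320)
  fit <- airml_fit(fx$data)
  vc0 <- list(sigma2_g = 0, sigma2_e = 1)
  eff0 <- blup_snp_effects(fx$z, fx$data, vc0, fit$beta)
  expect_equal(eff0$effect, rep(0, 8))

  # M = 1, N = 4, hand-built phenotype: a = s2g z' V^-1 (y - mean GLS)
  g1 <- genotype_matrix(cbind(c(0L, 1L, 2L, 1L)))
  z1 <- standardize(g1)
  y <- c(-0.5, 0.1, 0.9, 0.2)
  d1 <- mlm_data(y, z = z1)
  s2g <- 0.4; s2e <- 0.3
  zv <- as.vector(z1$Z)
  V <- s2g * outer(zv, zv) + s2e * diag(4)
  beta <- sum(solve(V, y)) / sum(solve(V, rep(1, 4)))
  a_hand <- s2g * sum(zv * solve(V, y - beta))
  eff1 <- blup_snp_effects(z1, d1, list(sigma2_g = s2g, sigma2_e = s2e),
                           beta)
  expect_equal(eff1$effect, a_hand, tolerance = 1e-12)
  expect_equal(eff1$mean, 1)
  expect_equal(eff1$sd, sqrt(0.5), tolerance = 1e-12)

  dbad <- mlm_data(fx$data$y, grm = fx$grm)
  dbad$grm$m_snps <- 99L
  expect_error(blup_snp_effects(fx$z, dbad, fit), "snp_count_mismatch")
})

test_that("polygenic scores: direct arithmetic, missing and identity cases", {
  eff <- structure(data.frame(snp_id = "rs1", a1 = "A", mean = 1,
                              sd = sqrt(0.5), effect = 0.5,
                              stringsAsFactors = FALSE),
                   class = c("snp_effects", "data.frame"))
  gnew <- genotype_matrix(cbind(c(2L, NA)),
                          snps = data.frame(chr = 1, id = "rs1", cm = 0,
                                            bp = 1, a1 = "A", a2 = "G"))
  sc <- polygenic_score(gnew, eff)
  expect_equal(sc$score[1], 0.5 * (2 - 1) / sqrt(0.5), tolerance = 1e-10)
  expect_equal(sc$score[1], 0.70711, tolerance = 1e-5)
  expect_equal(sc$score[2], 0)  # all genotypes missing
  expect_equal(sc$n_snps_used, c(1L, 0L))

  # scoring the training cohort reproduces the BLUP genetic values
  fx <- sim_mlm_fixture(120, 40, 10, 0.5, seed = 330)
  fit <- airml_fit(fx$data)
  effs <- blup_snp_effects(fx$z, fx$data, fit)
  sc2 <- polygenic_score(fx$g, effs)
  gh <- blup_genetic_values(fx$data, fit)
  expect_lt(max(abs(sc2$score - gh)), 1e-8)

  # a validation individual identical to a training one gets its score
  gdup <- genotype_matrix(fx$g$dosages[c(5, 5), ], snps = fx$g$snps)
  expect_equal(polygenic_score(gdup, effs)$score,
               rep(sum(fx$z$Z[5, ] * effs$effect), 2), tolerance = 1e-10)
})

test_that("allele-swapped validation coding leaves scores unchanged", {
  fx <- sim_mlm_fixture(50, 20, 5, 0.5, seed = 340)
  fit <- airml_fit(fx$data)
  eff <- blup_snp_effects(fx$z, fx$data, fit)
  gv <- fx$g
  flip <- c(3, 7, 11)
  gv$dosages[, flip] <- 2L - gv$dosages[, flip]
  tmp <- gv$snps$a1[flip]
  gv$snps$a1[flip] <- gv$snps$a2[flip]
  gv$snps$a2[flip] <- tmp
  expect_equal(polygenic_score(gv, eff)$score,
               polygenic_score(fx$g, eff)$score, tolerance = 1e-12)

  gv$snps$a1[3] <- "X"  # neither match nor swap
  gv$snps$a2[3] <- "Y"
  expect_error(polygenic_score(gv, eff), "irreconcilable_alleles")
  expect_error(polygenic_score(fx$g[, 1:10], eff), "snp_absent")
})

test_that("prediction accuracy: correlation oracle and max ratio", {
  set.seed(1)
  a <- rnorm(50); b <- 0.6 * a + rnorm(50)
  acc <- prediction_accuracy(a, b, h2 = 0.5)
  expect_equal(acc$r, oracle_cor(a, b), tolerance = 1e-12)
  expect_equal(prediction_accuracy(a, a, 1)$r, 1, tolerance = 1e-12)
  expect_equal(prediction_accuracy(a, b, 0.7)$r_over_max,
               acc$r / sqrt(0.7), tolerance = 1e-12)
  acc2 <- prediction_accuracy(rep(c(0.72, -0.72), 25),
                              rep(c(1, -1), 25), h2 = 0.7)
  expect_equal(acc2$r_over_max, 1 / sqrt(0.7), tolerance = 1e-12)
  expect_error(prediction_accuracy(rep(1, 10), rnorm(10), 0.5),
               "zero_variance")
})

test_that("SNP-effect tables round-trip through TSV", {
  fx <- sim_mlm_fixture(30, 10, 4, 0.5, seed = 350)
  fit <- airml_fit(fx$data)
  eff <- blup_snp_effects(fx$z, fx$data, fit)
  tmp <- withr::local_tempfile()
  write_snp_effects(eff, tmp)
  back <- read_snp_effects(tmp)
  expect_equal(back$effect, eff$effect, tolerance = 1e-12)
  expect_identical(back$snp_id, eff$snp_id)
  expect_identical(back$a1, eff$a1)
})
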