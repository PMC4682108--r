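# Independent oracles and fixture builders used across the suite.
# These deliberately use naive linear algebra (explicit solve/det,
# double loops) so they share no code path with the implementation.

# random genotype fixture, optionally with missing entries
random_geno <- function(n, m, seed, miss_rate = 0) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2L, runif(m, 0.1, 0.5)[rep(seq_len(m),
                                                       each = n)]),
              n, m)
  if (miss_rate > 0)
    d[runif(n * m) < miss_rate] <- NA_integer_
  genotype_matrix(d,
                  snps = data.frame(chr = sample(1:22, m, TRUE),
                                    id = paste0("rs", seq_len(m)),
                                    cm = 0, bp = sort(sample.int(1e6, m)),
                                    a1 = sample(c("A", "C"), m, TRUE),
                                    a2 = sample(c("G", "T"), m, TRUE)))
}

# brute-force GRM: double loop over sample pairs of explicit dot products
oracle_grm <- function(Z) {
  n <- nrow(Z); m <- ncol(Z)
  G <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      G[i, j] <- sum(Z[i, ] * Z[j, ]) / m
  G
}

# restricted log-likelihood by direct dense construction: explicit V,
# determinants and naive solves (no Cholesky reuse)
oracle_loglik <- function(G, y, X, s2g, s2e) {
  V <- s2g * G + s2e * diag(length(y))
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(M) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus[1] + determinant(M)$modulus[1] +
            drop(t(y) %*% P %*% y))
}

# 2-D grid search of the restricted likelihood: coarse pass over
# [eps, 2 var(y)]^2 then a fine local grid at resolution fine_res.
# Assumes (as holds for these surfaces) a unimodal restricted likelihood.
oracle_grid_fit <- function(G, y, X, fine_res = 1e-3 * var(y)) {
  vy <- var(y)
  coarse <- seq(fine_res, 2 * vy, length.out = 61)
  best <- c(NA, NA); bestll <- -Inf
  for (a in coarse) for (b in coarse) {
    ll <- oracle_loglik(G, y, X, a, b)
    if (ll > bestll) { bestll <- ll; best <- c(a, b) }
  }
  step <- coarse[2] - coarse[1]
  fine_a <- seq(max(fine_res, best[1] - step), best[1] + step,
                by = fine_res)
  fine_b <- seq(max(fine_res, best[2] - step), best[2] + step,
                by = fine_res)
  for (a in fine_a) for (b in fine_b) {
    ll <- oracle_loglik(G, y, X, a, b)
    if (ll > bestll) { bestll <- ll; best <- c(a, b) }
  }
  list(theta = best, ll = bestll, res = fine_res)
}

# textbook two-pass Pearson correlation
oracle_cor <- function(a, b) {
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# standard normal-equation GLS solve with explicit inverses
oracle_gls <- function(G, y, X, s2g, s2e) {
  V <- s2g * G + s2e * diag(length(y))
  Vi <- solve(V)
  M <- solve(t(X) %*% Vi %*% X)
  list(beta = drop(M %*% t(X) %*% Vi %*% y), cov = M)
}

# simulate a small cohort + trait and wrap as mlm_data (intercept only);
# SNPs monomorphic in the sampled cohort are dropped so tiny fixtures
# stay valid
sim_mlm_fixture <- function(n, m, n_qtn, h2, seed) {
  g <- filter_snps(simulate_genotypes(n, m, seed = seed), min_maf = 1e-9)
  tr <- simulate_trait(g, min(n_qtn, ncol(g$dosages)), h2, seed = seed + 1)
  z <- standardize(g)
  grm <- compute_grm(z)
  list(g = g, trait = tr, z = z, grm = grm,
       data = mlm_data(tr$y, grm = grm, z = z))
}
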