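#' Run a genomic-prediction experiment grid
#'
#' Desk-scale driver for prediction-accuracy experiments: for each
#' training-set size and replicate it simulates a cohort, simulates an
#' additive trait, restricts genotypes to the chosen array scenario,
#' splits into training and validation, standardizes the validation-free
#' training genotypes, fits the mixed model by the eigen-rotation REML
#' path, computes BLUP SNP effects and scores the validation samples,
#' recording the correlation of the score with the observed phenotype
#' (\code{r_pheno}) and with the true genetic value (\code{r_gen}).
#'
#' All randomness derives from the single master seed: child seeds for
#' (genotypes, trait, array, split) of every (cell, replicate) run are
#' drawn up-front from \code{sample.int} under \code{set.seed(seed)}, so
#' every cell is independently reproducible.
#'
#' @param geno_spec list: \code{n_snps}, optional \code{maf_range},
#'   \code{ld_rho}.
#' @param trait_spec list: \code{n_qtn}, \code{h2}.
#' @param scenario array scenario, see
#'   \code{\link{build_array_scenario}}.
#' @param n_train_grid integer vector of training-set sizes.
#' @param n_replicates replicates per grid point.
#' @param seed master seed.
#' @param train_frac fraction of the cohort used for training; the total
#'   cohort size is \code{round(n_train / train_frac)} (default 0.9, a
#'   90/10 split).
#' @param qtn_on_array_frac QTN fraction on the array under
#'   \code{"partial_qtn"} (default 0.2).
#' @return Data frame of class \code{"prediction_experiment"} with one
#'   row per (n_train, replicate): accuracy measures, the ratio
#'   \code{r_over_max = r_pheno / sqrt(h2)}, fitted components and
#'   convergence flag.
#' @export
run_prediction_experiment <- function(geno_spec, trait_spec, scenario,
                                      n_train_grid, n_replicates, seed,
                                      train_frac = 0.9,
                                      qtn_on_array_frac = 0.2) {
  stopifnot(is.list(geno_spec), is.list(trait_spec),
            !is.null(geno_spec$n_snps), !is.null(trait_spec$n_qtn),
            !is.null(trait_spec$h2), n_replicates >= 1)
  maf_range <- if (is.null(geno_spec$maf_range)) c(0.05, 0.5)
               else geno_spec$maf_range
  ld_rho <- if (is.null(geno_spec$ld_rho)) 0 else geno_spec$ld_rho
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      n_train = n_train_grid)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  child <- matrix(sample.int(.Machine$integer.max - 1L, 4L * nrow(grid)),
                  ncol = 4L)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    nt <- grid$n_train[i]
    res <- tryCatch(
      .run_prediction_cell(nt, geno_spec$n_snps, maf_range, ld_rho,
                           trait_spec$n_qtn, trait_spec$h2, scenario,
                           train_frac, qtn_on_array_frac, child[i, ]),
      error = function(e) list(r_pheno = NA_real_, r_gen = NA_real_,
                               sigma2_g = NA_real_, sigma2_e = NA_real_,
                               h2_hat = NA_real_, converged = FALSE))
    data.frame(n_train = nt, h2 = trait_spec$h2, scenario = scenario,
               replicate = grid$replicate[i], r_pheno = res$r_pheno,
               r_gen = res$r_gen,
               r_over_max = res$r_pheno / sqrt(trait_spec$h2),
               sigma2_g = res$sigma2_g, sigma2_e = res$sigma2_e,
               h2_hat = res$h2_hat, converged = res$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prediction_experiment", "data.frame")
  out
}

.run_prediction_cell <- function(n_train, n_snps, maf_range, ld_rho,
                                 n_qtn, h2, scenario, train_frac,
                                 qtn_frac, seeds) {
  n_total <- round(n_train / train_frac)
  g <- simulate_genotypes(n_total, n_snps, maf_range, ld_rho,
                          seed = seeds[1])
  trait <- simulate_trait(g, n_qtn, h2, seed = seeds[2])
  idx <- build_array_scenario(g, trait, scenario, qtn_frac,
                              seed = seeds[3])
  sp <- train_validation_split(g, trait, seed = seeds[4],
                               n_train = n_train)
  g_tr <- sp$train$geno[, idx]
  st <- compute_snp_stats(g_tr)
  poly <- which(!st$monomorphic)  # drop SNPs monomorphic in training
  g_tr <- g_tr[, poly]
  z_tr <- standardize(g_tr)
  eig <- grm_eigen_from_genotypes(z_tr)
  dat <- mlm_data(sp$train$y, z = z_tr)
  fit <- reml_fit_eigen(dat, eig)
  eff <- blup_snp_effects(z_tr, dat, fit, grm_eigen = eig)
  sc <- polygenic_score(sp$validation$geno, eff)
  list(r_pheno = stats::cor(sc$score, sp$validation$y),
       r_gen = stats::cor(sc$score, sp$validation$g),
       sigma2_g = fit$sigma2_g, sigma2_e = fit$sigma2_e,
       h2_hat = fit$h2, converged = fit$converged)
}

#' Regression of inverse squared accuracy on inverse sample size
#'
#' Theory for genomic prediction with M independent markers predicts
#' \code{1 / r_gen^2 = 1 + (M / h2) (1 / N)}: the inverse of the squared
#' correlation between true and estimated genetic values is linear in the
#' inverse of the training sample size, with intercept one. This fits
#' that line by OLS to the replicate means.
#'
#' @param results a \code{prediction_experiment} (needs >= 3 distinct
#'   \code{n_train} values with valid \code{r_gen}).
#' @return List with \code{intercept}, \code{slope} and the per-point
#'   data frame \code{points} (\code{n_train}, \code{inv_n},
#'   \code{mean_inv_r2}).
#' @export
inverse_r2_regression <- function(results) {
  res <- results[!is.na(results$r_gen), , drop = FALSE]
  if (any(res$r_gen == 0)) stop("zero_accuracy: r_gen = 0", call. = FALSE)
  agg <- stats::aggregate(list(mean_inv_r2 = 1 / res$r_gen^2),
                          by = list(n_train = res$n_train), FUN = mean)
  if (nrow(agg) < 3)
    stop("need >= 3 distinct n_train values", call. = FALSE)
  agg$inv_n <- 1 / agg$n_train
  fit <- stats::lm(mean_inv_r2 ~ inv_n, data = agg)
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       points = agg[, c("n_train", "inv_n", "mean_inv_r2")])
}

#' Accuracy as a percentage of the theoretical maximum
#'
#' The correlation between a polygenic score and the phenotype cannot
#' exceed \code{sqrt(h2)}; this reports \code{100 r / sqrt(h2)} rounded
#' to the nearest integer percent.
#'
#' @param r observed correlation between predicted and true phenotypes.
#' @param h2 heritability, in (0, 1].
#' @return Integer percent.
#' @export
theoretical_max_ratio <- function(r, h2) {
  if (!(h2 > 0 && h2 <= 1)) stop("h2 must be in (0, 1]", call. = FALSE)
  round(100 * r / sqrt(h2))
}
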