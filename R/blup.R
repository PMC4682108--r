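#' BLUP of individual genetic values
#'
#' \code{g_hat = sigma2_g G V^-1 (y - X beta)} at the fitted variance
#' components — the best linear unbiased prediction of each individual's
#' total additive genetic effect.
#'
#' @param data an \code{mlm_data} object.
#' @param vc a \code{reml_fit}.
#' @param beta fixed-effect estimates (defaults to \code{vc$beta}).
#' @param grm_eigen optional \code{grm_eigen} of the data's GRM for the
#'   O(N r) fast path.
#' @return Numeric N-vector of predicted genetic values.
#' @export
blup_genetic_values <- function(data, vc, beta = vc$beta,
                                grm_eigen = NULL) {
  stopifnot(inherits(data, "mlm_data"))
  r <- data$y - drop(data$X %*% beta)
  s2g <- vc$sigma2_g; s2e <- vc$sigma2_e
  if (!is.null(grm_eigen)) {
    U <- grm_eigen$vectors
    trt <- drop(crossprod(U, r))
    v <- s2g * grm_eigen$values + s2e
    return(s2g * drop(U %*% (grm_eigen$values * trt / v)))
  }
  G <- .mlm_grm_matrix(data)
  V <- s2g * G + diag(s2e, data$n)
  s2g * drop(G %*% solve(V, r))
}

# V^-1 (y - X beta) via an eigen factor: split into span and null parts
.vinv_resid_eigen <- function(eig, resid, s2g, s2e) {
  U <- eig$vectors
  trt <- drop(crossprod(U, resid))
  v <- s2g * eig$values + s2e
  resid / s2e + drop(U %*% (trt / v - trt / s2e))
}

#' BLUP of SNP effects
#'
#' \code{a_hat = (sigma2_g / M) Z' V^-1 (y - X beta)} — the joint BLUP of
#' all marker effects on the standardized-genotype scale, satisfying the
#' identity \code{g_hat = Z a_hat} exactly when the fit's GRM is
#' \code{Z Z'/M}. The returned table carries the training-cohort allele
#' mean and s.d. needed to score new samples.
#'
#' @param z the \code{std_genotypes} used to build the GRM of the fit.
#' @param data an \code{mlm_data} object.
#' @param vc a \code{reml_fit}.
#' @param beta fixed effects (defaults to \code{vc$beta}).
#' @param grm_eigen optional \code{grm_eigen} for the fast path.
#' @return Data frame of class \code{"snp_effects"}: \code{snp_id},
#'   \code{a1}, \code{mean}, \code{sd}, \code{effect}.
#' @export
blup_snp_effects <- function(z, data, vc, beta = vc$beta,
                             grm_eigen = NULL) {
  stopifnot(inherits(z, "std_genotypes"), inherits(data, "mlm_data"))
  m <- ncol(z$Z)
  if (!is.null(data$grm) && !is.na(data$grm$m_snps) &&
      data$grm$m_snps != m)
    stop("snp_count_mismatch: fit GRM used ", data$grm$m_snps,
         " SNPs, genotypes have ", m, call. = FALSE)
  resid <- data$y - drop(data$X %*% beta)
  vr <- if (!is.null(grm_eigen)) {
    .vinv_resid_eigen(grm_eigen, resid, vc$sigma2_g, vc$sigma2_e)
  } else {
    V <- vc$sigma2_g * .mlm_grm_matrix(data) + diag(vc$sigma2_e, data$n)
    solve(V, resid)
  }
  a <- drop(crossprod(z$Z, vr)) * vc$sigma2_g / m
  st <- z$stats
  out <- data.frame(snp_id = st$id,
                    a1 = if ("a1" %in% names(st)) st$a1 else NA_character_,
                    mean = st$mean, sd = st$sd, effect = a,
                    stringsAsFactors = FALSE)
  class(out) <- c("snp_effects", "data.frame")
  out
}

#' Polygenic scores from a SNP-effect table
#'
#' Scores individual \code{i} as \code{sum_j a_j (s_ij - mean_j) / sd_j}
#' over the SNPs in the table, where \code{s_ij} counts the table's
#' reference allele and \code{mean_j}, \code{sd_j} are the training-cohort
#' statistics stored in the table (never recomputed from the cohort being
#' scored). Alleles are reconciled per SNP: if the cohort's A1 matches the
#' table's reference allele the dosage is used as-is; if its A2 matches,
#' \code{2 - s} is used; anything else is an error. Missing genotypes
#' contribute 0 (training-mean imputation). Scores are centred; no
#' intercept is added.
#'
#' @param g_new a \code{genotype_matrix} of the cohort to score.
#' @param effects a \code{snp_effects} table.
#' @return Data frame with \code{fid}, \code{iid}, \code{score},
#'   \code{n_snps_used}.
#' @export
polygenic_score <- function(g_new, effects) {
  stopifnot(inherits(g_new, "genotype_matrix"))
  if (any(effects$sd <= 0))
    stop("monomorphic_effect_snp: sd must be positive", call. = FALSE)
  idx <- match(effects$snp_id, g_new$snps$id)
  if (anyNA(idx))
    stop("snp_absent: not genotyped: ",
         paste(utils::head(effects$snp_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  a1 <- g_new$snps$a1[idx]
  a2 <- g_new$snps$a2[idx]
  asis <- effects$a1 == a1
  swap <- !asis & effects$a1 == a2
  if (any(!asis & !swap))
    stop("irreconcilable_alleles: ",
         paste(utils::head(effects$snp_id[!asis & !swap], 5),
               collapse = ", "), call. = FALSE)
  S <- g_new$dosages[, idx, drop = FALSE]
  if (any(swap)) S[, swap] <- 2L - S[, swap]
  W <- sweep(S, 2, effects$mean, `-`)
  W <- sweep(W, 2, effects$sd, `/`)
  W <- sweep(W, 2, effects$effect, `*`)
  used <- rowSums(!is.na(W))
  W[is.na(W)] <- 0
  data.frame(fid = g_new$samples$fid, iid = g_new$samples$iid,
             score = rowSums(W), n_snps_used = used,
             stringsAsFactors = FALSE)
}

#' Prediction accuracy of polygenic scores
#'
#' Pearson correlation between scores and observed phenotypes, and its
#' ratio to the theoretical maximum \code{sqrt(h2)} (a correlation with
#' the phenotype cannot exceed the square root of the heritability).
#'
#' @param scores numeric vector of scores, or the data frame returned by
#'   \code{\link{polygenic_score}}.
#' @param y_true observed phenotypes, aligned with \code{scores}.
#' @param h2 heritability of the trait, in (0, 1].
#' @return List with \code{r} and \code{r_over_max = r / sqrt(h2)}.
#' @export
prediction_accuracy <- function(scores, y_true, h2) {
  if (is.data.frame(scores)) scores <- scores$score
  stopifnot(length(scores) == length(y_true), length(scores) >= 3,
            h2 > 0, h2 <= 1)
  if (stats::sd(scores) == 0 || stats::sd(y_true) == 0)
    stop("zero_variance: correlation undefined", call. = FALSE)
  r <- stats::cor(scores, y_true)
  list(r = r, r_over_max = r / sqrt(h2))
}

#' Write / read a SNP-effect table as TSV
#'
#' Columns \code{snp_id}, \code{a1}, \code{mean}, \code{sd},
#' \code{effect}; header line required.
#'
#' @param effects a \code{snp_effects} table.
#' @param path file path.
#' @return \code{path} (write) or the table (read).
#' @export
write_snp_effects <- function(effects, path) {
  utils::write.table(effects, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_effects
#' @export
read_snp_effects <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(snp_id = "character",
                                          a1 = "character"))
  stopifnot(all(c("snp_id", "a1", "mean", "sd", "effect") %in% names(out)))
  class(out) <- c("snp_effects", "data.frame")
  out
}
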