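#' Principal components of the genomic relationship matrix
#'
#' Top-k spectral pairs of G for studying population structure. PCA on
#' the GRM is equivalent (up to scaling) to PCA on the standardized
#' genotype matrix itself, since \code{G = Z Z'/M}. Negative eigenvalues
#' (numerical noise) are clipped to zero when computing variance
#' proportions. Eigenvector sign is fixed by making each column's
#' largest-magnitude element positive.
#'
#' @param grm a \code{grm} object.
#' @param k number of components, 1 <= k <= N.
#' @return Object of class \code{"grm_pca"}: \code{values} (k, descending),
#'   \code{vectors} (N x k, orthonormal), \code{proportions}
#'   (\code{lambda_i / sum(lambda)} over the clipped full spectrum),
#'   \code{samples}.
#' @export
pca_grm <- function(grm, k) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$G)
  if (k < 1 || k > n) stop("k_out_of_range: need 1 <= k <= N",
                           call. = FALSE)
  e <- eigendecompose_grm(grm)
  dpos <- pmax(e$values, 0)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  structure(list(values = e$values[seq_len(k)], vectors = U,
                 proportions = dpos[seq_len(k)] / sum(dpos),
                 samples = grm$samples),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat(sprintf("grm_pca: %d components, top proportions %s\n",
              length(x$values),
              paste(sprintf("%.3f", utils::head(x$proportions, 5)),
                    collapse = " ")))
  invisible(x)
}

#' Write PCA results in GCTA-like .eigenval/.eigenvec files
#'
#' @param pca a \code{grm_pca}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_pca <- function(pca, prefix) {
  writeLines(sprintf("%.10g", pca$values), paste0(prefix, ".eigenval"))
  ev <- data.frame(pca$samples$fid, pca$samples$iid, pca$vectors)
  utils::write.table(ev, paste0(prefix, ".eigenvec"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Single-marker association scan
#'
#' Per-SNP ordinary least squares of the phenotype on covariates plus
#' the allele dosage; reports the dosage coefficient (trait units per
#' copy of A1), its standard error, t statistic and two-sided p-value on
#' \code{n_used - c - 1} degrees of freedom. Samples missing a SNP are
#' dropped for that SNP only (complete-case per marker). SNPs monomorphic
#' among the used samples are flagged with \code{NA} results. p-values
#' are floored at the smallest positive double so that a perfect fit does
#' not report zero.
#'
#' @param g a \code{genotype_matrix}.
#' @param y numeric phenotype vector aligned with \code{g}.
#' @param X_cov covariate design matrix including the intercept; defaults
#'   to intercept only.
#' @return Data frame with \code{snp_id}, \code{chr}, \code{bp},
#'   \code{a1}, \code{beta}, \code{se}, \code{t}, \code{p}, \code{n}.
#' @export
gwas_linear <- function(g, y, X_cov = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  stopifnot(length(y) == n)
  if (is.null(X_cov)) X_cov <- matrix(1, n, 1)
  X_cov <- as.matrix(X_cov)
  cc <- ncol(X_cov)
  if (n < cc + 2) stop("too_few_samples", call. = FALSE)
  m <- ncol(g$dosages)
  beta <- se <- tval <- pval <- rep(NA_real_, m)
  nused <- integer(m)
  for (j in seq_len(m)) {
    s <- g$dosages[, j]
    ok <- !is.na(s) & !is.na(y)
    nu <- sum(ok)
    nused[j] <- nu
    if (nu < cc + 2) next
    sj <- as.numeric(s[ok])
    if (stats::var(sj) == 0) next  # monomorphic among used samples
    D <- cbind(X_cov[ok, , drop = FALSE], sj)
    XtXi <- tryCatch(chol2inv(chol(crossprod(D))),
                     error = function(e) NULL)
    if (is.null(XtXi)) next
    bh <- drop(XtXi %*% crossprod(D, y[ok]))
    res <- y[ok] - drop(D %*% bh)
    df <- nu - cc - 1L
    s2 <- sum(res^2) / df
    k <- cc + 1L
    beta[j] <- bh[k]
    se[j] <- sqrt(s2 * XtXi[k, k])
    tval[j] <- if (se[j] > 0) beta[j] / se[j] else sign(beta[j]) * Inf
    pval[j] <- max(2 * stats::pt(-abs(tval[j]), df),
                   .Machine$double.xmin)
  }
  data.frame(snp_id = g$snps$id, chr = g$snps$chr, bp = g$snps$bp,
             a1 = g$snps$a1, beta = beta, se = se, t = tval, p = pval,
             n = nused, stringsAsFactors = FALSE)
}
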