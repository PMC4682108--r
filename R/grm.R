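#' Compute a genomic relationship matrix
#'
#' \code{G = Z Z' / M} from standardized genotypes, the covariance
#' structure of the additive polygenic term (\code{cov(g) = G sigma2_g}
#' with \code{sigma2_g = M sigma2_a}).
#'
#' @param z a \code{std_genotypes} object (or bare numeric matrix).
#' @param samples optional sample data frame (\code{fid}, \code{iid}).
#' @return Object of class \code{"grm"}: list with \code{G} (N x N),
#'   \code{samples}, \code{m_snps}.
#' @export
compute_grm <- function(z, samples = NULL) {
  Z <- if (inherits(z, "std_genotypes")) z$Z else as.matrix(z)
  m <- ncol(Z)
  if (m == 0L) stop("empty_snp_set: GRM requires at least one SNP",
                    call. = FALSE)
  G <- tcrossprod(Z) / m
  G <- (G + t(G)) / 2
  n <- nrow(G)
  if (is.null(samples))
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)),
                          stringsAsFactors = FALSE)
  structure(list(G = G, samples = samples, m_snps = m), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d samples, %d SNPs, mean diagonal %.4f\n",
              nrow(x$G), x$m_snps, mean(diag(x$G))))
  invisible(x)
}

#' Write a GRM in GCTA binary format
#'
#' Writes \code{prefix.grm.bin} (lower triangle including the diagonal,
#' row-major, little-endian float32), \code{prefix.grm.id} (FID IID) and
#' \code{prefix.grm.N.bin} (SNP count per pair, float32).
#'
#' @param grm a \code{grm} object.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  G <- grm$G
  # column-major upper triangle == row-major lower triangle of a
  # symmetric matrix
  vals <- G[upper.tri(G, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m_snps), length(vals)), con, size = 4L,
           endian = "little")
  close(con)
  utils::write.table(grm$samples[, c("fid", "iid")],
                     paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM
#'
#' @param prefix path prefix of the \code{.grm.bin}/\code{.grm.id} pair
#'   (\code{.grm.N.bin} read when present).
#' @return A \code{grm} object (float32 precision).
#' @export
read_grm_gcta <- function(prefix) {
  idf <- paste0(prefix, ".grm.id")
  binf <- paste0(prefix, ".grm.bin")
  if (!file.exists(idf) || !file.exists(binf))
    stop("grm_missing_file: need ", binf, " and ", idf, call. = FALSE)
  ids <- utils::read.table(idf, header = FALSE, colClasses = "character")
  n <- nrow(ids)
  nvals <- n * (n + 1) / 2
  vals <- readBin(binf, "numeric", n = file.size(binf) / 4 + 1, size = 4L,
                  endian = "little")
  if (length(vals) != nvals)
    stop(sprintf("grm_size_mismatch: %d ids imply %d values, file has %d",
                 n, nvals, length(vals)), call. = FALSE)
  G <- matrix(0, n, n)
  G[upper.tri(G, diag = TRUE)] <- vals
  G <- G + t(G) - diag(diag(G), n)
  m <- NA_integer_
  nf <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nf))
    m <- as.integer(readBin(nf, "numeric", n = 1, size = 4L,
                            endian = "little"))
  structure(list(G = G,
                 samples = data.frame(fid = ids[[1]], iid = ids[[2]],
                                      stringsAsFactors = FALSE),
                 m_snps = m),
            class = "grm")
}

.new_grm_eigen <- function(values, vectors, n) {
  structure(list(values = values, vectors = vectors, n = n),
            class = "grm_eigen")
}

#' Full eigen decomposition of a GRM
#'
#' @param grm a \code{grm} object (or bare symmetric matrix).
#' @param clip_negative clip small negative eigenvalues (above
#'   \code{-1e-8 * N}) to zero.
#' @return Object of class \code{"grm_eigen"}: \code{values} (descending,
#'   length \code{rank}, trailing exact zeros dropped only in the low-rank
#'   constructor), \code{vectors} (N x length(values), orthonormal
#'   columns), \code{n}.
#' @export
eigendecompose_grm <- function(grm, clip_negative = TRUE) {
  G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
  if (!all(is.finite(G))) stop("non_finite_grm", call. = FALSE)
  n <- nrow(G)
  e <- eigen(G, symmetric = TRUE)
  d <- e$values
  if (clip_negative) d[d < 0 & d > -1e-8 * n] <- 0
  .new_grm_eigen(d, e$vectors, n)
}

#' Exact low-rank eigen structure of a GRM from its genotype factor
#'
#' When \code{G = Z Z' / M} with \code{M < N}, the non-zero spectrum of G
#' is that of \code{Z'Z / M}; this computes the corresponding eigen pairs
#' from the M x M cross-product, which is much cheaper than decomposing
#' the N x N matrix. Eigenvalues not represented are exactly zero.
#'
#' @param z a \code{std_genotypes} object or numeric matrix.
#' @param tol relative tolerance below which eigenvalues are treated as
#'   zero and dropped.
#' @return A \code{grm_eigen} whose \code{vectors} span only the non-null
#'   eigenspace (N x r, r <= M).
#' @export
grm_eigen_from_genotypes <- function(z, tol = 1e-10) {
  Z <- if (inherits(z, "std_genotypes")) z$Z else as.matrix(z)
  n <- nrow(Z)
  m <- ncol(Z)
  if (m == 0L) stop("empty_snp_set", call. = FALSE)
  if (m >= n) return(eigendecompose_grm(tcrossprod(Z) / m))
  e <- eigen(crossprod(Z) / m, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  d <- e$values[keep]
  # right singular vectors -> left: u_k = Z v_k / sqrt(M d_k)
  U <- Z %*% sweep(e$vectors[, keep, drop = FALSE], 2,
                   sqrt(m * d), `/`)
  .new_grm_eigen(d, U, n)
}

#' @export
print.grm_eigen <- function(x, ...) {
  cat(sprintf("grm_eigen: n = %d, rank represented = %d, top value %.4f\n",
              x$n, length(x$values), x$values[1]))
  invisible(x)
}
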