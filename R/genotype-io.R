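#' Construct a genotype matrix object
#'
#' Container for biallelic SNP genotypes coded as counts of the reference
#' allele (PLINK A1). Rows are samples, columns are SNPs; entries are 0, 1,
#' 2 or \code{NA} for missing.
#'
#' @param dosages integer (or numeric) N x M matrix of A1 allele counts in
#'   \{0, 1, 2, NA\}.
#' @param samples data frame with columns \code{fid}, \code{iid}; defaults
#'   to \code{fid = "F1..FN"}, \code{iid = "I1..IN"}.
#' @param snps data frame with columns \code{chr}, \code{id}, \code{cm},
#'   \code{bp}, \code{a1}, \code{a2}; sensible defaults generated when
#'   omitted.
#' @return An object of class \code{"genotype_matrix"} with elements
#'   \code{dosages}, \code{samples}, \code{snps}.
#' @export
genotype_matrix <- function(dosages, samples = NULL, snps = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  n <- nrow(dosages)
  m <- ncol(dosages)
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(samples)) {
    samples <- data.frame(fid = paste0("F", seq_len(n)),
                          iid = paste0("I", seq_len(n)),
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(nrow(samples) == n, all(c("fid", "iid") %in% names(samples)))
  if (anyDuplicated(paste(samples$fid, samples$iid)))
    stop("duplicated (fid, iid) pairs", call. = FALSE)
  if (is.null(snps)) {
    snps <- data.frame(chr = rep(1L, m), id = sprintf("snp%d", seq_len(m)),
                       cm = rep(0, m), bp = seq_len(m),
                       a1 = rep("A", m), a2 = rep("G", m),
                       stringsAsFactors = FALSE)
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(nrow(snps) == m,
            all(c("chr", "id", "cm", "bp", "a1", "a2") %in% names(snps)))
  if (anyDuplicated(snps$id)) stop("duplicated SNP ids", call. = FALSE)
  structure(list(dosages = dosages, samples = samples, snps = snps),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param x a \code{genotype_matrix}.
#' @param i sample (row) index.
#' @param j SNP (column) index.
#' @param ... ignored.
#' @return A \code{genotype_matrix} restricted to the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  genotype_matrix(x$dosages[i, j, drop = FALSE],
                  samples = x$samples[i, , drop = FALSE],
                  snps = x$snps[j, , drop = FALSE])
}

# 2-bit PLINK codes within a byte, LSB-first: 00 -> 2 copies of A1,
# 01 -> missing, 10 -> 1 copy, 11 -> 0 copies.
.plink_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
.plink_dosage_to_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  code
}

# 4 x 256 lookup: dosage of sample slot k (1..4) for each byte value
.plink_byte_lut <- local({
  b <- 0:255
  rbind(.plink_code_to_dosage[bitwAnd(b, 3L) + 1L],
        .plink_code_to_dosage[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
        .plink_code_to_dosage[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
        .plink_code_to_dosage[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L])
})

#' Read PLINK 1 binary genotypes
#'
#' Reads a \code{.bed}/\code{.bim}/\code{.fam} triplet in SNP-major mode
#' (magic bytes \code{0x6C 0x1B}, mode byte \code{0x01}).
#'
#' @param prefix path prefix; \code{prefix.bed}, \code{prefix.bim} and
#'   \code{prefix.fam} must exist.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop("plink_missing_file: ", paste(miss, collapse = ", "), call. = FALSE)
  fam <- utils::read.table(paths[3], header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(paths[2], header = FALSE,
                           col.names = c("chr", "id", "cm", "bp", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("plink_bad_magic: not a PLINK .bed file", call. = FALSE)
  if (raw[3] != as.raw(0x01))
    stop("plink_unsupported_mode: only SNP-major (mode 0x01) .bed supported",
         call. = FALSE)
  bps <- ceiling(n / 4)  # bytes per SNP
  if (length(raw) != 3L + bps * m)
    stop(sprintf("plink_truncated_bed: expected %d data bytes, found %d",
                 bps * m, length(raw) - 3L), call. = FALSE)
  if (m == 0L || n == 0L) {
    dos <- matrix(NA_integer_, n, m)
  } else {
    bytes <- as.integer(raw[-(1:3)])
    dos <- matrix(.plink_byte_lut[, bytes + 1L], nrow = 4L * bps)[seq_len(n), ,
                                                                  drop = FALSE]
  }
  genotype_matrix(dos,
                  samples = data.frame(fid = fam[[1]], iid = fam[[2]],
                                       stringsAsFactors = FALSE),
                  snps = bim)
}

#' Write PLINK 1 binary genotypes
#'
#' Writes a SNP-major \code{.bed} plus matching \code{.bim}/\code{.fam};
#' \code{read_plink(write_plink(g, p))} is the identity.
#'
#' @param g a \code{genotype_matrix}.
#' @param prefix output path prefix.
#' @return \code{prefix}, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages)
  m <- ncol(g$dosages)
  bps <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L && n > 0L) {
    codes <- matrix(0L, nrow = 4L * bps, ncol = m)
    codes[seq_len(n), ] <- matrix(.plink_dosage_to_code(g$dosages), n, m)
    # pack 4 two-bit codes per byte, LSB-first
    k <- seq_len(bps) * 4L
    bytes <- codes[k - 3L, , drop = FALSE] +
      4L * codes[k - 2L, , drop = FALSE] +
      16L * codes[k - 1L, , drop = FALSE] +
      64L * codes[k, , drop = FALSE]
    writeBin(as.raw(bytes), con)
  }
  fam <- data.frame(g$samples$fid, g$samples$iid, 0L, 0L, 0L, -9L)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(g$snps[, c("chr", "id", "cm", "bp", "a1", "a2")],
                     paste0(prefix, ".bim"), quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Per-SNP allele statistics
#'
#' Computes, for each SNP, the A1 allele frequency, the mean dosage, the
#' standardization s.d. and the number of non-missing genotypes. The s.d.
#' is by default the Hardy-Weinberg value \code{sqrt(2 p (1 - p))} (GCTA
#' convention); set \code{sd_method = "empirical"} for the sample s.d. of
#' the dosages.
#'
#' @param g a \code{genotype_matrix}.
#' @param sd_method \code{"hwe"} (default) or \code{"empirical"}.
#' @return Data frame of class \code{"snp_stats"} with columns \code{id},
#'   \code{freq}, \code{mean}, \code{sd}, \code{n_obs}, \code{monomorphic}.
#' @export
compute_snp_stats <- function(g, sd_method = c("hwe", "empirical")) {
  stopifnot(inherits(g, "genotype_matrix"))
  sd_method <- match.arg(sd_method)
  d <- g$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0L))
    stop("all_missing_snp: SNP(s) with no observed genotypes: ",
         paste(g$snps$id[n_obs == 0L], collapse = ", "), call. = FALSE)
  mu <- colMeans(d, na.rm = TRUE)
  p <- mu / 2
  if (sd_method == "hwe") {
    s <- sqrt(2 * p * (1 - p))
  } else {
    s <- apply(d, 2, stats::sd, na.rm = TRUE)
    s[n_obs == 1L] <- 0
  }
  out <- data.frame(id = g$snps$id, a1 = g$snps$a1, a2 = g$snps$a2,
                    freq = p, mean = mu, sd = s,
                    n_obs = n_obs, monomorphic = s == 0,
                    stringsAsFactors = FALSE)
  attr(out, "sd_method") <- sd_method
  class(out) <- c("snp_stats", "data.frame")
  out
}

#' Standardize genotypes
#'
#' Centres and scales dosages SNP-wise, \code{z = (s - mean) / sd}, using
#' the supplied statistics (typically from the training cohort); missing
#' genotypes become 0 (mean imputation on the standardized scale).
#'
#' @param g a \code{genotype_matrix}.
#' @param stats a \code{snp_stats} table; defaults to
#'   \code{compute_snp_stats(g)} (self-standardization).
#' @param sd_method passed to \code{compute_snp_stats} when \code{stats} is
#'   \code{NULL}.
#' @return Object of class \code{"std_genotypes"}: list with \code{Z}
#'   (N x M numeric matrix) and \code{stats}.
#' @export
standardize <- function(g, stats = NULL, sd_method = c("hwe", "empirical")) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(stats)) stats <- compute_snp_stats(g, match.arg(sd_method))
  if (!identical(stats$id, g$snps$id))
    stop("snp_stats_mismatch: stats SNP set does not match genotypes",
         call. = FALSE)
  if (any(stats$sd <= 0))
    stop("monomorphic_snp: sd = 0 for SNP(s) ",
         paste(stats$id[stats$sd <= 0], collapse = ", "),
         "; filter before standardizing", call. = FALSE)
  z <- sweep(g$dosages, 2, stats$mean, `-`)
  z <- sweep(z, 2, stats$sd, `/`)
  z[is.na(z)] <- 0
  dimnames(z) <- list(NULL, stats$id)
  structure(list(Z = z, stats = stats), class = "std_genotypes")
}

#' @export
print.std_genotypes <- function(x, ...) {
  cat(sprintf("std_genotypes: %d x %d (sd method: %s)\n",
              nrow(x$Z), ncol(x$Z), attr(x$stats, "sd_method")))
  invisible(x)
}

#' Filter SNPs on minor allele frequency and missingness
#'
#' @param g a \code{genotype_matrix}.
#' @param min_maf minimum minor allele frequency (0 <= min_maf < 0.5).
#' @param max_missing_rate maximum fraction of missing genotypes per SNP.
#' @return A \code{genotype_matrix} with the retained SNPs, order preserved.
#' @export
filter_snps <- function(g, min_maf = 0, max_missing_rate = 1) {
  stopifnot(inherits(g, "genotype_matrix"),
            min_maf >= 0, min_maf < 0.5,
            max_missing_rate >= 0, max_missing_rate <= 1)
  d <- g$dosages
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  keep <- maf >= min_maf & miss <= max_missing_rate
  if (!any(keep)) stop("all_snps_filtered: no SNPs pass the filters",
                       call. = FALSE)
  g[, which(keep)]
}
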