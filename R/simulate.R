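#' Simulate biallelic genotypes
#'
#' Generates a cohort of unrelated individuals. Per-SNP allele
#' frequencies are drawn uniformly from \code{maf_range}. With
#' \code{ld_rho = 0} genotypes are independent Binomial(2, p) draws
#' (Hardy-Weinberg, linkage equilibrium). With \code{ld_rho > 0} each
#' individual receives two haplotypes generated by a first-order Markov
#' chain over sites whose stationary allele frequency at site j is p_j
#' and whose adjacent-site correlation is \code{ld_rho}; the two
#' haplotypes are summed. Transition probabilities are clamped to [0, 1],
#' so when adjacent frequencies differ strongly the realized correlation
#' is attenuated toward its Frechet bound; it is exact when adjacent
#' frequencies are equal.
#'
#' @param n_samples number of individuals.
#' @param n_snps number of SNPs.
#' @param maf_range length-2 vector of allele-frequency bounds, within
#'   (0, 0.5]; default \code{c(0.05, 0.5)}.
#' @param ld_rho adjacent-SNP haplotype correlation in [0, 1); 0 gives
#'   linkage equilibrium.
#' @param seed integer seed (mandatory; the generator is a pure function
#'   of its arguments).
#' @return A \code{\link{genotype_matrix}}.
#' @export
simulate_genotypes <- function(n_samples, n_snps,
                               maf_range = c(0.05, 0.5), ld_rho = 0,
                               seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(maf_range) == 2, maf_range[1] > 0,
            maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  if (ld_rho == 0) {
    dos <- matrix(stats::rbinom(n_samples * n_snps, 2L,
                                rep(p, each = n_samples)),
                  n_samples, n_snps)
  } else {
    hap <- function() {
      h <- matrix(0L, n_samples, n_snps)
      h[, 1] <- stats::rbinom(n_samples, 1L, p[1])
      for (j in 2:n_snps) {
        cj <- ld_rho * sqrt(p[j] * (1 - p[j]) /
                              (p[j - 1] * (1 - p[j - 1])))
        pr <- pmin(pmax(p[j] + cj * (h[, j - 1] - p[j - 1]), 0), 1)
        h[, j] <- stats::rbinom(n_samples, 1L, pr)
      }
      h
    }
    dos <- hap() + hap()
  }
  genotype_matrix(dos)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an additive quantitative trait
#'
#' Draws \code{n_qtn} causal SNPs (QTNs) uniformly without replacement;
#' effects are standard normal on the standardized-genotype scale (so
#' every QTN has equal expected variance contribution, and dosage-scale
#' effects scale as \code{u_j / sd_j}). The genetic values \code{g = Z u}
#' are rescaled so their empirical variance is exactly \code{h2}; the
#' residuals are drawn normal, orthogonalized against \code{[1, g]} and
#' rescaled to empirical variance \code{1 - h2}. Hence the realized
#' heritability \code{var(g)/var(y)} equals \code{h2} exactly, for any
#' seed.
#'
#' @param g a \code{genotype_matrix}.
#' @param n_qtn number of causal SNPs; must not exceed the SNP count.
#' @param h2 heritability, strictly inside (0, 1).
#' @param seed integer seed (mandatory).
#' @return Object of class \code{"sim_trait"}: \code{y} (phenotypes),
#'   \code{g} (true genetic values), \code{qtn_idx}, \code{qtn_id},
#'   \code{effects} (standardized scale), \code{h2}, \code{realized_h2}.
#' @export
simulate_trait <- function(g, n_qtn, h2, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  m <- ncol(g$dosages)
  n <- nrow(g$dosages)
  if (!(h2 > 0 && h2 < 1))
    stop("h2 must be strictly inside (0, 1)", call. = FALSE)
  if (n_qtn > m) stop("n_qtn exceeds the number of SNPs", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  qtn <- sort(sample.int(m, n_qtn))
  sub <- g[, qtn]
  st <- compute_snp_stats(sub)
  if (any(st$monomorphic))
    stop("monomorphic_qtn: selected QTN(s) are monomorphic: ",
         paste(st$id[st$monomorphic], collapse = ", "), call. = FALSE)
  u <- stats::rnorm(n_qtn)
  graw <- drop(standardize(sub, st)$Z %*% u)
  vg <- stats::var(graw)
  if (vg == 0) stop("degenerate_genetic_value", call. = FALSE)
  gval <- graw * sqrt(h2 / vg)
  e <- stats::rnorm(n)
  # orthogonalize e against [1, g] so var(y) = var(g) + var(e) exactly
  e <- stats::lm.fit(cbind(1, gval), e)$residuals
  e <- e * sqrt((1 - h2) / stats::var(e))
  y <- gval + e
  structure(list(y = y, g = gval, qtn_idx = qtn, qtn_id = g$snps$id[qtn],
                 effects = u, h2 = h2,
                 realized_h2 = stats::var(gval) / stats::var(y)),
            class = "sim_trait")
}

#' @export
print.sim_trait <- function(x, ...) {
  cat(sprintf("sim_trait: %d individuals, %d QTNs, h2 = %g (realized %.12f)\n",
              length(x$y), length(x$qtn_idx), x$h2, x$realized_h2))
  invisible(x)
}

#' Random train/validation split
#'
#' Uniform random partition of the samples; genotypes, phenotypes and
#' true genetic values stay aligned within each part.
#'
#' @param g a \code{genotype_matrix}.
#' @param trait a \code{sim_trait} (or a bare phenotype vector).
#' @param train_frac fraction of samples used for training (default 0.9,
#'   ignored when \code{n_train} is given).
#' @param seed integer seed.
#' @param n_train optional explicit training-set size (used by cohorts
#'   specified as absolute sizes rather than fractions).
#' @return List with elements \code{train} and \code{validation}, each a
#'   list of \code{geno}, \code{y}, \code{g} (true genetic values, when
#'   available) and \code{idx}.
#' @export
train_validation_split <- function(g, trait, train_frac = 0.9, seed,
                                   n_train = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n <- nrow(g$dosages)
  y <- if (inherits(trait, "sim_trait")) trait$y else as.numeric(trait)
  gv <- if (inherits(trait, "sim_trait")) trait$g else NULL
  stopifnot(length(y) == n)
  if (is.null(n_train)) {
    stopifnot(train_frac > 0, train_frac < 1)
    n_train <- round(train_frac * n)
  }
  if (n_train < 1 || n_train > n - 1)
    stop("empty_partition: both parts must be non-empty", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n, n_train))
  va <- setdiff(seq_len(n), tr)
  part <- function(idx) list(geno = g[idx, ], y = y[idx],
                             g = if (is.null(gv)) NULL else gv[idx],
                             idx = idx)
  list(train = part(tr), validation = part(va))
}

#' Genotyping-array scenarios for prediction experiments
#'
#' Returns the SNP column indices present on the array under three
#' designs: \code{"partial_qtn"} — all non-causal SNPs plus a random
#' fraction \code{qtn_on_array_frac} of the QTNs (poor tagging);
#' \code{"all_qtn"} — every SNP, causal and non-causal;
#' \code{"qtn_only"} — exactly the causal set.
#'
#' @param g a \code{genotype_matrix}.
#' @param trait a \code{sim_trait} carrying the QTN indices.
#' @param scenario one of \code{"partial_qtn"}, \code{"all_qtn"},
#'   \code{"qtn_only"}.
#' @param qtn_on_array_frac fraction of QTNs on the array under
#'   \code{"partial_qtn"} (default 0.2).
#' @param seed integer seed (used only by \code{"partial_qtn"}).
#' @return Sorted integer vector of SNP indices.
#' @export
build_array_scenario <- function(g, trait,
                                 scenario = c("partial_qtn", "all_qtn",
                                              "qtn_only"),
                                 qtn_on_array_frac = 0.2, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(trait, "sim_trait"))
  scenario <- match.arg(scenario)
  m <- ncol(g$dosages)
  qtn <- trait$qtn_idx
  switch(scenario,
         all_qtn = seq_len(m),
         qtn_only = sort(qtn),
         partial_qtn = {
           old <- .save_rng(); on.exit(.restore_rng(old))
           set.seed(as.integer(seed))
           k <- round(qtn_on_array_frac * length(qtn))
           on_array <- if (k > 0) sort(sample(qtn, k)) else integer(0)
           sort(c(setdiff(seq_len(m), qtn), on_array))
         })
}

#' Write phenotypes in PLINK .phen format (FID IID value)
#'
#' @param samples data frame with \code{fid}, \code{iid}.
#' @param y numeric phenotypes (NA written as NA).
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
write_pheno <- function(samples, y, path) {
  utils::write.table(data.frame(samples$fid, samples$iid, y), path,
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PLINK-style phenotype/covariate file
#'
#' Whitespace-delimited, columns FID IID value1 [value2 ...]; \code{NA}
#' and \code{-9} are treated as missing.
#'
#' @param path file path.
#' @param samples optional sample data frame (\code{fid}, \code{iid}) to
#'   align against; rows are reordered to match and absent samples get NA.
#' @return Data frame with \code{fid}, \code{iid} and numeric value
#'   columns \code{V1}, \code{V2}, ...
#' @export
read_pheno <- function(path, samples = NULL) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 3) stop("pheno file needs FID IID value columns",
                          call. = FALSE)
  vals <- as.data.frame(lapply(raw[-(1:2)], function(v) {
    x <- suppressWarnings(as.numeric(v))
    x[!is.na(x) & x == -9] <- NA
    x
  }))
  names(vals) <- paste0("V", seq_along(vals))
  out <- cbind(data.frame(fid = raw[[1]], iid = raw[[2]],
                          stringsAsFactors = FALSE), vals)
  if (!is.null(samples)) {
    key <- paste(out$fid, out$iid)
    want <- paste(samples$fid, samples$iid)
    out <- out[match(want, key), ]
    out$fid <- samples$fid
    out$iid <- samples$iid
    rownames(out) <- NULL
  }
  out
}
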