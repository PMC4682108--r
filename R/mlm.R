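#' Assemble data for a univariate mixed linear model
#'
#' The model is \code{y = X beta + g + e} with \code{g ~ N(0, G sigma2_g)}
#' and \code{e ~ N(0, I sigma2_e)}; equivalently \code{y_i = mu + sum_j
#' z_ij a_j + e_i} with SNP effects \code{a ~ N(0, I sigma2_a)} and
#' \code{sigma2_g = M sigma2_a}.
#'
#' @param y numeric phenotype vector, length N.
#' @param X fixed-effect design matrix (N x c); defaults to an
#'   intercept-only column of ones. Must have full column rank.
#' @param grm a \code{grm} object aligned with \code{y} (optional when a
#'   genotype factor \code{z} is supplied instead).
#' @param z optional \code{std_genotypes}; when \code{grm} is missing the
#'   GRM is \code{Z Z' / M} and fast eigen structure can be derived from
#'   \code{z} directly.
#' @return Object of class \code{"mlm_data"}.
#' @export
mlm_data <- function(y, X = NULL, grm = NULL, z = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "intercept"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, n > ncol(X))
  if (qr(X)$rank < ncol(X))
    stop("rank_deficient_design: X does not have full column rank",
         call. = FALSE)
  if (is.null(grm) && is.null(z))
    stop("need a grm or standardized genotypes", call. = FALSE)
  if (!is.null(grm)) {
    G <- if (inherits(grm, "grm")) grm$G else as.matrix(grm)
    stopifnot(nrow(G) == n)
    if (!inherits(grm, "grm"))
      grm <- structure(list(G = G, samples = NULL, m_snps = NA_integer_),
                       class = "grm")
  }
  if (!is.null(z)) stopifnot(nrow(if (inherits(z, "std_genotypes")) z$Z
                                  else z) == n)
  structure(list(y = y, X = X, grm = grm, z = z, n = n, c = ncol(X)),
            class = "mlm_data")
}

.mlm_grm_matrix <- function(data) {
  if (!is.null(data$grm)) return(data$grm$G)
  Z <- if (inherits(data$z, "std_genotypes")) data$z$Z else data$z
  tcrossprod(Z) / ncol(Z)
}

.mlm_eigen <- function(data) {
  if (!is.null(data$z)) grm_eigen_from_genotypes(data$z)
  else eigendecompose_grm(data$grm)
}

# ---- dense-path REML quantities (reference implementation) -------------

# Restricted log-likelihood, score and average-information matrix computed
# with V built explicitly. Used for small problems and as the oracle the
# rotated path is tested against.
.reml_dense_eval <- function(G, y, X, s2g, s2e,
                             what = c("ll", "score", "ai")) {
  n <- length(y)
  V <- s2g * G + diag(s2e, n)
  R <- tryCatch(chol(V), error = function(e)
    stop("singular_v: V not positive definite", call. = FALSE))
  ldV <- 2 * sum(log(diag(R)))
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  M <- crossprod(X, ViX)
  Rm <- tryCatch(chol(M), error = function(e)
    stop("singular_xvx: X'V^-1X not positive definite", call. = FALSE))
  ldM <- 2 * sum(log(diag(Rm)))
  Mi <- chol2inv(Rm)
  beta <- drop(Mi %*% crossprod(ViX, y))
  Py <- drop(Vi %*% y - ViX %*% (Mi %*% crossprod(ViX, y)))
  yPy <- sum(y * Py)
  out <- list(ll = -0.5 * (ldV + ldM + yPy), beta = beta, Mi = Mi)
  if (any(c("score", "ai") %in% what)) {
    P <- Vi - ViX %*% tcrossprod(Mi, ViX)
    GPy <- drop(G %*% Py)
    out$score <- c(-0.5 * (sum(P * G) - sum(Py * GPy)),
                   -0.5 * (sum(diag(P)) - sum(Py * Py)))
    PGPy <- drop(P %*% GPy)
    PPy <- drop(P %*% Py)
    out$ai <- 0.5 * matrix(c(sum(GPy * PGPy), sum(GPy * PPy),
                             sum(GPy * PPy), sum(Py * PPy)), 2, 2)
  }
  out
}

# ---- rotated-path REML quantities --------------------------------------

# Precompute the sufficient statistics for REML in the GRM eigenbasis.
# Works with a partial (low-rank) basis U (N x r) provided the remaining
# eigenvalues are exactly zero: all quantities involving the null space
# reduce to Gram-matrix corrections.
.reml_rot_pre <- function(eig, y, X) {
  U <- eig$vectors
  list(d = eig$values, ty = drop(crossprod(U, y)), tX = crossprod(U, X),
       yy = sum(y^2), Xy = drop(crossprod(X, y)), XX = crossprod(X),
       n = eig$n, c = ncol(X))
}

.reml_rot_eval <- function(pre, s2g, s2e, what = c("ll", "score", "ai")) {
  d <- pre$d; ty <- pre$ty; tX <- pre$tX
  n <- pre$n; cc <- pre$c; r <- length(d)
  v <- s2g * d + s2e
  if (any(v <= 0) || s2e <= 0) stop("singular_v", call. = FALSE)
  tXtX <- crossprod(tX)
  XXp <- pre$XX - tXtX          # X'X restricted to the null space
  Xyp <- pre$Xy - drop(crossprod(tX, ty))
  yyp <- pre$yy - sum(ty^2)
  M <- crossprod(tX, tX / v) + XXp / s2e
  b <- drop(crossprod(tX, ty / v)) + Xyp / s2e
  Rm <- tryCatch(chol(M), error = function(e)
    stop("singular_xvx", call. = FALSE))
  Mi <- chol2inv(Rm)
  beta <- drop(Mi %*% b)
  yVy <- sum(ty^2 / v) + yyp / s2e
  yPy <- yVy - sum(b * beta)
  ldV <- sum(log(v)) + (n - r) * log(s2e)
  ll <- -0.5 * (ldV + 2 * sum(log(diag(Rm))) + yPy)
  out <- list(ll = ll, beta = beta, Mi = Mi)
  if (!any(c("score", "ai") %in% what)) return(out)
  rt <- ty - drop(tX %*% beta)          # rotated residual, span part
  ut <- rt / v                          # Py, span part
  Xrp <- Xyp - drop(XXp %*% beta)       # X' r, null-space part
  R2p <- max(yyp - 2 * sum(Xyp * beta) + sum(beta * (XXp %*% beta)), 0)
  # scores
  XVGVX <- crossprod(tX, tX * (d / v^2))
  trPG <- sum(d / v) - sum(Mi * XVGVX)
  XV2X <- crossprod(tX, tX / v^2) + XXp / s2e^2
  trP <- sum(1 / v) + (n - r) / s2e - sum(Mi * XV2X)
  yPGPy <- sum(d * ut^2)
  yPPy <- sum(ut^2) + R2p / s2e^2
  out$score <- c(-0.5 * (trPG - yPGPy), -0.5 * (trP - yPPy))
  if (!("ai" %in% what)) return(out)
  at <- d * ut                          # G Py (lies in the span)
  XVa <- drop(crossprod(tX, at / v))
  ga <- drop(Mi %*% XVa)
  Pa_t <- (at - drop(tX %*% ga)) / v
  XVu <- drop(crossprod(tX, ut / v)) + Xrp / s2e^2
  gu <- drop(Mi %*% XVu)
  Pu_t <- (ut - drop(tX %*% gu)) / v
  ai_gg <- 0.5 * sum(at * Pa_t)
  ai_ge <- 0.5 * sum(at * Pu_t)
  uVu <- sum(ut^2 / v) + R2p / s2e^3
  ai_ee <- 0.5 * (uVu - sum(XVu * (Mi %*% XVu)))
  out$ai <- matrix(c(ai_gg, ai_ge, ai_ge, ai_ee), 2, 2)
  out
}

#' Restricted log-likelihood of the mixed model
#'
#' Evaluates \code{-1/2 [ log|V| + log|X'V^-1 X| + y'Py ]} with
#' \code{V = G sigma2_g + I sigma2_e} and
#' \code{P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1}. The additive constant
#' \code{-((N - c)/2) log 2 pi} is omitted, consistently across all REML
#' routines in the package.
#'
#' @param theta numeric length-2 vector \code{c(sigma2_g, sigma2_e)}.
#' @param data an \code{mlm_data} object.
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(theta, data) {
  stopifnot(inherits(data, "mlm_data"), length(theta) == 2,
            theta[2] > 0, theta[1] >= 0)
  .reml_dense_eval(.mlm_grm_matrix(data), data$y, data$X,
                   theta[1], theta[2], what = "ll")$ll
}

.new_reml_fit <- function(s2g, s2e, se = c(NA, NA), se_h2 = NA,
                          ll, n_iter, converged, boundary, beta, beta_se,
                          method, trace = NULL) {
  structure(list(sigma2_g = s2g, sigma2_e = s2e,
                 h2 = s2g / (s2g + s2e),
                 se_sigma2_g = se[1], se_sigma2_e = se[2], se_h2 = se_h2,
                 loglik = ll, n_iter = n_iter, converged = converged,
                 boundary = boundary, beta = beta, beta_se = beta_se,
                 method = method, trace = trace),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s)\n", x$method))
  cat(sprintf("  V(G)  %10.6f  (se %.6f)\n", x$sigma2_g, x$se_sigma2_g))
  cat(sprintf("  V(e)  %10.6f  (se %.6f)\n", x$sigma2_e, x$se_sigma2_e))
  cat(sprintf("  h2    %10.6f  (se %.6f)\n", x$h2, x$se_h2))
  cat(sprintf("  logL  %10.6f   iterations %d  converged %s%s\n",
              x$loglik, x$n_iter, x$converged,
              if (x$boundary) "  [at boundary]" else ""))
  invisible(x)
}

# standard errors from the inverse AI matrix; h2 se by the delta method
.reml_se <- function(ai, s2g, s2e) {
  aii <- tryCatch(solve(ai), error = function(e) NULL)
  if (is.null(aii) || any(diag(aii) < 0))
    return(list(se = c(NA_real_, NA_real_), se_h2 = NA_real_))
  tot <- s2g + s2e
  grad <- c(s2e, -s2g) / tot^2
  vh2 <- drop(t(grad) %*% aii %*% grad)
  list(se = sqrt(diag(aii)), se_h2 = sqrt(max(vh2, 0)))
}

#' Fit the mixed model by average-information REML
#'
#' Maximizes the restricted likelihood over \code{(sigma2_g, sigma2_e)} by
#' AI (average-information) updates with step-halving; components that fall
#' below \code{1e-6 * var(y)} are clamped there and flagged as boundary
#' solutions. Standard errors come from the inverse AI matrix at the
#' optimum (delta method for \code{h2}).
#'
#' Two computational backends produce identical iterates: \code{"dense"}
#' builds \code{V} explicitly each iteration; \code{"eigen"} performs the
#' same updates after an orthogonal rotation to the GRM eigenbasis, where
#' every per-iteration quantity is O(N c^2). The rotation is exact, not an
#' approximation. \code{"auto"} picks \code{"eigen"} for N > 800 or when a
#' decomposition is supplied.
#'
#' @param data an \code{mlm_data} object.
#' @param opts list of options: \code{max_iter} (100), \code{tol} (1e-6,
#'   applied to both the log-likelihood change and the maximum relative
#'   parameter change), \code{backend} ("auto"/"dense"/"eigen"),
#'   \code{eigen} (a precomputed \code{grm_eigen}), \code{keep_trace}
#'   (record per-iteration log-likelihoods).
#' @return A \code{"reml_fit"} with variance components, \code{h2},
#'   standard errors, restricted log-likelihood, iteration count,
#'   convergence and boundary flags, and GLS fixed effects.
#' @export
airml_fit <- function(data, opts = list()) {
  stopifnot(inherits(data, "mlm_data"))
  o <- utils::modifyList(list(max_iter = 100L, tol = 1e-6, backend = "auto",
                              eigen = NULL, keep_trace = FALSE), opts)
  backend <- match.arg(o$backend, c("auto", "dense", "eigen"))
  if (backend == "auto")
    backend <- if (!is.null(o$eigen) || data$n > 800) "eigen" else "dense"
  y <- data$y
  vy <- stats::var(y)
  eps <- 1e-6 * vy
  if (backend == "eigen") {
    eig <- if (!is.null(o$eigen)) o$eigen else .mlm_eigen(data)
    pre <- .reml_rot_pre(eig, y, data$X)
    evalq_ <- function(th, what) .reml_rot_eval(pre, th[1], th[2], what)
  } else {
    G <- .mlm_grm_matrix(data)
    evalq_ <- function(th, what) .reml_dense_eval(G, y, data$X, th[1],
                                                  th[2], what)
  }
  theta <- c(vy / 2, vy / 2)
  cur <- evalq_(theta, c("ll", "score", "ai"))
  trace <- if (o$keep_trace) cur$ll else NULL
  converged <- FALSE
  iter <- 0L
  while (iter < o$max_iter) {
    iter <- iter + 1L
    dir <- tryCatch(solve(cur$ai, cur$score), error = function(e) NULL)
    if (is.null(dir) || !all(is.finite(dir))) {
      # singular AI: step-halved gradient ascent, scaled to the parameters
      dir <- cur$score * vy / max(abs(cur$score), .Machine$double.eps)
    }
    step <- 1
    accepted <- NULL
    for (h in 0:10) {
      cand <- pmax(theta + step * dir, eps)
      nxt <- tryCatch(evalq_(cand, c("ll", "score", "ai")),
                      error = function(e) NULL)
      if (!is.null(nxt) && is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-10) {
        accepted <- list(theta = cand, q = nxt)
        break
      }
      step <- step / 2
    }
    if (is.null(accepted)) {  # no ascent even at the smallest step
      cand <- pmax(theta + step * dir, eps)
      nxt <- tryCatch(evalq_(cand, c("ll", "score", "ai")),
                      error = function(e) NULL)
      if (is.null(nxt)) break
      accepted <- list(theta = cand, q = nxt)
    }
    dll <- accepted$q$ll - cur$ll
    rel <- max(abs(accepted$theta - theta) / pmax(abs(theta), eps))
    theta <- accepted$theta
    cur <- accepted$q
    if (o$keep_trace) trace <- c(trace, cur$ll)
    if (abs(dll) < o$tol && rel < o$tol) { converged <- TRUE; break }
  }
  boundary <- any(theta <= eps * (1 + 1e-12))
  se <- .reml_se(cur$ai, theta[1], theta[2])
  beta_se <- sqrt(pmax(diag(as.matrix(cur$Mi)), 0))
  .new_reml_fit(theta[1], theta[2], se$se, se$se_h2, cur$ll, iter,
                converged, boundary, cur$beta, beta_se,
                method = paste0("AI-REML/", backend), trace = trace)
}

#' Fit the mixed model by the eigen-rotation fast path
#'
#' Rotates the model into the GRM eigenbasis, where the covariance is
#' \code{sigma2_e diag(delta d_k + 1)} with \code{delta =
#' sigma2_g/sigma2_e}; \code{sigma2_e} and the fixed effects are profiled
#' out in closed form and the restricted likelihood is maximized over
#' \code{log10 delta} in [-5, 5] by Brent's method. Exact: no
#' approximation is involved, and the optimum agrees with
#' \code{\link{airml_fit}}.
#'
#' @param data an \code{mlm_data} object.
#' @param grm_eigen a \code{grm_eigen} decomposing the data's GRM
#'   (computed from the data when omitted; a low-rank factor from
#'   \code{\link{grm_eigen_from_genotypes}} is supported and exact).
#' @param opts list: \code{tol} (1e-8 on log10 delta).
#' @return A \code{"reml_fit"}; see \code{\link{airml_fit}}.
#' @export
reml_fit_eigen <- function(data, grm_eigen = NULL, opts = list()) {
  stopifnot(inherits(data, "mlm_data"))
  o <- utils::modifyList(list(tol = 1e-8), opts)
  if (is.null(grm_eigen)) grm_eigen <- .mlm_eigen(data)
  stopifnot(inherits(grm_eigen, "grm_eigen"), grm_eigen$n == data$n)
  pre <- .reml_rot_pre(grm_eigen, data$y, data$X)
  n <- pre$n; cc <- pre$c
  tXtX <- crossprod(pre$tX)
  XXp <- pre$XX - tXtX
  Xyp <- pre$Xy - drop(crossprod(pre$tX, pre$ty))
  yyp <- pre$yy - sum(pre$ty^2)
  neval <- 0L
  sigma2e_of <- function(l10d) {
    delta <- 10^l10d
    vd <- delta * pre$d + 1
    M <- crossprod(pre$tX, pre$tX / vd) + XXp
    b <- drop(crossprod(pre$tX, pre$ty / vd)) + Xyp
    beta <- drop(solve(M, b))
    rss <- sum(pre$ty^2 / vd) + yyp - sum(b * beta)
    max(rss, .Machine$double.xmin) / (n - cc)
  }
  profile_ll <- function(l10d) {
    neval <<- neval + 1L
    s2e <- sigma2e_of(l10d)
    .reml_rot_eval(pre, 10^l10d * s2e, s2e, what = "ll")$ll
  }
  opt <- stats::optimize(profile_ll, interval = c(-5, 5), maximum = TRUE,
                         tol = o$tol)
  cand <- c(opt$maximum, -5, 5)
  lls <- c(opt$objective, profile_ll(-5), profile_ll(5))
  best <- which.max(lls)
  l10 <- cand[best]
  boundary <- best > 1L
  s2e <- sigma2e_of(l10)
  s2g <- 10^l10 * s2e
  q <- .reml_rot_eval(pre, s2g, s2e, what = c("ll", "ai"))
  se <- .reml_se(q$ai, s2g, s2e)
  beta_se <- sqrt(pmax(diag(as.matrix(q$Mi)), 0))
  .new_reml_fit(s2g, s2e, se$se, se$se_h2, q$ll, neval, TRUE, boundary,
                q$beta, beta_se, method = "REML/eigen-rotation")
}

#' Generalized least-squares fixed effects at fitted variances
#'
#' \code{beta = (X'V^-1X)^-1 X'V^-1 y} with \code{V = G sigma2_g +
#' I sigma2_e}; standard errors from the diagonal of \code{(X'V^-1X)^-1}.
#'
#' @param data an \code{mlm_data} object.
#' @param vc a \code{reml_fit} (or list with \code{sigma2_g},
#'   \code{sigma2_e}).
#' @param grm_eigen optional \code{grm_eigen} for the fast path.
#' @return List with \code{beta} and \code{se}.
#' @export
gls_fixed_effects <- function(data, vc, grm_eigen = NULL) {
  stopifnot(inherits(data, "mlm_data"))
  if (!is.null(grm_eigen)) {
    pre <- .reml_rot_pre(grm_eigen, data$y, data$X)
    q <- .reml_rot_eval(pre, vc$sigma2_g, vc$sigma2_e, what = "ll")
  } else {
    q <- .reml_dense_eval(.mlm_grm_matrix(data), data$y, data$X,
                          vc$sigma2_g, vc$sigma2_e, what = "ll")
  }
  list(beta = q$beta, se = sqrt(pmax(diag(as.matrix(q$Mi)), 0)))
}

#' Write a GCTA-style .hsq variance-component table
#'
#' @param fit a \code{reml_fit}.
#' @param n sample size used in the fit.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_hsq <- function(fit, n, path) {
  vp <- fit$sigma2_g + fit$sigma2_e
  lines <- c("Source\tVariance\tSE",
             sprintf("V(G)\t%.6f\t%.6f", fit$sigma2_g, fit$se_sigma2_g),
             sprintf("V(e)\t%.6f\t%.6f", fit$sigma2_e, fit$se_sigma2_e),
             sprintf("Vp\t%.6f\tNA", vp),
             sprintf("V(G)/Vp\t%.6f\t%.6f", fit$h2, fit$se_h2),
             sprintf("logL\t%.4f", fit$loglik),
             sprintf("n\t%d", n),
             sprintf("n_iter\t%d", fit$n_iter))
  writeLines(lines, path)
  invisible(path)
}
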