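#' PCA reduction of a feature matrix
#'
#' Column-centers the matrix and returns the scores of the leading principal
#' components from the singular value decomposition, ordered by singular
#' value, together with the variance explained.
#'
#' @param features numeric matrix, subjects x variables.
#' @param n_components number of components to keep.
#' @return list with \code{scores} (subjects x components),
#'   \code{var_explained} (per component) and \code{cum_var_explained}.
#' @export
pca_reduce <- function(features, n_components) {
  X <- as.matrix(features)
  Xc <- sweep(X, 2L, colMeans(X))
  s <- svd(Xc)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  rk <- sum(s$d > tol)
  if (n_components > min(nrow(X) - 1L, ncol(X)) || n_components > rk)
    stop("n_components exceeds the rank of the centered data")
  k <- seq_len(n_components)
  scores <- s$u[, k, drop = FALSE] %*% diag(s$d[k], n_components)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", k)
  ve <- s$d^2 / sum(s$d^2)
  list(scores = scores, var_explained = ve[k],
       cum_var_explained = cumsum(ve)[n_components])
}

#' Residualize variables on confounds
#'
#' Replaces each column by its OLS residual on the confound matrix (an
#' intercept is always included), leaving residuals orthogonal to every
#' confound.
#'
#' @param X numeric matrix, subjects x variables.
#' @param confounds numeric matrix, subjects x confound variables, or
#'   \code{NULL} for intercept-only (demeaning).
#' @return residual matrix of the same shape as \code{X}.
#' @export
residualize_confounds <- function(X, confounds = NULL) {
  X <- as.matrix(X)
  C <- if (is.null(confounds)) matrix(1, nrow(X), 1L)
       else cbind(1, as.matrix(confounds))
  if (nrow(C) != nrow(X)) stop("confounds and data disagree on subjects")
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("rank-deficient confound matrix")
  res <- qr.resid(qrC, X)
  dimnames(res) <- dimnames(X)
  res
}

# canonical correlation core on centered full-rank inputs, via QR + SVD.
# Also returns orthonormal bases of both column spans rotated into canonical
# order (Gy, Gx): the leading min(p, q) columns are the normalized canonical
# variates, the trailing ones complete each span.
.cca_core <- function(Y, X) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2L, colMeans(Y))
  Xc <- sweep(X, 2L, colMeans(X))
  qy <- qr(Yc); qx <- qr(Xc)
  if (qy$rank < ncol(Yc) || qx$rank < ncol(Xc))
    stop("rank-deficient variable set in CCA")
  Qy <- qr.Q(qy)[, seq_len(ncol(Yc)), drop = FALSE]
  Qx <- qr.Q(qx)[, seq_len(ncol(Xc)), drop = FALSE]
  s <- svd(crossprod(Qy, Qx), nu = ncol(Yc), nv = ncol(Xc))
  k <- min(ncol(Yc), ncol(Xc))
  r <- pmin(pmax(s$d[seq_len(k)], 0), 1)
  Ry <- qr.R(qy); Rx <- qr.R(qx)
  A <- backsolve(Ry, s$u[, seq_len(k), drop = FALSE]) * sqrt(n - 1)
  B <- backsolve(Rx, s$v[, seq_len(k), drop = FALSE]) * sqrt(n - 1)
  rownames(A) <- colnames(Y); rownames(B) <- colnames(X)
  list(r = r, A = A, B = B,
       Gy = Qy %*% s$u, Gx = Qx %*% s$v)
}

#' Stepwise permutation canonical correlation analysis
#'
#' Estimates canonical modes relating two variable sets after confound
#' residualization, and tests each mode by permutation with the variance of
#' earlier modes removed. For mode k, both sides are projected onto the
#' canonical directions of modes k..K estimated on the unpermuted data, one
#' side's rows are permuted under the exchangeability restrictions, and the
#' Wilks-type statistic \code{-sum(log(1 - r^2))} over the remaining
#' correlations is recomputed. Family-wise error across modes uses the
#' permutation distribution of the maximum statistic over modes, followed by
#' a cumulative-maximum step so corrected p-values are non-decreasing over
#' modes.
#'
#' Permutations respect family structure when \code{family} is given: whole
#' families swap only with same-size families and subjects shuffle within
#' family (see \code{\link{make_family_permutations}}).
#'
#' @param Y numeric matrix, subjects x imaging features.
#' @param X numeric matrix, subjects x behavioral variables.
#' @param confounds optional confound matrix, residualized out of both sides.
#' @param family optional family id per subject.
#' @param n_perm number of permutations (identity included); default 1000.
#' @param seed optional RNG seed.
#' @param alpha FWE significance level for flagging modes; default 0.05.
#' @return object of class \code{cca_modes}: canonical correlations \code{r},
#'   uncorrected \code{p} and \code{fwe_p} per mode, significance flags,
#'   canonical weights \code{A} (imaging) and \code{B} (behavior), unit
#'   variance canonical variates \code{U} and \code{V} (subject scores), and
#'   the residualized inputs used.
#' @export
permcca <- function(Y, X, confounds = NULL, family = NULL,
                    n_perm = 1000, seed = NULL, alpha = 0.05) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X disagree on subjects")
  n <- nrow(Y)
  if (!is.null(family) && length(family) != n)
    stop("family labels must cover every subject")
  Yr <- residualize_confounds(Y, confounds)
  Xr <- residualize_confounds(X, confounds)
  full <- .cca_core(Yr, Xr)
  K <- length(full$r)
  perms <- if (is.null(family)) {
    sch <- permutation_scheme(n_perm, seed = seed)
    make_permutations(n, sch)
  } else {
    make_family_permutations(family, n_perm, seed = seed)
  }
  stat_tail <- function(r) rev(cumsum(rev(-log1p(-pmin(r^2, 1 - 1e-12)))))
  stats_obs <- stat_tail(full$r)
  # Deflation: at step k, drop the first k-1 canonical directions from each
  # side's orthonormal span basis, keeping the full remaining dimensionality
  # of both spans. On the unpermuted data this reproduces r[k:K]; under a
  # permutation the statistic is a full CCA of the permuted remaining
  # Y-span against the remaining X-span, so observed and null statistics
  # optimize over spaces of identical dimension.
  null_stats <- matrix(NA_real_, n_perm, K)
  null_stats[1L, ] <- stats_obs
  py <- ncol(full$Gy); qx <- ncol(full$Gx)
  for (b in seq_len(n_perm)[-1L]) {
    # cross-products of the permuted Y-span basis with the X-span basis;
    # the trailing submatrix [k:py, k:qx] is exactly the deflated problem
    M <- crossprod(full$Gy[perms[b, ], , drop = FALSE], full$Gx)
    for (k in seq_len(K)) {
      d <- svd(M[k:py, k:qx, drop = FALSE], nu = 0, nv = 0)$d
      null_stats[b, k] <- -sum(log1p(-pmin(d[seq_len(K - k + 1L)]^2,
                                           1 - 1e-12)))
    }
  }
  p_unc <- vapply(seq_len(K), function(k)
    mean(null_stats[, k] >= stats_obs[k]), numeric(1))
  null_max <- apply(null_stats, 1L, max)
  fwe_p <- cummax(vapply(stats_obs, function(o)
    mean(null_max >= o), numeric(1)))
  U <- sweep(Yr, 2L, colMeans(Yr)) %*% full$A
  V <- sweep(Xr, 2L, colMeans(Xr)) %*% full$B
  colnames(U) <- colnames(V) <- paste0("mode", seq_len(K))
  structure(list(r = full$r, p = p_unc, fwe_p = fwe_p,
                 significant = fwe_p < alpha,
                 A = full$A, B = full$B, U = U, V = V,
                 Y_resid = Yr, X_resid = Xr,
                 n_perm = n_perm, alpha = alpha),
            class = "cca_modes")
}

#' @export
print.cca_modes <- function(x, ...) {
  cat(sprintf("cca_modes: %d modes, %d permutations\n",
              length(x$r), x$n_perm))
  for (k in seq_along(x$r))
    cat(sprintf("  mode %d: r = %.3f, FWE-corrected p = %.4g%s\n",
                k, x$r[k], x$fwe_p[k],
                if (x$significant[k]) " *" else ""))
  invisible(x)
}

#' Cross-loadings of original variables on a canonical variate
#'
#' Pearson correlation of each (residualized) variable with the opposite
#' set's canonical variate for one mode. Constant variables yield \code{NA}
#' (flagged missing) rather than an error.
#'
#' @param variables numeric matrix, subjects x variables.
#' @param canonical_variate numeric vector of subject scores (unit variance).
#' @return named numeric vector of correlations.
#' @export
cross_loadings <- function(variables, canonical_variate) {
  V <- as.matrix(variables)
  u <- as.numeric(canonical_variate)
  if (nrow(V) != length(u)) stop("subjects disagree")
  sds <- apply(V, 2L, stats::sd)
  out <- rep(NA_real_, ncol(V))
  ok <- sds > 0
  if (any(ok)) out[ok] <- drop(stats::cor(V[, ok, drop = FALSE], u))
  names(out) <- colnames(V)
  if (any(!ok)) warning("constant variable(s): loading flagged missing")
  out
}

#' Single-component PCA of a cross-loading matrix
#'
#' Decomposes a regions x networks cross-loading matrix with one principal
#' component (uncentered SVD): the unit-norm network-space coefficients give
#' the involvement fingerprint of each network in the mode, and the region
#' scores (matrix projected on the coefficients) give the brain correlate.
#' The sign is fixed so the largest-magnitude coefficient is positive.
#'
#' @param crossloading_matrix numeric matrix, regions x networks.
#' @return list of class \code{loading_decomposition} with
#'   \code{coefficients} (networks), \code{scores} (regions) and
#'   \code{var_explained}.
#' @export
loading_pca <- function(crossloading_matrix) {
  M <- as.matrix(crossloading_matrix)
  if (all(M == 0)) stop("zero cross-loading matrix")
  s <- svd(M)
  v1 <- s$v[, 1L]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  coefficients <- stats::setNames(v1, colnames(M))
  scores <- drop(M %*% v1)
  names(scores) <- rownames(M)
  structure(list(coefficients = coefficients, scores = scores,
                 var_explained = s$d[1L]^2 / sum(s$d^2)),
            class = "loading_decomposition")
}

#' Median-split group comparison of behavioral variables
#'
#' Ranks subjects by their canonical subject score, splits them at the
#' median (ties to the low-scoring group), and compares each behavioral
#' variable between high- and low-scoring groups by one-way ANOVA, with
#' Bonferroni correction across modes and the variables of the domain.
#'
#' @param subject_scores numeric vector of canonical variate values.
#' @param behavior numeric matrix or data frame, subjects x variables.
#' @param variables column names of \code{behavior} to test; default all.
#' @param n_modes Bonferroni factor for the number of modes tested jointly;
#'   default 1.
#' @return data frame: per variable the low/high group means, F statistic,
#'   uncorrected p and Bonferroni-corrected p.
#' @export
split_and_compare <- function(subject_scores, behavior,
                              variables = colnames(behavior), n_modes = 1L) {
  s <- as.numeric(subject_scores)
  B <- as.matrix(behavior)
  if (length(s) != nrow(B)) stop("scores and behavior disagree on subjects")
  if (stats::sd(s) == 0) stop("all subject scores identical: no split")
  grp <- factor(ifelse(s <= stats::median(s), "low", "high"),
                levels = c("low", "high"))
  k_bonf <- n_modes * length(variables)
  rows <- lapply(variables, function(v) {
    y <- B[, v]
    fit <- stats::lm(y ~ grp)
    av <- stats::anova(fit)
    data.frame(variable = v,
               mean_low = mean(y[grp == "low"]),
               mean_high = mean(y[grp == "high"]),
               F = av$`F value`[1L],
               p = av$`Pr(>F)`[1L],
               p_bonf = min(1, av$`Pr(>F)`[1L] * k_bonf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
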