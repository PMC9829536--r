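#' Contrast t-statistics from a mass-univariate GLM
#'
#' Fits the same linear model to every element (column of \code{data}) by
#' ordinary least squares and returns the t-statistic of the supplied
#' contrast with residual degrees of freedom n - p.
#'
#' @param data numeric matrix, observations x elements.
#' @param design numeric design matrix, observations x predictors (include
#'   the intercept explicitly).
#' @param contrast numeric contrast vector of length \code{ncol(design)}.
#' @return numeric vector of t-statistics, one per element.
#' @export
glm_tstats <- function(data, design, contrast) {
  X <- as.matrix(design)
  Y <- as.matrix(data)
  n <- nrow(X); p <- ncol(X)
  if (nrow(Y) != n) stop("data and design disagree on observations")
  if (length(contrast) != p) stop("contrast length must equal predictors")
  if (qr(X)$rank < p) stop("rank-deficient design")
  if (n < p + 2L) stop("need at least predictors + 2 observations")
  pre <- .glm_precompute(X, contrast)
  .glm_tstats_core(Y, X, pre, colSums(Y^2))
}

.glm_precompute <- function(X, contrast) {
  XtXi <- chol2inv(chol(crossprod(X)))
  list(XtXi = XtXi,
       contrast = as.numeric(contrast),
       cvc = drop(t(contrast) %*% XtXi %*% contrast),
       df = nrow(X) - ncol(X))
}

# t-stats given a (possibly row-permuted) response; ss_y = colSums(Y^2),
# which is permutation-invariant and precomputed by callers in hot loops
.glm_tstats_core <- function(Yp, X, pre, ss_y) {
  XtY <- crossprod(X, Yp)
  beta <- pre$XtXi %*% XtY
  rss <- pmax(ss_y - colSums(beta * XtY), 0)
  sigma2 <- rss / pre$df
  num <- drop(crossprod(pre$contrast, beta))
  tval <- num / sqrt(sigma2 * pre$cvc)
  # an exact fit with a negligible contrast (relative to the data scale)
  # is a zero effect, not an infinite statistic
  tiny <- ss_y * 1e-12
  exact <- rss <= tiny & num^2 <= pre$cvc * tiny
  tval[exact] <- 0
  tval
}

#' Permutation inference with max-statistic FWE correction
#'
#' Recomputes the contrast statistic under a stream of permutations (identity
#' first), optionally applies one-dimensional TFCE along the element axis
#' within each network, and corrects family-wise over all elements, networks
#' and both signed tails via the permutation distribution of the maximum
#' enhanced statistic. \code{fwe_p} of an element is the fraction of
#' permutations (identity counted) whose maximum reaches that element's
#' observed enhanced value, so p-values are never below \code{1/n_perm}.
#'
#' @param data numeric matrix, observations x (elements * networks); columns
#'   ordered network by network (all elements of network 1, then network 2,
#'   ...). Elements are time points (stage-1 inference) or regions (stage-2).
#' @param design design matrix, observations x predictors.
#' @param contrast contrast vector.
#' @param scheme a \code{\link{permutation_scheme}}.
#' @param tfce optional \code{\link{tfce_params}}; when supplied, each
#'   network's statistic series is cluster-enhanced per tail before taking
#'   maxima (use only when elements are ordered time points).
#' @param n_networks number of networks the columns are grouped into.
#' @param groups optional group labels forwarded to
#'   \code{\link{make_permutations}} for enumeration.
#' @param element_type \code{"time"} or \code{"regions"}, recorded in the
#'   result.
#' @return an object of class \code{permutation_result}: observed statistics
#'   and enhanced statistics (elements x networks), per-tail and two-tailed
#'   FWE-corrected p-values, \code{-log10} p, the null max distribution and
#'   the correction family description.
#' @export
permute_and_correct <- function(data, design, contrast, scheme,
                                tfce = NULL, n_networks = 1L,
                                groups = NULL,
                                element_type = c("time", "regions")) {
  element_type <- match.arg(element_type)
  X <- as.matrix(design)
  Y <- as.matrix(data)
  if (ncol(Y) %% n_networks != 0L)
    stop("columns must divide evenly into networks")
  m <- ncol(Y) %/% n_networks
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design")
  perms <- make_permutations(nrow(Y), scheme, groups = groups)
  n_perm <- nrow(perms)
  pre <- .glm_precompute(X, contrast)
  ss_y <- colSums(Y^2)
  enhance <- function(tval) {
    tm <- matrix(tval, m, n_networks)
    if (is.null(tfce)) return(list(pos = tm * (tm > 0), neg = -tm * (tm < 0)))
    dh <- .tfce_dh(tfce, max(abs(tm)))
    if (is.na(dh)) {
      z <- matrix(0, m, n_networks)
      return(list(pos = z, neg = z))
    }
    pos <- neg <- matrix(0, m, n_networks)
    for (k in seq_len(n_networks)) {
      pos[, k] <- .tfce1d_pos(tm[, k], tfce$E, tfce$H, dh)
      neg[, k] <- .tfce1d_pos(-tm[, k], tfce$E, tfce$H, dh)
    }
    list(pos = pos, neg = neg)
  }
  null_max <- numeric(n_perm)
  obs <- NULL
  for (b in seq_len(n_perm)) {
    Yp <- if (b == 1L) Y else Y[perms[b, ], , drop = FALSE]
    tval <- .glm_tstats_core(Yp, X, pre, ss_y)
    e <- enhance(tval)
    null_max[b] <- max(e$pos, e$neg)
    if (b == 1L) obs <- c(e, list(tval = matrix(tval, m, n_networks)))
  }
  sorted_null <- sort(null_max)
  count_ge <- function(v) {
    # fraction of permutation maxima reaching each observed value;
    # findInterval(..., left.open) counts null maxima strictly below v
    matrix((n_perm - findInterval(as.numeric(v), sorted_null,
                                  left.open = TRUE)) / n_perm,
           m, n_networks)
  }
  fwe_pos <- count_ge(obs$pos)
  fwe_neg <- count_ge(obs$neg)
  fwe_two <- count_ge(pmax(obs$pos, obs$neg))
  structure(list(
    tstat = obs$tval, enhanced_pos = obs$pos, enhanced_neg = obs$neg,
    fwe_p_pos = fwe_pos, fwe_p_neg = fwe_neg, fwe_p = fwe_two,
    neg_log10_fwe_p = -log10(fwe_two),
    null_max = null_max, n_perm = n_perm,
    enumerated = isTRUE(attr(perms, "enumerated")),
    family = sprintf("%s x networks x tails", element_type)),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %d x %d elements, %d permutations (%s), FWE over %s\n",
    nrow(x$tstat), ncol(x$tstat), x$n_perm,
    if (x$enumerated) "enumerated" else "Monte-Carlo", x$family))
  cat(sprintf("  min FWE-corrected p = %.4g\n", min(x$fwe_p)))
  invisible(x)
}

#' Spearman partial-correlation specificity analysis
#'
#' Relates each receptor's regional expression map to a regional effect map
#' (e.g. stimulation-evoked connectivity change) while adjusting for the
#' expression of receptors from other neuromodulator families. All variables
#' are rank-transformed (average ranks); target and effect ranks are
#' residualized on the covariate ranks and Pearson-correlated. Significance
#' is assessed by permuting the effect map's region labels, with FWE
#' correction across receptors via the null distribution of the maximum
#' absolute partial correlation. Same-family receptors should be excluded
#' from the covariates by the caller, since their strong intrinsic
#' co-expression would absorb the signal of interest.
#'
#' @param receptor_maps numeric matrix, regions x receptors.
#' @param effect_map numeric vector over the same regions.
#' @param covariate_maps optional numeric matrix, regions x covariates.
#' @param n_perm number of permutations, identity included; default 1000.
#' @param alpha FWE significance level; default 0.025.
#' @param seed optional RNG seed.
#' @return data frame with one row per receptor: partial Spearman rho,
#'   FWE-corrected p and significance flag.
#' @export
spearman_partial_specificity <- function(receptor_maps, effect_map,
                                         covariate_maps = NULL,
                                         n_perm = 1000, alpha = 0.025,
                                         seed = NULL) {
  Rm <- as.matrix(receptor_maps)
  y <- as.numeric(effect_map)
  n <- length(y)
  if (nrow(Rm) != n) stop("receptor maps and effect map disagree on regions")
  if (n < 5L) stop("need at least 5 regions")
  if (stats::sd(y) == 0) stop("constant effect map")
  rank_cols <- function(M) apply(as.matrix(M), 2L, rank, ties.method = "average")
  Rr <- rank_cols(Rm)
  yr <- rank(y, ties.method = "average")
  if (!is.null(covariate_maps)) {
    Cr <- cbind(1, rank_cols(covariate_maps))
    qrC <- qr(Cr)
    Rres <- qr.resid(qrC, Rr)
    resid_y <- function(v) qr.resid(qrC, v)
  } else {
    Rres <- sweep(Rr, 2L, colMeans(Rr))
    resid_y <- function(v) v - mean(v)
  }
  partial_rho <- function(yperm) {
    e <- resid_y(yperm)
    drop(stats::cor(Rres, e))
  }
  rho_obs <- partial_rho(yr)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- if (b == 1L) yr else yr[sample.int(n)]
      max(abs(partial_rho(yp)))
    }, numeric(1))
  })
  fwe_p <- vapply(abs(rho_obs), function(o) mean(null_max >= o), numeric(1))
  data.frame(receptor = colnames(Rm) %||% paste0("r", seq_len(ncol(Rm))),
             rho = rho_obs, fwe_p = fwe_p,
             significant = fwe_p < alpha, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
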