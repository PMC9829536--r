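# Shared helper: least squares with an intercept and demeaned predictors.
# Returns only the predictor coefficients (the intercept absorbs means).
.ols_coef <- function(X, Y) {
  stats::lm.fit(X, Y)$coefficients
}

# demean columns and refuse near-collinear template sets
.check_design <- function(A, what = "templates", max_cond = 1e8) {
  Ac <- sweep(A, 2L, colMeans(A))
  d <- svd(Ac, nu = 0, nv = 0)$d
  if (min(d) == 0 || max(d) / min(d) > max_cond) {
    cc <- abs(stats::cor(Ac))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "collinear %s (condition number %.3g): most collinear pair '%s' and '%s'",
      what, max(d) / min(d), colnames(A)[worst[1L]], colnames(A)[worst[2L]]))
  }
  Ac
}

#' Dual regression, stage 1: spatial regression of templates into fMRI
#'
#' For each time point, regresses the regional signal vector on all template
#' maps jointly (ordinary least squares with an intercept; template columns
#' demeaned across regions). The K coefficients over time form the network
#' amplitude time-courses.
#'
#' @param run a \code{\link{parcellated_ts}}.
#' @param templates an \code{\link{expression_atlas}} whose regions match the
#'   run's regions (matched by region id).
#' @return a \code{\link{network_timecourses}}, time x networks.
#' @export
dr_stage1 <- function(run, templates) {
  stopifnot(inherits(run, "parcellated_ts"),
            inherits(templates, "expression_atlas"))
  A <- templates$values
  regions <- colnames(run$values)
  if (!all(regions %in% rownames(A)))
    stop("run contains regions absent from the template atlas")
  A <- A[regions, , drop = FALSE]
  if (nrow(run$values) < ncol(A) + 1L)
    stop("need more time points than templates")
  Ac <- .check_design(A)
  X <- cbind(`(Intercept)` = 1, Ac)
  B <- .ols_coef(X, t(run$values))       # (K+1) x time
  tc <- t(B[-1L, , drop = FALSE])
  colnames(tc) <- colnames(A)
  network_timecourses(tc)
}

#' Standardize network time-courses
#'
#' Centers each column and scales it to unit (sample) standard deviation, as
#' applied between the two regression stages.
#'
#' @param tc a \code{\link{network_timecourses}}.
#' @return the standardized \code{\link{network_timecourses}}.
#' @export
standardize_timecourses <- function(tc) {
  stopifnot(inherits(tc, "network_timecourses"))
  sds <- apply(tc$values, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant time-course column(s): ",
         paste(colnames(tc$values)[sds == 0], collapse = ", "))
  v <- scale(tc$values)
  attr(v, "scaled:center") <- NULL
  attr(v, "scaled:scale") <- NULL
  out <- network_timecourses(v, standardized = TRUE,
                             baseline_corrected = tc$baseline_corrected)
  out
}

#' Dual regression, stage 2: temporal regression of time-courses into fMRI
#'
#' For each region, regresses that region's time-series on all K standardized
#' network time-courses jointly (OLS with intercept). The coefficients form
#' the region's row of the subject's functional connectivity map.
#'
#' @param run a \code{\link{parcellated_ts}}.
#' @param tc a standardized \code{\link{network_timecourses}} from stage 1.
#' @return a \code{\link{connectivity_matrix}}, regions x networks.
#' @export
dr_stage2 <- function(run, tc) {
  stopifnot(inherits(run, "parcellated_ts"),
            inherits(tc, "network_timecourses"))
  if (!tc$standardized)
    stop("stage-2 time-courses must be standardized first")
  if (nrow(tc$values) != nrow(run$values))
    stop("time dimension of run and time-courses differ")
  Tc <- .check_design(tc$values, what = "time-courses")
  X <- cbind(`(Intercept)` = 1, Tc)
  B <- .ols_coef(X, run$values)          # (K+1) x regions
  fc <- t(B[-1L, , drop = FALSE])
  dimnames(fc) <- list(colnames(run$values), colnames(tc$values))
  connectivity_matrix(fc, subject = run$subject)
}

#' Residualized stage 1: spatial regression with confound templates
#'
#' Fits the joint spatial regression on the stacked design of interest plus
#' confound templates per time point, returning only the interest
#' coefficients. By the Frisch-Waugh theorem these equal the regression of
#' confound-residualized signal on confound-residualized interest templates,
#' so the returned amplitudes reflect spatial variance unique to the
#' templates of interest.
#'
#' @param run a \code{\link{parcellated_ts}}.
#' @param templates an \code{\link{expression_atlas}} of interest templates.
#' @param confounds an \code{\link{expression_atlas}} of confound templates.
#' @return a \code{\link{network_timecourses}} with interest columns only.
#' @export
residualized_dr_stage1 <- function(run, templates, confounds) {
  stopifnot(inherits(run, "parcellated_ts"),
            inherits(templates, "expression_atlas"),
            inherits(confounds, "expression_atlas"))
  regions <- colnames(run$values)
  A <- templates$values[regions, , drop = FALSE]
  C <- confounds$values[regions, , drop = FALSE]
  shared <- intersect(colnames(A), colnames(C))
  if (length(shared))
    stop("template(s) appear in both interest and confound sets: ",
         paste(shared, collapse = ", "))
  dup <- outer(seq_len(ncol(A)), seq_len(ncol(C)), Vectorize(function(i, j)
    isTRUE(all.equal(unname(A[, i]), unname(C[, j])))))
  if (any(dup))
    stop("a confound template is numerically identical to an interest template")
  full <- cbind(A, C)
  Fc <- .check_design(full, what = "stacked templates")
  X <- cbind(`(Intercept)` = 1, Fc)
  B <- .ols_coef(X, t(run$values))
  tc <- t(B[1L + seq_len(ncol(A)), , drop = FALSE])
  colnames(tc) <- colnames(A)
  network_timecourses(tc)
}

#' Baseline-correct amplitude time-courses
#'
#' Subtracts from each network's trace the mean over the first
#' \code{n_baseline} volumes (the pre-stimulation rest period), so amplitude
#' changes are expressed relative to the pre-stimulus baseline.
#'
#' @param tc a \code{\link{network_timecourses}}.
#' @param n_baseline number of leading volumes defining the baseline;
#'   default 40.
#' @return the corrected \code{\link{network_timecourses}}.
#' @export
baseline_correct <- function(tc, n_baseline = 40) {
  stopifnot(inherits(tc, "network_timecourses"))
  if (n_baseline <= 0) stop("n_baseline must be positive")
  if (n_baseline >= nrow(tc$values))
    stop("n_baseline must be smaller than the run length")
  mu <- colMeans(tc$values[seq_len(n_baseline), , drop = FALSE])
  network_timecourses(sweep(tc$values, 2L, mu),
                      standardized = FALSE, baseline_corrected = TRUE)
}

#' Average connectivity maps across runs of one subject
#'
#' @param maps list of \code{\link{connectivity_matrix}} objects with
#'   identical shape, network order and subject.
#' @return a single element-wise mean \code{\link{connectivity_matrix}}.
#' @export
average_runs <- function(maps) {
  stopifnot(length(maps) >= 1L,
            all(vapply(maps, inherits, logical(1), "connectivity_matrix")))
  subj <- unique(vapply(maps, `[[`, character(1), "subject"))
  if (length(subj) != 1L)
    stop("cannot average runs across different subjects: ",
         paste(subj, collapse = ", "))
  ref <- dimnames(maps[[1L]]$values)
  for (m in maps[-1L]) {
    if (!identical(dim(m$values), dim(maps[[1L]]$values)) ||
        !identical(dimnames(m$values), ref))
      stop("all maps must share shape, region order and network order")
  }
  avg <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  connectivity_matrix(avg, subject = subj)
}
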