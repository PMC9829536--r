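#' Expression atlas container
#'
#' A regions-by-genes matrix of normalized regional expression, used as the
#' spatial template set of the dual regression. Row names are region ids,
#' column names gene (network) names.
#'
#' @param values numeric matrix, regions x genes, with dimnames.
#' @param normalization one of \code{"raw_log2"}, \code{"zscore"},
#'   \code{"rank_inverse_normal"} recording how columns were scaled.
#' @return An object of class \code{expression_atlas}: a list with elements
#'   \code{values} and \code{normalization}.
#' @export
expression_atlas <- function(values,
                             normalization = c("raw_log2", "zscore",
                                               "rank_inverse_normal")) {
  normalization <- match.arg(normalization)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression atlas requires region row names and gene column names")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression atlas must not contain missing or non-finite values")
  if (normalization == "zscore") {
    mu <- colMeans(values)
    sds <- apply(values, 2L, stats::sd)
    if (any(abs(mu) > 1e-10) || any(abs(sds - 1) > 1e-10))
      stop("zscore-tagged atlas columns must have mean 0 and unit sd")
  }
  structure(list(values = values, normalization = normalization),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("expression_atlas: %d regions x %d genes (%s)\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' Parcellated fMRI time-series for one run
#'
#' @param values numeric matrix, time x regions; column names are region ids.
#' @param tr sampling interval in seconds.
#' @param subject,run identifier strings.
#' @return An object of class \code{parcellated_ts}.
#' @export
parcellated_ts <- function(values, tr, subject = "s1", run = "r1") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time-series must not contain missing values")
  if (is.null(colnames(values)))
    stop("time-series requires region ids as column names")
  if (!is.numeric(tr) || tr <= 0) stop("tr must be a positive number")
  structure(list(values = values, tr = tr,
                 subject = as.character(subject), run = as.character(run)),
            class = "parcellated_ts")
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("parcellated_ts: %d volumes x %d regions (TR = %gs, %s/%s)\n",
              nrow(x$values), ncol(x$values), x$tr, x$subject, x$run))
  invisible(x)
}

#' Network amplitude time-courses (dual-regression stage 1 output)
#'
#' @param values numeric matrix, time x networks; column names are network
#'   (gene) names.
#' @param standardized,baseline_corrected logical flags recording processing.
#' @return An object of class \code{network_timecourses}.
#' @export
network_timecourses <- function(values, standardized = FALSE,
                                baseline_corrected = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("time-courses must not contain missing values")
  if (is.null(colnames(values)))
    stop("time-courses require network names as column names")
  structure(list(values = values,
                 standardized = isTRUE(standardized),
                 baseline_corrected = isTRUE(baseline_corrected)),
            class = "network_timecourses")
}

#' @export
print.network_timecourses <- function(x, ...) {
  cat(sprintf(
    "network_timecourses: %d volumes x %d networks (standardized: %s, baseline-corrected: %s)\n",
    nrow(x$values), ncol(x$values), x$standardized, x$baseline_corrected))
  invisible(x)
}

#' Functional connectivity map (dual-regression stage 2 output)
#'
#' @param values numeric matrix, regions x networks, regression coefficients
#'   in signal units per unit (standardized) amplitude.
#' @param subject subject identifier.
#' @return An object of class \code{connectivity_matrix}.
#' @export
connectivity_matrix <- function(values, subject = "s1") {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("connectivity coefficients must be finite")
  structure(list(values = values, subject = as.character(subject)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix: %d regions x %d networks (subject %s)\n",
              nrow(x$values), ncol(x$values), x$subject))
  invisible(x)
}
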