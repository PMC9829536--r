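#' TFCE parameters
#'
#' Parameters of one-dimensional threshold-free cluster enhancement. The
#' defaults are the reference implementation's enhancement exponents
#' (extent exponent E = 0.5, height exponent H = 2) with an adaptive step
#' of \code{max(|stat|)/n_steps}; \code{dh} overrides the adaptive step.
#'
#' @param E extent exponent (> 0).
#' @param H height exponent (> 0).
#' @param n_steps number of integration steps when \code{dh} is adaptive.
#' @param dh explicit integration step in statistic units, or \code{NULL}
#'   for the adaptive step.
#' @return a list of class \code{tfce_params}.
#' @export
tfce_params <- function(E = 0.5, H = 2, n_steps = 100, dh = NULL) {
  if (E <= 0 || H <= 0) stop("TFCE exponents must be positive")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  if (is.null(dh) && (!is.numeric(n_steps) || n_steps < 1))
    stop("n_steps must be a positive count")
  structure(list(E = E, H = H, n_steps = n_steps, dh = dh),
            class = "tfce_params")
}

.tfce_dh <- function(params, scale_max) {
  if (!is.null(params$dh)) return(params$dh)
  if (scale_max <= 0) return(NA_real_)
  scale_max / params$n_steps
}

#' One-dimensional threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over thresholds along a 1-D
#' statistic series: \code{enhanced(t) = sum_h extent(t,h)^E * h^H * dh}
#' over thresholds \code{h = dh, 2dh, ... <= stat(t)}, where the extent is
#' the length of the contiguous suprathreshold run containing \code{t}.
#' Positive values are enhanced on the series itself and negative values on
#' its negation; the result carries the original sign.
#'
#' @param stat numeric vector, e.g. a per-time-point t-statistic series.
#' @param params a \code{\link{tfce_params}}.
#' @return numeric vector of signed enhanced values, same length as
#'   \code{stat}.
#' @export
tfce_1d <- function(stat, params = tfce_params()) {
  stopifnot(inherits(params, "tfce_params"))
  stat <- as.numeric(stat)
  if (length(stat) == 0L) return(numeric(0))
  dh <- .tfce_dh(params, max(abs(stat)))
  if (is.na(dh)) return(numeric(length(stat)))
  .tfce1d_pos(stat, params$E, params$H, dh) -
    .tfce1d_pos(-stat, params$E, params$H, dh)
}
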