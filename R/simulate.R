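#' Optogenetic stimulation block design
#'
#' Describes the on/off stimulation protocol of one run: a pre-stimulation
#' baseline followed by repeated cycles of light-on then rest. Defaults match
#' the protocol the analysis pipeline is built around: 6 cycles of 20 s
#' stimulation followed by 40 s rest at a 2 s sampling interval, preceded by
#' 40 baseline volumes.
#'
#' @param n_cycles number of stimulation cycles.
#' @param on_s stimulation duration per cycle, seconds.
#' @param off_s rest duration per cycle, seconds.
#' @param tr sampling interval, seconds; on/off durations must be divisible
#'   by it.
#' @param n_baseline_volumes volumes acquired before the first cycle.
#' @return list of class \code{stimulus_design}.
#' @export
stimulus_design <- function(n_cycles = 6, on_s = 20, off_s = 40, tr = 2,
                            n_baseline_volumes = 40) {
  if (tr <= 0) stop("tr must be positive")
  if (n_cycles < 0 || n_baseline_volumes < 0)
    stop("counts must be non-negative")
  if (on_s %% tr != 0 || off_s %% tr != 0)
    stop("on/off durations must be divisible by the sampling interval")
  structure(list(n_cycles = as.integer(n_cycles), on_s = on_s, off_s = off_s,
                 tr = tr,
                 n_baseline_volumes = as.integer(n_baseline_volumes)),
            class = "stimulus_design")
}

#' Binary stimulation vector over volumes
#'
#' Expands a \code{\link{stimulus_design}} into a 0/1 indicator per volume:
#' baseline zeros, then per cycle the on-volumes of ones followed by the
#' off-volumes of zeros. Under the defaults this is 40 + 6 x (10 + 20) = 220
#' volumes with 60 stimulation-on volumes.
#'
#' @param design a \code{\link{stimulus_design}}.
#' @return integer vector of 0/1 over volumes.
#' @export
make_block_design <- function(design = stimulus_design()) {
  stopifnot(inherits(design, "stimulus_design"))
  on_vol <- design$on_s / design$tr
  off_vol <- design$off_s / design$tr
  c(rep(0L, design$n_baseline_volumes),
    rep(c(rep(1L, on_vol), rep(0L, off_vol)), design$n_cycles))
}

# single-gamma response kernel in sampling-interval units (shape 6, scale 1)
.gamma_kernel <- function(len = 16, shape = 6, scale = 1) {
  k <- stats::dgamma(seq_len(len) - 1, shape = shape, scale = scale)
  k / sum(k)
}

#' Synthetic expression atlas
#'
#' Draws a regions x networks template matrix from a correlated Gaussian
#' (equicorrelated across networks, emulating receptor co-expression), then
#' z-scores each column across regions. Defaults mirror the mouse geometry:
#' 90 regions and 9 receptor-gene networks with inter-template correlation
#' 0.3.
#'
#' @param n_regions number of regions.
#' @param n_networks number of networks (template columns).
#' @param cor_between latent correlation between template columns, in
#'   \code{[0, 1)}.
#' @param network_names template names; defaults to receptor-gene style
#'   names.
#' @param seed optional RNG seed.
#' @return an \code{\link{expression_atlas}} tagged \code{zscore}.
#' @export
synthetic_atlas <- function(n_regions = 90, n_networks = 9,
                            cor_between = 0.3, network_names = NULL,
                            seed = NULL) {
  if (cor_between < 0 || cor_between >= 1)
    stop("cor_between must lie in [0, 1)")
  if (is.null(network_names)) {
    default_names <- c("Htr1a", "Htr1b", "Htr1f", "Htr2a", "Htr2c",
                       "Htr3a", "Htr3b", "Htr4", "Htr5b")
    network_names <- if (n_networks <= length(default_names))
      default_names[seq_len(n_networks)]
    else paste0("net", seq_len(n_networks))
  }
  with_seed(seed, {
    Sg <- matrix(cor_between, n_networks, n_networks)
    diag(Sg) <- 1
    Z <- matrix(stats::rnorm(n_regions * n_networks), n_regions) %*% chol(Sg)
    Z <- apply(Z, 2L, function(x) (x - mean(x)) / stats::sd(x))
    dimnames(Z) <- list(sprintf("R%03d", seq_len(n_regions)), network_names)
    expression_atlas(Z, normalization = "zscore")
  })
}

#' Simulate one parcellated ofMRI run
#'
#' Generates \code{signal = templates \%*\% t(timecourses) + noise}: latent
#' network time-courses follow the stimulation boxcar (optionally convolved
#' with a single-gamma response kernel), scaled by per-network amplitudes,
#' mixed through the template maps, with i.i.d. Gaussian noise (optionally
#' AR(1)-filtered in time). This is exactly the linear mixing model under
#' which dual regression recovers the latent structure.
#'
#' @param atlas an \code{\link{expression_atlas}} of K templates.
#' @param amplitude numeric vector of per-network amplitude multipliers
#'   (recycled to K).
#' @param design a \code{\link{stimulus_design}}.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param convolve convolve the boxcar with the gamma kernel; default FALSE.
#' @param ar AR(1) coefficient for temporal noise autocorrelation; 0 = white.
#' @param subject,run identifiers.
#' @param seed optional RNG seed.
#' @return a \code{\link{parcellated_ts}}; the latent time-courses are
#'   attached as attribute \code{"latent_tc"}.
#' @export
simulate_ofmri_run <- function(atlas, amplitude = 1,
                               design = stimulus_design(),
                               noise_sd = 1, convolve = FALSE, ar = 0,
                               subject = "s1", run = "r1", seed = NULL) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  A <- atlas$values
  K <- ncol(A)
  amplitude <- rep_len(amplitude, K)
  stim <- make_block_design(design)
  course <- as.numeric(stim)
  if (convolve) {
    kern <- .gamma_kernel()
    course <- stats::convolve(course, rev(kern), type = "open")
    course <- course[seq_along(stim)]
  }
  tc <- outer(course, amplitude)                  # time x K
  colnames(tc) <- colnames(A)
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(stim) * nrow(A), sd = noise_sd),
                    length(stim), nrow(A))
    if (ar != 0 && noise_sd > 0)
      noise <- apply(noise, 2L, function(e)
        as.numeric(stats::filter(e, ar, method = "recursive"))) *
        sqrt(1 - ar^2)
    vals <- tc %*% t(A) + noise
    colnames(vals) <- rownames(A)
    out <- parcellated_ts(vals, tr = design$tr, subject = subject, run = run)
    attr(out, "latent_tc") <- tc
    out
  })
}

#' Simulate a two-group ofMRI study
#'
#' Generates runs for two groups (e.g. opsin-expressing vs control animals)
#' with group-specific amplitude multipliers: the default geometry is 8
#' effective runs in group 1 versus 4 in group 2. Under the null set both
#' amplitude vectors to zero.
#'
#' @param atlas an \code{\link{expression_atlas}}.
#' @param n_group1,n_group2 runs per group.
#' @param amplitude_group1,amplitude_group2 per-network amplitudes.
#' @param design a \code{\link{stimulus_design}}.
#' @param noise_sd noise standard deviation.
#' @param seed optional RNG seed.
#' @return list with \code{runs} (list of \code{\link{parcellated_ts}}) and
#'   \code{group} (factor of group labels per run).
#' @export
simulate_ofmri_study <- function(atlas, n_group1 = 8, n_group2 = 4,
                                 amplitude_group1 = 1, amplitude_group2 = 0,
                                 design = stimulus_design(), noise_sd = 1,
                                 seed = NULL) {
  with_seed(seed, {
    g <- factor(rep(c("group1", "group2"), c(n_group1, n_group2)),
                levels = c("group1", "group2"))
    amps <- list(group1 = amplitude_group1, group2 = amplitude_group2)
    runs <- lapply(seq_along(g), function(i)
      simulate_ofmri_run(atlas, amplitude = amps[[as.character(g[i])]],
                         design = design, noise_sd = noise_sd,
                         subject = sprintf("s%02d", i),
                         run = sprintf("r%02d", i)))
    list(runs = runs, group = g)
  })
}

#' Simulate a population with a planted brain-behavior canonical mode
#'
#' Each subject draws a latent imaging factor \code{u ~ N(0,1)} and a
#' behavioral factor \code{v = rho*u + sqrt(1-rho^2)*e}. The latent occupies
#' one coordinate of each side's feature space (the remaining coordinates
#' are independent noise) and each side is then mixed through a fixed random
#' orthonormal rotation, so the population's first (and only) canonical
#' correlation is exactly \code{rho} while every observed feature carries a
#' share of the latent. Optional confounds with known coefficients are added
#' to the imaging features; family ids are assigned by the declared family
#' sizes. Defaults mirror the human analysis scale: 20 imaging features and
#' 45 behavioral variables.
#'
#' @param n_subjects number of subjects (>= 20).
#' @param rho true canonical correlation in \code{[0, 1)}.
#' @param n_imaging,n_behavior numbers of imaging/behavioral variables.
#' @param noise_sd feature noise standard deviation.
#' @param family_sizes integer vector of family sizes summing to
#'   \code{n_subjects}; default: families of two plus a singleton remainder.
#' @param confounds subjects x q confound matrix to mix into the imaging
#'   features, or \code{NULL}.
#' @param confound_coef coefficient applied to each confound column.
#' @param seed optional RNG seed.
#' @return list with \code{imaging}, \code{behavior}, \code{confounds},
#'   \code{family} and \code{truth} (latents, weights, rho).
#' @export
simulate_population <- function(n_subjects = 200, rho = 0.5,
                                n_imaging = 20, n_behavior = 45,
                                noise_sd = 1, family_sizes = NULL,
                                confounds = NULL, confound_coef = 1,
                                seed = NULL) {
  if (n_subjects < 20) stop("need at least 20 subjects")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (is.null(family_sizes)) {
    n_pairs <- n_subjects %/% 2L
    family_sizes <- c(rep(2L, n_pairs), rep(1L, n_subjects - 2L * n_pairs))
  }
  if (sum(family_sizes) != n_subjects)
    stop("family sizes must sum to the number of subjects")
  with_seed(seed, {
    u <- stats::rnorm(n_subjects)
    v <- rho * u + sqrt(1 - rho^2) * stats::rnorm(n_subjects)
    # random orthonormal rotations mixing the latent coordinate into all
    # features without changing the canonical structure
    rot <- function(p) qr.Q(qr(matrix(stats::rnorm(p * p), p)))
    Q_img <- rot(n_imaging)
    Q_beh <- rot(n_behavior)
    img_coord <- cbind(u, matrix(stats::rnorm(n_subjects * (n_imaging - 1L),
                                              sd = noise_sd), n_subjects))
    beh_coord <- cbind(v, matrix(stats::rnorm(n_subjects * (n_behavior - 1L),
                                              sd = noise_sd), n_subjects))
    imaging <- img_coord %*% t(Q_img)
    behavior <- beh_coord %*% t(Q_beh)
    w_img <- Q_img[, 1L]
    w_beh <- Q_beh[, 1L]
    if (!is.null(confounds)) {
      Cm <- as.matrix(confounds)
      if (nrow(Cm) != n_subjects) stop("confound rows must match subjects")
      imaging <- imaging + Cm %*%
        matrix(confound_coef, ncol(Cm), n_imaging)
    }
    colnames(imaging) <- sprintf("img%02d", seq_len(n_imaging))
    colnames(behavior) <- sprintf("beh%02d", seq_len(n_behavior))
    family <- rep(sprintf("f%03d", seq_along(family_sizes)), family_sizes)
    list(imaging = imaging, behavior = behavior,
         confounds = if (is.null(confounds)) NULL else as.matrix(confounds),
         family = family,
         truth = list(u = u, v = v, w_img = w_img, w_beh = w_beh, rho = rho))
  })
}
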