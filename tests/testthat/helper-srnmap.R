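# Shared fixture builders; everything is generated in code under fixed seeds.

# small bilateral parcellation with two midline regions
toy_region_atlas <- function(n_pairs = 4, n_midline = 2, seed = 11) {
  set.seed(seed)
  left <- sprintf("L%02d", seq_len(n_pairs))
  right <- sprintf("R%02d", seq_len(n_pairs))
  mid <- sprintf("M%02d", seq_len(n_midline))
  ids <- c(left, right, mid)
  n <- length(ids)
  region_atlas(data.frame(
    region_id = ids,
    label = paste0("area_", ids),
    hemisphere = c(rep("left", n_pairs), rep("right", n_pairs),
                   rep("midline", n_midline)),
    homolog_id = c(right, left, rep(NA_character_, n_midline)),
    cx = c(-abs(rnorm(n_pairs, 20, 5)), abs(rnorm(n_pairs, 20, 5)),
           rep(0, n_midline)),
    cy = rnorm(n, 0, 20), cz = rnorm(n, 0, 20),
    stringsAsFactors = FALSE))
}

# noise-free linear mixing run: signal = tc %*% t(templates)
mixing_run <- function(atlas, tc, noise_sd = 0, seed = 1, tr = 2) {
  set.seed(seed)
  vals <- tc %*% t(atlas$values)
  if (noise_sd > 0)
    vals <- vals + matrix(rnorm(length(vals), sd = noise_sd), nrow(vals))
  colnames(vals) <- rownames(atlas$values)
  parcellated_ts(vals, tr = tr)
}

random_timecourses <- function(n_time, k, seed = 1) {
  set.seed(seed)
  tc <- matrix(rnorm(n_time * k), n_time, k)
  colnames(tc) <- paste0("net", seq_len(k))
  tc
}

# independent normal-equations OLS oracle: solve (X'X) b = X'Y directly
normal_equations_coef <- function(X, Y) {
  solve(t(X) %*% X) %*% t(X) %*% Y
}
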