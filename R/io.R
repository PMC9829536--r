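#' Write a labeled matrix as TSV
#'
#' Single tabular dialect of the package: tab-delimited, "." decimal, UTF-8,
#' one header row of column labels and one leading column of row labels.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @param label_name header of the row-label column; default \code{"id"}.
#' @return the path, invisibly.
#' @export
write_matrix <- function(m, path, label_name = "id") {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry row and column labels")
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- label_name
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' Counterpart of \code{\link{write_matrix}}. Fails loudly on duplicated
#' labels, empty input and non-numeric cells (naming the offending cell).
#'
#' @param path TSV file with a header row and a leading label column.
#' @return numeric matrix with row and column labels.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character",
                          fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty input: ", path, " has no data rows")
  labels <- df[[1L]]
  if (anyDuplicated(labels))
    stop("duplicated row label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicated column label(s): ",
         paste(unique(names(df)[-1L][duplicated(names(df)[-1L])]),
               collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]],
                 labels[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  dimnames(num) <- list(labels, colnames(vals))
  num
}

# write a small metadata sidecar next to a TSV
.write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Run the mapping pipeline end to end on a set of runs
#'
#' Orchestrates the stimulation-experiment analysis: stage-1 spatial
#' regression of the templates into every run (optionally residualized on
#' confound templates), baseline correction, standardization, stage-2
#' connectivity maps, then permutation inference on the baseline-corrected
#' amplitudes (with 1-D TFCE) and on the connectivity maps (no enhancement).
#' All intermediates, results and a provenance record are written to
#' \code{out_dir}.
#'
#' @param runs list of \code{\link{parcellated_ts}} objects.
#' @param templates an \code{\link{expression_atlas}}.
#' @param group factor of group labels per run (two levels) for the
#'   between-group contrast.
#' @param out_dir output directory, created if needed.
#' @param confound_templates optional \code{\link{expression_atlas}} for
#'   residualized stage 1.
#' @param n_baseline baseline volumes for amplitude correction; default 40.
#' @param n_perm permutations; default 1000.
#' @param tfce \code{\link{tfce_params}} for the time-resolved test.
#' @param seed RNG seed recorded in the provenance.
#' @return invisibly, a list with the per-run time-courses, connectivity
#'   maps and the two \code{\link{permute_and_correct}} results.
#' @export
run_pipeline <- function(runs, templates, group, out_dir,
                         confound_templates = NULL, n_baseline = 40,
                         n_perm = 1000, tfce = tfce_params(), seed = 1) {
  stopifnot(length(runs) >= 4L, length(group) == length(runs))
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage1 <- lapply(runs, function(r) {
    if (is.null(confound_templates)) dr_stage1(r, templates)
    else residualized_dr_stage1(r, templates, confound_templates)
  })
  corrected <- lapply(stage1, baseline_correct, n_baseline = n_baseline)
  fc <- mapply(function(r, tc) dr_stage2(r, standardize_timecourses(tc)),
               runs, stage1, SIMPLIFY = FALSE)
  for (i in seq_along(runs)) {
    rid <- sprintf("run%02d", i)
    tcv <- corrected[[i]]$values
    rownames(tcv) <- sprintf("t%03d", seq_len(nrow(tcv)))
    write_matrix(tcv, file.path(out_dir, paste0(rid, "_tc.tsv")),
                 label_name = "volume")
    write_matrix(fc[[i]]$values, file.path(out_dir, paste0(rid, "_fc.tsv")),
                 label_name = "region")
  }
  amp_data <- t(vapply(corrected, function(tc) as.numeric(tc$values),
                       numeric(length(corrected[[1L]]$values))))
  fc_data <- t(vapply(fc, function(f) as.numeric(f$values),
                      numeric(length(fc[[1L]]$values))))
  design <- cbind(intercept = 1,
                  group = as.numeric(group == levels(group)[1L]))
  contrast <- c(0, 1)
  k <- ncol(templates$values)
  sch <- permutation_scheme(n_perm, seed = seed)
  amp_res <- permute_and_correct(amp_data, design, contrast, sch,
                                 tfce = tfce, n_networks = k,
                                 groups = group, element_type = "time")
  fc_res <- permute_and_correct(fc_data, design, contrast, sch,
                                tfce = NULL, n_networks = k,
                                groups = group, element_type = "regions")
  nets <- colnames(templates$values)
  dump <- function(res, prefix, elem_labels) {
    for (nm in c("tstat", "fwe_p", "neg_log10_fwe_p")) {
      mm <- res[[nm]]
      dimnames(mm) <- list(elem_labels, nets)
      write_matrix(mm, file.path(out_dir, sprintf("%s_%s.tsv", prefix, nm)),
                   label_name = "element")
    }
  }
  n_t <- nrow(amp_res$tstat)
  dump(amp_res, "amplitude", sprintf("t%03d", seq_len(n_t)))
  dump(fc_res, "connectivity", rownames(templates$values))
  .write_sidecar(list(
    package = "srnmap",
    version = as.character(utils::packageVersion("srnmap")),
    r_version = R.version.string,
    seed = seed, n_perm = n_perm, n_baseline = n_baseline,
    tfce = tfce[c("E", "H", "n_steps")],
    normalization = templates$normalization,
    n_runs = length(runs), groups = as.list(table(group))),
    file.path(out_dir, "provenance.json"))
  invisible(list(timecourses = corrected, connectivity = fc,
                 amplitude_test = amp_res, connectivity_test = fc_res))
}
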