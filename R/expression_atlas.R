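#' Region atlas table
#'
#' Validates a parcellation table: one row per region with an id, a label, a
#' hemisphere tag and (for lateralized regions) the id of the contralateral
#' homolog, plus the centroid coordinates in mm used for nearest-centroid
#' sample assignment.
#'
#' @param df data frame with columns \code{region_id}, \code{label},
#'   \code{hemisphere} (\code{"left"}, \code{"right"} or \code{"midline"}),
#'   \code{homolog_id} (NA where undefined), \code{cx}, \code{cy}, \code{cz}.
#' @return The validated data frame with class \code{region_atlas}.
#' @export
region_atlas <- function(df) {
  need <- c("region_id", "label", "hemisphere", "homolog_id",
            "cx", "cy", "cz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("region atlas lacks columns: ", paste(miss, collapse = ", "))
  df$region_id <- as.character(df$region_id)
  df$homolog_id <- as.character(df$homolog_id)
  if (anyDuplicated(df$region_id))
    stop("region ids must be unique")
  if (!all(df$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left, right or midline")
  hom <- df$homolog_id[!is.na(df$homolog_id)]
  if (!all(hom %in% df$region_id))
    stop("homolog ids must reference existing regions")
  left <- df[df$hemisphere == "left" & !is.na(df$homolog_id), ]
  if (anyDuplicated(left$homolog_id))
    stop("a left region's homolog must map to exactly one right region")
  class(df) <- c("region_atlas", "data.frame")
  df
}

#' Aggregate probe-level expression to gene level
#'
#' Discards probes without a gene assignment and probes passing the
#' intensity-based filter in fewer than \code{min_pass_fraction} of samples,
#' then averages the surviving probes of each gene in linear space:
#' per sample, \code{log2(mean(2^x))} over the gene's probes.
#'
#' @param values numeric matrix, probes x samples, log2 expression.
#' @param probe_ids character vector of probe ids (rows of \code{values}).
#' @param gene_ids character vector, gene per probe; \code{NA} where the probe
#'   has no gene assignment.
#' @param pass_filter 0/1 matrix, probes x samples, intensity-filter
#'   indicators.
#' @param min_pass_fraction probes passing in a smaller fraction of samples
#'   are dropped; default 0.5.
#' @return numeric matrix, genes x samples, log2 units.
#' @export
aggregate_probes <- function(values, probe_ids, gene_ids, pass_filter,
                             min_pass_fraction = 0.5) {
  values <- as.matrix(values)
  pass_filter <- as.matrix(pass_filter)
  if (!identical(dim(values), dim(pass_filter)))
    stop("values and pass_filter must have identical dimensions")
  if (length(probe_ids) != nrow(values) || length(gene_ids) != nrow(values))
    stop("probe_ids and gene_ids must have one entry per probe")
  if (min_pass_fraction < 0 || min_pass_fraction > 1)
    stop("min_pass_fraction must lie in [0, 1]")
  gene_ids <- as.character(gene_ids)
  gene_ids[!is.na(gene_ids) & gene_ids == ""] <- NA_character_
  keep <- !is.na(gene_ids) & rowMeans(pass_filter) >= min_pass_fraction
  if (!any(keep))
    stop("empty atlas: all probes were filtered out")
  values <- values[keep, , drop = FALSE]
  gene_ids <- gene_ids[keep]
  genes <- unique(gene_ids)
  lin <- 2^values
  out <- matrix(NA_real_, length(genes), ncol(values),
                dimnames = list(genes, colnames(values)))
  for (g in genes) {
    rows <- lin[gene_ids == g, , drop = FALSE]
    out[g, ] <- log2(colMeans(rows))
  }
  out
}

#' Assign expression samples to atlas regions by nearest centroid
#'
#' Each sample receives the label of the region whose centroid minimizes the
#' Euclidean distance to the sample's coordinates (both in the same mm
#' coordinate convention). Ties break to the lowest region index, i.e. the
#' earliest row of the atlas table.
#'
#' @param sample_coords numeric matrix, samples x 3 (x, y, z in mm).
#' @param atlas a \code{\link{region_atlas}}.
#' @return character vector of region ids, one per sample.
#' @export
assign_samples_to_regions <- function(sample_coords, atlas) {
  atlas <- region_atlas(atlas)
  if (nrow(atlas) == 0L) stop("empty atlas")
  sample_coords <- as.matrix(sample_coords)
  if (ncol(sample_coords) != 3L)
    stop("sample coordinates must be samples x 3")
  cen <- as.matrix(atlas[, c("cx", "cy", "cz")])
  # squared distances via the expansion |s - c|^2 = |s|^2 - 2 s.c + |c|^2
  d2 <- outer(rowSums(sample_coords^2), rep(1, nrow(cen))) -
    2 * sample_coords %*% t(cen) +
    outer(rep(1, nrow(sample_coords)), rowSums(cen^2))
  atlas$region_id[apply(d2, 1L, which.min)]
}

#' Summarize gene expression by region, within then across donors
#'
#' Within each donor, samples sharing an atlas label are averaged in linear
#' space (\code{log2(mean(2^x))}). Across the designated donor subset, the
#' per-donor log2 values are averaged arithmetically. Regions with no samples
#' in any donor are returned as \code{NA} (flagged missing).
#'
#' @param gene_by_sample numeric matrix, genes x samples, log2 units.
#' @param labels character vector of region ids, one per sample.
#' @param donor_ids character vector of donor ids, one per sample.
#' @param donors donor subset to average across; default all donors present.
#' @param region_ids region universe for the output columns; default the
#'   sorted unique labels.
#' @return numeric matrix, genes x regions, log2 units; \code{NA} columns mark
#'   unsampled regions.
#' @export
summarize_by_region <- function(gene_by_sample, labels, donor_ids,
                                donors = NULL, region_ids = NULL) {
  gene_by_sample <- as.matrix(gene_by_sample)
  ns <- ncol(gene_by_sample)
  if (length(labels) != ns || length(donor_ids) != ns)
    stop("labels and donor_ids must have one entry per sample")
  donor_ids <- as.character(donor_ids)
  if (is.null(donors)) donors <- unique(donor_ids)
  if (length(donors) == 0L || !any(donor_ids %in% donors))
    stop("donor subset is empty")
  if (is.null(region_ids)) region_ids <- sort(unique(as.character(labels)))
  per_donor <- lapply(donors, function(d) {
    sel <- donor_ids == d
    vals <- gene_by_sample[, sel, drop = FALSE]
    labs <- as.character(labels)[sel]
    out <- matrix(NA_real_, nrow(gene_by_sample), length(region_ids),
                  dimnames = list(rownames(gene_by_sample), region_ids))
    for (r in intersect(region_ids, labs)) {
      lin <- 2^vals[, labs == r, drop = FALSE]
      out[, r] <- log2(rowMeans(lin))
    }
    out
  })
  arr <- array(unlist(per_donor),
               dim = c(nrow(gene_by_sample), length(region_ids),
                       length(per_donor)))   # genes x regions x donors
  out <- apply(arr, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  dimnames(out) <- list(rownames(gene_by_sample), region_ids)
  out
}

#' Normalize a regional expression map
#'
#' \code{zscore} centers and scales to unit (sample) standard deviation
#' across regions. \code{rank_inverse_normal} maps average ranks to standard
#' normal quantiles with the Blom offset: \code{qnorm((rank - 3/8)/(n + 1/4))}.
#' Both are monotone transforms of the input.
#'
#' @param x numeric vector of per-region values for one gene.
#' @param mode \code{"zscore"} or \code{"rank_inverse_normal"}.
#' @return numeric vector of the same length and names.
#' @export
normalize_map <- function(x, mode = c("zscore", "rank_inverse_normal")) {
  mode <- match.arg(mode)
  if (length(x) < 3L) stop("need at least 3 regions to normalize")
  if (anyNA(x)) stop("normalize_map requires complete values")
  if (mode == "zscore") {
    s <- stats::sd(x)
    if (s == 0) stop("constant column: zero variance under zscore")
    (x - mean(x)) / s
  } else {
    n <- length(x)
    c_off <- 3 / 8
    r <- rank(x, ties.method = "average")
    out <- stats::qnorm((r - c_off) / (n - 2 * c_off + 1))
    names(out) <- names(x)
    out
  }
}

#' Mirror a unilateral regional map across the sagittal plane
#'
#' Copies each region's value to its empty contralateral homolog, making a
#' map sampled on one hemisphere symmetric. Values already present on both
#' sides, and midline regions, are left untouched; regions with a value on
#' neither side remain \code{NA}.
#'
#' @param map named numeric vector over atlas regions (\code{NA} = missing).
#' @param atlas a \code{\link{region_atlas}} with homolog mapping.
#' @return named numeric vector over the same regions.
#' @export
mirror_sagittal <- function(map, atlas) {
  atlas <- region_atlas(atlas)
  if (is.null(names(map))) stop("map must be named by region id")
  out <- map[atlas$region_id]
  names(out) <- atlas$region_id
  hom <- stats::setNames(atlas$homolog_id, atlas$region_id)
  for (r in atlas$region_id) {
    h <- hom[[r]]
    if (is.na(h)) next
    if (is.na(out[[r]]) && !is.na(out[[h]])) out[[r]] <- out[[h]]
  }
  out
}

#' Build a normalized expression atlas from probe-level input
#'
#' Full pipeline: probe filtering and gene aggregation, nearest-centroid
#' region assignment, within/across-donor regional summaries in linear space,
#' optional sagittal mirroring for genes sampled on one hemisphere, then
#' per-gene normalization across regions. Regions left unsampled by every
#' donor are dropped with a warning.
#'
#' @inheritParams aggregate_probes
#' @param sample_coords samples x 3 coordinate matrix (mm).
#' @param atlas a \code{\link{region_atlas}}.
#' @param donor_ids donor id per sample.
#' @param donors donor subset averaged across (default all).
#' @param normalization \code{"zscore"} or \code{"rank_inverse_normal"}.
#' @param mirror_genes gene names to mirror sagittally before normalization.
#' @return an \code{\link{expression_atlas}} (regions x genes).
#' @export
build_expression_atlas <- function(values, probe_ids, gene_ids, pass_filter,
                                   sample_coords, atlas, donor_ids,
                                   donors = NULL,
                                   min_pass_fraction = 0.5,
                                   normalization = c("zscore",
                                                     "rank_inverse_normal"),
                                   mirror_genes = character()) {
  normalization <- match.arg(normalization)
  atlas <- region_atlas(atlas)
  gxs <- aggregate_probes(values, probe_ids, gene_ids, pass_filter,
                          min_pass_fraction)
  labels <- assign_samples_to_regions(sample_coords, atlas)
  gxr <- summarize_by_region(gxs, labels, donor_ids, donors,
                             region_ids = atlas$region_id)
  if (length(mirror_genes)) {
    for (g in intersect(mirror_genes, rownames(gxr)))
      gxr[g, ] <- mirror_sagittal(gxr[g, ], atlas)
  }
  empty <- colSums(!is.na(gxr)) == 0L
  if (any(empty)) {
    warning("dropping regions with no expression samples: ",
            paste(colnames(gxr)[empty], collapse = ", "))
    gxr <- gxr[, !empty, drop = FALSE]
  }
  if (anyNA(gxr))
    stop("genes with partially missing regional coverage after mirroring: ",
         paste(rownames(gxr)[rowSums(is.na(gxr)) > 0], collapse = ", "))
  norm <- apply(gxr, 1L, normalize_map, mode = normalization)  # regions x genes
  expression_atlas(norm, normalization = normalization)
}
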