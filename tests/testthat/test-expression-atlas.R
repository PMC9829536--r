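test_that("probe aggregation averages in linear space and applies the pass filter", {
  # two probes of one gene, log2 values 2 and 4: linear mean (4+16)/2 = 10
  vals <- rbind(p1 = c(2, 2), p2 = c(4, 4))
  pf <- matrix(1, 2, 2)
  out <- aggregate_probes(vals, c("p1", "p2"), c("g1", "g1"), pf)
  expect_equal(unname(out["g1", ]), rep(log2(10), 2))

  # single probe per gene, all passing: identity up to re-keying by gene
  vals2 <- rbind(p1 = c(1.5, 2.5), p2 = c(3, 4))
  out2 <- aggregate_probes(vals2, c("p1", "p2"), c("gA", "gB"),
                           matrix(1, 2, 2))
  expect_equal(unname(out2), unname(vals2))
  expect_equal(rownames(out2), c("gA", "gB"))

  # probe passing in 40% of samples is dropped at the 50% threshold
  vals3 <- rbind(p1 = rep(0, 10), p2 = rep(4, 10))
  pf3 <- rbind(rep(c(1, 0), c(4, 6)), rep(1, 10))
  out3 <- aggregate_probes(vals3, c("p1", "p2"), c("g1", "g1"), pf3,
                           min_pass_fraction = 0.5)
  expect_equal(unname(out3["g1", ]), rep(4, 10))

  # probes without a gene id are removed
  out4 <- aggregate_probes(vals3, c("p1", "p2"), c(NA, "g1"),
                           matrix(1, 2, 10))
  expect_equal(rownames(out4), "g1")

  # everything filtered out is an explicit error, not an empty matrix
  expect_error(
    aggregate_probes(vals3, c("p1", "p2"), c(NA, NA), matrix(1, 2, 10)),
    "empty atlas")
})

test_that("samples map to the nearest centroid with a deterministic tie-break", {
  atlas <- toy_region_atlas()
  # a sample exactly at a centroid gets that region
  cen <- as.matrix(atlas[, c("cx", "cy", "cz")])
  lab <- assign_samples_to_regions(cen[3, , drop = FALSE], atlas)
  expect_equal(lab, atlas$region_id[3])

  # equidistant between regions 3 and 7: the earlier row wins
  a2 <- region_atlas(data.frame(
    region_id = paste0("r", 1:8), label = paste0("r", 1:8),
    hemisphere = "midline", homolog_id = NA_character_,
    cx = c(5, 5, -1, 5, 5, 5, 1, 5), cy = 0, cz = 0))
  lab2 <- assign_samples_to_regions(cbind(0, 0, 0), a2)
  expect_equal(lab2, "r3")

  # brute-force all-pairs oracle on random samples
  set.seed(42)
  sc <- matrix(rnorm(60, sd = 15), 20, 3)
  got <- assign_samples_to_regions(sc, atlas)
  oracle <- apply(sc, 1, function(s) {
    d <- sqrt(colSums((t(cen) - s)^2))
    atlas$region_id[which.min(d)]
  })
  expect_equal(got, oracle)

  expect_error(assign_samples_to_regions(cbind(0, 0, 0), atlas[0, ]),
               "empty atlas")
})

test_that("regional summaries use linear-space means within donors", {
  # two samples, log2 1 and 3, one region: log2((2+8)/2) = log2(5)
  g <- matrix(c(1, 3), 1, 2, dimnames = list("g1", NULL))
  out <- summarize_by_region(g, c("rA", "rA"), c("d1", "d1"))
  expect_equal(unname(out["g1", "rA"]), log2(5))

  # one donor, one sample per region: relabeled identity
  g2 <- matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL))
  out2 <- summarize_by_region(g2, c("rC", "rA", "rB"), rep("d1", 3))
  expect_equal(unname(out2["g1", c("rC", "rA", "rB")]), c(1, 2, 3))

  # two donors with identical data: cross-donor mean is either donor
  g3 <- matrix(c(1, 3, 1, 3), 1, dimnames = list("g1", NULL))
  out3 <- summarize_by_region(g3, rep(c("rA", "rB"), 2),
                              rep(c("d1", "d2"), each = 2))
  expect_equal(unname(out3["g1", c("rA", "rB")]), c(1, 3))

  # unsampled regions are NA, empty donor subset errors
  out4 <- summarize_by_region(g2, c("rC", "rA", "rB"), rep("d1", 3),
                              region_ids = c("rA", "rB", "rC", "rD"))
  expect_true(is.na(out4["g1", "rD"]))
  expect_error(summarize_by_region(g2, c("rC", "rA", "rB"), rep("d1", 3),
                                   donors = "nope"), "empty")
})

test_that("normalization modes are correct and monotone", {
  expect_equal(normalize_map(c(1, 2, 3), "zscore"), c(-1, 0, 1))
  expect_error(normalize_map(rep(2, 5), "zscore"), "constant")

  # odd-length distinct input: the median maps exactly to 0
  set.seed(7)
  x <- sample(seq(-3, 3, length.out = 11))
  rin <- normalize_map(x, "rank_inverse_normal")
  expect_equal(rin[which(x == sort(x)[6])], 0)

  # symmetric Blom offsets make the quantile set symmetric: mean 0
  expect_lt(abs(mean(rin)), 1e-12)

  # both modes preserve order among distinct values
  for (mode in c("zscore", "rank_inverse_normal")) {
    y <- normalize_map(x, mode)
    expect_equal(order(y), order(x))
  }
})

test_that("sagittal mirroring fills homologs, is idempotent and keeps midline", {
  atlas <- toy_region_atlas(n_pairs = 3, n_midline = 1)
  map <- setNames(rep(NA_real_, nrow(atlas)), atlas$region_id)
  map[c("L01", "L02", "L03")] <- c(2, -1, 0.5)
  map["M01"] <- 9
  out <- mirror_sagittal(map, atlas)
  expect_equal(unname(out[c("R01", "R02", "R03")]), c(2, -1, 0.5))
  expect_equal(unname(out["M01"]), 9)
  # idempotent
  expect_equal(mirror_sagittal(out, atlas), out)
  # bilateral input unchanged
  full <- setNames(rnorm(nrow(atlas)), atlas$region_id)
  expect_equal(mirror_sagittal(full, atlas), full[atlas$region_id])
  # value on neither side stays missing
  map2 <- map; map2[c("L02")] <- NA
  out2 <- mirror_sagittal(map2, atlas)
  expect_true(is.na(out2["L02"]) && is.na(out2["R02"]))
})

test_that("full atlas build z-scores every gene and respects relabeling", {
  atlas <- toy_region_atlas(n_pairs = 5, n_midline = 2, seed = 3)
  n_reg <- nrow(atlas)
  set.seed(5)
  n_probe <- 12; n_samp <- 3 * n_reg
  vals <- matrix(rnorm(n_probe * n_samp, mean = 6), n_probe, n_samp)
  genes <- rep(c("Htr1a", "Htr2a", "Htr4", NA), 3)
  pf <- matrix(rbinom(n_probe * n_samp, 1, 0.9), n_probe, n_samp)
  coords <- as.matrix(atlas[rep(seq_len(n_reg), 3), c("cx", "cy", "cz")]) +
    matrix(rnorm(3 * n_samp, sd = 0.01), n_samp, 3)
  donors <- rep(c("d1", "d2", "d1"), each = n_reg)

  ea <- build_expression_atlas(vals, paste0("p", 1:n_probe), genes, pf,
                               coords, atlas, donors,
                               normalization = "zscore")
  expect_s3_class(ea, "expression_atlas")
  expect_equal(sort(colnames(ea$values)), c("Htr1a", "Htr2a", "Htr4"))
  expect_lt(max(abs(colMeans(ea$values))), 1e-10)
  expect_lt(max(abs(apply(ea$values, 2, sd) - 1)), 1e-10)

  # permuting region rows of the atlas table permutes output rows identically
  perm <- sample(n_reg)
  atlas_p <- region_atlas(atlas[perm, ])
  ea_p <- build_expression_atlas(vals, paste0("p", 1:n_probe), genes, pf,
                                 coords, atlas_p, donors,
                                 normalization = "zscore")
  expect_equal(ea_p$values[rownames(ea$values), colnames(ea$values)],
               ea$values)
})
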