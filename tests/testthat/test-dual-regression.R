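test_that("stage 1 matches the normal-equations oracle and recovers mixing", {
  atlas <- synthetic_atlas(n_regions = 40, n_networks = 3, seed = 2)
  tc <- random_timecourses(60, 3, seed = 8)
  run <- mixing_run(atlas, tc)

  # noise-free linear mixing is inverted exactly
  got <- dr_stage1(run, atlas)
  expect_lt(max(abs(got$values - tc)), 1e-8)

  # all-zero signal gives all-zero time-courses
  zrun <- parcellated_ts(matrix(0, 10, 40,
                                dimnames = list(NULL,
                                                rownames(atlas$values))),
                         tr = 2)
  expect_equal(max(abs(dr_stage1(zrun, atlas)$values)), 0)

  # random instance equals an independent (X'X)^-1 X'Y solve
  small <- synthetic_atlas(n_regions = 8, n_networks = 2, seed = 4)
  set.seed(9)
  y <- matrix(rnorm(80), 10, 8,
              dimnames = list(NULL, rownames(small$values)))
  srun <- parcellated_ts(y, tr = 2)
  Ac <- sweep(small$values, 2, colMeans(small$values))
  X <- cbind(1, Ac)
  oracle <- t(normal_equations_coef(X, t(y))[-1, , drop = FALSE])
  expect_lt(max(abs(dr_stage1(srun, small)$values - oracle)), 1e-10)
})

test_that("stage 1 rejects collinear template sets naming the culprits", {
  atlas <- synthetic_atlas(n_regions = 30, n_networks = 3, seed = 2)
  v <- atlas$values
  v[, 3] <- v[, 2]
  colnames(v)[3] <- "copy_of_2"
  bad <- expression_atlas(v, normalization = "raw_log2")
  run <- mixing_run(atlas, random_timecourses(50, 3, seed = 1))
  expect_error(dr_stage1(run, bad), "collinear.*copy_of_2")
})

test_that("time-course standardization is exact and idempotent", {
  tc <- network_timecourses(cbind(net1 = c(1, 2, 3)))
  z <- standardize_timecourses(tc)
  expect_equal(mean(z$values), 0)
  expect_equal(sd(z$values), 1)
  expect_true(z$standardized)
  z2 <- standardize_timecourses(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)
  # standardization preserves shape: correlation 1 with the source
  tc2 <- network_timecourses(cbind(net1 = rnorm(30)))
  expect_equal(cor(standardize_timecourses(tc2)$values[, 1],
                   tc2$values[, 1]), 1)
  expect_error(standardize_timecourses(
    network_timecourses(cbind(net1 = rep(2, 5)))), "constant")
})

test_that("stage 2 recovers template-proportional maps and the simple-regression form", {
  atlas <- synthetic_atlas(n_regions = 40, n_networks = 3, seed = 12)
  tc <- random_timecourses(80, 3, seed = 13)
  run <- mixing_run(atlas, tc)
  fc <- dr_stage2(run, standardize_timecourses(dr_stage1(run, atlas)))
  for (k in 1:3)
    expect_gt(abs(cor(fc$values[, k], atlas$values[, k])), 0.999)

  # K = 1, time-course = one region's standardized signal:
  # that region's coefficient is its signal's sample sd
  set.seed(3)
  y <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("R", 1:4)))
  run2 <- parcellated_ts(y, tr = 2)
  z <- (y[, 2] - mean(y[, 2])) / sd(y[, 2])
  tc1 <- network_timecourses(cbind(net1 = z), standardized = TRUE)
  fc2 <- dr_stage2(run2, tc1)
  expect_equal(unname(fc2$values["R2", "net1"]), sd(y[, 2]))

  # an all-zero region yields a zero row
  y3 <- y; y3[, 3] <- 0
  fc3 <- dr_stage2(parcellated_ts(y3, tr = 2), tc1)
  expect_equal(unname(fc3$values["R3", ]), 0)

  expect_error(dr_stage2(run2, network_timecourses(cbind(net1 = z))),
               "standardized")
  expect_error(
    dr_stage2(run2,
              network_timecourses(cbind(net1 = z[1:30]),
                                  standardized = TRUE)),
    "time")
})

test_that("stage-2 maps are permutation-equivariant in regions and scale with normalization", {
  atlas <- synthetic_atlas(n_regions = 25, n_networks = 3, seed = 21)
  tc <- random_timecourses(60, 3, seed = 22)
  run <- mixing_run(atlas, tc, noise_sd = 0.5, seed = 23)
  z <- standardize_timecourses(dr_stage1(run, atlas))
  fc <- dr_stage2(run, z)

  perm <- sample(25)
  run_p <- parcellated_ts(run$values[, perm], tr = 2)
  fc_p <- dr_stage2(run_p, z)
  expect_equal(fc_p$values, fc$values[perm, ])

  # without variance normalization, columns differ by positive scales only
  raw <- dr_stage1(run, atlas)
  fc_raw <- dr_stage2(run, network_timecourses(
    sweep(raw$values, 2, colMeans(raw$values)), standardized = TRUE))
  ratio <- fc_raw$values / fc$values
  for (k in 1:3) {
    expect_lt(diff(range(ratio[, k])), 1e-8)
    expect_gt(ratio[1, k], 0)
  }
})

test_that("residualized stage 1 equals the Frisch-Waugh partialled regression", {
  set.seed(31)
  n_reg <- 30
  regions <- sprintf("R%03d", 1:n_reg)
  mk_atlas <- function(k, prefix) {
    v <- matrix(rnorm(n_reg * k), n_reg,
                dimnames = list(regions, paste0(prefix, 1:k)))
    expression_atlas(v, normalization = "raw_log2")
  }
  interest <- mk_atlas(3, "int")
  confound <- mk_atlas(4, "cov")
  y <- matrix(rnorm(n_reg * 20), 20, n_reg,
              dimnames = list(NULL, regions))
  run <- parcellated_ts(y, tr = 2)

  got <- residualized_dr_stage1(run, interest, confound)$values
  # oracle: residualize signal and interest templates on confounds, regress
  C <- cbind(1, confound$values)
  P <- diag(n_reg) - C %*% solve(t(C) %*% C) %*% t(C)
  Ar <- P %*% sweep(interest$values, 2, colMeans(interest$values))
  Yr <- P %*% t(y)
  oracle <- t(solve(t(Ar) %*% Ar) %*% t(Ar) %*% Yr)
  expect_lt(max(abs(got - oracle)), 1e-9)

  # orthogonal confounds leave plain stage 1 unchanged
  qint <- qr.Q(qr(cbind(1, interest$values)))
  orth <- qr.resid(qr(qint), confound$values)
  colnames(orth) <- paste0("orth", 1:4)
  conf_orth <- expression_atlas(orth, normalization = "raw_log2")
  plain <- dr_stage1(run, interest)$values
  resid <- residualized_dr_stage1(run, interest, conf_orth)$values
  expect_lt(max(abs(plain - resid)), 1e-10)

  # a template in both sets is an error
  dup <- interest$values
  colnames(dup) <- paste0("cov_dup", 1:3)
  dup[, 2:3] <- matrix(rnorm(n_reg * 2), n_reg)
  expect_error(
    residualized_dr_stage1(run, interest,
                           expression_atlas(dup, "raw_log2")),
    "identical")
})

test_that("baseline correction zeroes the pre-stimulus window", {
  tc <- network_timecourses(cbind(net1 = rep(3.5, 100)))
  out <- baseline_correct(tc, 40)
  expect_equal(max(abs(out$values)), 0)
  expect_true(out$baseline_corrected)

  tc2 <- network_timecourses(matrix(rnorm(300), 100, 3,
                                    dimnames = list(NULL, paste0("n", 1:3))))
  out2 <- baseline_correct(tc2, 40)
  expect_lt(max(abs(colMeans(out2$values[1:40, ]))), 1e-12)
  expect_error(baseline_correct(tc2, 0), "positive")
  expect_error(baseline_correct(tc2, 100), "smaller")
})

test_that("run averaging is the element-wise mean within one subject", {
  set.seed(41)
  mk <- function(subject = "s1")
    connectivity_matrix(matrix(rnorm(12), 4, 3,
                               dimnames = list(paste0("R", 1:4),
                                               paste0("n", 1:3))),
                        subject = subject)
  m <- mk()
  expect_equal(average_runs(list(m, m, m, m))$values, m$values)
  neg <- connectivity_matrix(-m$values, subject = "s1")
  expect_equal(max(abs(average_runs(list(m, neg))$values)), 0)
  a <- mk(); b <- mk(); c <- mk()
  expect_equal(average_runs(list(a, b, c))$values,
               (a$values + b$values + c$values) / 3)
  expect_error(average_runs(list(m, mk("s2"))), "subjects")
})
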