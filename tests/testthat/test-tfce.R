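grid_edges_6 <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(1, 4))

test_that("TFCE reproduces the hand-summed single-point value", {
  # isolated point with stat 2.0, default E=0.5, H=2, h0=0, dh=0.4:
  # sum over h in {0.4, ..., 2.0} of 1^0.5 * h^2 * 0.4 = 3.52
  st <- matrix(c(2, 0, 0, 0), 2, 2)
  out <- tfce_enhance(st, rbind(c(1, 2)))
  expect_equal(out[1, 1], 3.52, tolerance = 1e-12)
  expect_equal(out[2, ], c(0, 0))
  # all-zero map stays all-zero
  expect_equal(tfce_enhance(matrix(0, 3, 3), rbind(c(1, 2), c(2, 3))),
               matrix(0, 3, 3))
})

test_that("TFCE matches the brute-force oracle on small maps", {
  skip_if_not_installed("igraph")
  set.seed(30)
  for (r in 1:20) {
    st <- matrix(rnorm(36, sd = 2), 6, 6)
    expect_equal(tfce_enhance(st, grid_edges_6),
                 oracle_tfce(st, grid_edges_6), tolerance = 1e-10)
  }
  # one-sided maps too
  p1 <- tfce_params(two_sided = FALSE)
  st <- matrix(abs(rnorm(36, sd = 2)), 6, 6)
  expect_equal(tfce_enhance(st, grid_edges_6, p1),
               oracle_tfce(st, grid_edges_6, two_sided = FALSE),
               tolerance = 1e-10)
})

test_that("doubling a statistic map never decreases its enhancement", {
  set.seed(31)
  for (r in 1:10) {
    st <- matrix(rnorm(36, sd = 1.5), 6, 6)
    a <- tfce_enhance(st, grid_edges_6)
    b <- tfce_enhance(2 * st, grid_edges_6)
    expect_true(all(abs(b) >= abs(a) - 1e-12))
    expect_true(all(sign(b) == sign(a) | a == 0))
  }
})

test_that("spatiotemporal connected components respect the lattice", {
  edges <- rbind(c(1, 2), c(2, 3))
  m <- matrix(FALSE, 3, 3)
  m[1, 1] <- TRUE; m[3, 1] <- TRUE         # not spatially adjacent, same time
  lab <- connected_components(m, edges)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 2L)
  m <- matrix(FALSE, 3, 3)
  m[2, 1] <- TRUE; m[2, 2] <- TRUE         # same vertex, adjacent times
  lab <- connected_components(m, edges)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 1L)
  # cross shape on a 3x3 grid (vertices = rows, time = cols)
  m <- matrix(FALSE, 3, 3)
  m[2, ] <- TRUE; m[, 2] <- TRUE
  lab <- connected_components(m, edges)
  expect_equal(sum(lab > 0), 5)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 1L)
})

test_that("clusters never merge across hemispheres", {
  sp <- small_space()
  m <- matrix(TRUE, sp$n, 2)
  lab <- connected_components(m, sp$edges)
  expect_equal(length(setdiff(unique(as.vector(lab)), 0L)), 2L)
  expect_true(all(lab[sp$hemi == "L", ] != lab[sp$hemi == "R", ]))
})

test_that("one-sample test: zero diffs give no significance; small n enumerates exhaustively", {
  sp <- small_space()
  diffs <- array(0, dim = c(5, sp$n, 4))
  set.seed(32)
  res <- one_sample_tfce_test(diffs, sp, tfce_params(n_perm = 500))
  expect_false(any(res$sig_mask))
  expect_true(all(res$p_map == 1))
  expect_equal(res$n_perm, 32)             # 2^5 sign patterns enumerated
})

test_that("permutation p-values are reproducible given the seed", {
  sp <- small_space()
  set.seed(33)
  diffs <- array(rnorm(12 * sp$n * 10), dim = c(12, sp$n, 10))
  set.seed(34); a <- one_sample_tfce_test(diffs, sp, tfce_params(n_perm = 200))
  set.seed(34); b <- one_sample_tfce_test(diffs, sp, tfce_params(n_perm = 200))
  expect_identical(a$p_map, b$p_map)
})

test_that("an injected effect is recovered inside its support and not outside", {
  sp <- small_space()
  stg <- region_vertices(sp, "stg_all")
  Tn <- 40                                  # 20 ms steps over 0-800 ms
  times <- seq(0, 780, by = 20)
  support_t <- times >= 200 & times <= 500
  set.seed(35)
  n <- 16
  diffs <- array(rnorm(n * sp$n * Tn), dim = c(n, sp$n, Tn))
  diffs[, stg, support_t] <- diffs[, stg, support_t] - 1.5
  res <- one_sample_tfce_test(diffs, sp, tfce_params(n_perm = 500))
  support <- matrix(FALSE, sp$n, Tn); support[stg, support_t] <- TRUE
  expect_gte(mean(res$sig_mask[support]), 0.8)
  expect_lt(mean(res$sig_mask[!support]), 0.01)
})

test_that("two-sample test is symmetric under group exchange", {
  sp <- small_space()
  set.seed(36)
  a <- array(rnorm(8 * sp$n * 8), dim = c(8, sp$n, 8))
  b <- array(rnorm(8 * sp$n * 8, mean = 0.4), dim = c(8, sp$n, 8))
  set.seed(37); r1 <- two_sample_tfce_test(a, b, sp, tfce_params(n_perm = 200))
  set.seed(37); r2 <- two_sample_tfce_test(b, a, sp, tfce_params(n_perm = 200))
  expect_equal(r1$stat_map, -r2$stat_map, tolerance = 1e-10)
  expect_equal(abs(r1$tfce_map), abs(r2$tfce_map), tolerance = 1e-10)
  # the null is re-sampled over the reordered rows, so p agrees only up to
  # Monte-Carlo error of the 200-permutation null
  expect_lt(max(abs(r1$p_map - r2$p_map)), 4 * sqrt(0.25 / 200))
})

test_that("an injected group deficit is detected in its region", {
  sp <- small_space()
  set.seed(38)
  sim <- simulate_evoked(sp, fast_cohort())
  pre <- baseline_crop_resample(align_polarity(sim$evoked, sp), fs_out = 250)
  d <- differential_response(pre, "nonperiodic_vowel")
  grp <- sim$records$group
  res <- two_sample_tfce_test(d[grp == "TD", , ], d[grp == "ASD", , ], sp,
                              tfce_params(n_perm = 300))
  expect_true(any(res$sig_mask))
  inj <- region_vertices(sp, c("A4", "pINS"))
  sig_sources <- which(rowSums(res$sig_mask) > 0)
  expect_gte(mean(sig_sources %in% inj), 0.8)
})
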