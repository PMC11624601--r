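# build a minimal tfce_result by hand for selection tests
fake_result <- function(space, p_map, tfce_map = 1 - p_map) {
  sig <- p_map < 0.05
  structure(list(stat_map = tfce_map, tfce_map = tfce_map, p_map = p_map,
                 sig_mask = sig,
                 clusters = connected_components(sig, space$edges),
                 space = space, params = tfce_params(), n_perm = 500),
            class = "tfce_result")
}

test_that("most-significant-source selection implements the below-average rule", {
  sp <- small_space()
  stg_l <- region_vertices(sp, "stg_all", "L")
  # uniform p inside the cluster: the strict rule selects nothing
  p <- matrix(1, sp$n, 5)
  p[stg_l, 2:4] <- 0.01
  res <- fake_result(sp, p)
  sel <- select_most_significant_sources(res, sp)
  expect_length(sel$L, 0)
  # one clearly dominant source is the sole selection
  p[stg_l[1], 2:4] <- 1e-4
  sel <- select_most_significant_sources(fake_result(sp, p), sp)
  expect_equal(sel$L, stg_l[1])
  # identical input, identical selection
  sel2 <- select_most_significant_sources(fake_result(sp, p), sp)
  expect_identical(sel, sel2)
  # clusters with no STG+ member warn and select nothing
  p2 <- matrix(1, sp$n, 5)
  outside_r <- region_vertices(sp, "outside", "R")
  p2[outside_r, 2:3] <- 0.01
  expect_warning(
    sel3 <- select_most_significant_sources(fake_result(sp, p2), sp),
    "no sources")
  expect_length(sel3$R, 0)
  # no significant cluster at all is an error
  expect_error(select_most_significant_sources(fake_result(sp, matrix(1, sp$n, 5)), sp),
               "no significant cluster")
})

test_that("pointwise paired contrast with FDR finds what it should", {
  set.seed(40)
  n <- 12; Tn <- 50
  base <- matrix(rnorm(n * Tn), n, Tn)
  # identical inputs: nothing significant
  pc <- pointwise_contrast(base, base + 0 * base)
  expect_false(any(pc$sig))
  expect_equal(nrow(pc$runs), 0)
  # a shift far beyond the noise: everything significant
  pc <- pointwise_contrast(base + 10, base)
  expect_true(all(pc$sig))
  expect_equal(nrow(pc$runs), 1)
  expect_error(pointwise_contrast(base[1:2, ], base[1:2, ]), "at least 3")
})

test_that("BH step-up matches the textbook procedure", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  out <- bh_fdr(p)
  expect_equal(out$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$reject, oracle_bh_reject(p))
  p5 <- c(0.001, 0.011, 0.02, 0.04, 0.9)
  expect_equal(bh_fdr(p5)$reject, oracle_bh_reject(p5))
  expect_equal(bh_fdr(0.01)$reject, TRUE)
  expect_false(any(bh_fdr(rep(1, 10))$reject))
  expect_error(bh_fdr(numeric(0)), "empty")
  set.seed(41)
  for (r in 1:20) {
    p <- runif(25)^2
    expect_equal(bh_fdr(p)$reject, oracle_bh_reject(p))
  }
})

test_that("group-difference windows average per-source onsets and ends", {
  one <- list(data.frame(start = 150, end = 400))
  expect_equal(group_difference_window(one), c(onset = 150, end = 400))
  two <- list(data.frame(start = 100, end = 300),
              data.frame(start = 200, end = 500))
  expect_equal(group_difference_window(two), c(onset = 150, end = 400))
  # sources without runs are excluded; all-empty errors
  three <- c(two, list(data.frame(start = numeric(0), end = numeric(0))))
  expect_equal(group_difference_window(three), c(onset = 150, end = 400))
  w <- group_difference_window(two)
  expect_gte(w["end"], w["onset"])
  expect_error(group_difference_window(list(data.frame(start = numeric(0),
                                                       end = numeric(0)))),
               "no source")
})

test_that("SPNadj residuals satisfy the normal equations and their invariances", {
  set.seed(42)
  n <- 5
  ctrl <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  sq <- sqrt(c(100, 140, 90, 200, 160))
  # exact linear combination: residuals vanish
  test_lin <- 2 + 0.7 * ctrl
  expect_lt(max(abs(compute_spn_adj(test_lin, ctrl, sq))), 1e-10)
  # regressors unrelated to the response: residuals ~ centred response
  y <- c(3, -1, 0.5, 2, -2)
  adj <- compute_spn_adj(y, ctrl, sq)
  expect_equal(mean(adj), 0, tolerance = 1e-12)
  # closed-form OLS via the normal equations
  X <- cbind(1, ctrl, sq)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(adj, as.vector(y - X %*% beta), tolerance = 1e-10)
  # orthogonality to the regressors
  expect_lt(abs(sum(adj * ctrl)), 1e-9)
  expect_lt(abs(sum(adj * sq)), 1e-9)
  # invariance: adding back multiples of the regressors changes nothing
  expect_equal(compute_spn_adj(y + 3 * ctrl - 2 * sq, ctrl, sq), adj,
               tolerance = 1e-10)
  expect_error(compute_spn_adj(y, ctrl, 2 * ctrl + 1), "collinear")
  expect_error(compute_spn_adj(y[1:3], ctrl[1:3], sq[1:3]), "at least 4")
})
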