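# deterministic correctness array: word w correct with probability given by
# `acc[w]` in every cell, encoded as all-correct / all-wrong / alternating
fixture_win <- function(n_easy = 10, n_hard = 8, n_mid = 142, n_sub = 8) {
  nw <- n_easy + n_hard + n_mid
  win <- array(NA, dim = c(nw, 4, 2, n_sub),
               dimnames = list(NULL, c("0", "-3", "-6", "-9"), c("ST", "AM"),
                               NULL))
  win[seq_len(n_easy), , , ] <- TRUE
  win[n_easy + seq_len(n_hard), , , ] <- FALSE
  mid <- n_easy + n_hard + seq_len(n_mid)
  # mid words are right half the time in every cell (index-parity pattern)
  idx <- as.matrix(expand.grid(w = mid, s = 1:4, t = 1:2, j = seq_len(n_sub)))
  win[idx] <- rowSums(idx) %% 2 == 0
  win
}

test_that("word exclusion removes the constructed extremes and only those", {
  win <- fixture_win()
  retained <- exclude_words(win)
  expect_equal(length(retained), 142)
  expect_equal(sort(attr(retained, "excluded")), 1:18)
  # permissive thresholds exclude nothing
  all_kept <- exclude_words(win, easy_thresh = 1.0, hard_thresh = 0.0)
  expect_equal(length(all_kept), 160)
  # a word everyone gets right at -6 dB is excluded under the default 0.95
  expect_true(1 %in% attr(retained, "excluded"))
  expect_error(exclude_words(win[1:18, , , , drop = FALSE]), "all words")
})

test_that("WiN scoring aggregates exactly and excludes -9 dB from the summaries", {
  win <- fixture_win(n_sub = 2)
  # subject with every retained word correct
  win[19:160, , , 1] <- TRUE
  sc <- score_win(win, retained = 19:160)
  expect_true(all(sc[1, grep("^pct_", names(sc))] == 100))
  expect_equal(sc$WiNst[1], 100); expect_equal(sc$WiNam[1], 100)
  # alternating correct/incorrect scores 50 percent in every cell
  win[19:160, , , 2] <- rep(c(TRUE, FALSE), length.out = 142 * 8)
  sc <- score_win(win, retained = 19:160)
  expect_true(all(unlist(sc[2, grep("^pct_", names(sc))]) == 50))
  expect_equal(sc$WiNam[2], 50)
  # hand-computed 6-word table
  w6 <- array(NA, dim = c(6, 4, 2, 1),
              dimnames = list(NULL, c("0", "-3", "-6", "-9"), c("ST", "AM"), NULL))
  w6[, "0", "ST", 1] <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  w6[, "-3", "ST", 1] <- c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  w6[, "0", "AM", 1] <- TRUE
  w6[, "-3", "AM", 1] <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  w6[, "-6", , 1] <- FALSE; w6[, "-9", , 1] <- FALSE
  sc <- score_win(w6)
  expect_equal(sc$`pct_0_ST`, 400 / 6, tolerance = 1e-9)
  expect_equal(sc$`pct_-3_AM`, 50)
  expect_equal(sc$WiNst, (400 / 6 + 200 / 6 + 0) / 3, tolerance = 1e-9)
  expect_equal(sc$WiNam, (100 + 50 + 0) / 3)
  expect_equal(sc$`release_0`, 100 - 400 / 6, tolerance = 1e-9)
})

test_that("the normality gate picks the right branch", {
  set.seed(60)
  skewed <- rexp(25)^3
  normal <- rnorm(25)
  expect_equal(group_compare(skewed, normal)$test, "mann-whitney")
  # two clean normal samples take the parametric branch most of the time
  branches <- replicate(20, group_compare(rnorm(30), rnorm(30))$test)
  expect_gte(sum(branches == "t"), 15)
  # identical samples cannot be told apart
  x <- rnorm(10)
  expect_gt(group_compare(x, x)$p, 0.99)
  expect_error(group_compare(1:2, 1:5), "at least 3")
})

test_that("the Group x Type permutation interaction behaves under null and effect", {
  set.seed(61)
  mk_scores <- function(shift_asd) {
    n <- 40
    data.frame(WiNam = rnorm(n, 50 + rep(c(0, shift_asd), each = n / 2), 5),
               WiNst = rnorm(n, 50, 5),
               group = rep(c("TD", "ASD"), each = n / 2))
  }
  # a +10 masking-release shift confined to one group is highly significant
  out <- interaction_group_by_type(mk_scores(10), n_perm = 2000)
  expect_lt(out$p, 0.001)
  expect_gt(out$estimate, 5)
  # under the null, p is not extreme and the estimate is near zero
  pv <- replicate(15, interaction_group_by_type(mk_scores(0), n_perm = 300)$p)
  expect_gt(mean(pv), 0.2)
  expect_gt(min(pv), 1 / 301 - 1e-12)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(62)
  n <- 8
  Z <- data.frame(age = rnorm(n), iq = rnorm(n))
  x <- rnorm(n) + Z$age
  y <- rnorm(n) - Z$age
  out <- partial_correlation(x, y, Z)
  expect_equal(out$r, oracle_partial_cor(x, y, Z), tolerance = 1e-10)
  # no covariates: ordinary correlation
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # y identical to a covariate: nothing left to correlate
  expect_lt(abs(partial_correlation(x, Z$age, Z["age"])$r), 1e-6)
  # spearman equals pearson on ranks, and is monotone-invariant
  sp1 <- partial_correlation(x, y, Z, method = "spearman")$r
  expect_equal(sp1, partial_correlation(exp(x), y^3 + 2 * y, Z,
                                        method = "spearman")$r,
               tolerance = 1e-12)
  rr <- apply(cbind(x, y, as.matrix(Z)), 2, rank)
  expect_equal(sp1, oracle_partial_cor(rr[, 1], rr[, 2], rr[, 3:4]),
               tolerance = 1e-10)
  expect_error(partial_correlation(x[1:3], y[1:3], Z[1:3, ]), "observations")
})

test_that("Fisher Z for independent correlations follows the closed form", {
  expect_equal(fisher_z_independent(0.4, 30, 0.4, 50)$Z, 0)
  out <- fisher_z_independent(0.5, 28, 0, 28)
  expect_equal(out$Z, atanh(0.5) / sqrt(2 / 25), tolerance = 1e-12)
  a <- fisher_z_independent(0.7, 40, 0.2, 35)
  b <- fisher_z_independent(0.2, 35, 0.7, 40)
  expect_equal(a$Z, -b$Z, tolerance = 1e-12)
  expect_error(fisher_z_independent(1, 30, 0.2, 30), "\\|r\\| < 1")
})

test_that("Steiger's dependent-correlation Z matches the reference formula", {
  expect_equal(fisher_z_dependent(0.5, 0.5, 0.3, 26)$Z, 0)
  # worked example: r(x,y1)=.63, r(x,y2)=.31, r(y1,y2)=.42, n=103
  out <- fisher_z_dependent(0.63, 0.31, 0.42, 103)
  expect_equal(out$Z, oracle_steiger_z(0.63, 0.31, 0.42, 103),
               tolerance = 1e-10)
  expect_gt(out$Z, 0); expect_lt(out$p, 0.01)
  # |Z| grows with the overlap correlation at a fixed difference
  zs <- sapply(c(0.1, 0.3, 0.5, 0.7), function(r23)
    abs(fisher_z_dependent(0.6, 0.4, r23, 40)$Z))
  expect_true(all(diff(zs) > 0))
  expect_error(fisher_z_dependent(0.9, -0.9, 0.9, 30), "inconsistent")
})
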