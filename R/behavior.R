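#' Exclude over-easy and over-hard words
#'
#' A word is removed when its accuracy, pooled over subjects and noise types,
#' exceeds `easy_thresh` at the hardest retained SNR (-6 dB: even in the
#' hardest scored condition virtually everyone repeats it) or falls below
#' `hard_thresh` at the easiest SNR (0 dB: virtually no one repeats it even in
#' the easiest condition).
#'
#' @param win logical array `[word, snr, type, subject]` (`NA` = not
#'   presented), as produced by [simulate_win_behavior()].
#' @param easy_thresh,hard_thresh pooled-accuracy thresholds in (0, 1).
#' @param hardest,easiest SNR labels (dimnames of `win`) used for the two
#'   criteria.
#' @return integer vector of retained word indices, with attribute
#'   `"excluded"`.
#' @export
exclude_words <- function(win, easy_thresh = 0.95, hard_thresh = 0.05,
                          hardest = "-6", easiest = "0") {
  stopifnot(easy_thresh > hard_thresh, easy_thresh <= 1, hard_thresh >= 0)
  acc_hard <- apply(win[, hardest, , , drop = FALSE], 1, mean, na.rm = TRUE)
  acc_easy <- apply(win[, easiest, , , drop = FALSE], 1, mean, na.rm = TRUE)
  excl <- which(acc_hard > easy_thresh | acc_easy < hard_thresh)
  retained <- setdiff(seq_len(dim(win)[1]), excl)
  if (length(retained) == 0L) stop("all words excluded; thresholds too tight")
  attr(retained, "excluded") <- excl
  retained
}

#' Words-in-noise scores
#'
#' Percent correct per subject in each (SNR, noise type) cell over the
#' retained words, plus the WiNst and WiNam summary scores (mean percent over
#' SNR 0, -3, -6 dB; the -9 dB condition is computed but excluded from the
#' summaries) and the per-SNR masking release (AM minus ST).
#'
#' @param win logical array `[word, snr, type, subject]`.
#' @param retained retained word indices from [exclude_words()].
#' @return data.frame, one row per subject: `pct_<snr>_<type>` columns,
#'   `WiNst`, `WiNam`, `release_<snr>`.
#' @export
score_win <- function(win, retained = seq_len(dim(win)[1])) {
  snr <- dimnames(win)[[2]]; types <- dimnames(win)[[3]]
  n_sub <- dim(win)[4]
  cells <- apply(win[retained, , , , drop = FALSE], c(2, 3, 4), mean,
                 na.rm = TRUE) * 100
  out <- data.frame(subject = seq_len(n_sub))
  for (s in snr) for (ty in types)
    out[[paste0("pct_", s, "_", ty)]] <- cells[s, ty, ]
  keep <- setdiff(snr, "-9")
  summarise <- function(ty) {
    m <- cells[keep, ty, , drop = FALSE]
    dim(m) <- c(length(keep), n_sub)
    colMeans(m)
  }
  out$WiNst <- summarise("ST")
  out$WiNam <- summarise("AM")
  for (s in keep)
    out[[paste0("release_", s)]] <- cells[s, "AM", ] - cells[s, "ST", ]
  out
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each sample; if either deviates from normality at p < 0.05
#' a Mann-Whitney U test is used, otherwise a two-sample t-test. The branch
#' taken is recorded.
#'
#' @param a,b numeric samples.
#' @return list with `test` (`"t"` or `"mann-whitney"`), `statistic`, `p`,
#'   `shapiro_p` (length 2).
#' @export
group_compare <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L) stop("need at least 3 observations per group")
  sw <- c(shapiro.test(a)$p.value, shapiro.test(b)$p.value)
  if (any(sw < 0.05)) {
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p = wt$p.value, shapiro_p = sw)
  } else {
    tt <- t.test(a, b)
    list(test = "t", statistic = unname(tt$statistic), p = tt$p.value,
         shapiro_p = sw)
  }
}

#' Group x noise-type interaction by permutation
#'
#' With two within-subject noise types, the random-intercept Group x Type
#' interaction reduces exactly to a between-group comparison of per-subject
#' difference scores (AM minus ST, averaged over SNR). The observed difference
#' in group means is compared against `n_perm` random relabelings.
#'
#' @param scores data.frame from [score_win()] with a `group` column attached.
#' @param n_perm number of label permutations.
#' @return list with `estimate` (mean ASD release minus mean TD release), `p`
#'   (two-tailed permutation p), `n_perm`.
#' @export
interaction_group_by_type <- function(scores, n_perm = 10000L) {
  stopifnot("group" %in% names(scores))
  d <- scores$WiNam - scores$WiNst
  keep <- is.finite(d)
  if (any(!keep)) message(sum(!keep), " subject(s) dropped for missing cells")
  d <- d[keep]; g <- scores$group[keep]
  obs <- mean(d[g == "ASD"]) - mean(d[g == "TD"])
  perm <- vapply(seq_len(n_perm), function(k) {
    gp <- sample(g)
    mean(d[gp == "ASD"]) - mean(d[gp == "TD"])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(estimate = obs, p = p, n_perm = n_perm)
}

#' Partial correlation with covariates
#'
#' Partial correlation of `x` and `y` given the covariates, computed as the
#' correlation of the two sets of OLS residuals after regressing each variable
#' on the covariates (equivalent to inverting the joint correlation matrix
#' when it is nonsingular). For `method = "spearman"` all variables are
#' rank-transformed first. The two-tailed p comes from the t distribution with
#' `n - 2 - k` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of covariates (may be empty).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `statistic` (t), `df`, `p`, `n`, `method`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Z <- if (is.null(covariates) || NCOL(covariates) == 0L)
    NULL else as.matrix(covariates)
  k <- if (is.null(Z)) 0L else ncol(Z)
  n <- length(x)
  if (n <= k + 2L) stop("need more observations than covariates plus two")
  M <- cbind(x = x, y = y, Z)
  if (method == "spearman") M <- apply(M, 2, rank)
  if (!is.null(Z)) {
    D <- cbind(1, M[, -(1:2), drop = FALSE])
    if (qr(D)$rank < ncol(D)) stop("singular covariate matrix")
    rx <- resid(lm.fit(D, M[, 1]))
    ry <- resid(lm.fit(D, M[, 2]))
  } else {
    rx <- M[, 1] - mean(M[, 1]); ry <- M[, 2] - mean(M[, 2])
  }
  # a variable fully explained by the covariates has nothing left to correlate
  r <- if (sd(rx) < 1e-12 * sd(M[, 1]) || sd(ry) < 1e-12 * sd(M[, 2])) 0
       else cor(rx, ry)
  df <- n - 2L - k
  t_stat <- r * sqrt(df / (1 - r^2))
  list(r = r, statistic = t_stat, df = df, p = 2 * pt(-abs(t_stat), df),
       n = n, method = method)
}

#' Fisher Z comparison of two independent correlations
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed
#' normal p.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (>= 4).
#' @return list with `Z`, `p`.
#' @export
fisher_z_independent <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |r| < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each sample")
  Z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Fisher Z comparison of two dependent, overlapping correlations
#'
#' Steiger's test for correlations `r(x, y1)` and `r(x, y2)` sharing the
#' variable `x`, measured on the same `n` subjects, with `r(y1, y2)` the
#' correlation between the two overlapping variables.
#'
#' @param r_xy1,r_xy2 the two correlations being compared.
#' @param r_y1y2 correlation between the overlapping variables.
#' @param n sample size.
#' @return list with `Z`, `p`.
#' @export
fisher_z_dependent <- function(r_xy1, r_xy2, r_y1y2, n) {
  C <- matrix(c(1, r_xy1, r_xy2,
                r_xy1, 1, r_y1y2,
                r_xy2, r_y1y2, 1), 3, 3)
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("inconsistent correlation triple (not positive semi-definite)")
  if (abs(r_xy1) >= 1 || abs(r_xy2) >= 1) stop("correlations must satisfy |r| < 1")
  rbar <- (r_xy1 + r_xy2) / 2
  psi <- r_y1y2 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_y1y2^2)
  cov_z <- psi / (1 - rbar^2)^2
  Z <- (atanh(r_xy1) - atanh(r_xy2)) * sqrt((n - 3) / (2 - 2 * cov_z))
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Benjamini-Hochberg FDR decisions
#'
#' Step-up FDR control: adjusted p-values and the rejection set at level `q`.
#'
#' @param pvals numeric vector of p-values.
#' @param q FDR level.
#' @return list with `p_adj` (monotone adjusted p-values) and `reject`
#'   (logical).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0L) stop("empty p-value vector")
  p_adj <- p.adjust(pvals, method = "BH")
  list(p_adj = p_adj, reject = p_adj <= q)
}
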