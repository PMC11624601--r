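#' Select the most significant sources of a TFCE cluster
#'
#' Within each hemisphere's significant cluster (the one with the largest
#' total enhanced mass, if several), restricted to the STG+ auditory region,
#' each source's p-values are averaged over the cluster's temporal extent and
#' sources whose average is strictly below the cluster-wide mean of those
#' averages are selected.
#'
#' @param result a `tfce_result`.
#' @param space the `source_space` (defaults to the one in `result`).
#' @param region region restriction: `"stg_all"` (default STG+ union) or a
#'   vector of region labels.
#' @return named list with elements `L` and `R`, each an integer vector of
#'   selected vertex ids (possibly empty, with a warning when a cluster has no
#'   STG+ sources).
#' @export
select_most_significant_sources <- function(result, space = result$space,
                                            region = "stg_all") {
  stopifnot(inherits(result, "tfce_result"))
  if (!any(result$sig_mask)) stop("no significant cluster in the TFCE result")
  out <- list(L = integer(0), R = integer(0))
  for (h in c("L", "R")) {
    vs_h <- space$hemi == h
    labs <- unique(result$clusters[vs_h, ][result$clusters[vs_h, ] > 0])
    if (length(labs) == 0L) next
    mass <- vapply(labs, function(l)
      sum(abs(result$tfce_map[result$clusters == l])), numeric(1))
    cl <- labs[which.max(mass)]
    member <- result$clusters == cl
    t_ext <- which(colSums(member) > 0)                 # temporal extent
    cl_sources <- which(rowSums(member) > 0)
    sel_region <- region_vertices(space, region, hemi = h)
    cand <- intersect(cl_sources, sel_region)
    if (length(cand) == 0L) {
      warning("cluster in hemisphere ", h, " has no sources in the ",
              paste(region, collapse = "/"), " region")
      next
    }
    avg_p <- rowMeans(result$p_map[cand, t_ext, drop = FALSE])
    out[[h]] <- cand[avg_p < mean(avg_p)]
  }
  out
}

#' Pointwise paired contrast of two timecourse sets with FDR correction
#'
#' Paired t-test at each timepoint, Benjamini-Hochberg correction across
#' timepoints, and the maximal runs of significant samples.
#'
#' @param tc_test,tc_ctrl matrices `[subject, time]`, paired by row.
#' @param times time axis in ms (defaults to column index).
#' @param alpha FDR level.
#' @param min_run minimum length (in samples) for a run of significant
#'   timepoints to be reported.
#' @return list with `t` (statistic per timepoint), `p`, `p_adj`, `sig`
#'   (logical), and `runs` (data.frame `start`, `end` in `times` units).
#' @export
pointwise_contrast <- function(tc_test, tc_ctrl, times = seq_len(ncol(tc_test)),
                               alpha = 0.05, min_run = 1L) {
  stopifnot(all(dim(tc_test) == dim(tc_ctrl)))
  if (nrow(tc_test) < 3L) stop("need at least 3 paired subjects")
  d <- tc_test - tc_ctrl
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2, sd)
  t_stat <- ifelse(s > 0, m / (s / sqrt(n)),
                   ifelse(m == 0, 0, sign(m) * Inf))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  p_adj <- p.adjust(p, method = "BH")
  sig <- p_adj < alpha
  list(t = t_stat, p = p, p_adj = p_adj, sig = sig,
       runs = sig_runs(sig, times, min_run))
}

#' Pointwise two-sample contrast with FDR correction
#'
#' Welch t-test at each timepoint between two groups of timecourses,
#' Benjamini-Hochberg corrected across timepoints.
#'
#' @param tc_a,tc_b matrices `[subject, time]`.
#' @param times time axis in ms.
#' @param alpha FDR level.
#' @param min_run minimum significant-run length in samples.
#' @return as [pointwise_contrast()].
#' @export
pointwise_group_contrast <- function(tc_a, tc_b,
                                     times = seq_len(ncol(tc_a)),
                                     alpha = 0.05, min_run = 1L) {
  stopifnot(ncol(tc_a) == ncol(tc_b))
  if (nrow(tc_a) < 3L || nrow(tc_b) < 3L) stop("need at least 3 subjects per group")
  na <- nrow(tc_a); nb <- nrow(tc_b)
  va <- apply(tc_a, 2, var) / na
  vb <- apply(tc_b, 2, var) / nb
  dm <- colMeans(tc_a) - colMeans(tc_b)
  t_stat <- ifelse(va + vb > 0, dm / sqrt(va + vb),
                   ifelse(dm == 0, 0, sign(dm) * Inf))
  df <- ifelse(va + vb > 0,
               (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)), 1)
  p <- 2 * pt(-abs(t_stat), df = df)
  p_adj <- p.adjust(p, method = "BH")
  sig <- p_adj < alpha
  list(t = t_stat, p = p, p_adj = p_adj, sig = sig,
       runs = sig_runs(sig, times, min_run))
}

# maximal runs of TRUE in a logical vector, reported on the times axis
sig_runs <- function(sig, times, min_len = 1L) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = times[starts[keep]], end = times[ends[keep]])
}

#' Group-difference time window across sources
#'
#' For each source with at least one significant run, takes the time of its
#' first and last significant sample; the window is the mean onset and mean
#' end over those sources.
#'
#' @param runs_per_source list of data.frames as returned in `$runs` by the
#'   pointwise contrasts (one element per source).
#' @return numeric `c(onset, end)` in ms.
#' @export
group_difference_window <- function(runs_per_source) {
  on <- vapply(runs_per_source, function(r)
    if (nrow(r)) min(r$start) else NA_real_, numeric(1))
  en <- vapply(runs_per_source, function(r)
    if (nrow(r)) max(r$end) else NA_real_, numeric(1))
  if (all(is.na(on))) stop("no source has a significant run")
  c(onset = mean(on, na.rm = TRUE), end = mean(en, na.rm = TRUE))
}

#' Mean current of selected sources in a time window
#'
#' @param ev a preprocessed `evoked_set`.
#' @param condition condition name.
#' @param sources vertex ids.
#' @param window numeric `c(onset, end)` ms (inclusive).
#' @return numeric vector, one mean current per subject.
#' @export
window_mean_current <- function(ev, condition, sources, window) {
  tsel <- ev$times >= window[1] & ev$times <= window[2]
  apply(ev$current[, condition, sources, tsel, drop = FALSE], 1, mean)
}

#' Adjusted SPN magnitude
#'
#' Residuals of the test-stimulus response magnitude after ordinary least
#' squares on the control-stimulus magnitude and the square root of the mean
#' number of averaged epochs, removing inter-individual variability in overall
#' response size and averaging noise.
#'
#' @param test_mag numeric vector of per-subject test-condition magnitudes.
#' @param ctrl_mag control-condition magnitudes.
#' @param sqrt_n_epochs square root of the per-subject mean epoch count.
#' @return numeric vector of residuals (`spn_adj`), orthogonal to both
#'   regressors.
#' @export
compute_spn_adj <- function(test_mag, ctrl_mag, sqrt_n_epochs) {
  n <- length(test_mag)
  stopifnot(length(ctrl_mag) == n, length(sqrt_n_epochs) == n)
  if (n < 4L) stop("need at least 4 subjects")
  X <- cbind(1, ctrl_mag, sqrt_n_epochs)
  if (qr(X)$rank < 3L)
    stop("collinear regressors: ctrl_mag and sqrt_n_epochs do not span a full-rank design")
  unname(resid(lm(test_mag ~ ctrl_mag + sqrt_n_epochs)))
}
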