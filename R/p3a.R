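#' Detect a P3a-like positive deflection on a single timecourse
#'
#' The trace (including the prestimulus baseline) is low-passed with a
#' zero-phase 4th-order Butterworth filter at `cutoff` Hz. The candidate peak
#' is the largest local maximum inside `window` (200--400 ms); its amplitude
#' is measured relative to the mean of the nearest local minima before and
#' after the peak (searched over 0--800 ms; if a side has no local minimum,
#' that side's global minimum is used). The peak counts as present only when
#' both peak-to-minimum margins reach the RMS of the raw baseline about its
#' mean (the trace's noise floor); otherwise the amplitude is set to zero.
#'
#' @param tc numeric timecourse.
#' @param times time axis in ms; must cover -200--800 ms.
#' @param fs sampling rate, Hz.
#' @param window search window for the positive peak, ms.
#' @param cutoff low-pass cutoff, Hz.
#' @return list with `present`, `amplitude` (>= 0; 0 when absent),
#'   `peak_latency` (ms; `NA` when absent) and `baseline_rms`.
#' @export
detect_p3a <- function(tc, times, fs, window = c(200, 400), cutoff = 10) {
  stopifnot(length(tc) == length(times))
  dt <- 1000 / fs
  if (min(times) > -200 + dt || max(times) < 800 - dt)
    stop("trace must cover -200 to 800 ms")
  ba <- signal::butter(4, cutoff / (fs / 2), type = "low")
  npad <- min(length(tc) - 1L, round(3 * fs / cutoff))
  x <- as.vector(cpp_filtfilt(matrix(tc, ncol = 1), ba$b, ba$a, npad))
  # noise floor: RMS of the raw (unfiltered) baseline about its mean, so the
  # criterion compares the low-passed peak against the trace's full-band noise
  # and is invariant to constant offsets
  b <- tc[times >= -200 & times < 0]
  base_rms <- rms(b - mean(b))
  absent <- list(present = FALSE, amplitude = 0, peak_latency = NA_real_,
                 baseline_rms = base_rms)

  n <- length(x)
  interior <- 2:(n - 1)
  is_max <- c(FALSE, x[interior] > x[interior - 1] & x[interior] >= x[interior + 1], FALSE)
  is_min <- c(FALSE, x[interior] < x[interior - 1] & x[interior] <= x[interior + 1], FALSE)
  cand <- which(is_max & times >= window[1] & times <= window[2])
  if (length(cand) == 0L) return(absent)
  pk <- cand[which.max(x[cand])]

  search <- which(times >= 0 & times <= 800)
  mins <- intersect(which(is_min), search)
  before <- mins[mins < pk]
  after <- mins[mins > pk]
  side <- search[search < pk]
  v_before <- if (length(before)) x[max(before)] else min(x[side])
  side <- search[search > pk]
  v_after <- if (length(after)) x[min(after)] else min(x[side])

  amp <- x[pk] - mean(c(v_before, v_after))
  present <- (x[pk] - v_before) >= base_rms && (x[pk] - v_after) >= base_rms
  if (!present) return(absent)
  list(present = TRUE, amplitude = amp, peak_latency = times[pk],
       baseline_rms = base_rms)
}

#' P3a measures for every subject of an evoked set
#'
#' Averages the (already preprocessed, 0--800 ms) timecourses of the given
#' sources per subject, re-attaches the baseline from a baseline-bearing
#' evoked set when supplied, and applies [detect_p3a()].
#'
#' @param ev an `evoked_set` whose time axis covers -200--800 ms.
#' @param condition condition name.
#' @param sources vertex ids to average.
#' @param ... passed to [detect_p3a()].
#' @return data.frame with one row per subject: `present`, `amplitude`,
#'   `peak_latency`, `baseline_rms`.
#' @export
p3a_measures <- function(ev, condition, sources, ...) {
  n <- dim(ev$current)[1]
  out <- lapply(seq_len(n), function(i) {
    tc <- apply(ev$current[i, condition, sources, , drop = FALSE], 4, mean)
    as.data.frame(detect_p3a(tc, ev$times, ev$fs, ...))
  })
  cbind(subject = seq_len(n), do.call(rbind, out))
}

#' Compare P3a occurrence between two sets of detection flags
#'
#' 2 x 2 Pearson chi-square on detected/absent counts, without continuity
#' correction.
#'
#' @param flags_a,flags_b logical vectors of detection flags.
#' @return list with `chisq`, `df`, `p`, and the 2 x 2 `table`.
#' @export
compare_occurrence <- function(flags_a, flags_b) {
  stopifnot(length(flags_a) >= 1, length(flags_b) >= 1)
  tab <- rbind(A = c(sum(flags_a), sum(!flags_a)),
               B = c(sum(flags_b), sum(!flags_b)))
  colnames(tab) <- c("present", "absent")
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' Compare P3a amplitudes between groups (Mann-Whitney)
#'
#' Rank-based two-sample test with tie correction; reports U, the normal
#' approximation Z, the two-tailed p, and the eta-squared effect size
#' `Z^2 / N`.
#'
#' @param amps_a,amps_b numeric amplitude vectors.
#' @return list with `U`, `Z`, `p`, `eta2`, `n`.
#' @export
compare_amplitude <- function(amps_a, amps_b) {
  n1 <- length(amps_a); n2 <- length(amps_b); n <- n1 + n2
  r <- rank(c(amps_a, amps_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, Z = 0, p = 1, eta2 = 0, n = n))
  Z <- (U - mu) / sqrt(sigma2)
  p <- 2 * pnorm(-abs(Z))
  list(U = U, Z = Z, p = min(p, 1), eta2 = Z^2 / n, n = n)
}
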