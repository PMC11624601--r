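#' Align source-current polarity within each hemisphere
#'
#' Source orientations on a folded cortical sheet are sign-ambiguous, so
#' per-vertex sign flips are chosen, separately per subject and hemisphere,
#' from the leading left singular vector of the condition-averaged
#' vertex-by-time matrix (each vertex is flipped to agree with the dominant
#' current direction, to which every vertex then correlates positively). The
#' remaining global sign per subject/hemisphere is fixed by the convention
#' that the ROI-mean P100m window (50--150 ms) is positive. The procedure is
#' exactly idempotent. After alignment the ROI mean is checked for P100m
#' positivity and 300--800 ms negativity; subjects failing either check are
#' reported, not silently accepted.
#'
#' @param ev an `evoked_set`.
#' @param space the matching `source_space`.
#' @return the aligned `evoked_set`, with attributes `"flips"` (subject x
#'   vertex sign matrix) and `"flagged"` (data.frame of validation failures,
#'   zero rows if all subjects pass).
#' @export
align_polarity <- function(ev, space) {
  stopifnot(inherits(ev, "evoked_set"), inherits(space, "source_space"))
  tsel_p1 <- ev$times >= 50 & ev$times <= 150
  tsel_spn <- ev$times >= 300 & ev$times <= 800
  if (!any(tsel_p1) || !any(tsel_spn))
    stop("traces must cover both the 50-150 ms and 300-800 ms validation windows")
  n_sub <- dim(ev$current)[1]
  flips <- matrix(1, n_sub, space$n)
  flagged <- list()
  for (i in seq_len(n_sub)) {
    m <- ev$current[i, , , , drop = FALSE][1, , , , drop = TRUE]    # cond x V x T
    if (length(dim(m)) == 2L) dim(m) <- c(1L, dim(m))               # single condition
    avg <- colMeans(m, dims = 1)                                    # V x T
    for (h in c("L", "R")) {
      vs <- which(space$hemi == h)
      X <- avg[vs, , drop = FALSE]
      u <- svd(X, nu = 1, nv = 0)$u[, 1]
      s <- ifelse(u >= 0, 1, -1)
      ref <- colMeans(X * s)
      if (mean(ref[tsel_p1]) < 0) s <- -s       # P100m positivity convention
      flips[i, vs] <- s
      ref <- colMeans(X * s)
      ok_p1 <- mean(ref[tsel_p1]) > 0
      ok_spn <- mean(ref[tsel_spn]) < 0
      if (!ok_p1 || !ok_spn)
        flagged[[length(flagged) + 1L]] <-
          data.frame(subject = i, hemi = h, p100_positive = ok_p1,
                     sustained_negative = ok_spn)
    }
    ev$current[i, , , ] <- sweep(m, 2, flips[i, ], `*`)
  }
  attr(ev, "flips") <- flips
  attr(ev, "flagged") <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(subject = integer(0), hemi = character(0),
               p100_positive = logical(0), sustained_negative = logical(0))
  ev
}

# zero-phase IIR filtering of the time axis (rows = time) with reflection
# padding; b, a from signal::butter
filtfilt_mat <- function(x, b, a) {
  npad <- 3L * (max(length(a), length(b)) - 1L)
  cpp_filtfilt(x, b, a, npad)
}

#' Baseline-correct, crop and downsample an evoked set
#'
#' Subtracts the per-trace mean over the baseline window, low-passes with a
#' zero-phase 4th-order Butterworth anti-alias filter at `0.4 * fs_out`, then
#' crops to the half-open analysis window and decimates to `fs_out`.
#'
#' @param ev an `evoked_set`.
#' @param baseline numeric length-2, baseline window in ms (half-open).
#' @param window numeric length-2, analysis window in ms (half-open; the
#'   default yields 400 samples at 500 Hz).
#' @param fs_out output sampling rate, Hz.
#' @return the processed `evoked_set`.
#' @export
baseline_crop_resample <- function(ev, baseline = c(-200, 0),
                                   window = c(0, 800), fs_out = 500) {
  stopifnot(inherits(ev, "evoked_set"))
  if (fs_out > ev$fs) stop("fs_out exceeds the input sampling rate")
  tin <- ev$times
  if (window[1] < min(tin) || window[2] - 1000 / ev$fs > max(tin))
    stop("analysis window [", window[1], ", ", window[2],
         ") lies outside the data time range")
  bsel <- tin >= baseline[1] & tin < baseline[2]
  if (!any(bsel)) stop("baseline window contains no samples")
  d <- dim(ev$current)
  n_out <- round((window[2] - window[1]) * fs_out / 1000)
  t_out <- window[1] + (seq_len(n_out) - 1L) * 1000 / fs_out
  out <- array(0, dim = c(d[1], d[2], d[3], n_out),
               dimnames = c(dimnames(ev$current)[1:3], list(NULL)))
  decim <- ev$fs / fs_out
  ba <- if (fs_out < ev$fs)
    signal::butter(4, 0.4 * fs_out / (ev$fs / 2), type = "low") else NULL
  for (i in seq_len(d[1])) for (ci in seq_len(d[2])) {
    x <- ev$current[i, ci, , ]                       # V x T
    x <- x - rowMeans(x[, bsel, drop = FALSE])
    stopifnot(max(abs(rowMeans(x[, bsel, drop = FALSE]))) < 1e-8)
    xt <- t(x)                                       # time in rows
    if (!is.null(ba)) xt <- filtfilt_mat(xt, ba$b, ba$a)
    if (abs(decim - round(decim)) < 1e-9) {
      idx <- round((t_out - tin[1]) * ev$fs / 1000) + 1L
      out[i, ci, , ] <- t(xt[idx, , drop = FALSE])
    } else {
      out[i, ci, , ] <- t(apply(xt, 2, function(col)
        approx(tin, col, xout = t_out)$y))
    }
  }
  structure(list(current = out, times = t_out, fs = fs_out,
                 conditions = ev$conditions, n_epochs = ev$n_epochs),
            class = "evoked_set")
}

#' Differential responses (test minus control) for one condition
#'
#' @param ev a preprocessed `evoked_set`.
#' @param test test condition name.
#' @param control control condition name.
#' @return array `[subject, vertex, time]` of differential responses.
#' @export
differential_response <- function(ev, test, control = "control") {
  stopifnot(test %in% ev$conditions, control %in% ev$conditions)
  ev$current[, test, , ] - ev$current[, control, , ]
}
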