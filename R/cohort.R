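#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the pipeline is designed for: 39
#' typically developing (TD) and 35 ASD boys aged ~7--13, a mean of 231
#' averaged epochs per condition, a positive P100m transient near 100 ms, a
#' condition-dependent sustained negative shift (SPN) in the auditory (STG+)
#' band with onset before 100 ms and duration of several hundred ms, an ASD
#' group deficit confined to the A4/pINS patches and to 150--450 ms for the
#' vowel conditions, and a left-lateralized P3a-like positive bump at 300 ms
#' that is larger in ASD for periodic vowels. Amplitudes are in arbitrary
#' source-current units; only relative effects are meaningful.
#'
#' @param ... named overrides of any default listed below.
#' @return a list of generator parameters (class `cohort_config`).
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_td = 39L, n_asd = 35L,
    fs = 1000, tmin = -200, tmax = 900,
    conditions = c("periodic_vowel", "nonperiodic_vowel",
                   "periodic_nonvowel", "control"),
    # epochs retained after artifact rejection
    epochs_mean = 231, epochs_sd = 45, epochs_range = c(130, 350),
    # noise: temporally smoothed Gaussian, per-trace SD = noise_sd0 / sqrt(n_epochs)
    noise_sd0 = 20, noise_smooth_ms = 8,
    # P100m transient (positive)
    p100_amp = 25, p100_lat = 100, p100_width = 20,
    # sustained component amplitude per condition (negative shift);
    # differential (test - control) amplitudes are therefore -4 .. -6 a.u.
    sustained_amp = c(periodic_vowel = -14, nonperiodic_vowel = -13,
                      periodic_nonvowel = -12, control = -8),
    sustained_rise = c(60, 140), sustained_fall = c(600, 750),
    # regional gains applied to all components
    region_gain = c(A1 = 1, A4 = 0.85, pINS = 0.7, `STG+` = 0.6, outside = 0.05),
    # multiplicative subject gain: exp(N(0, subject_gain_sd))
    subject_gain_sd = 0.15,
    # ASD deficit: fraction of the vowel differential lost in A4/pINS
    deficit_mean = 0.45, deficit_sd = 0.25,
    deficit_window = c(150, 450), deficit_edge = 10,
    deficit_regions = c("A4", "pINS"),
    deficit_conditions = c("periodic_vowel", "nonperiodic_vowel"),
    # P3a-like bump (left hemisphere, vowel conditions)
    p3a_amp = 6, p3a_lat = 300, p3a_width = 45, p3a_hemi = "L",
    p3a_conditions = c("periodic_vowel", "nonperiodic_vowel"),
    p3a_asd_periodic_scale = 1.6, p3a_subject_sd = 0.4,
    # demographics
    age_range = c(7, 13),
    iq_td = c(116, 13), iq_asd = c(83, 16)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown cohort_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$p100_amp <= 0) stop("p100_amp must be positive (P100m is a positive transient)")
  if (any(cfg$sustained_amp > 0)) stop("sustained_amp entries must be <= 0 (negative shift)")
  if (cfg$noise_sd0 <= 0) stop("noise_sd0 must be positive")
  structure(cfg, class = "cohort_config")
}

# smooth 0 -> 1 raised-cosine step between t0 and t1 (ms)
smoothstep <- function(t, t0, t1) {
  s <- (t - t0) / (t1 - t0)
  s <- pmin(pmax(s, 0), 1)
  0.5 * (1 - cos(pi * s))
}

#' Simulate the subject table
#'
#' Draws group, age, IQ, per-subject response gain and the latent ASD deficit
#' fraction (0 for TD), and derives the latent left-hemisphere vowel SPN
#' effect used as ground truth by recovery tests. Analysis operations never
#' read the latent columns.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame with one row per subject.
#' @export
simulate_subjects <- function(cfg = cohort_config()) {
  n <- cfg$n_td + cfg$n_asd
  group <- rep(c("TD", "ASD"), c(cfg$n_td, cfg$n_asd))
  age <- runif(n, cfg$age_range[1], cfg$age_range[2])
  iq <- ifelse(group == "TD",
               rnorm(n, cfg$iq_td[1], cfg$iq_td[2]),
               rnorm(n, cfg$iq_asd[1], cfg$iq_asd[2]))
  gain <- exp(rnorm(n, 0, cfg$subject_gain_sd))
  lambda <- ifelse(group == "ASD",
                   pmax(rnorm(n, cfg$deficit_mean, cfg$deficit_sd), 0), 0)
  p3a_gain <- pmax(rnorm(n, 1, cfg$p3a_subject_sd), 0)
  # latent left-hemisphere SPN to periodic vowels (signed; more negative =
  # stronger SPN); the deficit scales the vowel-specific increment
  incr <- cfg$sustained_amp[["periodic_vowel"]] - cfg$sustained_amp[["control"]]
  latent_spn <- incr * (1 - lambda) * gain
  data.frame(subject = seq_len(n), group = group, age = age, iq = iq,
             gain = gain, deficit = lambda, p3a_gain = p3a_gain,
             latent_spn = latent_spn)
}

#' Simulate source-space evoked responses for a cohort
#'
#' Per subject and condition, each vertex trace is the sum of a positive P100m
#' Gaussian bump, a condition-dependent sustained negative plateau (onset
#' before 100 ms, lasting beyond 600 ms), an optional left-hemisphere
#' P3a-like bump for vowel conditions, and temporally smoothed Gaussian noise
#' whose SD scales as `1/sqrt(n_epochs)`. The TD and ASD groups differ only
#' through the configured deficit and P3a terms. Deterministic given the seed.
#'
#' @param space a [make_source_space()] source space.
#' @param cfg a [cohort_config()].
#' @param records optional subject table from [simulate_subjects()]; drawn
#'   fresh if `NULL`.
#' @return list with `evoked` (class `evoked_set`: `current` array
#'   `[subject, condition, vertex, time]`, `times` ms, `fs`, `n_epochs`
#'   matrix) and `records` (the subject table).
#' @export
simulate_evoked <- function(space, cfg = cohort_config(), records = NULL) {
  stopifnot(inherits(space, "source_space"))
  if (is.null(records)) records <- simulate_subjects(cfg)
  n_sub <- nrow(records)
  conds <- cfg$conditions
  times <- seq(cfg$tmin, cfg$tmax, by = 1000 / cfg$fs)
  nt <- length(times)
  V <- space$n

  gv <- cfg$region_gain[space$region]          # per-vertex regional gain
  p100 <- exp(-(times - cfg$p100_lat)^2 / (2 * cfg$p100_width^2))
  p100[times < 0] <- 0
  plateau <- smoothstep(times, cfg$sustained_rise[1], cfg$sustained_rise[2]) *
    (1 - smoothstep(times, cfg$sustained_fall[1], cfg$sustained_fall[2]))
  p3a_shape <- exp(-(times - cfg$p3a_lat)^2 / (2 * cfg$p3a_width^2))
  p3a_shape[times < 0] <- 0
  wdef <- smoothstep(times, cfg$deficit_window[1],
                     cfg$deficit_window[1] + cfg$deficit_edge) *
    (1 - smoothstep(times, cfg$deficit_window[2] - cfg$deficit_edge,
                    cfg$deficit_window[2]))
  def_vert <- space$region %in% cfg$deficit_regions
  p3a_vert <- space$stg & space$hemi == cfg$p3a_hemi

  n_epochs <- matrix(pmin(pmax(round(rnorm(n_sub * length(conds),
                                           cfg$epochs_mean, cfg$epochs_sd)),
                               cfg$epochs_range[1]), cfg$epochs_range[2]),
                     n_sub, length(conds),
                     dimnames = list(NULL, conds))

  # gaussian smoothing kernel for the noise (unit output variance)
  ks <- cfg$noise_smooth_ms / 1000 * cfg$fs
  kern <- exp(-((-ceiling(3 * ks)):ceiling(3 * ks))^2 / (2 * ks^2))
  kern <- kern / sqrt(sum(kern^2))

  cur <- array(0, dim = c(n_sub, length(conds), V, nt),
               dimnames = list(NULL, conds, NULL, NULL))
  a_ctrl <- cfg$sustained_amp[["control"]]
  for (i in seq_len(n_sub)) {
    g <- records$gain[i]
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      amp <- cfg$sustained_amp[[cond]]
      # sustained term; the ASD deficit removes a fraction of the
      # condition-specific increment in the designated vertices/time window
      sust <- tcrossprod(gv * amp, plateau)                       # V x nt
      if (records$deficit[i] > 0 && cond %in% cfg$deficit_conditions) {
        # move the deficit vertices toward the control amplitude inside the
        # deficit window: amp_eff = amp - deficit * (amp - a_ctrl) * wdef
        lost <- records$deficit[i] * (amp - a_ctrl)
        sust[def_vert, ] <- sust[def_vert, ] -
          tcrossprod(gv[def_vert] * lost, plateau * wdef)
      }
      sig <- tcrossprod(gv * cfg$p100_amp, p100) + sust
      if (cond %in% cfg$p3a_conditions) {
        p3a_amp <- cfg$p3a_amp * records$p3a_gain[i]
        if (records$group[i] == "ASD" && cond == "periodic_vowel")
          p3a_amp <- p3a_amp * cfg$p3a_asd_periodic_scale
        sig[p3a_vert, ] <- sig[p3a_vert, ] +
          tcrossprod(gv[p3a_vert] * p3a_amp, p3a_shape)
      }
      noise <- matrix(rnorm(V * (nt + length(kern))), nt + length(kern), V)
      noise <- stats::filter(noise, kern, sides = 2)
      noise <- t(noise[seq_len(nt) + floor(length(kern) / 2), , drop = FALSE])
      sd_trace <- cfg$noise_sd0 / sqrt(n_epochs[i, ci])
      cur[i, ci, , ] <- g * sig + sd_trace * noise
    }
  }
  evoked <- structure(list(current = cur, times = times, fs = cfg$fs,
                           conditions = conds, n_epochs = n_epochs),
                      class = "evoked_set")
  list(evoked = evoked, records = records)
}

#' @export
print.evoked_set <- function(x, ...) {
  d <- dim(x$current)
  cat(sprintf("<evoked_set> %d subjects x %d conditions x %d vertices x %d samples (%g..%g ms @ %g Hz)\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times), x$fs))
  invisible(x)
}

#' Words-in-noise linkage configuration
#'
#' Defaults encode a logistic psychometric model for single-word recognition:
#' accuracy falls with SNR, improves with age, is better in amplitude-modulated
#' (AM) than stationary (ST) noise (masking release), and -- in AM noise only
#' -- depends on the subject's latent left-hemisphere SPN (more negative SPN,
#' better recognition; `beta_spn_am < 0`). IQ is independent of performance.
#' The word inventory contains 160 words of which 10 are made very easy and 8
#' very hard, mirroring the 18-word exclusion count.
#'
#' @param ... named overrides.
#' @return list of parameters (class `win_link_config`).
#' @export
win_link_config <- function(...) {
  cfg <- list(
    n_words = 160L, n_easy = 10L, n_hard = 8L,
    word_mean = 0.85, word_sd = 0.6, easy_shift = 8, hard_shift = -9,
    snr_levels = c(0, -3, -6, -9),
    beta_snr = 0.45,           # logits per dB
    beta_age = 0.25,           # logits per year, centred at age 10
    masking_release = 0.8,     # AM benefit, logits
    beta_spn_am = -0.25,       # logits per latent-SPN unit, AM only
    latent_ref = -6,           # latent value at which the SPN term vanishes
    group_shift_asd = -0.4,    # ASD overall deficit, logits
    subject_sd = 0.6,          # subject random intercept SD
    words_per_cell = 20L       # words presented per (snr, noise type) cell
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown win_link_config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "win_link_config")
}

#' Simulate words-in-noise responses for a cohort
#'
#' Each subject hears every word exactly once, randomly assigned to one of the
#' eight (SNR x noise type) cells (20 words per cell for the default 160-word
#' inventory); unassigned cells are `NA`. Outcomes are Bernoulli draws from
#' the logistic model of [win_link_config()].
#'
#' @param records subject table from [simulate_subjects()].
#' @param link a [win_link_config()].
#' @return list with `win` (logical array `[word, snr, type, subject]`, `NA`
#'   where the word was not presented in that cell), `flagged` (indices of the
#'   18 extreme words), `word_intercepts`, and `records` with a `win_intercept`
#'   column appended.
#' @export
simulate_win_behavior <- function(records, link = win_link_config()) {
  nw <- link$n_words
  snr <- link$snr_levels
  types <- c("ST", "AM")
  n_sub <- nrow(records)
  alpha <- rnorm(nw, link$word_mean, link$word_sd)
  easy <- seq_len(link$n_easy)
  hard <- link$n_easy + seq_len(link$n_hard)
  alpha[easy] <- alpha[easy] + link$easy_shift
  alpha[hard] <- alpha[hard] + link$hard_shift
  n_cells <- length(snr) * length(types)
  if (nw %% n_cells != 0L)
    stop("n_words must be divisible by the number of (snr, type) cells")
  u <- rnorm(n_sub, 0, link$subject_sd)
  win <- array(NA, dim = c(nw, length(snr), length(types), n_sub),
               dimnames = list(NULL, as.character(snr), types, NULL))
  for (i in seq_len(n_sub)) {
    cell <- rep(seq_len(n_cells), each = nw %/% n_cells)[sample.int(nw)]
    si <- (cell - 1L) %% length(snr) + 1L
    ti <- (cell - 1L) %/% length(snr) + 1L
    lp <- alpha + link$beta_snr * snr[si] +
      link$beta_age * (records$age[i] - 10) + u[i] +
      (records$group[i] == "ASD") * link$group_shift_asd +
      (ti == 2L) * (link$masking_release +
                      link$beta_spn_am * (records$latent_spn[i] - link$latent_ref))
    p <- stats::plogis(lp)
    correct <- rbinom(nw, 1L, p) == 1L
    win[cbind(seq_len(nw), si, ti, i)] <- correct
  }
  records$win_intercept <- u
  list(win = win, flagged = c(easy, hard), word_intercepts = alpha,
       records = records)
}
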