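#' Default vowel formant table (adult male)
#'
#' Centre frequencies (Hz) of the four lowest formants for the five strong
#' vowels, in the style of classic adult-male formant measurements, clipped to
#' the per-formant bands used for formant randomization
#' (F1 270--1300, F2 850--2260, F3 1750--3000, F4 3300--5500 Hz).
#'
#' @return a 5 x 4 numeric matrix, rows named by vowel.
#' @export
formant_table <- function() {
  m <- rbind(
    a = c(730, 1090, 2440, 3400),
    e = c(530, 1840, 2480, 3600),
    i = c(270, 2260, 2990, 3700),
    o = c(570,  850, 2410, 3300),
    u = c(300,  870, 2240, 3300)
  )
  colnames(m) <- paste0("F", 1:4)
  m
}

#' Per-formant frequency bands for formant randomization
#' @return 4 x 2 matrix of (low, high) Hz per formant.
#' @export
formant_bands <- function() {
  b <- rbind(c(270, 1300), c(850, 2260), c(1750, 3000), c(3300, 5500))
  dimnames(b) <- list(paste0("F", 1:4), c("low", "high"))
  b
}

#' Candidate carrier sets for non-vowel stimuli
#'
#' Eight log-spaced frequencies per formant spanning each formant band, used to
#' randomize the carrier of every pulse in non-vowel stimuli.
#'
#' @param n number of candidates per formant (default 8).
#' @return 4 x `n` numeric matrix.
#' @export
nonvowel_carrier_sets <- function(n = 8L) {
  b <- formant_bands()
  t(vapply(seq_len(4), function(f)
    pmin(pmax(exp(seq(log(b[f, 1]), log(b[f, 2]), length.out = n)), b[f, 1]),
         b[f, 2]), numeric(n)))
}

stimulus_classes <- c("periodic_vowel", "nonperiodic_vowel",
                      "periodic_nonvowel", "nonperiodic_nonvowel")

#' Construct a stimulus specification
#'
#' Describes one 812-ms vowel-like stimulus built from four formant trains of
#' damped sinusoids repeated every 12 ms (f0 = 83.3 Hz). Periodicity is
#' violated by jittering pulse onsets within +/- `jitter_bound` ms; formant
#' constancy is violated by drawing each pulse's carrier from a per-formant
#' candidate set.
#'
#' @param klass one of `"periodic_vowel"`, `"nonperiodic_vowel"`,
#'   `"periodic_nonvowel"`, `"nonperiodic_nonvowel"`.
#' @param vowel vowel label (`"a"`, `"e"`, `"i"`, `"o"`, `"u"`) for vowel
#'   classes, or a variant index 1--3 for non-vowel classes.
#' @param period pulse repetition period, ms.
#' @param jitter_bound onset jitter bound, ms (used by nonperiodic classes).
#' @param duration stimulus duration, ms.
#' @param ramp rise/fall time, ms.
#' @param half_life exponential decay half-life of each damped sinusoid, ms.
#' @param pulse_len length of each damped sinusoid, ms.
#' @param rate sample rate, Hz.
#' @param formants optional 4-vector of formant centres (vowel classes).
#' @param carrier_sets optional 4 x 8 matrix of candidate carriers
#'   (non-vowel classes).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(klass, vowel = "a", period = 12, jitter_bound = 6,
                          duration = 812, ramp = 10, half_life = 3,
                          pulse_len = 12, rate = 44100,
                          formants = NULL, carrier_sets = NULL) {
  klass <- match.arg(klass, stimulus_classes)
  is_vowel <- klass %in% c("periodic_vowel", "nonperiodic_vowel")
  if (is_vowel) {
    if (is.null(formants)) {
      tab <- formant_table()
      stopifnot(as.character(vowel) %in% rownames(tab))
      formants <- tab[as.character(vowel), ]
    }
    stopifnot(length(formants) == 4L)
  } else if (is.null(carrier_sets)) {
    carrier_sets <- nonvowel_carrier_sets()
  }
  structure(list(
    klass = klass, vowel = vowel, f0 = 1000 / period, period = period,
    jitter_bound = jitter_bound, duration = duration, ramp = ramp,
    half_life = half_life, pulse_len = pulse_len, rate = rate,
    formants = formants, carrier_sets = carrier_sets
  ), class = "stimulus_spec")
}

new_waveform <- function(samples, rate) {
  structure(list(samples = samples, rate = rate,
                 duration = length(samples) / rate * 1000),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %.1f ms @ %d Hz, peak %.3f\n",
              x$duration, x$rate, max(abs(x$samples))))
  invisible(x)
}

#' Synthesize one damped sinusoid pulse
#'
#' Returns `sin(2*pi*carrier*t) * 2^(-t / half_life)` sampled at `rate`,
#' starting at phase 0.
#'
#' @param carrier carrier frequency, Hz; must be below Nyquist.
#' @param half_life exponential amplitude half-life, ms.
#' @param pulse_len pulse duration, ms.
#' @param rate sample rate, Hz.
#' @return a `waveform`.
#' @export
synth_damped_pulse <- function(carrier, half_life = 3, pulse_len = 12,
                               rate = 44100) {
  if (carrier >= rate / 2)
    stop("carrier frequency ", carrier, " Hz is at or above the Nyquist frequency ",
         rate / 2, " Hz")
  if (half_life <= 0) stop("half_life must be positive")
  n <- round(pulse_len / 1000 * rate)
  t <- (seq_len(n) - 1L) / rate                  # seconds, from 0
  new_waveform(sin(2 * pi * carrier * t) * 2^(-(t * 1000) / half_life), rate)
}

#' Synthesize a vowel-like stimulus
#'
#' Sums four formant pulse trains of damped sinusoids over the stimulus
#' duration with raised-cosine rise/fall ramps, then peak-normalizes. Periodic
#' classes place pulse onsets on the exact 12-ms grid; nonperiodic classes add
#' i.i.d. uniform onset jitter in `[-jitter_bound, +jitter_bound]` ms per pulse
#' per formant (onsets clipped to the stimulus window). Vowel classes keep each
#' formant's carrier fixed; non-vowel classes draw every pulse's carrier from
#' the per-formant candidate set. Uses the current R RNG stream, so a fixed
#' seed yields a bit-identical waveform.
#'
#' @param spec a [stimulus_spec()].
#' @return a `waveform` with attribute `"pulses"`: a data.frame with one row
#'   per rendered pulse (formant, nominal and actual onset ms, deviation ms,
#'   carrier Hz).
#' @export
synth_stimulus <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  rate <- spec$rate
  n <- round(spec$duration / 1000 * rate)
  out <- numeric(n)
  nonperiodic <- spec$klass %in% c("nonperiodic_vowel", "nonperiodic_nonvowel")
  nonvowel <- spec$klass %in% c("periodic_nonvowel", "nonperiodic_nonvowel")
  nominal <- seq(0, spec$duration - 1e-9, by = spec$period)
  log <- list()
  for (f in 1:4) {
    onsets <- nominal
    if (nonperiodic)
      onsets <- onsets + runif(length(onsets), -spec$jitter_bound, spec$jitter_bound)
    onsets <- pmin(pmax(onsets, 0), spec$duration)   # clip to stimulus window
    carriers <- if (nonvowel) {
      cand <- spec$carrier_sets[f, ]
      cand[sample.int(length(cand), length(onsets), replace = TRUE)]
    } else rep(spec$formants[f], length(onsets))
    pulse_cache <- new.env(parent = emptyenv())
    for (k in seq_along(onsets)) {
      key <- as.character(carriers[k])
      p <- get0(key, envir = pulse_cache)
      if (is.null(p)) {
        p <- synth_damped_pulse(carriers[k], spec$half_life, spec$pulse_len, rate)$samples
        assign(key, p, envir = pulse_cache)
      }
      i0 <- round(onsets[k] / 1000 * rate) + 1L
      i1 <- min(i0 + length(p) - 1L, n)
      if (i1 >= i0) out[i0:i1] <- out[i0:i1] + p[seq_len(i1 - i0 + 1L)]
    }
    log[[f]] <- data.frame(formant = f, pulse = seq_along(onsets),
                           nominal_ms = nominal, onset_ms = onsets,
                           deviation_ms = onsets - nominal, carrier = carriers)
  }
  out <- apply_ramp(out, spec$ramp, rate)
  peak <- max(abs(out))
  if (peak > 0) out <- out / peak
  w <- new_waveform(out, rate)
  attr(w, "pulses") <- do.call(rbind, log)
  attr(w, "spec") <- spec
  w
}

#' Generate a randomized trial sequence
#'
#' 270 stimuli per class by default, with three variants equally represented
#' (90 each), in random order, with inter-stimulus intervals drawn uniformly
#' from 500--800 ms.
#'
#' @param n_per_class trials per stimulus class.
#' @param n_variants variants per class; must divide `n_per_class`.
#' @param isi numeric length-2, ISI range in ms.
#' @param duration stimulus duration in ms (used to compute onsets).
#' @return data.frame with columns `trial`, `class`, `variant`, `onset_ms`,
#'   `isi_ms`.
#' @export
make_trial_sequence <- function(n_per_class = 270L, n_variants = 3L,
                                isi = c(500, 800), duration = 812) {
  if (n_per_class %% n_variants != 0L)
    stop("n_per_class (", n_per_class, ") is not divisible by n_variants (",
         n_variants, ")")
  per_var <- n_per_class %/% n_variants
  d <- expand.grid(variant = seq_len(n_variants), class = stimulus_classes,
                   rep = seq_len(per_var), stringsAsFactors = FALSE)
  d <- d[sample.int(nrow(d)), c("class", "variant")]
  d$isi_ms <- runif(nrow(d), isi[1], isi[2])
  d$onset_ms <- c(0, cumsum(duration + d$isi_ms))[seq_len(nrow(d))]
  d$trial <- seq_len(nrow(d))
  rownames(d) <- NULL
  d[, c("trial", "class", "variant", "onset_ms", "isi_ms")]
}

#' Construct a masker specification
#'
#' @param noise_type `"ST"` (stationary pink noise) or `"AM"`
#'   (10 Hz sinusoidally amplitude-modulated pink noise).
#' @param snr_db signal-to-noise ratio in dB relative to a unit-RMS word.
#' @param am_rate modulation rate, Hz.
#' @param duration noise duration, ms.
#' @param lead noise onset before word onset, ms.
#' @param ramp onset/offset smoothing, ms.
#' @param rate sample rate, Hz.
#' @return an object of class `masker_spec`.
#' @export
masker_spec <- function(noise_type = c("ST", "AM"), snr_db = 0, am_rate = 10,
                        duration = 1000, lead = 75, ramp = 1, rate = 44100) {
  noise_type <- match.arg(noise_type)
  stopifnot(snr_db %in% c(0, -3, -6, -9) || is.finite(snr_db))
  structure(list(noise_type = noise_type, snr_db = snr_db, am_rate = am_rate,
                 duration = duration, lead = lead, ramp = ramp, rate = rate),
            class = "masker_spec")
}

# Pink noise (power spectral density proportional to 1/f, i.e. -3 dB/octave)
# by frequency-domain shaping of white Gaussian noise.
pink_noise <- function(n, rate) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))                      # avoid division by zero at DC
  f <- pmin(f, n - f + 1)                        # mirror for negative freqs
  X <- X / sqrt(f)
  X[1] <- 0
  y <- Re(fft(X, inverse = TRUE) / n)
  y / rms(y)
}

#' Synthesize a masking-noise waveform
#'
#' Stationary pink noise (PSD slope -3 dB/octave), optionally amplitude
#' modulated by a sinusoid starting at phase 0 degrees, with 1-ms onset/offset
#' smoothing. The output RMS realizes `snr_db` against a unit-RMS word:
#' `rms = 10^(-snr_db/20)`.
#'
#' @param spec a [masker_spec()].
#' @return a `waveform`.
#' @export
synth_masker <- function(spec) {
  stopifnot(inherits(spec, "masker_spec"))
  n <- round(spec$duration / 1000 * spec$rate)
  x <- pink_noise(n, spec$rate)
  if (spec$noise_type == "AM") {
    t <- (seq_len(n) - 1L) / spec$rate
    x <- x * (1 + sin(2 * pi * spec$am_rate * t)) / 2
  }
  x <- apply_ramp(x, spec$ramp, spec$rate)
  x <- x / rms(x) * 10^(-spec$snr_db / 20)
  new_waveform(x, spec$rate)
}

#' Mix a word with a masking noise
#'
#' The masker starts at time 0 and the word exactly `lead` ms (default 75)
#' later; the word is scaled to unit RMS (fixed level) and the masker level is
#' set by `snr_db`.
#'
#' @param word a `waveform` containing the word.
#' @param spec a [masker_spec()].
#' @return a `waveform` of the mixture, with attribute `"word_onset_ms"`.
#' @export
mix_word_with_masker <- function(word, spec) {
  stopifnot(inherits(word, "waveform"), inherits(spec, "masker_spec"))
  if (word$rate != spec$rate) stop("word and masker sample rates differ")
  if (word$duration > spec$duration - spec$lead)
    stop("word duration ", round(word$duration), " ms exceeds ",
         spec$duration - spec$lead, " ms available after the noise lead")
  masker <- synth_masker(spec)
  w <- word$samples / rms(word$samples)
  out <- masker$samples
  i0 <- round(spec$lead / 1000 * spec$rate) + 1L
  idx <- i0:(i0 + length(w) - 1L)
  out[idx] <- out[idx] + w
  m <- new_waveform(out, spec$rate)
  attr(m, "word_onset_ms") <- spec$lead
  m
}
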