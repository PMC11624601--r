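test_that("damped pulse follows its analytic definition", {
  w <- synth_damped_pulse(1000, half_life = 3, pulse_len = 12, rate = 44100)
  expect_equal(w$samples[1], 0)                       # sin at phase 0
  t <- (seq_along(w$samples) - 1) / 44100
  expect_equal(w$samples, sin(2 * pi * 1000 * t) * 2^(-(t * 1000) / 3))
  env <- abs(w$samples)
  i3 <- round(0.003 * 44100)
  # envelope at one half-life is half the initial envelope
  expect_lt(abs(max(env[i3 + seq_len(45)]) / max(env[seq_len(45)]) - 0.5), 0.05)
})

test_that("damped pulse spectral peak sits at the carrier", {
  w <- synth_damped_pulse(500, half_life = 10, pulse_len = 200, rate = 44100)
  sp <- Mod(fft(w$samples))
  half <- seq_len(length(sp) %/% 2)
  f <- (half - 1) * 44100 / length(sp)
  expect_lt(abs(f[which.max(sp[half])] - 500), 44100 / length(sp) * 2)
})

test_that("carriers at or above Nyquist are rejected", {
  expect_error(synth_damped_pulse(23000, rate = 44100), "Nyquist")
})

test_that("periodic stimuli have a 12-ms envelope period and f0 = 83.3 Hz", {
  set.seed(1)
  for (k in c("periodic_vowel", "periodic_nonvowel")) {
    w <- synth_stimulus(stimulus_spec(k, if (k == "periodic_vowel") "a" else 1))
    f <- estimate_f0(w)
    expect_lt(abs(f$period - 12), 0.1)
    expect_lt(abs(f$f0 - 83.3), 0.5)
    expect_gte(f$ac, 0.8)
    expect_lt(abs(w$duration - 812), 1000 / w$rate)   # within one sample
    expect_lte(max(abs(w$samples)), 1)
  }
})

test_that("jitter destroys envelope periodicity and stays within its bound", {
  for (s in 1:20) {
    set.seed(s)
    wp <- synth_stimulus(stimulus_spec("periodic_vowel", "a"))
    wn <- synth_stimulus(stimulus_spec("nonperiodic_vowel", "a"))
    lag12 <- round(0.012 * wp$rate)
    acp <- autocorr(envelope(wp$samples), lag12)[lag12 + 1]
    acn <- autocorr(envelope(wn$samples), lag12)[lag12 + 1]
    expect_lt(acn, acp)
    dev <- attr(wn, "pulses")$deviation_ms
    expect_lte(max(abs(dev)), 6)
    expect_gt(max(abs(dev)), 1)        # jitter is actually applied
  }
})

test_that("zero jitter degenerates the nonperiodic class to the periodic one", {
  set.seed(2)
  a <- synth_stimulus(stimulus_spec("periodic_vowel", "a"))
  set.seed(2)
  b <- synth_stimulus(stimulus_spec("nonperiodic_vowel", "a", jitter_bound = 0))
  expect_equal(a$samples, b$samples)
})

test_that("identical seed and spec give a bit-identical waveform", {
  set.seed(7); a <- synth_stimulus(stimulus_spec("nonperiodic_nonvowel", 1))
  set.seed(7); b <- synth_stimulus(stimulus_spec("nonperiodic_nonvowel", 1))
  expect_identical(a$samples, b$samples)
})

test_that("vowel band energy peaks near the formant centres, non-vowel carriers stay in band", {
  set.seed(3)
  spec <- stimulus_spec("periodic_vowel", "a")
  w <- synth_stimulus(spec)
  sp <- Mod(fft(w$samples))^2
  f <- (seq_along(sp) - 1) * w$rate / length(sp)
  bands <- formant_bands()
  for (fo in 1:2) {                      # strongest two formants
    sel <- f >= bands[fo, 1] & f <= bands[fo, 2]
    pk <- f[sel][which.max(sp[sel])]
    expect_lt(abs(pk - spec$formants[fo]), diff(bands[fo, ]) / 2)
  }
  wn <- synth_stimulus(stimulus_spec("periodic_nonvowel", 1))
  pulses <- attr(wn, "pulses")
  for (fo in 1:4) {
    cf <- pulses$carrier[pulses$formant == fo]
    expect_true(all(cf >= bands[fo, 1] & cf <= bands[fo, 2]))
    expect_gt(length(unique(cf)), 1)     # carriers are randomized
  }
})

test_that("stimulus onset and offset ramps rise and fall", {
  # the raised-cosine window itself is strictly monotone over each ramp
  win <- apply_ramp(rep(1, 4410), 10, 44100)
  nr <- round(0.010 * 44100)
  expect_true(all(diff(win[1:nr]) > 0))
  expect_true(all(diff(win[(4410 - nr + 1):4410]) < 0))
  expect_true(all(win[(nr + 1):(4410 - nr)] == 1))
  # and it is actually applied: the ramped stimulus is attenuated at the
  # edges exactly by the window relative to an unramped synthesis
  set.seed(4)
  w1 <- synth_stimulus(stimulus_spec("periodic_vowel", "o"))
  set.seed(4)
  w0 <- synth_stimulus(stimulus_spec("periodic_vowel", "o", ramp = 0))
  n <- length(w1$samples)
  wfull <- apply_ramp(rep(1, n), 10, w1$rate)
  scale <- max(abs(w0$samples * wfull)) / 1   # both are peak-normalized
  idx <- which(abs(w0$samples) > 0.05)
  ratio <- (w1$samples * scale / w0$samples)[idx]
  expect_equal(ratio, wfull[idx], tolerance = 1e-6)
})

test_that("trial sequences have exact counts and uniform ISIs", {
  set.seed(5)
  d <- make_trial_sequence()
  expect_equal(nrow(d), 1080)
  expect_true(all(table(d$class) == 270))
  expect_true(all(table(d$class, d$variant) == 90))
  expect_true(all(d$isi_ms >= 500 & d$isi_ms <= 800))
  expect_error(make_trial_sequence(n_per_class = 10, n_variants = 3),
               "divisible")
  d3 <- make_trial_sequence(n_per_class = 3, n_variants = 3)
  expect_true(all(table(d3$class, d3$variant) == 1))
  isi <- replicate(40, make_trial_sequence(n_per_class = 9)$isi_ms)
  expect_gt(min(isi), 500); expect_lt(max(isi), 800)
  expect_lt(abs(mean(isi) - 650), 5)     # uniform-law mean
})

test_that("maskers realize pink 1/f spectra, 10 Hz AM and the requested level", {
  set.seed(6)
  st <- synth_masker(masker_spec("ST", snr_db = -3))
  expect_equal(rms(st$samples), 10^(3 / 20), tolerance = 1e-9)
  slope_db_oct <- function(x, rate) {
    pg <- spec.pgram(ts(x, frequency = rate), spans = 31, plot = FALSE)
    sel <- pg$freq > 100 & pg$freq < 5000
    unname(coef(lm(log10(pg$spec[sel]) ~ log10(pg$freq[sel])))[2]) *
      10 * log10(2)
  }
  expect_lt(abs(slope_db_oct(st$samples, st$rate) + 3), 1)
  st2 <- synth_masker(masker_spec("ST", snr_db = -3))
  expect_false(identical(st$samples, st2$samples))
  expect_lt(abs(slope_db_oct(st2$samples, st2$rate) + 3), 1)

  am <- synth_masker(masker_spec("AM", snr_db = 0))
  env <- envelope(am$samples); env <- env - mean(env)
  sp <- Mod(fft(env))
  f <- (seq_along(sp) - 1) / (length(env) / am$rate)
  sel <- f > 1 & f < 100
  expect_equal(round(f[sel][which.max(sp[sel])]), 10)
})

test_that("word-masker mixtures place the word 75 ms after noise onset at the requested SNR", {
  set.seed(8)
  word <- synth_stimulus(stimulus_spec("periodic_vowel", "a"))
  m <- mix_word_with_masker(word, masker_spec("ST", snr_db = 0))
  expect_equal(attr(m, "word_onset_ms"), 75)
  lead <- seq_len(round(0.075 * m$rate))
  # at +60 dB SNR the masker is negligible: lead is near-silent and the word
  # segment correlates > 0.99 with the word
  hi <- mix_word_with_masker(word, masker_spec("ST", snr_db = 60))
  expect_lt(rms(hi$samples[lead]), 0.01)
  seg <- hi$samples[max(lead) + seq_along(word$samples)]
  expect_gt(cor(seg, word$samples), 0.99)
  # measured word-vs-masker RMS ratio matches the requested SNR within 0.5 dB
  for (snr in c(0, -6)) {
    mm <- mix_word_with_masker(word, masker_spec("ST", snr_db = snr))
    masker_only <- mm$samples
    masker_only[max(lead) + seq_along(word$samples)] <-
      masker_only[max(lead) + seq_along(word$samples)] -
      word$samples / rms(word$samples)
    measured <- 20 * log10(1 / rms(masker_only))
    expect_lt(abs(measured - snr), 0.5)
  }
  long_word <- word; long_word$duration <- 990
  expect_error(mix_word_with_masker(long_word, masker_spec("ST")), "exceeds")
})

test_that("WAV files round-trip bit-exactly at 16 bits", {
  set.seed(9)
  w <- synth_stimulus(stimulus_spec("periodic_vowel", "i"))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$rate, w$rate)
  expect_equal(back$duration, w$duration)
  quantized <- round(pmin(pmax(w$samples, -1), 1) * 32767) / 32767
  expect_equal(back$samples, quantized, tolerance = 1e-12)
  # a second round trip is the identity
  write_wav(back, path)
  expect_identical(read_wav(path)$samples, back$samples)
})
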