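#!/usr/bin/env Rscript
# Stage 1: synthesize the auditory stimuli and the words-in-noise maskers,
# verify their acoustic construction figures, and write example audio plus the
# trial sequence.
#
# Findings this script prints: the periodic classes carry an 83.3 Hz envelope
# periodicity (12 ms pulse grid) that the +/-6 ms onset jitter destroys; the
# maskers realize a 1/f (pink) spectrum and, for the AM variant, a 10 Hz
# envelope; the trial sequence holds 270 stimuli per class with 500-800 ms
# ISIs.

suppressPackageStartupMessages(library(spnpipe))
set.seed(1)
out <- "results/stimuli"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (klass in c("periodic_vowel", "nonperiodic_vowel",
                "periodic_nonvowel", "nonperiodic_nonvowel")) {
  vowel <- if (grepl("nonvowel$", klass)) 1 else "a"
  w <- synth_stimulus(stimulus_spec(klass, vowel))
  f <- estimate_f0(w)
  dev <- max(abs(attr(w, "pulses")$deviation_ms))
  write_wav(w, file.path(out, paste0(klass, ".wav")))
  rows[[klass]] <- data.frame(
    class = klass, duration_ms = round(w$duration, 2),
    envelope_period_ms = round(f$period, 3),
    envelope_f0_hz = round(f$f0, 1),
    periodicity_ac = round(f$ac, 3),
    max_onset_deviation_ms = round(dev, 3))
  cat(sprintf("%-22s period %6.2f ms  f0 %5.1f Hz  ac %5.2f  max|jitter| %4.2f ms\n",
              klass, f$period, f$f0, f$ac, dev))
}
stim_tab <- do.call(rbind, rows)
write.csv(stim_tab, file.path(out, "stimulus_checks.csv"), row.names = FALSE)

seq_tab <- make_trial_sequence()
write.csv(seq_tab, file.path(out, "trial_sequence.csv"), row.names = FALSE)
cat(sprintf("trial sequence: %d trials, ISI %.0f-%.0f ms (mean %.0f)\n",
            nrow(seq_tab), min(seq_tab$isi_ms), max(seq_tab$isi_ms),
            mean(seq_tab$isi_ms)))

for (ty in c("ST", "AM")) {
  m <- synth_masker(masker_spec(ty, snr_db = 0))
  write_wav(m, file.path(out, paste0("masker_", ty, ".wav")))
}
env <- envelope(synth_masker(masker_spec("AM"))$samples)
env <- env - mean(env)
sp <- Mod(fft(env))
freq <- (seq_along(sp) - 1) / (length(env) / 44100)
sel <- freq > 1 & freq < 100
cat(sprintf("AM masker envelope peak: %.0f Hz\n",
            freq[sel][which.max(sp[sel])]))
word <- synth_stimulus(stimulus_spec("periodic_vowel", "a"))
mix <- mix_word_with_masker(word, masker_spec("AM", snr_db = -3))
write_wav(mix, file.path(out, "word_in_AM_noise_-3dB.wav"))
cat("word-in-noise example written (75 ms noise lead, -3 dB SNR)\n")
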