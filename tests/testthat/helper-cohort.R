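# Shared fixtures for cohort-level tests: small, fast configurations of the
# generator. All stochastic fixtures are built under an explicit seed inside
# each test.

small_space <- function() make_source_space(50)

# fast cohort at the analysis sampling rate (no decimation needed)
fast_cohort <- function(...) {
  cohort_config(fs = 250, tmax = 800,
                conditions = c("nonperiodic_vowel", "control"), ...)
}

# cohort with every group difference and every evoked component that could
# distinguish test from control switched off: differential responses are pure
# noise, groups are exchangeable
null_cohort <- function(...) {
  cohort_config(fs = 25, tmax = 800, n_td = 10L, n_asd = 10L,
                conditions = c("periodic_vowel", "control"),
                sustained_amp = c(periodic_vowel = -8, nonperiodic_vowel = -8,
                                  periodic_nonvowel = -8, control = -8),
                p3a_amp = 0, deficit_mean = 0, deficit_sd = 0, ...)
}

# generate, align and crop a cohort in one step
run_cohort <- function(cfg, space, fs_out = cfg$fs) {
  sim <- simulate_evoked(space, cfg)
  pre <- baseline_crop_resample(align_polarity(sim$evoked, space),
                                fs_out = fs_out)
  list(pre = pre, records = sim$records)
}

# constructed P3a test trace: negative sustained plateau, optional positive
# bump whose absolute peak reaches `peak` at 300 ms, plus white noise
p3a_trace <- function(peak = 0, plateau_amp = -0.5, noise = 0.05, fs = 500,
                      bump_sd = 40) {
  times <- seq(-200, 800, by = 1000 / fs)
  plateau <- spnpipe:::smoothstep(times, 60, 140) *
    (1 - spnpipe:::smoothstep(times, 600, 750))
  bump_height <- if (peak != 0) peak - plateau_amp else 0
  x <- plateau_amp * plateau + bump_height * exp(-(times - 300)^2 / (2 * bump_sd^2)) +
    rnorm(length(times), 0, noise)
  list(x = x, times = times, fs = fs)
}
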