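#!/usr/bin/env Rscript
# Stage 3: the source-space cluster analysis. Runs the full pipeline on a
# synthetic cohort at the desk-scale test profile (50 vertices/hemisphere,
# 500 permutations, 250 Hz): one-sample TFCE per group for the sustained
# processing negativity (SPN, test vs control), the two-sample TFCE on
# differential responses for the group deficit, most-significant-source
# selection, the group-difference time window, SPNadj and the P3a measures.
#
# Findings this script prints: both groups show a significant SPN; the group
# difference is confined to the A4/pINS patches with a time window close to
# the injected 150-450 ms; the P3a-like deflection is detected in most
# subjects in the left auditory region.

suppressPackageStartupMessages(library(spnpipe))
out <- "results/pipeline"

cfg <- pipeline_config(seed = 11L, profile = "test",
                       cohort = cohort_config(fs = 500),
                       test_condition = "nonperiodic_vowel")
report <- suppressWarnings(run_full(cfg, out_dir = out))

for (g in names(report$one_sample))
  cat(sprintf("one-sample TFCE (%s): %d significant points, min p = %.4g\n",
              g, sum(report$one_sample[[g]]$sig_mask),
              min(report$one_sample[[g]]$p_map)))
cat(sprintf("two-sample TFCE: %d significant points\n",
            sum(report$two_sample$sig_mask)))
print(cluster_summary(report$two_sample))

inj <- region_vertices(report$space, c("A4", "pINS"))
for (h in c("L", "R")) {
  src <- report$selection[[h]]
  if (length(src) == 0) next
  cat(sprintf("hemisphere %s: %d selected sources (%d inside A4/pINS), window %.0f-%.0f ms\n",
              h, length(src), sum(src %in% inj),
              report$windows[[h]]["onset"], report$windows[[h]]["end"]))
}
cat(sprintf("P3a-like response detected in %.0f%% of subjects (left auditory region)\n",
            100 * mean(report$p3a$present)))
if (!is.null(report$linkage$partial)) {
  cat("partial Spearman correlations of SPNadj with WiN scores (ASD group):\n")
  print(report$linkage$partial, row.names = FALSE)
}
cat("report tables written under", out, "\n")
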