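#' Pipeline configuration
#'
#' Bundles every stage's parameters behind one structure with two profiles:
#' `"full"` (5000 permutations) and `"test"` (500 permutations and a
#' coarser analysis rate for desk-scale runs).
#'
#' @param seed integer seed governing every stochastic stage.
#' @param profile `"test"` or `"full"`.
#' @param n_per_hemi vertices per hemisphere of the surrogate source space.
#' @param fs_out analysis sampling rate after preprocessing, Hz.
#' @param cohort a [cohort_config()].
#' @param link a [win_link_config()].
#' @param tfce a [tfce_params()]; `n_perm` is derived from the profile when
#'   not supplied.
#' @param test_condition condition used for the group-difference branch.
#' @param alpha significance level.
#' @param min_run minimum significant-run length (samples) for window
#'   estimation.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, profile = c("test", "full"),
                            n_per_hemi = 50L, fs_out = 250,
                            cohort = cohort_config(fs = 500),
                            link = win_link_config(),
                            tfce = NULL,
                            test_condition = "periodic_vowel",
                            alpha = 0.05, min_run = 5L) {
  profile <- match.arg(profile)
  if (is.null(tfce))
    tfce <- tfce_params(n_perm = if (profile == "test") 500L else 5000L)
  structure(list(seed = as.integer(seed), profile = profile,
                 n_per_hemi = n_per_hemi, fs_out = fs_out, cohort = cohort,
                 link = link, tfce = tfce, test_condition = test_condition,
                 alpha = alpha, min_run = min_run),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes generate, preprocess, per-condition one-sample TFCE (per group),
#' two-sample TFCE on the differential responses, most-significant-source
#' selection, group-difference windows, SPNadj, P3a measures and the
#' behavioral partial-correlation linkage. When `out_dir` is given, writes the
#' result tables as CSV plus a JSON manifest of seeds and parameters.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of stage results (class `spn_report`).
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  set.seed(config$seed)
  space <- stage("source_space", make_source_space(config$n_per_hemi))
  sim <- stage("simulate", simulate_evoked(space, config$cohort))
  beh <- stage("behavior_sim", simulate_win_behavior(sim$records, config$link))
  records <- beh$records

  pre <- stage("preprocess", {
    al <- align_polarity(sim$evoked, space)
    baseline_crop_resample(al, fs_out = config$fs_out)
  })
  # uncropped (baseline-bearing) version for P3a detection
  pre_full <- stage("preprocess_full", {
    al <- align_polarity(sim$evoked, space)
    baseline_crop_resample(al, window = c(-200, 800), fs_out = config$fs_out)
  })

  test_cond <- config$test_condition
  grp <- records$group
  diffs <- differential_response(pre, test_cond)

  one_sample <- stage("one_sample_tfce", lapply(
    stats::setNames(nm = unique(grp)),
    function(g) one_sample_tfce_test(diffs[grp == g, , , drop = FALSE],
                                     space, config$tfce)))
  two_sample <- stage("two_sample_tfce",
                      two_sample_tfce_test(diffs[grp == "TD", , , drop = FALSE],
                                           diffs[grp == "ASD", , , drop = FALSE],
                                           space, config$tfce))

  linkage <- NULL; windows <- NULL; spn_tab <- NULL; sel <- NULL
  if (any(two_sample$sig_mask)) {
    sel <- stage("source_selection",
                 select_most_significant_sources(two_sample, space))
    windows <- list(); spn_rows <- list()
    for (h in c("L", "R")) {
      src <- sel[[h]]
      if (length(src) == 0L) next
      runs <- lapply(src, function(v)
        pointwise_group_contrast(diffs[grp == "TD", v, , drop = TRUE],
                                 diffs[grp == "ASD", v, , drop = TRUE],
                                 times = pre$times, alpha = config$alpha,
                                 min_run = config$min_run)$runs)
      if (all(vapply(runs, nrow, integer(1)) == 0L)) next
      win <- group_difference_window(runs)
      windows[[h]] <- win
      test_mag <- window_mean_current(pre, test_cond, src, win)
      ctrl_mag <- window_mean_current(pre, "control", src, win)
      sq_ep <- sqrt(rowMeans(pre$n_epochs))
      asd <- grp == "ASD"
      spn_adj <- rep(NA_real_, nrow(records))
      spn_adj[asd] <- compute_spn_adj(test_mag[asd], ctrl_mag[asd], sq_ep[asd])
      spn_rows[[h]] <- data.frame(subject = records$subject, hemi = h,
                                  condition = test_cond,
                                  onset = win["onset"], end = win["end"],
                                  spn = test_mag, spn_adj = spn_adj)
    }
    spn_tab <- if (length(spn_rows)) do.call(rbind, spn_rows) else NULL

    linkage <- stage("behavior_linkage", {
      retained <- exclude_words(beh$win)
      scores <- score_win(beh$win, retained)
      scores$group <- grp
      asd <- grp == "ASD"
      link_rows <- list()
      if (!is.null(spn_tab)) for (h in unique(spn_tab$hemi)) {
        sa <- spn_tab$spn_adj[spn_tab$hemi == h][asd]
        for (score in c("WiNam", "WiNst")) {
          pc <- partial_correlation(sa, scores[[score]][asd],
                                    records[asd, c("age", "iq")],
                                    method = "spearman")
          link_rows[[paste(h, score)]] <-
            data.frame(hemi = h, score = score, r_part = pc$r, p = pc$p,
                       n = pc$n)
        }
      }
      list(retained = retained, scores = scores,
           partial = if (length(link_rows)) do.call(rbind, link_rows) else NULL,
           interaction = interaction_group_by_type(scores, n_perm = 2000L))
    })
  }

  p3a <- stage("p3a", {
    src <- region_vertices(space, "stg_all", hemi = config$cohort$p3a_hemi)
    p3a_measures(pre_full, test_cond, src)
  })

  report <- structure(list(
    config = config, space = space, records = records,
    one_sample = one_sample, two_sample = two_sample,
    selection = sel, windows = windows, spn = spn_tab,
    p3a = p3a, linkage = linkage
  ), class = "spn_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) if (!is.null(x)) write.csv(x, file.path(out_dir, f),
                                                 row.names = FALSE)
  w(report$records, "records.csv")
  w(report$spn, "spn_measures.csv")
  w(report$p3a, "p3a_measures.csv")
  if (!is.null(report$linkage)) {
    w(report$linkage$scores, "win_scores.csv")
    w(report$linkage$partial, "partial_correlations.csv")
  }
  w(cluster_summary(report$two_sample), "group_clusters.csv")
  jsonlite::write_json(list(
    seed = report$config$seed, profile = report$config$profile,
    n_perm = report$config$tfce$n_perm,
    n_per_hemi = report$config$n_per_hemi, fs_out = report$config$fs_out,
    package_version = as.character(utils::packageVersion("spnpipe"))
  ), file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Summarize significant clusters of a TFCE result
#'
#' @param result a `tfce_result`.
#' @return data.frame with one row per cluster: hemisphere, vertex count,
#'   temporal extent (sample indices), peak statistic and minimum p.
#' @export
cluster_summary <- function(result) {
  labs <- setdiff(unique(as.vector(result$clusters)), 0)
  if (length(labs) == 0L)
    return(data.frame(cluster = integer(0), hemi = character(0),
                      n_vertices = integer(0), t_start = integer(0),
                      t_end = integer(0), peak_stat = numeric(0),
                      min_p = numeric(0)))
  do.call(rbind, lapply(sort(labs), function(l) {
    m <- result$clusters == l
    vs <- which(rowSums(m) > 0)
    ts <- which(colSums(m) > 0)
    data.frame(cluster = l, hemi = result$space$hemi[vs[1]],
               n_vertices = length(vs), t_start = min(ts), t_end = max(ts),
               peak_stat = max(abs(result$stat_map[m])),
               min_p = min(result$p_map[m]))
  }))
}
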