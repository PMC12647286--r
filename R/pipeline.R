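# End-to-end orchestration: cohort -> (optional voxel realisation) ->
# metrics -> statistical battery -> report bundle.

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()]. A single global
#' seed fans out to fixed per-stage child seeds (cohort `seed`, imaging
#' `seed + 10000`, motion `seed + 20000`, statistics `seed + 30000`) so that
#' stages can be re-run in isolation and the whole run is reproducible.
#'
#' @param n_subjects cohort size.
#' @param seed global seed.
#' @param mode `"tabular"` (copula indices; the statistically calibrated
#'   surface) or `"voxel"` (phantom-realised indices).
#' @param n_boot bootstrap draws per mediation model.
#' @param cohort a [cohort_config()]; built from `n_subjects`/`seed` when
#'   omitted.
#' @param phantom a [phantom_spec()] for voxel mode.
#' @param snr voxel-mode simulation SNR.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 50L, seed = 1L,
                            mode = c("tabular", "voxel"), n_boot = 1000L,
                            cohort = NULL, phantom = phantom_spec(),
                            snr = NULL) {
  mode <- match.arg(mode)
  cohort <- cohort %||% cohort_config(n_subjects = n_subjects, seed = seed)
  structure(list(n_subjects = n_subjects, seed = seed, mode = mode,
                 n_boot = n_boot, cohort = cohort, phantom = phantom,
                 snr = snr),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stop_stage(stage, conditionMessage(e)))
}

#' Run the full synthetic ALPS analysis pipeline
#'
#' Generates the synthetic cohort, optionally realises every scan as a
#' noisy diffusion phantom, simulates head-motion traces, and runs the
#' statistical battery: the marker correlation table, FDR-corrected
#' imaging-by-sleep correlation panels for the 4 PM, 9 AM and session-change
#' views, standardized regressions of the volumetric ratios on the indices
#' (forest-plot data), the ten-model mediation battery, one-sample t tests
#' of the variant indices against 1, the motion-bias check, and both
#' sensitivity subsets. All tables are written as CSV and the headline
#' numbers as a machine-readable `summary.json`; any stage failure aborts
#' with the stage name. Output is deterministic for a fixed config. The
#' statistical battery needs at least 20 scans (the mediation minimum);
#' smaller runs emit the cohort, motion metrics and descriptive summary only.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output and just returns the results.
#' @return Invisibly, a list with the cohort table, every statistics object
#'   and the summary list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) message(sprintf(...))
  log_msg("alpsim pipeline: seed %d, mode %s, %d subjects",
          config$seed, config$mode, config$n_subjects)

  tab <- run_stage("cohort", {
    tab <- generate_cohort(config$cohort)
    attach_imaging(tab, mode = config$mode, spec = config$phantom,
                   snr = config$snr, seed = config$seed + 10000L)
  })

  motion <- run_stage("motion", {
    traces <- simulate_motion_cohort(config$n_subjects,
                                     seed = config$seed + 20000L)
    fds <- vapply(traces, function(tr) framewise_displacement(tr)$mean_fd,
                  numeric(1))
    list(traces = traces, mean_fd = fds)
  })

  # the full battery needs a reasonable cohort (mediation requires >= 20
  # complete cases); miniature runs still emit cohort, metrics and summary
  run_battery <- nrow(tab) >= 20L
  stats_out <- if (!run_battery) list(skipped = TRUE) else run_stage("stats", {
    seed_stats <- config$seed + 30000L
    markers <- c("rCPV", "rWMHV", "alps", "ccgALPS", "ccbALPS", "ccsALPS")
    imaging <- c("alps", "ccgALPS", "ccbALPS", "ccsALPS", "rCPV", "rWMHV",
                 "ccbDxx", "ccbDyy", "ccbDzz", "ccbFA")
    psg <- c("age", "total_sleep_time", "sleep_latency", "rem_latency",
             "waso", "sleep_efficiency", "pct_n1", "pct_n2", "pct_n3",
             "pct_rem", "arousal_index", "apnea_index", "hypopnea_index",
             "ahi", "lowest_spo2", "odi3", "t_spo2_below_90", "plm_index")
    t4 <- tab[tab$session == "4PM", ]
    t9 <- tab[tab$session == "9AM", ]
    deltas <- cohort_deltas(tab)
    dsub <- cbind(deltas, t4[match(deltas$subject, t4$subject),
                             c(psg, "diagnosis", "cpap")])
    list(
      marker_table = marker_correlation_table(tab, markers),
      panel_4pm = pearson_matrix_fdr(t4, imaging, psg),
      panel_9am = pearson_matrix_fdr(t9, imaging, psg),
      panel_delta = pearson_matrix_fdr(dsub, paste0("d_", c("alps", "ccgALPS",
                    "ccbALPS", "ccsALPS", "rCPV", "rWMHV", "ccsDzz")), psg),
      forest_rcpv = forest_data(tab, "rCPV",
                                c("alps", "ccgALPS", "ccbALPS", "ccsALPS")),
      forest_rwmhv = forest_data(tab, "rWMHV",
                                 c("alps", "ccgALPS", "ccbALPS", "ccsALPS")),
      forest_rcpv_diff = forest_data(tab, "rCPV",
        c("projDyy", "projDzz", "assocDyy", "assocDzz",
          "ccbDxx", "ccbDyy", "ccbDzz")),
      forest_rwmhv_diff = forest_data(tab, "rWMHV",
        c("projDyy", "projDzz", "assocDyy", "assocDzz",
          "ccbDxx", "ccbDyy", "ccbDzz")),
      mediation = mediation_battery(tab, n_boot = config$n_boot,
                                    seed = seed_stats),
      variant_t = lapply(stats::setNames(nm = c("ccgALPS", "ccbALPS", "ccsALPS")),
                         function(v) one_sample_t(tab[[v]], 1)),
      fd_alps = fd_alps_check(tab),
      sens_no_psych = subset_sensitivity(tab, "no_psych"),
      sens_no_cpap = subset_sensitivity(tab, "no_cpap"))
  })

  summary_list <- run_stage("summary", {
    t4 <- tab[tab$session == "4PM", ]
    t9 <- tab[tab$session == "9AM", ]
    deltas <- cohort_deltas(tab)
    battery <- if (run_battery) list(
      fd_alps_r = stats_out$fd_alps$r, fd_alps_p = stats_out$fd_alps$p,
      variant_t_p = lapply(stats_out$variant_t, `[[`, "p"),
      n_no_psych_subjects = length(unique(stats_out$sens_no_psych$subject)),
      n_no_psych_scans = nrow(stats_out$sens_no_psych),
      n_no_cpap_subjects = length(unique(stats_out$sens_no_cpap$subject)))
    else list(battery_skipped = TRUE)
    c(list(
      seed = config$seed, mode = attr(tab, "mode"),
      n_subjects = config$n_subjects, n_scans = nrow(tab),
      alps_mean_4pm = mean(t4$alps), alps_sd_4pm = stats::sd(t4$alps),
      alps_mean_9am = mean(t9$alps), alps_sd_9am = stats::sd(t9$alps),
      delta_alps_mean = mean(deltas$d_alps),
      delta_alps_sd = stats::sd(deltas$d_alps),
      mean_fd = mean(motion$mean_fd), sd_fd = stats::sd(motion$mean_fd),
      r_alps_rcpv = unname(stats::cor(tab$alps, tab$rCPV)),
      r_alps_rwmhv = unname(stats::cor(tab$alps, tab$rWMHV)),
      r_rcpv_rwmhv = unname(stats::cor(tab$rCPV, tab$rWMHV))),
      battery)
  })

  if (!is.null(out_dir)) {
    run_stage("report", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(out_dir, f)
      write_cohort(tab, p("cohort.csv"))
      utils::write.csv(data.frame(subject = sprintf("S%03d",
        seq_along(motion$mean_fd)), mean_fd = motion$mean_fd),
        p("motion_fd.csv"), row.names = FALSE)
      if (run_battery) {
        utils::write.csv(stats_out$marker_table, p("marker_correlations.csv"))
        for (panel in c("panel_4pm", "panel_9am", "panel_delta")) {
          M <- corr_matrices(stats_out[[panel]])
          utils::write.csv(M$r, p(paste0(panel, "_r.csv")))
          utils::write.csv(M$p, p(paste0(panel, "_p.csv")))
          utils::write.csv(M$q, p(paste0(panel, "_q.csv")))
        }
        for (f in c("forest_rcpv", "forest_rwmhv", "forest_rcpv_diff",
                    "forest_rwmhv_diff")) {
          utils::write.csv(stats_out[[f]], p(paste0(f, ".csv")),
                           row.names = FALSE)
        }
        utils::write.csv(as.data.frame(stats_out$mediation),
                         p("mediation_battery.csv"), row.names = FALSE)
        vt <- do.call(rbind, lapply(names(stats_out$variant_t), function(v) {
          o <- stats_out$variant_t[[v]]
          data.frame(index = v, mean = o$mean, t = o$t, df = o$df, p = o$p)
        }))
        utils::write.csv(vt, p("variant_t_tests.csv"), row.names = FALSE)
      }
      jsonlite::write_json(summary_list, p("summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
    log_msg("report bundle written to %s", out_dir)
  }

  invisible(list(table = tab, motion = motion, stats = stats_out,
                 summary = summary_list))
}
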