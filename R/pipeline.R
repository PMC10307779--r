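#' Simulate a cohort and write its session-level CSVs
#'
#' Validates the configuration before touching the filesystem (an invalid
#' configuration produces no partial files), generates the cohort, writes
#' the four tidy CSVs plus a JSON config echo, and logs the seed and a
#' cohort summary to stderr.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress the log line.
#' @return The generated `study_dataset`, invisibly.
#' @export
run_simulate <- function(cfg, out_dir, quiet = FALSE) {
  validate_generator_config(cfg)
  study <- generate_study(cfg)
  write_study(study, out_dir)
  if (!quiet)
    message("simulate: seed=", cfg$seed, " n_animals=", cfg$n_animals,
            " -> ", out_dir)
  invisible(study)
}

#' Derive the measure table and write measures.csv
#'
#' Reads (or accepts) a study dataset, validates it, derives all outcome
#' measures and writes `measures.csv` (wide, one row per animal, headers =
#' measure names) plus a `transform_flags.csv` sidecar recording which
#' columns received the cohort-level square-root transform.
#'
#' @param study A `study_dataset`, or a directory to read one from.
#' @param out_dir Output directory.
#' @param sqrt_transform Transform policy (see [build_measure_table()]).
#' @param quiet Suppress log lines.
#' @return The measure table, invisibly.
#' @export
run_derive <- function(study, out_dir, sqrt_transform = "auto",
                       quiet = FALSE) {
  if (is.character(study)) study <- read_study(study)
  validate_study(study, test_length_s = if (!is.null(study$config))
    study$config$test_length_s else 1200)
  tab <- build_measure_table(study, sqrt_transform = sqrt_transform)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(out_dir, "measures.csv"),
                   row.names = FALSE)
  flags <- attr(tab, "transform_flags")
  utils::write.csv(data.frame(measure = names(flags), transformed = flags,
                              row.names = NULL),
                   file.path(out_dir, "transform_flags.csv"),
                   row.names = FALSE)
  if (!quiet) {
    tf <- names(flags)[flags]
    message("derive: ", nrow(tab), " animals; transformed columns: ",
            if (length(tf)) paste(tf, collapse = ", ") else "none")
    if (all(is.na(tab[, post_measure_names()])))
      message("derive: post-surgery phase absent; post-surgery columns NA")
  }
  invisible(tab)
}

battery_row <- function(test, measure, res) {
  df1 <- if (!is.null(res$df)) res$df[1] else NA_real_
  df2 <- if (!is.null(res$df) && length(res$df) > 1) res$df[2] else NA_real_
  data.frame(test = test, measure = measure,
             statistic_name = res$statistic_name,
             statistic = res$statistic, df1 = df1, df2 = df2, p = res$p,
             stringsAsFactors = FALSE)
}

#' Run the group-level statistical battery
#'
#' Reproduces the reported battery structure over a cohort: session-course
#' within-subjects ANOVAs (reflex latency, vehicle locomotion, normalized
#' oxycodone locomotion, CPP scores including the pre-test), one-sample t
#' tests of the four slope measures against zero, paired pre/post
#' conditioning comparisons, sham-vs-CCI comparisons for every post-surgery
#' measure (switching to Mann-Whitney when either group fails the per-group
#' Shapiro-Wilk normality check at p < 0.05), and the human-equivalent-dose
#' line.
#'
#' @param study A `study_dataset` (or directory).
#' @param measures Optional pre-computed measure table.
#' @param out_dir Optional output directory for `group_stats.csv`.
#' @param dose_mg_kg Animal dose for the dose-translation line.
#' @param quiet Suppress log lines.
#' @return Data.frame of test results (one row per test).
#' @export
run_report <- function(study, measures = NULL, out_dir = NULL,
                       dose_mg_kg = 0.56, quiet = FALSE) {
  if (is.character(study)) study <- read_study(study)
  if (is.null(measures)) measures <- build_measure_table(study)
  cfg <- study$config
  pretest_day <- if (!is.null(cfg)) cfg$pretest_day else 10
  test_days <- if (!is.null(cfg)) cfg$cpp_test_days else c(17, 24, 28, 38, 45, 49, 51)
  rows <- list()
  add <- function(test, measure, res)
    rows[[length(rows) + 1L]] <<- battery_row(test, measure, res)

  # session-course ANOVAs ---------------------------------------------------
  rt <- study$reflex_trials
  pre_rt <- rt[rt$day < 56, , drop = FALSE]
  ids <- sort(unique(pre_rt$animal))
  lat_mat <- t(vapply(ids, function(id)
    session_latencies(pre_rt[pre_rt$animal == id, , drop = FALSE]),
    numeric(length(unique(pre_rt$day)))))
  add("rm_anova_sessions", "reflex withdrawal latency",
      rm_anova_one_way(lat_mat))

  cd <- study$conditioning
  days <- sort(unique(cd$day))
  veh_mat <- t(vapply(ids, function(id) {
    vapply(days, function(d)
      cd$counts[cd$animal == id & cd$day == d & cd$drug == "VEH"],
      numeric(1))
  }, numeric(length(days))))
  oxy_mat <- t(vapply(ids, function(id) {
    vapply(days, function(d)
      cd$counts[cd$animal == id & cd$day == d & cd$drug == "OXY"],
      numeric(1))
  }, numeric(length(days))))
  add("rm_anova_sessions", "VEH locomotion", rm_anova_one_way(veh_mat))
  add("rm_anova_sessions", "VEH-normalized OXY locomotion",
      rm_anova_one_way(oxy_mat - veh_mat))
  add("paired_t_day1", "OXY vs VEH locomotion",
      paired_t(oxy_mat[, 1], veh_mat[, 1]))

  pt <- study$place_tests
  cpp_days <- c(pretest_day, test_days)
  cpp_mat <- t(vapply(ids, function(id) {
    pti <- pt[pt$animal == id, , drop = FALSE]
    pre <- oxy_time(pti, pretest_day)
    vapply(cpp_days, function(d) oxy_time(pti, d) - pre, numeric(1))
  }, numeric(length(cpp_days))))
  add("rm_anova_sessions", "CPP score (incl. pre-test)",
      rm_anova_one_way(cpp_mat))
  add("paired_t", "CPP at first test vs pre-test",
      paired_t(cpp_mat[, 1], cpp_mat[, 2]))
  add("paired_t", "CPP first vs final extinction test",
      paired_t(cpp_mat[, 2], cpp_mat[, ncol(cpp_mat)]))
  add("one_sample_t_vs_0", "final CPP score",
      one_sample_t(cpp_mat[, ncol(cpp_mat)], 0))

  # slope measures vs 0 ------------------------------------------------------
  for (m in c("Rate of change in reflex pain", "Rate of loco habituation",
              "Rate of behavioral sensitization", "Rate of CPP extinction")) {
    v <- measures[[m]]
    v <- v[!is.na(v)]
    if (length(v) >= 2) add("one_sample_t_vs_0", m, one_sample_t(v, 0))
  }

  # sham vs CCI on post-surgery measures -------------------------------------
  arms <- study$animals$surgery_arm[match(measures$animal,
                                          study$animals$animal)]
  for (m in post_measure_names()) {
    v <- measures[[m]]
    ok <- !is.na(v) & !is.na(arms)
    cci <- v[ok & arms == "CCI"]
    sham <- v[ok & arms == "sham"]
    if (length(cci) < 3 || length(sham) < 3) next
    normal <- function(g) {
      sw <- tryCatch(shapiro_wilk(g), error = function(e) NULL)
      is.null(sw) || sw$p >= 0.05
    }
    if (normal(cci) && normal(sham)) {
      add("sham_vs_CCI_unpaired_t", m, unpaired_t(cci, sham))
    } else {
      add("sham_vs_CCI_mann_whitney", m, mann_whitney(cci, sham))
    }
  }

  out <- do.call(rbind, rows)
  dose <- human_equivalent_dose(dose_mg_kg)
  attr(out, "human_equivalent_dose_mg") <- dose
  if (!quiet)
    message("report: ", nrow(out), " tests; ", dose_mg_kg,
            " mg/kg corresponds to a ", dose, " mg dose in a 70 kg human")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "group_stats.csv"),
                     row.names = FALSE)
    writeLines(paste0("human_equivalent_dose_mg,", dose),
               file.path(out_dir, "dose_translation.csv"))
  }
  out
}

#' Run the data-reduction analysis and write its artifacts
#'
#' Applies [run_clustering()] to the pre-surgery measure panel (cluster
#' count searched over 2-6) and, when post-surgery columns are present, to
#' the combined pre+post panel (searched over 2-4).  Writes, per panel:
#' `corr.csv`, `corr_p.csv`, `order.txt`, `mds_coords.csv`,
#' `cluster_report.csv` and a JSON twin of the report.
#'
#' @param measures Measure table (or path to a measures.csv).
#' @param out_dir Output directory (panel subdirectories are created).
#' @param k_pre,k_combined Integer length-2 search ranges.
#' @param seed Seed for k-means restarts.
#' @param quiet Suppress log lines.
#' @return Named list of `etho_clustering` results (`pre`, maybe
#'   `combined`), invisibly.
#' @export
run_cluster_analysis <- function(measures, out_dir = NULL,
                                 k_pre = c(2L, 6L), k_combined = c(2L, 4L),
                                 seed = 1L, quiet = FALSE) {
  if (is.character(measures))
    measures <- utils::read.csv(measures, check.names = FALSE)
  panels <- list(pre = pre_measure_names())
  post <- post_measure_names()
  if (all(post %in% names(measures)) &&
      any(stats::complete.cases(measures[, post])))
    panels$combined <- c(pre_measure_names(), post)
  ranges <- list(pre = k_pre, combined = k_combined)
  results <- list()
  for (panel in names(panels)) {
    res <- run_clustering(measures, panels[[panel]],
                          k_min = ranges[[panel]][1],
                          k_max = ranges[[panel]][2], seed = seed)
    results[[panel]] <- res
    if (!quiet)
      message("cluster [", panel, "]: k = ", res$k, " of range ",
              ranges[[panel]][1], "-", ranges[[panel]][2])
    if (!is.null(out_dir)) {
      pd <- file.path(out_dir, panel)
      dir.create(pd, recursive = TRUE, showWarnings = FALSE)
      ord <- res$correlation$order
      utils::write.csv(res$correlation$r[ord, ord], file.path(pd, "corr.csv"))
      utils::write.csv(res$correlation$p[ord, ord],
                       file.path(pd, "corr_p.csv"))
      writeLines(res$correlation$measures[ord], file.path(pd, "order.txt"))
      utils::write.csv(data.frame(measure = rownames(res$mds$points),
                                  res$mds$points, check.names = FALSE),
                       file.path(pd, "mds_coords.csv"), row.names = FALSE)
      rep_df <- data.frame(measure = names(res$labels),
                           cluster = unname(res$labels))
      utils::write.csv(rep_df, file.path(pd, "cluster_report.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(k = res$k, k_range = res$k_range,
             votes = as.list(res$selection$votes),
             index_table = res$selection$index_table,
             labels = as.list(res$labels), mds_error = res$mds_error),
        file.path(pd, "cluster_report.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
    }
  }
  invisible(results)
}
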