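# End-to-end orchestration: simulate or ingest a cohort, run
# kinematics -> subject summaries -> outlier screen -> group statistics,
# and emit delimited report tables.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read trial logs from `input_dir`).
#' @param experiment experiment preset, see [vmr_design()].
#' @param n_per_arm named group sizes (simulate mode).
#' @param outlier_fraction heavy-tail mixture weight (simulate mode).
#' @param seed master seed.
#' @param input_dir directory of trial logs (ingest mode).
#' @param out_dir optional output directory for report tables.
#' @param measures summary measures to test.
#' @param t_var_equal pooled Student t (default) vs Welch for pairwise tests.
#' @param bf attach JZS Bayes factors to ANOVA and t-test rows.
#' @param bf_rscale_t,bf_rscale_anova JZS prior scales.
#' @param alpha significance level recorded in the report.
#' @param render render 100 Hz trajectories in simulate mode (turn off for
#'   large replicate studies; the analyzer then uses the commanded kinematics).
#' @return list of class `vmr_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"),
                            experiment = "exp1",
                            n_per_arm = c(CB = 10L, dlPFC = 10L, SHAM = 10L),
                            outlier_fraction = 0.1,
                            seed = 1L,
                            input_dir = NULL,
                            out_dir = NULL,
                            measures = c("target_error_deg", "explicit_deg",
                                         "implicit_deg", "aftereffect_deg"),
                            t_var_equal = TRUE,
                            bf = FALSE,
                            bf_rscale_t = sqrt(2) / 2,
                            bf_rscale_anova = 0.5,
                            alpha = 0.05,
                            render = TRUE) {
  mode <- match.arg(mode)
  if (mode == "ingest" && is.null(input_dir))
    stopf("ingest mode requires input_dir", class = "vmr_config_error")
  structure(list(mode = mode, experiment = experiment, n_per_arm = n_per_arm,
                 outlier_fraction = outlier_fraction, seed = as.integer(seed),
                 input_dir = input_dir, out_dir = out_dir, measures = measures,
                 t_var_equal = t_var_equal, bf = bf,
                 bf_rscale_t = bf_rscale_t,
                 bf_rscale_anova = bf_rscale_anova,
                 alpha = alpha, render = render),
            class = "vmr_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stopf("unknown config key(s): %s", paste(bad, collapse = ", "),
          class = "vmr_config_error")
  if (!is.null(cfg$n_per_arm)) cfg$n_per_arm <- unlist(cfg$n_per_arm)
  do.call(pipeline_config, cfg)
}

# Tidy per-measure statistics table for one cohort of subject summaries.
cohort_stats <- function(summaries, measures, t_var_equal = TRUE,
                         bf = FALSE, bf_rscale_t = sqrt(2) / 2,
                         bf_rscale_anova = 0.5) {
  rows <- list()
  add <- function(measure, test, comparison, stat, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, test = test, comparison = comparison, stat = stat,
      value = value, stringsAsFactors = FALSE)
  arms <- unique(summaries$arm)
  for (m in measures) {
    vals <- split(summaries[[m]], summaries$arm)[arms]
    g <- group_summary_from_raw(vals)
    a <- one_way_anova(g, bf = bf, bf_rscale = bf_rscale_anova)
    for (s in c("F", "p", "eta_p_sq", "cohens_f"))
      add(m, "anova", "", s, a[[s]])
    if (bf) add(m, "anova", "", "bf", a$bf$bf)
    tk <- tukey_posthoc(g, a$ms_within, a$df_within)
    for (i in seq_len(nrow(tk)))
      for (s in c("p", "cohens_d", "hedges_g"))
        add(m, "tukey", paste0(tk$group1[i], "x", tk$group2[i]), s, tk[[s]][i])
    if ("SHAM" %in% arms) {
      for (arm in setdiff(arms, "SHAM")) {
        tt <- two_sample_t(g[g$label == arm, ], g[g$label == "SHAM", ],
                           var_equal = t_var_equal, bf = bf,
                           bf_rscale = bf_rscale_t)
        for (s in c("t", "p", "cohens_d", "hedges_g"))
          add(m, "ttest", paste0(arm, "xSHAM"), s, tt[[s]])
        if (bf) add(m, "ttest", paste0(arm, "xSHAM"), "bf", tt$bf$bf)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Simulates or ingests a cohort, computes per-trial kinematics, per-subject
#' summaries and epoch curves, applies the +/- 3 SD outlier screen, and runs
#' the group-statistics battery on the screened summaries. With `out_dir`
#' set, all stage outputs are written as delimited text plus a run manifest;
#' reruns with an identical config are byte-identical.
#'
#' @param config a [pipeline_config()] (or a YAML path for
#'   [read_pipeline_config()]).
#' @return object of class `vmr_report`: list with `kinematics`, `summaries`,
#'   `outliers`, `kept`, `epoch_curves`, `stats`, `config`, and in simulate
#'   mode `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "vmr_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e),
            class = "vmr_pipeline_error"))
  }
  manifest <- NULL
  logs <- stage("cohort", {
    if (config$mode == "simulate") {
      cc <- cohort_config(config$experiment, config$n_per_arm,
                          config$outlier_fraction, config$seed)
      sim <- simulate_cohort(cc, render = config$render)
      manifest <- sim$manifest
      sim$logs
    } else {
      read_cohort_logs(config$input_dir)
    }
  })
  kin <- stage("kinematics", analyze_cohort(logs))
  summaries <- stage("summaries", summarize_subjects(kin))
  screen <- stage("outlier_screen", screen_outliers(summaries))
  curves <- stage("epoch_curves", epoch_curves(kin))
  measures <- intersect(config$measures, names(summaries))
  stats_tab <- stage("group_stats",
    cohort_stats(screen$kept, measures, config$t_var_equal, config$bf,
                 config$bf_rscale_t, config$bf_rscale_anova))
  report <- structure(list(kinematics = kin, summaries = summaries,
                           outliers = screen, kept = screen$kept,
                           epoch_curves = curves, stats = stats_tab,
                           manifest = manifest, config = config),
                      class = "vmr_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$kinematics, "kinematics.tsv")
  wt(report$summaries, "subject_summaries.tsv")
  wt(report$outliers$bounds, "outlier_bounds.tsv")
  wt(report$outliers$excluded, "outlier_excluded.tsv")
  wt(report$epoch_curves, "epoch_curves.tsv")
  wt(report$stats, "group_stats.tsv")
  if (!is.null(report$manifest)) wt(report$manifest, "cohort_manifest.tsv")
  cfg <- report$config
  cfg$n_per_arm <- as.list(cfg$n_per_arm)
  yaml::write_yaml(
    c(unclass(cfg), list(package_version =
                           as.character(utils::packageVersion("vmradapt")))),
    file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.vmr_report <- function(x, ...) {
  cat(sprintf("Pipeline report: %d subjects (%d kept after screen), %d trials\n",
              nrow(x$summaries), nrow(x$kept), nrow(x$kinematics)))
  cat(sprintf("  incomplete trials: %d; excluded subjects: %s\n",
              attr(x$kinematics, "n_incomplete") %||% 0L,
              if (nrow(x$outliers$excluded))
                paste(unique(x$outliers$excluded$subject), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Recompute the published summary tables from (n, mean, sd)
#'
#' Every headline test statistic of the three-experiment study is a function
#' of the printed per-group (n, mean, sd) summaries alone. This reads those
#' summaries (the packaged transcription by default), recomputes the one-way
#' ANOVAs with JZS Bayes factors and Tukey / a-priori pairwise tests for the
#' two single-context experiments, the SHAM-only context comparison, and the
#' 2 x 3 CONTEXT x STIM Type-III factorial, and lines the results up against
#' the printed values.
#'
#' @param summary_file CSV of group summaries (experiment, context, measure,
#'   group, n, mean, sd). Default: the packaged transcription.
#' @param reference_file CSV of printed statistics to compare against
#'   (experiment, measure, test, comparison, stat, value), or `NULL` to skip
#'   the comparison. Default: the packaged transcription.
#' @return data.frame of class `vmr_table_check`: experiment, measure, test,
#'   comparison, stat, `recomputed`, and when a reference is given `printed`
#'   and `abs_diff`.
#' @export
reproduce_tables <- function(summary_file = NULL, reference_file = NULL) {
  summary_file <- summary_file %||%
    system.file("extdata", "study_summaries.csv", package = "vmradapt")
  reference_file <- reference_file %||%
    system.file("extdata", "study_reference_stats.csv", package = "vmradapt")
  sm <- utils::read.csv(summary_file, stringsAsFactors = FALSE)
  rows <- list()
  add <- function(experiment, measure, test, comparison, stat, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      experiment = experiment, measure = measure, test = test,
      comparison = comparison, stat = stat, recomputed = value,
      stringsAsFactors = FALSE)

  gs <- function(exp, meas) {
    s <- sm[sm$experiment == exp & sm$measure == meas, ]
    if (!nrow(s)) return(NULL)
    group_summary(s$group, s$n, s$mean, s$sd)
  }

  # single-context experiments: ANOVA + BF, Tukey, stim-vs-SHAM t-tests
  for (exp in c("exp1", "exp2")) {
    for (meas in unique(sm$measure[sm$experiment == exp])) {
      g <- gs(exp, meas)
      if (is.null(g)) next
      a <- one_way_anova(g, bf = TRUE)
      for (s in c("F", "p", "eta_p_sq", "cohens_f"))
        add(exp, meas, "anova", "", s, a[[s]])
      add(exp, meas, "anova", "", "bf", a$bf$bf)
      tk <- tukey_posthoc(g, a$ms_within, a$df_within)
      for (i in seq_len(nrow(tk)))
        for (s in c("p", "cohens_d", "hedges_g"))
          add(exp, meas, "tukey", paste0(tk$group1[i], "x", tk$group2[i]),
              s, tk[[s]][i])
      for (arm in setdiff(g$label, "SHAM")) {
        tt <- two_sample_t(g[g$label == arm, ], g[g$label == "SHAM", ])
        for (s in c("t", "p", "cohens_d", "hedges_g"))
          add(exp, meas, "ttest", paste0(arm, "xSHAM"), s, tt[[s]])
      }
    }
  }

  # SHAM-only context comparison (horizontal minus vertical)
  for (meas in c("target_error", "explicit", "implicit")) {
    gh <- gs("exp3_horizontal", meas); gv <- gs("exp2", meas)
    if (is.null(gh) || is.null(gv)) next
    tt <- two_sample_t(gh[gh$label == "SHAM", ], gv[gv$label == "SHAM", ])
    for (s in c("t", "p", "cohens_d", "hedges_g"))
      add("exp3a", meas, "ttest", "HORxVER", s, tt[[s]])
  }

  # 2 x 3 CONTEXT x STIM factorial (vertical cells from exp2)
  for (meas in c("target_error", "explicit", "implicit")) {
    gh <- gs("exp3_horizontal", meas); gv <- gs("exp2", meas)
    if (is.null(gh) || is.null(gv)) next
    cells <- rbind(
      data.frame(context = "HOR", stim = gh$label, n = gh$n, mean = gh$mean,
                 sd = gh$sd),
      data.frame(context = "VER", stim = gv$label, n = gv$n, mean = gv$mean,
                 sd = gv$sd))
    fa <- factorial_2x3(cells)
    for (i in seq_len(nrow(fa)))
      for (s in c("F", "p", "eta_p_sq", "cohens_f"))
        add("exp3b", meas, "factorial", fa$effect[i], s, fa[[s]][i])
  }

  out <- do.call(rbind, rows)
  if (!is.null(reference_file) && nzchar(reference_file)) {
    ref <- utils::read.csv(reference_file, stringsAsFactors = FALSE,
                           na.strings = character(0))
    ref$comparison[is.na(ref$comparison)] <- ""
    names(ref)[names(ref) == "value"] <- "printed"
    out <- merge(out, ref, all.x = TRUE,
                 by = c("experiment", "measure", "test", "comparison", "stat"))
    out$abs_diff <- abs(out$recomputed - out$printed)
  }
  out <- out[order(out$experiment, out$measure, out$test, out$comparison), ]
  rownames(out) <- NULL
  class(out) <- c("vmr_table_check", "data.frame")
  out
}
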