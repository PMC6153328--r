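# Trial-log text dialect: one CSV row per trial with an optional `samples`
# column holding the 100 Hz trajectory as "t;x;y|t;x;y|..." triplets.
# Angles degrees, distances cm, times seconds; decimal points, no separators.

TRIAL_LOG_REQUIRED <- c("subject", "arm", "context", "block", "trial_in_block",
                        "trial_global", "target_deg", "rotation_deg",
                        "feedback", "report", "stim", "report_number")

fmt_num <- function(x) {
  out <- vapply(x, function(v)
    if (is.na(v)) "" else sprintf("%.17g", v), character(1))
  out
}

encode_samples <- function(s) {
  paste(sprintf("%.17g;%.17g;%.17g", s$t, s$x, s$y), collapse = "|")
}

decode_samples <- function(str) {
  if (is.na(str) || !nzchar(str)) return(NULL)
  trip <- strsplit(strsplit(str, "|", fixed = TRUE)[[1]], ";", fixed = TRUE)
  m <- matrix(as.numeric(unlist(trip)), ncol = 3, byrow = TRUE)
  data.frame(t = m[, 1], x = m[, 2], y = m[, 3])
}

#' Write a trial log in the delimited-text dialect
#'
#' @param log a `vmr_triallog` (see [simulate_subject()]).
#' @param path output CSV path.
#' @param include_states write the hidden simulator states as sidecar columns
#'   (`explicit_state_deg`, `implicit_state_deg`); the analysis path ignores
#'   them.
#' @export
write_trial_log <- function(log, path, include_states = TRUE) {
  stopifnot(inherits(log, "vmr_triallog"))
  tr <- log$trials
  df <- tr[, TRIAL_LOG_REQUIRED]
  df$rt_s <- tr$rt_s
  df$mt_s <- tr$mt_s
  df$hand_deg <- tr$hand_deg
  if (include_states && !is.null(tr$explicit_state_deg)) {
    df$explicit_state_deg <- tr$explicit_state_deg
    df$implicit_state_deg <- tr$implicit_state_deg
  }
  if (!is.null(log$samples)) {
    sp <- split(log$samples, log$samples$trial_global)
    df$samples <- vapply(as.character(df$trial_global), function(k)
      if (k %in% names(sp)) encode_samples(sp[[k]]) else "", character(1))
  }
  num <- vapply(df, is.numeric, logical(1)) &
    !(names(df) %in% c("trial_in_block", "trial_global", "report_number"))
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a trial log written in the delimited-text dialect
#'
#' Validates the header and per-trial trajectory timestamps; malformed content
#' raises a classed error naming the offending trial.
#'
#' @param path CSV path produced by [write_trial_log()] (or equivalent).
#' @return a `vmr_triallog` object.
#' @export
read_trial_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject = "character"))
  missing_cols <- setdiff(TRIAL_LOG_REQUIRED, names(df))
  if (length(missing_cols))
    stopf("trial log %s is missing required column(s): %s", path,
          paste(missing_cols, collapse = ", "), class = "vmr_format_error")
  df$report <- as.logical(df$report)
  df$stim <- as.logical(df$stim)
  df$report_number <- suppressWarnings(as.integer(df$report_number))
  samples <- NULL
  if ("samples" %in% names(df)) {
    lst <- lapply(seq_len(nrow(df)), function(i) {
      s <- decode_samples(df$samples[i])
      if (is.null(s)) return(NULL)
      if (any(diff(s$t) <= 0))
        stopf("non-monotone timestamps in trial %d of %s",
              df$trial_global[i], path, class = "vmr_data_error")
      cbind(trial_global = df$trial_global[i], s)
    })
    samples <- do.call(rbind, lst)
    df$samples <- NULL
  }
  structure(list(trials = df, samples = samples), class = "vmr_triallog")
}

#' Read every trial log in a cohort directory
#'
#' @param dir directory holding per-subject CSV logs (and optionally a
#'   `manifest.tsv`, which is ignored here).
#' @return list of `vmr_triallog`, named by subject.
#' @export
read_cohort_logs <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files))
    stopf("no trial logs found in %s", dir, class = "vmr_io_error")
  logs <- lapply(files, read_trial_log)
  names(logs) <- vapply(logs, function(l) l$trials$subject[1], character(1))
  logs
}
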