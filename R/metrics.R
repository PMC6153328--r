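# Per-subject learning measures: epoching, baseline normalization, rotation
# summary, aftereffect, explicit/implicit decomposition, +/-3 SD screen.

#' Average a per-trial series into 8-trial epochs
#'
#' Because targets are balanced within every 8-trial epoch, each epoch mean
#' averages one reach to each of the 8 target locations, removing
#' target-specific variability. Invalid trials are omitted from the mean and
#' the per-epoch averaging count recorded; an epoch with no valid trials is
#' flagged missing (`NA` mean, `n_valid` 0).
#'
#' @param values numeric per-trial values for one block (length a multiple
#'   of 8).
#' @param valid logical vector marking trials that enter the means.
#' @return data.frame with `epoch`, `mean`, `n_valid`.
#' @export
epochize <- function(values, valid = NULL) {
  n <- length(values)
  if (n == 0 || n %% 8L != 0L)
    stopf("trial count (%d) must be a positive multiple of 8", n,
          class = "vmr_validation_error")
  if (is.null(valid)) valid <- !is.na(values)
  valid <- valid & !is.na(values)
  ep <- rep(seq_len(n / 8L), each = 8L)
  data.frame(
    epoch = seq_len(n / 8L),
    mean = as.numeric(tapply(ifelse(valid, values, NA_real_), ep,
                             function(v) if (all(is.na(v))) NA_real_
                             else mean(v, na.rm = TRUE))),
    n_valid = as.integer(tapply(valid, ep, sum))
  )
}

#' Baseline hand bias
#'
#' The mean hand angle over the final 8 trials of the last baseline block;
#' all rotation-block and aftereffect measures are normalized by subtracting
#' it, cancelling any idiosyncratic directional bias. If fewer than 8 of those
#' trials are valid the available ones are used (degraded mode, warned).
#'
#' @param hand_angles per-trial hand angles of the last baseline block,
#'   degrees.
#' @param valid logical validity flags (defaults to non-`NA`).
#' @return bias in degrees.
#' @export
baseline_bias <- function(hand_angles, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(hand_angles)
  valid <- valid & !is.na(hand_angles)
  n <- length(hand_angles)
  if (n < 8)
    stopf("baseline block has fewer than 8 trials", class = "vmr_data_error")
  idx <- (n - 7L):n
  use <- idx[valid[idx]]
  if (length(use) < 8L) {
    warning(sprintf(
      "baseline bias from %d valid trial(s) in the final epoch", length(use)),
      call. = FALSE)
    if (!length(use)) {
      use <- which(valid)
      use <- utils::tail(use, 8L)
      if (!length(use))
        stopf("no valid baseline trials", class = "vmr_data_error")
    }
  }
  mean(hand_angles[use])
}

#' Rotation-block summary: normalized hand angle and target error
#'
#' The rotation-block hand angle is the mean hand angle over all valid
#' rotation trials minus the baseline bias. Target error expresses it relative
#' to full compensation of the 45 deg clockwise rotation:
#' `target_error = hand_angle - 45`, so 0 means perfect compensation and
#' negative values mean clockwise undershoot.
#'
#' @param rotation_hand_angles per-trial rotation-block hand angles, degrees.
#' @param bias baseline bias from [baseline_bias()], degrees.
#' @param valid logical validity flags.
#' @param rotation_deg the applied cursor rotation (default -45).
#' @return list with `rotation_hand_angle_deg` and `target_error_deg`.
#' @export
rotation_summary <- function(rotation_hand_angles, bias, valid = NULL,
                             rotation_deg = -45) {
  if (is.null(valid)) valid <- !is.na(rotation_hand_angles)
  valid <- valid & !is.na(rotation_hand_angles)
  if (!any(valid))
    stopf("no valid rotation-block trials", class = "vmr_pipeline_error")
  ha <- mean(rotation_hand_angles[valid]) - bias
  list(rotation_hand_angle_deg = ha,
       target_error_deg = ha - (-rotation_deg))
}

#' Aftereffect
#'
#' Mean hand angle over the first 8 trials of the no-feedback block minus the
#' baseline bias: adaptation that persists without visual feedback, the
#' signature of the implicit component.
#'
#' @param no_feedback_hand_angles per-trial no-feedback-block hand angles.
#' @param bias baseline bias, degrees.
#' @param valid logical validity flags.
#' @return aftereffect in degrees.
#' @export
aftereffect <- function(no_feedback_hand_angles, bias, valid = NULL) {
  if (is.null(valid)) valid <- !is.na(no_feedback_hand_angles)
  valid <- valid & !is.na(no_feedback_hand_angles)
  if (length(no_feedback_hand_angles) < 8)
    stopf("no-feedback block has fewer than 8 trials",
          class = "vmr_data_error")
  idx <- 1:8
  use <- idx[valid[idx]]
  if (!length(use))
    stopf("no valid trials in the first no-feedback epoch",
          class = "vmr_data_error")
  mean(no_feedback_hand_angles[use]) - bias
}

#' Decompose hand angles into explicit and implicit components
#'
#' The explicit component of trial t is the reported aiming direction
#' converted to degrees ([number_to_hand_angle()]); the implicit component is
#' the remainder, `hand - explicit`: e.g. aiming at number -8 (45 deg) while
#' the hand travels toward number -6 (33.75 deg) leaves an implicit
#' contribution of -11.25 deg relative to the aim (a discrepancy of 2 number
#' units). Trials without a report are excluded (NA).
#'
#' @param hand_angles per-trial hand angles, degrees (normalize by the
#'   baseline bias before calling if normalized components are wanted).
#' @param report_numbers per-trial integer aim reports (NA when absent).
#' @return data.frame with `explicit_deg`, `implicit_deg` (NA off report
#'   trials).
#' @export
decompose_learning <- function(hand_angles, report_numbers) {
  if (length(hand_angles) != length(report_numbers))
    stopf("hand and report series differ in length",
          class = "vmr_validation_error")
  explicit <- number_to_hand_angle(report_numbers)
  data.frame(explicit_deg = explicit,
             implicit_deg = hand_angles - explicit)
}

#' Per-subject summary measures
#'
#' Reduces per-trial kinematics to the scalar measures used for group
#' statistics: baseline bias, normalized rotation-block hand angle, target
#' error, explicit and implicit means over the rotation block (from trials
#' with both valid kinematics and a recorded report, so that
#' `explicit + implicit` equals the normalized hand-angle mean over that same
#' trial set exactly), aftereffect, and block-wise mean rt/mt.
#'
#' @param kin a `vmr_kinematics` data.frame (one or more subjects).
#' @return data.frame of class `vmr_summaries`, one row per subject.
#' @export
summarize_subjects <- function(kin) {
  stopifnot(inherits(kin, "data.frame"))
  one <- function(k) {
    b4 <- k[k$block == "baseline_stim", ]
    b5 <- k[k$block == "rotation", ]
    b6 <- k[k$block == "no_feedback", ]
    if (!nrow(b5))
      stopf("subject %s has no rotation block", k$subject[1],
            class = "vmr_pipeline_error")
    bias <- baseline_bias(b4$hand_angle_deg, b4$valid)
    rot <- rotation_summary(b5$hand_angle_deg, bias, b5$valid)
    ae <- aftereffect(b6$hand_angle_deg, bias, b6$valid)
    dec_ok <- b5$valid & !is.na(b5$report_number)
    dc <- decompose_learning(b5$hand_angle_deg[dec_ok] - bias,
                             b5$report_number[dec_ok])
    blk_mean <- function(block, col) {
      kk <- k[k$block == block & k$valid, col]
      if (length(kk)) mean(kk) else NA_real_
    }
    data.frame(
      subject = k$subject[1], arm = k$arm[1], context = k$context[1],
      baseline_bias_deg = bias,
      rotation_hand_angle_deg = rot$rotation_hand_angle_deg,
      target_error_deg = rot$target_error_deg,
      explicit_deg = mean(dc$explicit_deg),
      implicit_deg = mean(dc$implicit_deg),
      aftereffect_deg = ae,
      rt_baseline_stim_s = blk_mean("baseline_stim", "rt_s"),
      rt_rotation_s = blk_mean("rotation", "rt_s"),
      rt_no_feedback_s = blk_mean("no_feedback", "rt_s"),
      mt_rotation_s = blk_mean("rotation", "mt_s"),
      n_valid = sum(k$valid),
      n_reported = sum(dec_ok),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(split(kin, kin$subject), one))
  rownames(out) <- NULL
  class(out) <- c("vmr_summaries", "data.frame")
  out
}

#' Per-epoch learning curves
#'
#' Epoch means (8 trials each) of the baseline-normalized hand angle and, on
#' report blocks, the explicit and implicit components, for every subject and
#' block. Useful for plotting group learning curves.
#'
#' @param kin a `vmr_kinematics` data.frame.
#' @return data.frame with subject, arm, context, block, epoch, measure
#'   columns (`hand_angle_deg`, `explicit_deg`, `implicit_deg`), `n_valid`.
#' @export
epoch_curves <- function(kin) {
  one <- function(k) {
    b4 <- k[k$block == "baseline_stim", ]
    bias <- baseline_bias(b4$hand_angle_deg, b4$valid)
    do.call(rbind, lapply(split(k, k$block), function(kb) {
      ha <- epochize(kb$hand_angle_deg - bias, kb$valid)
      dc <- decompose_learning(kb$hand_angle_deg - bias, kb$report_number)
      ex <- epochize(dc$explicit_deg, kb$valid & !is.na(kb$report_number))
      im <- epochize(dc$implicit_deg, kb$valid & !is.na(kb$report_number))
      data.frame(subject = kb$subject[1], arm = kb$arm[1],
                 context = kb$context[1], block = kb$block[1],
                 epoch = ha$epoch, hand_angle_deg = ha$mean,
                 explicit_deg = ex$mean, implicit_deg = im$mean,
                 n_valid = ha$n_valid, stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, lapply(split(kin, kin$subject), one))
  rownames(out) <- NULL
  out
}

#' Screen subjects for outliers (mean +/- 3 SD per group)
#'
#' Single-pass screen: within each group (arm x context), a subject is
#' excluded iff at least one of the screened measures lies strictly outside
#' the group mean +/- 3 standard deviations (values exactly on the bound are
#' kept). Groups smaller than 3 are skipped with a warning.
#'
#' @param summaries a `vmr_summaries` data.frame.
#' @param measures character vector of summary columns to screen.
#' @return object of class `vmr_outlier_report`: list with `bounds` (per
#'   group x measure mean/sd/limits), `excluded` (subject, group, triggering
#'   measure and value), and `kept` (filtered summaries).
#' @export
screen_outliers <- function(summaries,
                            measures = c("target_error_deg", "explicit_deg",
                                         "implicit_deg")) {
  stopifnot(all(measures %in% names(summaries)))
  grp <- interaction(summaries$arm, summaries$context, drop = TRUE)
  bounds <- list(); excluded <- list()
  for (g in levels(grp)) {
    sub <- summaries[grp == g, ]
    if (nrow(sub) < 3) {
      warning(sprintf("group %s has < 3 subjects; screen skipped", g),
              call. = FALSE)
      next
    }
    for (m in measures) {
      x <- sub[[m]]
      mu <- mean(x); s <- stats::sd(x)
      lo <- mu - 3 * s; hi <- mu + 3 * s
      bounds[[length(bounds) + 1L]] <-
        data.frame(group = g, measure = m, n = nrow(sub), mean = mu, sd = s,
                   lower = lo, upper = hi, stringsAsFactors = FALSE)
      out <- which(x < lo | x > hi)
      for (i in out)
        excluded[[length(excluded) + 1L]] <-
          data.frame(subject = sub$subject[i], group = g, measure = m,
                     value = x[i], stringsAsFactors = FALSE)
    }
  }
  bounds <- if (length(bounds)) do.call(rbind, bounds) else
    data.frame(group = character(), measure = character(), n = integer(),
               mean = numeric(), sd = numeric(), lower = numeric(),
               upper = numeric())
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(subject = character(), group = character(),
               measure = character(), value = numeric())
  kept <- summaries[!(summaries$subject %in% excluded$subject), ]
  structure(list(bounds = bounds, excluded = excluded, kept = kept),
            class = "vmr_outlier_report")
}

#' @export
print.vmr_outlier_report <- function(x, ...) {
  cat(sprintf("Outlier screen (+/- 3 SD): %d subject(s) excluded of %d\n",
              length(unique(x$excluded$subject)),
              length(unique(x$excluded$subject)) + nrow(x$kept)))
  if (nrow(x$excluded)) print(x$excluded, row.names = FALSE)
  invisible(x)
}
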