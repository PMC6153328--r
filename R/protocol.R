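#' Task protocol: block structure, targets and the aiming-number ring
#'
#' The task is a center-out reaching paradigm: 8 targets spaced 45 deg apart on
#' a 7 cm ring, flanked by 63 aiming numbers (-31..31) spaced 5.625 deg apart.
#' Subjects complete seven blocks (16/48/24/24/160/40/40 trials): a
#' familiarization block, three baseline blocks (the last two with verbal aim
#' reports; stimulation starts in the fourth block), a 160-trial rotation block
#' with a 45 deg clockwise cursor rotation (-45 in our sign convention),
#' a no-feedback block, and a washout block. Targets are pseudorandomized so
#' that every 8-trial epoch contains each target exactly once.
#'
#' @param experiment one of `"exp1"` (endpoint feedback, horizontal screen),
#'   `"exp2"` (online feedback, vertical screen) or `"exp3_horizontal"`
#'   (online feedback, horizontal screen).
#' @param block_trials optional named integer vector overriding the per-block
#'   trial counts (all must be positive multiples of 8).
#' @param rotation_deg rotation applied during the rotation block, degrees,
#'   clockwise negative. Default -45.
#' @param context optional override of the screen context implied by
#'   `experiment` (`"horizontal"` or `"vertical"`).
#' @return An object of class `vmr_design`: a list with `blocks` (data.frame:
#'   name, n_trials, rotation_deg, feedback, report, stim), `target_angles_deg`,
#'   `ring_radius_cm`, `n_aim_numbers`, `aim_spacing_deg`, `context`,
#'   `feedback`, `experiment`.
#' @examples
#' d <- vmr_design("exp1")
#' sum(d$blocks$n_trials) # 352
#' @export
vmr_design <- function(experiment = c("exp1", "exp2", "exp3_horizontal"),
                       block_trials = NULL,
                       rotation_deg = -45,
                       context = NULL) {
  experiment <- tryCatch(match.arg(experiment), error = function(e)
    stopf("unknown experiment id: %s", paste(experiment, collapse = ", "),
          class = "vmr_config_error"))
  feedback <- switch(experiment, exp1 = "endpoint", exp2 = "online",
                     exp3_horizontal = "online")
  context <- context %||%
    switch(experiment, exp1 = "horizontal", exp2 = "vertical",
           exp3_horizontal = "horizontal")
  context <- match.arg(context, c("horizontal", "vertical"))

  n_trials <- c(familiarization = 16L, baseline = 48L, baseline_report = 24L,
                baseline_stim = 24L, rotation = 160L, no_feedback = 40L,
                washout = 40L)
  if (!is.null(block_trials)) {
    bad <- setdiff(names(block_trials), names(n_trials))
    if (length(bad))
      stopf("unknown block name(s): %s", paste(bad, collapse = ", "),
            class = "vmr_config_error")
    n_trials[names(block_trials)] <- as.integer(block_trials)
  }
  if (any(n_trials <= 0L) || any(n_trials %% 8L != 0L))
    stopf("all block sizes must be positive multiples of 8",
          class = "vmr_schedule_error")

  blocks <- data.frame(
    name = names(n_trials),
    n_trials = unname(n_trials),
    rotation_deg = c(0, 0, 0, 0, rotation_deg, 0, 0),
    feedback = c(feedback, feedback, feedback, feedback, feedback,
                 "none", feedback),
    report = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
    stim = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  structure(list(
    blocks = blocks,
    target_angles_deg = c(0, 45, 90, 135, 180, -135, -90, -45),
    ring_radius_cm = 7,
    n_aim_numbers = 63L,
    aim_spacing_deg = 5.625,
    context = context,
    feedback = feedback,
    experiment = experiment
  ), class = "vmr_design")
}

#' @export
print.vmr_design <- function(x, ...) {
  cat(sprintf("Visuomotor rotation design '%s' (%s feedback, %s screen)\n",
              x$experiment, x$feedback, x$context))
  cat(sprintf("  %d blocks, %d trials total; rotation %g deg in block '%s'\n",
              nrow(x$blocks), sum(x$blocks$n_trials),
              x$blocks$rotation_deg[x$blocks$rotation_deg != 0][1], "rotation"))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Build a target-balanced pseudorandom trial schedule
#'
#' Every consecutive 8-trial epoch within a block is an independent random
#' permutation of the 8 target directions, so each epoch contains one reach to
#' each target. The schedule is a pure function of `(design, seed)`.
#'
#' @param design a [vmr_design()] object.
#' @param seed integer seed for the permutation stream.
#' @return data.frame of class `vmr_schedule` with columns `block`,
#'   `trial_in_block`, `trial_global`, `target_deg`, `rotation_deg`,
#'   `feedback`, `report`, `stim`.
#' @examples
#' s <- build_schedule(vmr_design("exp1"), seed = 1)
#' table(s$target_deg[s$block == "rotation"]) # 20 each
#' @export
build_schedule <- function(design, seed) {
  stopifnot(inherits(design, "vmr_design"))
  b <- design$blocks
  if (any(b$n_trials %% 8L != 0L))
    stopf("block sizes must be multiples of 8", class = "vmr_schedule_error")
  targets <- design$target_angles_deg
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(b)), function(i) {
      n_ep <- b$n_trials[i] / 8L
      tgt <- unlist(lapply(seq_len(n_ep), function(e) sample(targets)))
      data.frame(
        block = b$name[i],
        trial_in_block = seq_len(b$n_trials[i]),
        target_deg = tgt,
        rotation_deg = b$rotation_deg[i],
        feedback = b$feedback[i],
        report = b$report[i],
        stim = b$stim[i],
        stringsAsFactors = FALSE
      )
    })
  })
  out <- do.call(rbind, rows)
  out$trial_global <- seq_len(nrow(out))
  out <- out[, c("block", "trial_in_block", "trial_global", "target_deg",
                 "rotation_deg", "feedback", "report", "stim")]
  class(out) <- c("vmr_schedule", "data.frame")
  out
}

#' Convert a reported aiming number to a hand-space angle
#'
#' Aim reports are integers on the 63-number ring (-31..31), spaced 5.625 deg.
#' The mapping is `angle = -n * 5.625`: with the counterclockwise-positive
#' convention, a report of -8 corresponds to +45 deg of counterclockwise
#' compensation, i.e. exactly the strategy that cancels a 45 deg clockwise
#' cursor rotation.
#'
#' @param n integer aiming number(s) in \[-31, 31\]; `NA` passes through.
#' @return aiming angle(s) in degrees of hand-space compensation.
#' @examples
#' number_to_hand_angle(-8) # 45
#' @export
number_to_hand_angle <- function(n) {
  ok <- is.na(n) | (n == round(n) & n >= -31 & n <= 31)
  if (!all(ok))
    stopf("aim numbers must be integers in [-31, 31]; got %s",
          paste(utils::head(n[!ok], 3), collapse = ", "),
          class = "vmr_validation_error")
  -n * 5.625
}

#' Write a trial schedule as delimited text
#'
#' @param schedule a [build_schedule()] result.
#' @param path output file path (tab-separated, header row).
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
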