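# Reach kinematics: hand angle from the 1 cm / 7 cm chord, reaction time,
# movement time, and the 400 ms too-slow criterion.

# First time at which the radial distance crosses `radius`, by linear
# interpolation between the two samples straddling it. Returns the
# interpolated (t, x, y), or NULL if never crossed.
first_crossing <- function(t, x, y, radius) {
  r <- sqrt(x^2 + y^2)
  above <- r >= radius
  if (!any(above)) return(NULL)
  i <- which(above)[1]
  if (i == 1) return(list(t = t[1], x = x[1], y = y[1]))
  f <- (radius - r[i - 1]) / (r[i] - r[i - 1])
  list(t = t[i - 1] + f * (t[i] - t[i - 1]),
       x = x[i - 1] + f * (x[i] - x[i - 1]),
       y = y[i - 1] + f * (y[i] - y[i - 1]))
}

#' Hand angle of one reach
#'
#' The hand angle is the direction of the straight line (chord) between the
#' points where the trajectory first crosses radial distances of 1 cm and
#' 7 cm from the start, expressed relative to the target direction so that the
#' target sits at 0 deg; counterclockwise deviations are positive. Crossing
#' points are linearly interpolated between the straddling samples.
#'
#' @param traj data.frame with columns `t`, `x`, `y` (seconds, cm), origin at
#'   the start-circle center.
#' @param target_deg target direction, degrees.
#' @return hand angle in degrees, wrapped to (-180, 180].
#' @examples
#' tr <- render_trajectory(10, rt = 0.3, mt = 0.25, target_deg = 45)
#' hand_angle(tr, 45) # 10
#' @export
hand_angle <- function(traj, target_deg) {
  p1 <- first_crossing(traj$t, traj$x, traj$y, 1)
  p7 <- first_crossing(traj$t, traj$x, traj$y, 7)
  if (is.null(p1) || is.null(p7))
    stopf("trajectory never reaches the %s cm radius",
          if (is.null(p1)) "1" else "7", class = "vmr_incomplete_trial")
  chord <- atan2(p7$y - p1$y, p7$x - p1$x) * 180 / pi
  wrap_angle(chord - target_deg)
}

#' Reaction time, movement time and the too-slow flag
#'
#' Reaction time is the time from target onset until the hand is 1 cm from the
#' starting circle; movement time is the time to traverse from the 1 cm to the
#' 7 cm radial position. A movement time strictly longer than 400 ms raises
#' the too-slow flag (the task plays a "Too slow!" prompt).
#'
#' @inheritParams hand_angle
#' @param target_onset_t target onset time, seconds (same clock as `traj$t`).
#' @return list with `rt_s`, `mt_s`, `too_slow`.
#' @export
rt_mt <- function(traj, target_onset_t = 0) {
  p1 <- first_crossing(traj$t, traj$x, traj$y, 1)
  p7 <- first_crossing(traj$t, traj$x, traj$y, 7)
  if (is.null(p1) || is.null(p7))
    stopf("trajectory never reaches the %s cm radius",
          if (is.null(p1)) "1" else "7", class = "vmr_incomplete_trial")
  rt <- p1$t - target_onset_t
  mt <- p7$t - p1$t
  list(rt_s = rt, mt_s = mt, too_slow = mt > 0.400)
}

#' Per-trial kinematics for a whole trial log
#'
#' Computes hand angle, rt, mt and the too-slow flag for every trial. Trials
#' whose trajectory never reaches the 7 cm ring are flagged invalid (not
#' dropped) and reported in an attribute. Logs without rendered trajectories
#' (simulator output with `render = FALSE`) fall back to the commanded hand
#' angle and drawn rt/mt carried in the log, which noise-free rendering would
#' reproduce exactly.
#'
#' @param log a `vmr_triallog`.
#' @param drop_too_slow if `TRUE`, too-slow trials are additionally marked
#'   invalid (kept valid by default).
#' @return data.frame of class `vmr_kinematics`: identifiers plus
#'   `hand_angle_deg`, `rt_s`, `mt_s`, `too_slow`, `valid`. The number of
#'   incomplete trials is stored in `attr(, "n_incomplete")`.
#' @export
analyze_trials <- function(log, drop_too_slow = FALSE) {
  stopifnot(inherits(log, "vmr_triallog"))
  tr <- log$trials
  n <- nrow(tr)
  out <- tr[, c("subject", "arm", "context", "block", "trial_in_block",
                "trial_global", "target_deg", "report", "report_number")]
  ha <- numeric(n); rt <- numeric(n); mt <- numeric(n)
  valid <- rep(TRUE, n)
  if (is.null(log$samples)) {
    ha <- wrap_angle(tr$hand_deg)
    rt <- tr$rt_s
    mt <- tr$mt_s
  } else {
    sp <- split(log$samples, log$samples$trial_global)
    for (i in seq_len(n)) {
      s <- sp[[as.character(tr$trial_global[i])]]
      res <- tryCatch({
        a <- hand_angle(s, tr$target_deg[i])
        tm <- rt_mt(s)
        list(a = a, rt = tm$rt_s, mt = tm$mt_s)
      }, vmr_incomplete_trial = function(e) NULL)
      if (is.null(s) || is.null(res)) {
        valid[i] <- FALSE
        ha[i] <- NA_real_; rt[i] <- NA_real_; mt[i] <- NA_real_
      } else {
        ha[i] <- res$a; rt[i] <- res$rt; mt[i] <- res$mt
      }
    }
  }
  out$hand_angle_deg <- ha
  out$rt_s <- rt
  out$mt_s <- mt
  out$too_slow <- !is.na(mt) & mt > 0.400
  if (drop_too_slow) valid <- valid & !out$too_slow
  out$valid <- valid
  attr(out, "n_incomplete") <- sum(!valid)
  class(out) <- c("vmr_kinematics", "data.frame")
  out
}

#' Kinematics for every subject in a cohort
#'
#' @param logs list of `vmr_triallog` (e.g. `simulate_cohort(...)$logs` or
#'   [read_cohort_logs()]).
#' @param ... passed to [analyze_trials()].
#' @return one stacked `vmr_kinematics` data.frame.
#' @export
analyze_cohort <- function(logs, ...) {
  out <- do.call(rbind, lapply(logs, analyze_trials, ...))
  rownames(out) <- NULL
  class(out) <- c("vmr_kinematics", "data.frame")
  out
}
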