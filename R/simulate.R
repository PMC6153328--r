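#' Two-process learner parameters
#'
#' Synthetic subjects combine an explicit re-aiming strategy with an implicit
#' state-space adaptation process. On each trial the subject aims at
#' `clamp(explicit, +/- explicit_cap_deg)` (snapped to the 5.625 deg report
#' grid on report trials), and the hand lands at `aim + implicit + motor
#' noise`. When visual feedback is present the states update as
#' \deqn{explicit_{t+1} = explicit_t - \eta \, e_t}
#' \deqn{implicit_{t+1} = A \, implicit_t - B \,(cursor_t - aim_t)}
#' where `e_t` is the cursor's angular error relative to the target and
#' `cursor - aim` is the visual discrepancy between where the subject aimed
#' and where the cursor went (the implicit process adapts to cancel it).
#' During the no-feedback block the explicit state is frozen and the implicit
#' state decays by `A`. This is synthetic scaffolding: it supplies the
#' additive explicit + implicit structure the analysis assumes, not a fitted
#' model of any particular dataset.
#'
#' @param eta_explicit strategy learning rate on target error, in \[0, 1\].
#' @param A_implicit implicit retention factor, in \[0, 1\].
#' @param B_implicit implicit error sensitivity, in \[0, 1\].
#' @param sigma_motor reach execution noise SD, degrees.
#' @param sigma_report report noise SD, aiming-number units (added before the
#'   report is snapped to the integer grid).
#' @param explicit_cap_deg maximum magnitude of the explicit strategy, degrees.
#' @param rt_mean_s,rt_sd_s reaction time mean and SD, seconds (time of the
#'   1 cm radial crossing relative to target onset).
#' @param mt_mean_s,mt_sd_s movement time mean and SD, seconds (1 cm to 7 cm
#'   traversal).
#' @return object of class `vmr_learner` (a validated named list).
#' @export
learner_params <- function(eta_explicit = 0.15, A_implicit = 0.98,
                           B_implicit = 0.012, sigma_motor = 3.5,
                           sigma_report = 1, explicit_cap_deg = 60,
                           rt_mean_s = 0.8, rt_sd_s = 0.15,
                           mt_mean_s = 0.25, mt_sd_s = 0.04) {
  p <- list(eta_explicit = eta_explicit, A_implicit = A_implicit,
            B_implicit = B_implicit, sigma_motor = sigma_motor,
            sigma_report = sigma_report, explicit_cap_deg = explicit_cap_deg,
            rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
            mt_mean_s = mt_mean_s, mt_sd_s = mt_sd_s)
  if (p$A_implicit < 0 || p$A_implicit > 1 || p$B_implicit < 0 ||
      p$B_implicit > 1 || p$eta_explicit < 0 || p$eta_explicit > 1)
    stopf("learning rates and retention must lie in [0, 1]",
          class = "vmr_config_error")
  if (p$sigma_motor < 0 || p$sigma_report < 0 || p$rt_sd_s < 0 || p$mt_sd_s < 0)
    stopf("noise SDs must be nonnegative", class = "vmr_config_error")
  if (p$mt_mean_s <= 0 || p$rt_mean_s <= 0)
    stopf("rt_mean_s and mt_mean_s must be positive",
          class = "vmr_config_error")
  structure(p, class = "vmr_learner")
}

# Context-level mean parameters. The horizontal screen (1-to-1 visuomotor
# mapping) favors the explicit strategy; the vertical screen (90 deg
# transformation) suppresses it and shifts weight onto implicit adaptation.
context_base_params <- function(context) {
  switch(context,
    horizontal = list(eta_explicit = 0.15, B_implicit = 0.012),
    vertical   = list(eta_explicit = 0.08, B_implicit = 0.022),
    stopf("unknown context: %s", context, class = "vmr_config_error"))
}

# Arm-level multiplicative effects on the mean parameters. Cerebellar (CB)
# stimulation nudges implicit error sensitivity (mostly in the vertical
# context); dlPFC stimulation nudges the explicit learning rate (mostly in
# the horizontal context). SHAM is the unmodified baseline.
arm_effects <- function(arm, context) {
  eta_mult <- 1; B_mult <- 1
  if (arm == "CB")    B_mult  <- if (context == "vertical") 1.35 else 1.10
  if (arm == "dlPFC") eta_mult <- if (context == "horizontal") 1.20 else 1.05
  list(eta_mult = eta_mult, B_mult = B_mult)
}

#' Cohort configuration for the synthetic simulator
#'
#' Describes a cohort of simulated subjects: one stimulation arm per group
#' (CB / dlPFC / SHAM), a screen context inherited from the experiment preset,
#' per-subject parameter variability, and a heavy-tail mixture component that
#' emulates the few extreme performers seen in real groups: with probability
#' `outlier_fraction` a subject's `eta_explicit` and `B_implicit` are drawn
#' with 3x inflated SD.
#'
#' @param experiment experiment preset passed to [vmr_design()].
#' @param n_per_arm named integer vector of group sizes (names are arms).
#' @param outlier_fraction probability of the inflated-variance component,
#'   in \[0, 0.5\].
#' @param seed master seed; all randomness (parameter draws, schedules,
#'   trial noise) derives from it.
#' @param base_params optional named list overriding [learner_params()]
#'   defaults for every subject (applied before context/arm effects).
#' @param cv relative between-subject SD applied to `eta_explicit` and
#'   `B_implicit` (their SD is `cv * mean`).
#' @return object of class `vmr_cohort_config`.
#' @export
cohort_config <- function(experiment = "exp1",
                          n_per_arm = c(CB = 10L, dlPFC = 10L, SHAM = 10L),
                          outlier_fraction = 0.1,
                          seed = 1L,
                          base_params = NULL,
                          cv = 0.3) {
  if (is.null(names(n_per_arm)) || any(!nzchar(names(n_per_arm))))
    stopf("n_per_arm must be a named vector of group sizes",
          class = "vmr_config_error")
  if (any(n_per_arm < 2))
    stopf("group sizes must be >= 2", class = "vmr_config_error")
  if (outlier_fraction < 0 || outlier_fraction > 0.5)
    stopf("outlier_fraction must lie in [0, 0.5]", class = "vmr_config_error")
  if (cv < 0) stopf("cv must be nonnegative", class = "vmr_config_error")
  design <- vmr_design(experiment)
  structure(list(experiment = experiment, design = design,
                 n_per_arm = n_per_arm, outlier_fraction = outlier_fraction,
                 seed = as.integer(seed), base_params = base_params, cv = cv),
            class = "vmr_cohort_config")
}

#' Draw per-subject learner parameters for a cohort
#'
#' @param config a [cohort_config()] object.
#' @return data.frame with one row per subject: `subject`, `arm`, `context`,
#'   `outlier_component` (logical mixture label, kept for validation), and one
#'   column per [learner_params()] field.
#' @export
sample_cohort_params <- function(config) {
  stopifnot(inherits(config, "vmr_cohort_config"))
  context <- config$design$context
  base <- context_base_params(context)
  defaults <- learner_params()
  out <- with_seed(config$seed, {
    arms <- lapply(names(config$n_per_arm), function(arm) {
      n <- config$n_per_arm[[arm]]
      eff <- arm_effects(arm, context)
      eta_mu <- base$eta_explicit * eff$eta_mult
      B_mu <- base$B_implicit * eff$B_mult
      infl <- stats::runif(n) < config$outlier_fraction
      k <- ifelse(infl, 3, 1)   # inflated-variance mixture component
      data.frame(
        arm = arm, context = context, outlier_component = infl,
        eta_explicit = clamp(stats::rnorm(n, eta_mu, k * config$cv * eta_mu),
                             0, 1),
        A_implicit = clamp(stats::rnorm(n, 0.98, 0.005), 0.9, 1),
        B_implicit = clamp(stats::rnorm(n, B_mu, k * config$cv * B_mu), 0, 1),
        sigma_motor = pmax(stats::rnorm(n, 3.5, 0.5), 0.5),
        sigma_report = defaults$sigma_report,
        explicit_cap_deg = defaults$explicit_cap_deg,
        rt_mean_s = defaults$rt_mean_s, rt_sd_s = defaults$rt_sd_s,
        mt_mean_s = defaults$mt_mean_s, mt_sd_s = defaults$mt_sd_s,
        stringsAsFactors = FALSE)
    })
    do.call(rbind, arms)
  })
  if (!is.null(config$base_params))
    for (f in names(config$base_params))
      out[[f]] <- config$base_params[[f]]
  cbind(subject = sprintf("S%03d", seq_len(nrow(out))), out)
}

# Minimum-jerk position fraction s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5.
minjerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Time fraction at which the minimum-jerk profile to 8 cm crosses 1 cm.
# By the symmetry s(1 - tau) = 1 - s(tau), the 7 cm crossing is at 1 - tau1.
minjerk_tau1 <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- stats::uniroot(function(x) minjerk(x) - 1 / 8, c(0.1, 0.5),
                             tol = 1e-12)$root
    val
  }
})

#' Render a 100 Hz reach trajectory
#'
#' Produces tablet samples for one reach: stationary at the origin until the
#' movement starts, then a minimum-jerk radial profile out to 8 cm (past the
#' 7 cm target ring), in the direction `target_deg + hand_deg` plus a smooth
#' curvature perturbation. Timing is parameterized so that the 1 cm crossing
#' occurs at `rt` and the 1 cm to 7 cm traversal takes `mt`, matching how
#' reaction and movement time are measured downstream.
#'
#' @param hand_deg hand angle relative to the target, degrees, CCW positive.
#' @param rt time of the 1 cm radial crossing, seconds, relative to target
#'   onset at t = 0.
#' @param mt duration of the 1 cm to 7 cm traversal, seconds; must be > 0.
#' @param target_deg target direction in tablet space, degrees.
#' @param curvature_deg smooth curvature amplitude for this reach, degrees;
#'   drawn by the caller (0 gives a perfectly straight path). The induced
#'   chord-angle deviation between the 1 cm and 7 cm points is below
#'   `0.44 * |curvature_deg|`.
#' @param dt sample period, seconds (100 Hz default).
#' @return data.frame with columns `t`, `x`, `y` (seconds, cm).
#' @export
render_trajectory <- function(hand_deg, rt, mt, target_deg = 0,
                              curvature_deg = 0, dt = 0.01) {
  if (!is.finite(mt) || mt <= 0)
    stopf("movement time must be positive", class = "vmr_validation_error")
  tau1 <- minjerk_tau1()
  T_full <- mt / (1 - 2 * tau1)     # full 0 -> 8 cm duration
  t_start <- max(rt - tau1 * T_full, 0)
  t_end <- t_start + T_full
  t <- seq(0, t_end + 2 * dt, by = dt)
  tau <- clamp((t - t_start) / T_full, 0, 1)
  r <- 8 * minjerk(tau)
  # curvature: zero at start and ring, peaked mid-path
  dev <- curvature_deg * 4 * (r / 8) * (1 - r / 8)
  ang <- (target_deg + hand_deg + dev) * pi / 180
  data.frame(t = t, x = r * cos(ang), y = r * sin(ang))
}

#' Simulate one subject performing a scheduled session
#'
#' Iterates the two-process learner over a trial schedule (see
#' [learner_params()] for the update equations) and optionally renders a 100 Hz
#' trajectory per trial. The hidden explicit/implicit states are recorded in
#' sidecar columns (`explicit_state_deg`, `implicit_state_deg`) so that
#' parameter-recovery checks can compare pipeline output against the truth;
#' the analysis path never reads them. After the last report block the
#' aiming ring is gone and the subject aims straight at the target (aim = 0,
#' explicit state frozen), so the no-feedback aftereffect reflects the
#' implicit state alone.
#'
#' @param params a [learner_params()] object.
#' @param schedule a [build_schedule()] result.
#' @param seed integer seed for this subject's noise streams.
#' @param subject,arm,context identifier strings carried into the log.
#' @param render if `TRUE`, attach rendered trajectory samples; if `FALSE`
#'   the log carries only the commanded hand angle and drawn rt/mt, which the
#'   analyzer uses directly (exact, since rendered noise-free trajectories
#'   reproduce the commanded angle).
#' @param curvature_sd SD of the per-trial smooth curvature amplitude, degrees.
#' @return object of class `vmr_triallog`: list with `trials` (data.frame) and
#'   `samples` (data.frame of (trial_global, t, x, y), or `NULL`).
#' @export
simulate_subject <- function(params, schedule, seed, subject = "S001",
                             arm = "SHAM", context = "horizontal",
                             render = TRUE, curvature_sd = 0.15) {
  stopifnot(inherits(params, "vmr_learner"),
            inherits(schedule, "vmr_schedule"))
  n <- nrow(schedule)
  # The aiming-number ring is present through the report blocks; once it
  # disappears (no-feedback and washout blocks) subjects are instructed to
  # aim straight at the target, so the strategy is dropped (aim = 0) while
  # the explicit state stays frozen and the implicit state keeps evolving.
  strategy <- rep(TRUE, n)
  if (any(schedule$report))
    strategy[seq_len(n) > max(which(schedule$report))] <- FALSE
  res <- with_seed(seed, {
    explicit <- 0; implicit <- 0
    hand <- numeric(n); aim <- numeric(n); rep_num <- rep(NA_integer_, n)
    ex_st <- numeric(n); im_st <- numeric(n)
    rt <- pmax(stats::rnorm(n, params$rt_mean_s, params$rt_sd_s), 0.15)
    mt <- pmax(stats::rnorm(n, params$mt_mean_s, params$mt_sd_s), 0.08)
    curv <- clamp(stats::rnorm(n, 0, curvature_sd), -0.5, 0.5)
    motor <- stats::rnorm(n, 0, params$sigma_motor)
    repn <- stats::rnorm(n, 0, params$sigma_report)
    for (i in seq_len(n)) {
      ex_st[i] <- explicit; im_st[i] <- implicit
      aim_intent <- if (strategy[i])
        clamp(explicit, -params$explicit_cap_deg, params$explicit_cap_deg)
      else 0
      if (schedule$report[i]) {
        num <- round(-aim_intent / 5.625 + repn[i])
        num <- clamp(num, -31, 31)
        rep_num[i] <- as.integer(num)
        aim[i] <- -num * 5.625
      } else {
        aim[i] <- aim_intent
      }
      hand[i] <- aim[i] + implicit + motor[i]
      cursor <- hand[i] + schedule$rotation_deg[i]
      if (schedule$feedback[i] != "none") {
        explicit <- explicit - params$eta_explicit * cursor
        implicit <- params$A_implicit * implicit -
          params$B_implicit * (cursor - aim[i])
      } else {
        implicit <- params$A_implicit * implicit
      }
    }
    list(hand = hand, aim = aim, rep_num = rep_num, ex = ex_st, im = im_st,
         rt = rt, mt = mt, curv = curv)
  })

  trials <- data.frame(subject = subject, arm = arm, context = context,
                       schedule, report_number = res$rep_num,
                       hand_deg = res$hand, rt_s = res$rt, mt_s = res$mt,
                       explicit_state_deg = res$ex,
                       implicit_state_deg = res$im,
                       stringsAsFactors = FALSE)
  samples <- NULL
  if (render) {
    samples <- do.call(rbind, lapply(seq_len(n), function(i) {
      tr <- render_trajectory(res$hand[i], res$rt[i], res$mt[i],
                              target_deg = schedule$target_deg[i],
                              curvature_deg = res$curv[i])
      cbind(trial_global = schedule$trial_global[i], tr)
    }))
  }
  structure(list(trials = trials, samples = samples), class = "vmr_triallog")
}

#' Simulate a full cohort
#'
#' Draws per-subject parameters via [sample_cohort_params()], builds one
#' independent schedule per subject, and simulates every subject. When
#' `out_dir` is given, each subject's trial log is written in the documented
#' delimited-text dialect together with a cohort manifest.
#'
#' @param config a [cohort_config()] object.
#' @param out_dir optional output directory for trial-log files + manifest.
#' @param render passed to [simulate_subject()].
#' @return invisibly, a list with `logs` (list of `vmr_triallog`), `manifest`
#'   (data.frame of subject, arm, context, seed and true parameters) and
#'   `params`.
#' @export
simulate_cohort <- function(config, out_dir = NULL, render = TRUE) {
  stopifnot(inherits(config, "vmr_cohort_config"))
  pars <- sample_cohort_params(config)
  n_sub <- nrow(pars)
  seeds <- with_seed(config$seed + 1L, sample.int(.Machine$integer.max - 1L,
                                                  2L * n_sub))
  sched_seeds <- seeds[seq_len(n_sub)]
  noise_seeds <- seeds[n_sub + seq_len(n_sub)]
  pfields <- names(formals(learner_params))
  logs <- lapply(seq_len(n_sub), function(i) {
    sched <- build_schedule(config$design, sched_seeds[i])
    p <- do.call(learner_params, as.list(pars[i, pfields]))
    simulate_subject(p, sched, seed = noise_seeds[i],
                     subject = pars$subject[i], arm = pars$arm[i],
                     context = pars$context[i], render = render)
  })
  names(logs) <- pars$subject
  manifest <- cbind(pars[, c("subject", "arm", "context",
                             "outlier_component")],
                    schedule_seed = sched_seeds, noise_seed = noise_seeds,
                    master_seed = config$seed, pars[, pfields])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
      stopf("cannot create output directory %s", out_dir,
            class = "vmr_io_error")
    for (lg in logs)
      write_trial_log(lg, file.path(out_dir,
                                    paste0(lg$trials$subject[1], ".csv")))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(logs = logs, manifest = manifest, params = pars))
}
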