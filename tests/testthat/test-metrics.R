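test_that("epoch means equal brute-force grouped means", {
  expect_equal(nrow(epochize(rep(1, 160))), 20L)          # 160 trials -> 20
  expect_equal(epochize(rep(3.5, 24))$mean, rep(3.5, 3))  # constant series
  set.seed(1)
  v <- rnorm(48)
  expect_equal(epochize(v)$mean, oracle_epoch_means(v))
  # invalid trials reduce the averaging count; empty epochs flagged missing
  valid <- rep(TRUE, 48); valid[1:8] <- FALSE; valid[9] <- FALSE
  ep <- epochize(v, valid)
  expect_true(is.na(ep$mean[1]))
  expect_equal(ep$n_valid[1:2], c(0L, 7L))
  expect_equal(ep$mean[2], mean(v[10:16]))
  expect_error(epochize(rnorm(12)), class = "vmr_validation_error")
})

test_that("baseline bias averages the final 8 baseline trials", {
  expect_equal(baseline_bias(rep(2, 24)), 2)
  expect_equal(baseline_bias(1:24), 20.5)
  expect_warning(b <- baseline_bias(1:24, c(rep(TRUE, 20), rep(FALSE, 4))),
                 "valid trial")
  expect_equal(b, mean(17:20))
})

test_that("rotation summary and aftereffect follow the normalization rules", {
  rs <- rotation_summary(rep(45, 160), bias = 0)
  expect_equal(rs$rotation_hand_angle_deg, 45)
  expect_equal(rs$target_error_deg, 0)
  rs0 <- rotation_summary(rep(0, 160), bias = 0)
  expect_equal(rs0$target_error_deg, -45)
  expect_equal(aftereffect(c(rep(12, 8), rep(0, 32)), bias = 0), 12)
  expect_equal(aftereffect(c(rep(15, 8), rep(0, 32)), bias = 3), 12)

  # noise-free simulated subject: summaries equal the generator's states
  p <- learner_params(sigma_motor = 0, sigma_report = 0)
  sched <- build_schedule(vmr_design("exp1"), 17)
  log <- simulate_subject(p, sched, seed = 3, render = FALSE)
  kin <- analyze_trials(log)
  sm <- summarize_subjects(kin)
  rot <- sched$block == "rotation"
  expect_equal(sm$rotation_hand_angle_deg,
               mean(log$trials$hand_deg[rot]) - sm$baseline_bias_deg,
               tolerance = 1e-12)
  # aftereffect equals the implicit state decaying through the first epoch
  b6 <- which(sched$block == "no_feedback")[1:8]
  expect_equal(sm$aftereffect_deg,
               mean(log$trials$implicit_state_deg[b6]) - sm$baseline_bias_deg,
               tolerance = 1e-9)
})

test_that("aftereffect equals the frozen implicit state when A = 1", {
  p <- learner_params(sigma_motor = 0, sigma_report = 0, A_implicit = 1,
                      B_implicit = 0.02, eta_explicit = 0)
  sched <- build_schedule(vmr_design("exp1"), 23)
  log <- simulate_subject(p, sched, seed = 3, render = FALSE)
  sm <- summarize_subjects(analyze_trials(log))
  # perfect retention: the no-feedback hand angle is the frozen implicit state
  entry_state <- log$trials$implicit_state_deg[
    which(sched$block == "no_feedback")[1]]
  expect_equal(sm$aftereffect_deg + sm$baseline_bias_deg, entry_state,
               tolerance = 1e-9)
})

test_that("decomposition mirrors the worked -8 / -6 example", {
  # aiming at -8 (45 deg) while the hand goes where it aimed: implicit 0
  dc <- decompose_learning(45, -8L)
  expect_equal(dc$explicit_deg, 45)
  expect_equal(dc$implicit_deg, 0)
  # hand toward number -6 while aiming at -8: 2 number units = 11.25 deg
  dc2 <- decompose_learning(number_to_hand_angle(-6L), -8L)
  expect_equal(abs(dc2$implicit_deg), 11.25)
  # reports pinned at 0: explicit 0, implicit is the whole hand angle
  dc3 <- decompose_learning(c(10, 20, 30), c(0L, 0L, 0L))
  expect_equal(dc3$explicit_deg, rep(0, 3))
  expect_equal(dc3$implicit_deg, c(10, 20, 30))
})

test_that("explicit + implicit equals the normalized hand angle exactly", {
  cfg <- cohort_config("exp1", n_per_arm = c(CB = 3L, SHAM = 3L),
                       outlier_fraction = 0.2, seed = 19)
  sim <- simulate_cohort(cfg, render = FALSE)
  sm <- summarize_subjects(analyze_cohort(sim$logs))
  # identical trial sets (all valid, all reported) -> exact additivity
  expect_equal(sm$n_reported, rep(160L, 6L))
  expect_equal(sm$explicit_deg + sm$implicit_deg,
               sm$rotation_hand_angle_deg, tolerance = 1e-10)
})

test_that("adding a constant hand bias cancels out of the learning measures", {
  sched <- build_schedule(vmr_design("exp1"), 31)
  log <- simulate_subject(learner_params(), sched, seed = 6, render = FALSE)
  kin1 <- analyze_trials(log)
  log$trials$hand_deg <- log$trials$hand_deg + 7.5
  kin2 <- analyze_trials(log)
  s1 <- summarize_subjects(kin1); s2 <- summarize_subjects(kin2)
  expect_equal(s2$baseline_bias_deg, s1$baseline_bias_deg + 7.5)
  expect_equal(s2$target_error_deg, s1$target_error_deg, tolerance = 1e-10)
  expect_equal(s2$aftereffect_deg, s1$aftereffect_deg, tolerance = 1e-10)
  expect_equal(s2$implicit_deg + s2$explicit_deg,
               s1$implicit_deg + s1$explicit_deg, tolerance = 1e-10)
})

make_summaries <- function(te, ex, im, arm = "SHAM") {
  structure(data.frame(
    subject = sprintf("S%03d", seq_along(te)), arm = arm,
    context = "horizontal", target_error_deg = te, explicit_deg = ex,
    implicit_deg = im, stringsAsFactors = FALSE),
    class = c("vmr_summaries", "data.frame"))
}

test_that("the +/- 3 SD screen applies the group rule with closed bounds", {
  # identical subjects: sd 0, bounds collapse, nobody excluded
  s <- make_summaries(rep(1, 5), rep(2, 5), rep(3, 5))
  r <- screen_outliers(s)
  expect_equal(nrow(r$excluded), 0L)
  expect_equal(nrow(r$kept), 5L)

  # one extreme subject beyond the group's 3 SD bound is excluded,
  # with the triggering measure recorded
  te <- c(exact_moment_sample(29, 0, 1, seed = 4), 25)
  stopifnot(abs(te[30] - mean(te)) > 4 * sd(te))   # construction check
  s2 <- make_summaries(te, rep(0, 30), rep(0, 30))
  r2 <- screen_outliers(s2)
  expect_equal(r2$excluded$subject, "S030")
  expect_equal(r2$excluded$measure, "target_error_deg")
  expect_equal(nrow(r2$kept), 29L)

  # groups of < 3 are skipped with a warning
  expect_warning(screen_outliers(make_summaries(1:2, 1:2, 1:2)), "skipped")
})

test_that("screen exclusion rate on normal data matches the 3-sigma tail", {
  set.seed(101)
  s <- make_summaries(rnorm(1000), rnorm(1000), rnorm(1000))
  r <- screen_outliers(s)
  # each of the 3000 subject x measure scores is outside with prob ~ 2 Phi(-3)
  p0 <- 2 * pnorm(-3)
  rate <- nrow(r$excluded) / 3000
  se <- sqrt(p0 * (1 - p0) / 3000)
  expect_lt(abs(rate - p0), 3 * se)
})
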