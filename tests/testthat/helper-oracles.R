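# Independent oracles used across the suite. Each one recomputes a quantity
# by a different route than the package (dense resampling, direct numerical
# integration, Monte Carlo), so agreement is informative.

# Hand angle by brute force: linearly resample the sampled path at 10 kHz,
# find the circle crossings on the dense path, and take the chord angle.
oracle_hand_angle <- function(traj, target_deg) {
  tt <- seq(min(traj$t), max(traj$t), by = 1e-4)
  x <- stats::approx(traj$t, traj$x, tt)$y
  y <- stats::approx(traj$t, traj$y, tt)$y
  r <- sqrt(x^2 + y^2)
  i1 <- which(r >= 1)[1]
  i7 <- which(r >= 7)[1]
  chord <- atan2(y[i7] - y[i1], x[i7] - x[i1]) * 180 / pi
  ((chord - target_deg + 180) %% 360) - 180
}

# First-crossing time of a radius on the densely resampled path.
oracle_crossing_time <- function(traj, radius) {
  tt <- seq(min(traj$t), max(traj$t), by = 1e-4)
  x <- stats::approx(traj$t, traj$x, tt)$y
  y <- stats::approx(traj$t, traj$y, tt)$y
  tt[which(sqrt(x^2 + y^2) >= radius)[1]]
}

# Studentized-range CDF by direct double integration:
# P(Q <= q) = int f_S(s) * k int phi(z) [Phi(z) - Phi(z - q s)]^(k-1) dz ds
# where S = chi_df / sqrt(df) is the scaled residual SD.
oracle_ptukey <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) k * stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    stats::integrate(f, -8, 8, rel.tol = 1e-9)$value
  }
  dens_s <- function(s) # density of chi_df / sqrt(df)
    exp((df / 2) * log(df / 2) - lgamma(df / 2) + (df - 1) * log(s) -
          df * s^2 / 2 + log(2))
  f_outer <- Vectorize(function(s) dens_s(s) * inner(s))
  stats::integrate(f_outer, 0, 5, rel.tol = 1e-8)$value
}

# Monte-Carlo JZS t-test Bayes factor: average the noncentral-t likelihood
# ratio over Cauchy prior draws of the standardized effect size. A different
# formulation (noncentral-t density, no g integral) than the package's
# quadrature.
oracle_bf_ttest_mc <- function(t, n1, n2, rscale = sqrt(2) / 2,
                               n_draws = 2e5, seed = 99) {
  set.seed(seed)
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  delta <- stats::rcauchy(n_draws, 0, rscale)
  ncp <- delta * sqrt(neff)
  # the noncentral-t density under extreme Cauchy draws is numerically 0
  # (and R's series evaluation there is pathologically slow); skip them
  far <- abs(ncp - t) > 40
  ratio <- numeric(n_draws)
  # dt() warns about precision for many ncp values; harmless at MC accuracy
  ratio[!far] <- suppressWarnings(
    stats::dt(t, nu, ncp = ncp[!far]) / stats::dt(t, nu))
  list(bf = mean(ratio), se = stats::sd(ratio) / sqrt(n_draws))
}

# Monte-Carlo JZS one-way ANOVA Bayes factor: average the g-conditional
# Bayes factor over inverse-gamma(1/2, r^2/2) prior draws.
oracle_bf_anova_mc <- function(F, ns, rscale = 0.5, n_draws = 1e6,
                               seed = 99) {
  set.seed(seed)
  J <- length(ns); N <- sum(ns); p <- J - 1; neff <- N / J
  R2 <- (F * p) / (F * p + (N - J))
  g <- 1 / stats::rgamma(n_draws, shape = 0.5, rate = rscale^2 / 2)
  bfg <- exp((N - 1 - p) / 2 * log1p(neff * g) -
               (N - 1) / 2 * log1p(neff * g * (1 - R2)))
  list(bf = mean(bfg), se = stats::sd(bfg) / sqrt(n_draws))
}

# n values with exactly the requested sample mean and SD.
exact_moment_sample <- function(n, m, s, seed = 1) {
  set.seed(seed)
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  m + s * z
}

# Brute-force grouped mean over consecutive 8-trial windows.
oracle_epoch_means <- function(values) {
  vapply(seq_len(length(values) / 8), function(k)
    mean(values[(8 * (k - 1) + 1):(8 * k)], na.rm = TRUE), numeric(1))
}

# Iterate the two-process recurrences directly (independent implementation
# of the learner dynamics, including the report-grid snap), no noise.
oracle_two_process <- function(eta, A, B, rotation = -45, n_trials = 160,
                               cap = 60, snap = TRUE) {
  explicit <- 0; implicit <- 0
  hand <- numeric(n_trials); impl <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    aim <- max(min(explicit, cap), -cap)
    if (snap) aim <- -round(-aim / 5.625) * 5.625
    hand[i] <- aim + implicit
    cursor <- hand[i] + rotation
    explicit <- explicit - eta * cursor
    implicit <- A * implicit - B * (cursor - aim)
    impl[i] <- implicit
  }
  list(hand = hand, implicit = impl)
}

# Group summaries fixture shipped with the package.
study_groups <- function(experiment, measure) {
  sm <- read.csv(system.file("extdata", "study_summaries.csv",
                             package = "vmradapt"))
  s <- sm[sm$experiment == experiment & sm$measure == measure, ]
  group_summary(s$group, s$n, s$mean, s$sd)
}
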