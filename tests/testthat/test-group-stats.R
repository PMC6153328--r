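test_that("one-way ANOVA from summaries equals the raw-data route", {
  set.seed(3)
  raw <- list(a = rnorm(12, 0, 2), b = rnorm(9, 1, 2), c = rnorm(15, -1, 3))
  a_raw <- one_way_anova(raw)
  a_sum <- one_way_anova(group_summary_from_raw(raw))
  for (s in c("F", "p", "eta_p_sq", "cohens_f"))
    expect_equal(a_raw[[s]], a_sum[[s]], tolerance = 1e-10)
  # cross-check against the stock ANOVA fit
  df <- data.frame(y = unlist(raw),
                   g = rep(names(raw), vapply(raw, length, integer(1))))
  ref <- anova(stats::lm(y ~ g, df))
  expect_equal(a_raw$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(a_raw$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  # identities
  expect_equal(a_raw$cohens_f,
               sqrt(a_raw$eta_p_sq / (1 - a_raw$eta_p_sq)))
  # equal means -> F = 0
  g0 <- group_summary(c("a", "b"), c(5, 8), c(2, 2), c(1, 1.5))
  expect_equal(one_way_anova(g0)$F, 0)
  expect_error(one_way_anova(group_summary("a", 5, 0, 1)),
               class = "vmr_input_error")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(8)
  for (i in 1:10) {
    g <- group_summary(c("x", "y"), sample(3:20, 2), rnorm(2), runif(2, .5, 3))
    a <- one_way_anova(g)
    tt <- two_sample_t(g[1, ], g[2, ])
    expect_equal(a$F, tt$t^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p, tolerance = 1e-10)
  }
})

test_that("pooled t, d and g reproduce their defining formulas", {
  tt <- two_sample_t(list(n = 10, mean = -2.67, sd = 4.20),
                     list(n = 9, mean = -6.61, sd = 5.44))
  expect_equal(tt$df, 17)
  # printed values carry two decimals and stem from unrounded raw data
  expect_lt(abs(tt$t - 1.78), 0.01)
  expect_lt(abs(tt$cohens_d - 0.81), 0.01)
  expect_lt(abs(tt$hedges_g - 0.78), 0.01)
  # g/d is exactly the small-sample correction
  expect_equal(tt$hedges_g / tt$cohens_d, 1 - 3 / (4 * 19 - 9))
  # identical groups
  t0 <- two_sample_t(list(n = 6, mean = 1, sd = 2),
                     list(n = 6, mean = 1, sd = 2))
  expect_equal(t0$t, 0); expect_equal(t0$cohens_d, 0)
  # sign follows the mean difference
  expect_lt(two_sample_t(list(n = 8, mean = 0, sd = 1),
                         list(n = 8, mean = 2, sd = 1))$t, 0)
  # agreement with stats::t.test on raw data
  set.seed(11)
  x <- rnorm(14); y <- rnorm(11, 0.8)
  mine <- two_sample_t(x, y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  refw <- stats::t.test(x, y)
  minew <- two_sample_t(x, y, var_equal = FALSE)
  expect_equal(minew$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(minew$df, unname(refw$parameter), tolerance = 1e-10)
  # zero pooled variance with unequal means -> infinite-t sentinel
  inf <- two_sample_t(list(n = 3, mean = 1, sd = 0),
                      list(n = 3, mean = 0, sd = 0))
  expect_true(is.infinite(inf$t) && inf$t > 0)
})

test_that("large-n t-test p approaches the Gaussian limit", {
  tt <- two_sample_t(list(n = 1e5, mean = 0.01, sd = 1),
                     list(n = 1e5, mean = 0, sd = 1))
  p_norm <- 2 * pnorm(abs(tt$t), lower.tail = FALSE)
  expect_equal(tt$p, p_norm, tolerance = 1e-4)
})

test_that("Tukey-Kramer p-values match a direct studentized-range integration", {
  # balanced 3-group case against the independent double-integration oracle
  g <- group_summary(c("a", "b", "c"), c(12, 12, 12), c(0, 1.2, 2.1),
                     c(1.8, 2.0, 1.6))
  a <- one_way_anova(g)
  tk <- tukey_posthoc(g)
  for (i in seq_len(nrow(tk))) {
    p_oracle <- 1 - oracle_ptukey(tk$q[i], 3, a$df_within)
    expect_equal(tk$p[i], p_oracle, tolerance = 1e-4)
  }
  # identical group summaries -> p = 1
  gid <- group_summary(c("a", "b", "c"), c(5, 5, 5), c(1, 1, 1), c(2, 2, 2))
  expect_equal(tukey_posthoc(gid)$p, rep(1, 3))
  # unequal-n case against TukeyHSD on exact-moment raw data
  gu <- group_summary(c("a", "b", "c"), c(16, 15, 15),
                      c(-1.00, 1.41, -3.94), c(4.11, 2.51, 8.53))
  raw <- data.frame(
    y = c(exact_moment_sample(16, -1.00, 4.11, 1),
          exact_moment_sample(15, 1.41, 2.51, 2),
          exact_moment_sample(15, -3.94, 8.53, 3)),
    g = factor(rep(c("a", "b", "c"), c(16, 15, 15))))
  hsd <- TukeyHSD(aov(y ~ g, raw))$g
  tku <- tukey_posthoc(gu)
  expect_equal(sort(tku$p), sort(unname(hsd[, "p adj"])), tolerance = 1e-8)
})

test_that("Type-III factorial from cell summaries matches regression oracles", {
  skip_if_not_installed("car")
  set.seed(21)
  for (rep in 1:5) {
    cells <- expand.grid(context = c("HOR", "VER"),
                         stim = c("CB", "dlPFC", "SHAM"))
    cells$n <- sample(5:14, 6, replace = TRUE)
    cells$mean <- rnorm(6, 0, 5)
    cells$sd <- runif(6, 1, 6)
    mine <- factorial_2x3(cells)
    # raw data with exactly the summarized moments
    raw <- do.call(rbind, lapply(seq_len(6), function(i)
      data.frame(context = cells$context[i], stim = cells$stim[i],
                 y = exact_moment_sample(cells$n[i], cells$mean[i],
                                         cells$sd[i], seed = 100 * rep + i))))
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op), add = TRUE)
    fit <- stats::lm(y ~ context * stim, raw)
    ref <- car::Anova(fit, type = 3)
    expect_equal(mine$F[mine$effect == "context"], ref["context", "F value"],
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "stim"], ref["stim", "F value"],
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "interaction"],
                 ref["context:stim", "F value"], tolerance = 1e-8)
    expect_equal(mine$df_error[1], ref["Residuals", "Df"])
    # raw-data overload agrees with the summary path
    mraw <- factorial_2x3_raw(raw)
    expect_equal(mraw$F, mine$F, tolerance = 1e-8)
    # eta/f identity on every row
    expect_equal(mine$cohens_f,
                 sqrt(mine$eta_p_sq / (1 - mine$eta_p_sq)))
  }
  # balanced null: identical cell means give F = 0 for every effect
  cells0 <- expand.grid(context = c("HOR", "VER"),
                        stim = c("CB", "dlPFC", "SHAM"))
  cells0$n <- 8; cells0$mean <- 1.5; cells0$sd <- 2
  expect_equal(factorial_2x3(cells0)$F, rep(0, 3))
  cells0$n <- NULL
  expect_error(factorial_2x3(cells0), class = "vmr_input_error")
})

test_that("JZS t-test Bayes factor agrees with a Monte-Carlo prior average", {
  set.seed(31)
  cases <- list(c(t = 1.78, n1 = 10, n2 = 9),
                c(t = -0.5, n1 = 15, n2 = 16),
                c(t = 2.9, n1 = 12, n2 = 12))
  for (cs in cases) {
    q <- jzs_bf_ttest(cs["t"], cs["n1"], cs["n2"])
    mc <- oracle_bf_ttest_mc(cs["t"], cs["n1"], cs["n2"])
    expect_lt(abs(q$bf - mc$bf), 3 * mc$se + 1e-6)
  }
  # t = 0 favors the null, increasingly so with n
  b10 <- jzs_bf_ttest(0, 10, 10)$bf
  b50 <- jzs_bf_ttest(0, 50, 50)$bf
  expect_lt(b10, 1); expect_lt(b50, b10)
  expect_error(jzs_bf_ttest(Inf, 10, 10), class = "vmr_input_error")
})

test_that("JZS ANOVA Bayes factor agrees with Monte-Carlo integration", {
  for (cs in list(list(F = 3.4, ns = c(16, 15, 15)),
                  list(F = 0.8, ns = c(10, 10, 9)))) {
    q <- jzs_bf_anova(cs$F, cs$ns)
    mc <- oracle_bf_anova_mc(cs$F, cs$ns, n_draws = 5e5)
    expect_lt(abs(q$bf - mc$bf), 3 * mc$se + 1e-6)
  }
  expect_error(jzs_bf_anova(-1, c(5, 5)), class = "vmr_input_error")
})

test_that("sample-size search matches the exhaustive noncentral-t scan", {
  # brute-force scan over n for d = 0.5
  pow <- vapply(2:200, function(n) power_two_sample_t(n, 0.5), numeric(1))
  n_scan <- (2:200)[which(pow >= 0.80)[1]]
  expect_equal(sample_size_ttest(0.5), n_scan)
  # independent route: stats::power.t.test solves the continuous problem
  n_cont <- stats::power.t.test(delta = 0.5, sd = 1, power = 0.80)$n
  expect_equal(n_scan, ceiling(n_cont))
  # a target barely above alpha is reached at the minimum admissible n
  expect_equal(sample_size_ttest(3, alpha = 0.5, power = 0.51), 2L)
  expect_error(sample_size_ttest(1e-4, power = 0.99, n_max = 50),
               class = "vmr_search_error")
  expect_error(sample_size_ttest(-1), class = "vmr_input_error")
})

test_that("one-way ANOVA keeps its type-I error at the nominal level", {
  set.seed(77)
  n_rep <- 10000
  rej <- vapply(seq_len(n_rep), function(i) {
    raw <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
    one_way_anova(raw)$p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})
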