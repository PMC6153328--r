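# Between-group statistics computed either from raw per-subject values or
# from (n, mean, sd) group summaries. The two routes agree to numerical
# precision because every test here depends on the data only through those
# sufficient statistics.

#' Build a group-summary table
#'
#' `(n, mean, sd)` per group is the sufficient statistic for every test in
#' this module, which makes published summary tables directly recomputable.
#'
#' @param label character group labels.
#' @param n group sizes (each >= 2).
#' @param mean group means.
#' @param sd sample standard deviations (denominator n - 1).
#' @return data.frame of class `vmr_groups`.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (any(n < 2)) stopf("every group needs n >= 2", class = "vmr_input_error")
  if (any(sd < 0)) stopf("sd must be nonnegative", class = "vmr_input_error")
  structure(data.frame(label = as.character(label), n = as.integer(n),
                       mean = as.numeric(mean), sd = as.numeric(sd),
                       stringsAsFactors = FALSE),
            class = c("vmr_groups", "data.frame"))
}

#' Summarize raw per-group values into a group-summary table
#'
#' @param values named list of numeric vectors, one per group.
#' @return a [group_summary()] table.
#' @export
group_summary_from_raw <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  group_summary(names(values),
                vapply(values, length, integer(1)),
                vapply(values, mean, numeric(1)),
                vapply(values, stats::sd, numeric(1)))
}

as_groups <- function(groups) {
  if (is.list(groups) && !is.data.frame(groups))
    return(group_summary_from_raw(groups))
  if (!all(c("label", "n", "mean", "sd") %in% names(groups)))
    stopf("need columns label, n, mean, sd (or a named list of raw vectors)",
          class = "vmr_input_error")
  group_summary(groups$label, groups$n, groups$mean, groups$sd)
}

#' One-way between-subjects ANOVA
#'
#' Reconstructs the sums of squares from group summaries:
#' `SSW = sum((n_i - 1) s_i^2)`, `SSB = sum(n_i (m_i - grand mean)^2)` with
#' the weighted grand mean, so the result is identical to the classical ANOVA
#' on the raw data. Effect sizes: partial eta squared
#' `SSB / (SSB + SSW)` and Cohen's f `sqrt(eta / (1 - eta))`.
#'
#' @param groups a [group_summary()] table or a named list of raw vectors.
#' @param bf if `TRUE`, attach the JZS Bayes factor ([jzs_bf_anova()]).
#' @param bf_rscale fixed-effects Cauchy prior scale for the Bayes factor.
#' @return object of class `vmr_anova`: list with `F`, `df_between`,
#'   `df_within`, `p`, `eta_p_sq`, `cohens_f`, `ms_within`, `groups`, and
#'   optionally `bf`.
#' @examples
#' g <- group_summary(c("CB", "PFC", "SHAM"), c(16, 15, 15),
#'                    c(-1.00, 1.41, -3.94), c(4.11, 2.51, 8.53))
#' one_way_anova(g)
#' @export
one_way_anova <- function(groups, bf = FALSE, bf_rscale = 0.5) {
  g <- as_groups(groups)
  k <- nrow(g)
  if (k < 2) stopf("need >= 2 groups", class = "vmr_input_error")
  N <- sum(g$n)
  grand <- sum(g$n * g$mean) / N
  ssb <- sum(g$n * (g$mean - grand)^2)
  ssw <- sum((g$n - 1) * g$sd^2)
  df_b <- k - 1L
  df_w <- N - k
  msw <- ssw / df_w
  Fv <- (ssb / df_b) / msw
  eta <- ssb / (ssb + ssw)
  out <- list(F = Fv, df_between = df_b, df_within = df_w,
              p = stats::pf(Fv, df_b, df_w, lower.tail = FALSE),
              eta_p_sq = eta, cohens_f = sqrt(eta / (1 - eta)),
              ms_within = msw, groups = g)
  if (bf) out$bf <- jzs_bf_anova(Fv, g$n, rscale = bf_rscale)
  structure(out, class = "vmr_anova")
}

#' @export
print.vmr_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g, eta_p^2 = %.3f, f = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta_p_sq, x$cohens_f))
  if (!is.null(x$bf))
    cat(sprintf("  JZS BF10 = %.3f (quadrature error < %.2g)\n",
                x$bf$bf, x$bf$error))
  invisible(x)
}

# Pooled two-group SD from summaries.
pooled_sd <- function(n1, s1, n2, s2)
  sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))

# Hedges' small-sample correction J = 1 - 3 / (4 N - 9).
hedges_j <- function(N) 1 - 3 / (4 * N - 9)

#' Tukey-Kramer post-hoc pairwise comparisons
#'
#' Studentized-range p-values for every group pair, with the Kramer harmonic
#' adjustment for unequal n: `q = |m_i - m_j| / sqrt(MSW/2 (1/n_i + 1/n_j))`,
#' referred to the studentized-range distribution with the ANOVA's within
#' degrees of freedom. Pairwise Cohen's d and Hedges' g use the two groups'
#' pooled SD (not MS within), matching how pairwise effect sizes are usually
#' reported alongside these tests.
#'
#' @param groups a [group_summary()] table or a named list of raw vectors.
#' @param ms_within,df_within error mean square and df; taken from the
#'   one-way ANOVA on `groups` when omitted.
#' @return data.frame with one row per pair: `group1`, `group2`, `diff`,
#'   `q`, `p`, `cohens_d`, `hedges_g`.
#' @export
tukey_posthoc <- function(groups, ms_within = NULL, df_within = NULL) {
  g <- as_groups(groups)
  if (is.null(ms_within) || is.null(df_within)) {
    a <- one_way_anova(g)
    ms_within <- a$ms_within
    df_within <- a$df_within
  }
  if (df_within < 1) stopf("df_within must be >= 1", class = "vmr_input_error")
  k <- nrow(g)
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    diff <- g$mean[i1] - g$mean[i2]
    se <- sqrt(ms_within / 2 * (1 / g$n[i1] + 1 / g$n[i2]))
    q <- abs(diff) / se
    sp <- pooled_sd(g$n[i1], g$sd[i1], g$n[i2], g$sd[i2])
    d <- if (sp > 0) abs(diff) / sp else if (diff == 0) 0 else Inf
    data.frame(group1 = g$label[i1], group2 = g$label[i2], diff = diff,
               q = q, p = stats::ptukey(q, k, df_within, lower.tail = FALSE),
               cohens_d = d, hedges_g = d * hedges_j(g$n[i1] + g$n[i2]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Independent-samples t-test from group summaries
#'
#' Student's pooled-variance t by default (`df = n1 + n2 - 2`), with Welch as
#' an option. Effect sizes: Cohen's d `|m1 - m2| / pooled SD` and Hedges' g
#' `d * (1 - 3/(4 N - 9))`.
#'
#' @param g1,g2 single-row [group_summary()] tables (or lists/rows with
#'   `n`, `mean`, `sd`), or raw numeric vectors.
#' @param var_equal pooled-variance Student t (default) vs Welch.
#' @param bf if `TRUE`, attach the JZS Bayes factor ([jzs_bf_ttest()]).
#' @param bf_rscale Cauchy prior scale for the Bayes factor.
#' @return object of class `vmr_ttest`: `t`, `df`, `p` (two-sided),
#'   `cohens_d`, `hedges_g`, and optionally `bf`.
#' @examples
#' two_sample_t(list(n = 10, mean = -2.67, sd = 4.20),
#'              list(n = 9, mean = -6.61, sd = 5.44))
#' @export
two_sample_t <- function(g1, g2, var_equal = TRUE, bf = FALSE,
                         bf_rscale = sqrt(2) / 2) {
  as1 <- function(g) {
    if (is.numeric(g)) g <- list(n = length(g), mean = mean(g),
                                 sd = stats::sd(g))
    if (g$n < 2) stopf("need n >= 2 in each group", class = "vmr_input_error")
    g
  }
  g1 <- as1(g1); g2 <- as1(g2)
  delta <- g1$mean - g2$mean
  sp <- pooled_sd(g1$n, g1$sd, g2$n, g2$sd)
  if (var_equal) {
    df <- g1$n + g2$n - 2
    se <- sp * sqrt(1 / g1$n + 1 / g2$n)
  } else {
    v1 <- g1$sd^2 / g1$n; v2 <- g2$sd^2 / g2$n
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (g1$n - 1) + v2^2 / (g2$n - 1))
  }
  tv <- if (se > 0) delta / se else if (delta == 0) 0 else Inf * sign(delta)
  d <- if (sp > 0) abs(delta) / sp else if (delta == 0) 0 else Inf
  out <- list(t = tv, df = df,
              p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE),
              cohens_d = d, hedges_g = d * hedges_j(g1$n + g2$n),
              var_equal = var_equal)
  if (bf) out$bf <- jzs_bf_ttest(tv, g1$n, g2$n, rscale = bf_rscale)
  structure(out, class = "vmr_ttest")
}

#' @export
print.vmr_ttest <- function(x, ...) {
  cat(sprintf("t(%.4g) = %.3f, p = %.4g, d = %.3f, g = %.3f\n",
              x$df, x$t, x$p, x$cohens_d, x$hedges_g))
  if (!is.null(x$bf))
    cat(sprintf("  JZS BF10 = %.3f\n", x$bf$bf))
  invisible(x)
}

#' Two-by-three between-subjects factorial ANOVA (Type III)
#'
#' Computes the CONTEXT x STIM factorial from the six cell summaries using
#' Type-III (unweighted-marginal-means) sums of squares: each effect's
#' hypothesis is a contrast set `L` on the cell means and
#' `SS = (L m)' (L D L')^{-1} (L m)` with `D = diag(1/n_cell)`; the error
#' mean square pools the cell variances. This matches the default of the
#' standard statistics packages for unbalanced factorials. A raw-data
#' overload (`factorial_2x3_raw()`) fits the equivalent sum-to-zero
#' regression and agrees with the summary path.
#'
#' @param cells data.frame with columns `context` (2 levels), `stim`
#'   (3 levels), `n`, `mean`, `sd` — all six cells present.
#' @return data.frame of class `vmr_factorial` with one row per effect
#'   (`context`, `stim`, `interaction`): `F`, `df_effect`, `df_error`, `p`,
#'   `eta_p_sq`, `cohens_f`.
#' @export
factorial_2x3 <- function(cells) {
  req <- c("context", "stim", "n", "mean", "sd")
  if (!all(req %in% names(cells)))
    stopf("cells need columns %s", paste(req, collapse = ", "),
          class = "vmr_input_error")
  cells$context <- factor(cells$context)
  cells$stim <- factor(cells$stim)
  a <- levels(cells$context); b <- levels(cells$stim)
  if (length(a) != 2 || length(b) != 3 || nrow(cells) != 6 ||
      anyDuplicated(cells[, c("context", "stim")]))
    stopf("need exactly the 6 cells of a 2 x 3 design",
          class = "vmr_input_error")
  if (any(cells$n < 2))
    stopf("every cell needs n >= 2", class = "vmr_input_error")
  # fix cell order: context within stim
  cells <- cells[order(cells$context, cells$stim), ]
  m <- cells$mean; n <- cells$n
  D <- diag(1 / n)
  df_err <- sum(n - 1)
  ms_err <- sum((n - 1) * cells$sd^2) / df_err

  cell <- function(i, j) (i - 1) * 3 + j   # context i, stim j
  # contrast rows on the 6 cell means (unweighted marginal means)
  L_context <- matrix(0, 1, 6)
  L_context[1, cell(1, 1:3)] <- 1 / 3
  L_context[1, cell(2, 1:3)] <- -1 / 3
  L_stim <- matrix(0, 2, 6)
  for (r in 1:2) {
    L_stim[r, c(cell(1, r), cell(2, r))] <- 1 / 2
    L_stim[r, c(cell(1, 3), cell(2, 3))] <- -1 / 2
  }
  L_int <- matrix(0, 2, 6)
  for (r in 1:2) {
    L_int[r, cell(1, r)] <- 1; L_int[r, cell(1, 3)] <- -1
    L_int[r, cell(2, r)] <- -1; L_int[r, cell(2, 3)] <- 1
  }
  eff <- function(L, name) {
    Lm <- L %*% m
    ss <- drop(t(Lm) %*% solve(L %*% D %*% t(L)) %*% Lm)
    df <- nrow(L)
    Fv <- (ss / df) / ms_err
    eta <- ss / (ss + df_err * ms_err)
    data.frame(effect = name, F = Fv, df_effect = df, df_error = df_err,
               p = stats::pf(Fv, df, df_err, lower.tail = FALSE),
               eta_p_sq = eta, cohens_f = sqrt(eta / (1 - eta)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(eff(L_context, "context"), eff(L_stim, "stim"),
               eff(L_int, "interaction"))
  class(out) <- c("vmr_factorial", "data.frame")
  out
}

#' @rdname factorial_2x3
#' @param data data.frame with numeric `y` and factors `context`, `stim`.
#' @export
factorial_2x3_raw <- function(data) {
  stopifnot(all(c("y", "context", "stim") %in% names(data)))
  agg <- stats::aggregate(y ~ context + stim, data,
                          function(v) c(n = length(v), mean = mean(v),
                                        sd = stats::sd(v)))
  cells <- data.frame(context = agg$context, stim = agg$stim,
                      n = agg$y[, "n"], mean = agg$y[, "mean"],
                      sd = agg$y[, "sd"])
  factorial_2x3(cells)
}

#' JZS default Bayes factor for a two-sample t-test
#'
#' The Jeffreys-Zellner-Siow Bayes factor computed from the t statistic and
#' group sizes: a Cauchy(`rscale`) prior on the standardized effect size,
#' integrated over the implied inverse-gamma(1/2, rscale^2/2) prior on g by
#' adaptive quadrature.
#'
#' @param t observed t statistic.
#' @param n1,n2 group sizes.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2 ~ 0.707`).
#' @return list of class `vmr_bf` with `bf` (BF10) and `error` (quadrature
#'   absolute-error estimate on BF10).
#' @export
jzs_bf_ttest <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  if (!is.finite(t)) stopf("t must be finite", class = "vmr_input_error")
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  log_prior <- function(g)
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - rscale^2 / (2 * g)
  log_lik_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    ll <- -0.5 * log1p(neff * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + neff * g) * nu))
    exp(ll - log_lik_null + log_prior(g))
  }
  q <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)
  structure(list(bf = q$value, error = q$abs.error), class = "vmr_bf")
}

#' JZS default Bayes factor for a one-way ANOVA from its F statistic
#'
#' Fixed-effects JZS Bayes factor computed from the F statistic and the group
#' sizes, with a Cauchy(`rscale`) prior on the standardized effects
#' (equivalently inverse-gamma(1/2, rscale^2/2) on g). For a design with `J`
#' groups and `N` subjects total the g-conditional Bayes factor has the
#' closed form
#' \deqn{BF(g) = (1 + N_e g)^{(N-1-p)/2} / (1 + N_e g (1 - R^2))^{(N-1)/2}}
#' with `p = J - 1`, `R^2 = F p / (F p + N - J)` and the per-group size
#' `N_e = N / J` (exact for balanced designs; for mildly unbalanced group
#' sizes the induced error is far below the quadrature tolerance reported).
#'
#' @param F observed F statistic.
#' @param group_ns integer vector of group sizes.
#' @param rscale fixed-effects Cauchy scale (default 0.5).
#' @return list of class `vmr_bf` with `bf` (BF10) and `error`.
#' @examples
#' a <- one_way_anova(group_summary(c("CB", "PFC", "SHAM"), c(16, 15, 15),
#'                    c(-1.00, 1.41, -3.94), c(4.11, 2.51, 8.53)))
#' jzs_bf_anova(a$F, c(16, 15, 15))
#' @export
jzs_bf_anova <- function(F, group_ns, rscale = 0.5) {
  if (!is.finite(F) || F < 0)
    stopf("F must be finite and nonnegative", class = "vmr_input_error")
  J <- length(group_ns)
  N <- sum(group_ns)
  p <- J - 1
  neff <- N / J
  R2 <- (F * p) / (F * p + (N - J))
  log_prior <- function(g)
    0.5 * log(rscale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - rscale^2 / (2 * g)
  integrand <- function(g) {
    lbf <- (N - 1 - p) / 2 * log1p(neff * g) -
      (N - 1) / 2 * log1p(neff * g * (1 - R2))
    exp(lbf + log_prior(g))
  }
  q <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)
  structure(list(bf = q$value, error = q$abs.error), class = "vmr_bf")
}

#' @export
print.vmr_bf <- function(x, ...) {
  cat(sprintf("JZS BF10 = %.4f (quadrature error < %.2g)\n", x$bf, x$error))
  invisible(x)
}

#' Power of a two-sided two-sample pooled t-test
#'
#' Exact power under the noncentral-t distribution with noncentrality
#' `d * sqrt(n/2)` and `2n - 2` degrees of freedom.
#'
#' @param n per-group sample size.
#' @param d Cohen's d effect size.
#' @param alpha two-sided significance level.
#' @return power in \[0, 1\].
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05) {
  df <- 2 * n - 2
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n / 2)
  stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
}

#' Minimum per-group sample size for a two-sample t-test
#'
#' Smallest integer n per group such that the two-sided pooled t-test at level
#' `alpha` reaches the target power at effect size d, evaluated with the exact
#' noncentral-t power function.
#'
#' @param d Cohen's d (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param n_max search bound.
#' @return integer n per group.
#' @examples
#' sample_size_ttest(0.81, 0.05, 0.80) # 25
#' @export
sample_size_ttest <- function(d, alpha = 0.05, power = 0.80, n_max = 1e6) {
  if (d <= 0 || alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stopf("need d > 0 and alpha, power in (0, 1)", class = "vmr_input_error")
  n <- 2L
  while (n <= n_max) {
    if (power_two_sample_t(n, d, alpha) >= power) return(n)
    n <- n + 1L
  }
  stopf("target power not reachable with n <= %d", n_max,
        class = "vmr_search_error")
}
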