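# Repeated-measures ANOVA, post hoc tests and gain-slope regression

rm_table <- function(n_subj, levels_list, seed, effect = NULL) {
  grid <- expand.grid(c(list(subject = factor(seq_len(n_subj))),
                        levels_list), stringsAsFactors = TRUE)
  set.seed(seed)
  grid$y <- rnorm(nrow(grid))
  if (!is.null(effect)) grid$y <- grid$y + effect(grid)
  grid
}

test_that("within-subject degrees of freedom follow the design", {
  d <- rm_table(24, list(mode = c("a", "b")), seed = 1)
  res <- rm_anova(d, "y", "subject", "mode")
  expect_equal(res$df_num, 1)
  expect_equal(res$df_den, 23)
})

test_that("no condition differences give F = 0, p = 1", {
  d <- expand.grid(subject = factor(1:6), mode = c("a", "b"),
                   bg = c("x", "z"))
  d$y <- as.numeric(d$subject)  # varies by subject only
  res <- rm_anova(d, "y", "subject", c("mode", "bg"))
  expect_true(all(res$F == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$degenerate))
})

test_that("rm_anova matches the longhand sums-of-squares oracle", {
  # 6-subject 2x2 toy table
  d <- rm_table(6, list(A = c("a1", "a2"), B = c("b1", "b2")), seed = 11,
                effect = function(g) 0.8 * (g$A == "a2") +
                  0.3 * (g$A == "a2") * (g$B == "b2"))
  res <- rm_anova(d, "y", "subject", c("A", "B"))
  orc <- oracle_rm_anova(d, "y", "subject", c("A", "B"))
  for (eff in orc$effect) {
    i <- match(eff, res$effect); j <- match(eff, orc$effect)
    expect_lt(abs(res$F[i] - orc$F[j]), 1e-10)
    expect_lt(abs(res$p[i] - orc$p[j]), 1e-10)
    expect_lt(abs(res$eta_sq_partial[i] - orc$eta[j]), 1e-10)
  }

  # random 2x2x2 tables with 8 subjects
  for (seed in c(3, 7)) {
    d3 <- rm_table(8, list(A = c("a1", "a2"), B = c("b1", "b2"),
                           C = c("c1", "c2")), seed = seed)
    res3 <- rm_anova(d3, "y", "subject", c("A", "B", "C"))
    orc3 <- oracle_rm_anova(d3, "y", "subject", c("A", "B", "C"))
    expect_equal(nrow(res3), 7)
    for (eff in orc3$effect) {
      i <- match(eff, res3$effect); j <- match(eff, orc3$effect)
      expect_lt(abs(res3$F[i] - orc3$F[j]), 1e-10)
      expect_lt(abs(res3$eta_sq_partial[i] - orc3$eta[j]), 1e-10)
    }
  }
})

test_that("F equals t squared for 2-level factors", {
  for (seed in c(2, 5, 8)) {
    d <- rm_table(10, list(mode = c("a", "b")), seed = seed,
                  effect = function(g) 0.4 * (g$mode == "b"))
    res <- rm_anova(d, "y", "subject", "mode")
    a <- d$y[d$mode == "a"][order(d$subject[d$mode == "a"])]
    b <- d$y[d$mode == "b"][order(d$subject[d$mode == "b"])]
    tt <- paired_t(a, b)
    expect_equal(res$F, tt$statistic^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p, tolerance = 1e-10)
  }
})

test_that("GG epsilon is bounded and unit under compound symmetry", {
  # 3-level factor: epsilon in [1/2, 1]
  for (seed in c(4, 9, 16)) {
    d <- rm_table(8, list(gain = c("g1", "g2", "g3")), seed = seed)
    res <- rm_anova(d, "y", "subject", "gain")
    expect_gte(res$gg_epsilon, 0.5)
    expect_lte(res$gg_epsilon, 1)
    expect_equal(res$df_num, res$gg_epsilon * 2, tolerance = 1e-12)
  }

  # data built so the contrast-score sample covariance is spherical:
  # subject scores are rows of a scaled orthogonal, column-centred matrix
  k <- 3
  C <- qr.Q(qr(cbind(rep(1, k), contr.helmert(k))))[, -1]
  H <- qr.Q(qr(cbind(rep(1, 4), contr.helmert(4))))[, -1]  # 4 x 3, centred
  Z <- H[, 1:2] * 2
  Y <- Z %*% t(C) + 5
  d <- data.frame(subject = factor(rep(1:4, k)),
                  gain = factor(rep(1:k, each = 4)),
                  y = as.vector(Y))
  res <- rm_anova(d, "y", "subject", "gain")
  expect_equal(res$gg_epsilon, 1, tolerance = 1e-10)

  # 2-level factors need no correction
  d2 <- rm_table(6, list(mode = c("a", "b")), seed = 1)
  expect_equal(rm_anova(d2, "y", "subject", "mode")$gg_epsilon, 1)
})

test_that("observed power follows the noncentral-F convention", {
  d <- rm_table(12, list(mode = c("a", "b")), seed = 3,
                effect = function(g) 2 * (g$mode == "b"))
  res <- rm_anova(d, "y", "subject", "mode")
  lambda <- res$F * res$df_num
  expect_equal(res$power,
               pf(qf(0.95, res$df_num, res$df_den), res$df_num,
                  res$df_den, ncp = lambda, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(res$power, 0.9)
})

test_that("rm_anova validates its input", {
  d <- rm_table(6, list(mode = c("a", "b")), seed = 1)
  expect_error(rm_anova(d[-1, ], "y", "subject", "mode"), "balanced")
  expect_error(rm_anova(d[d$subject == 1, ], "y", "subject", "mode"),
               "2 subjects")
})

test_that("paired t-tests match longhand arithmetic and Bonferroni scaling", {
  a <- c(3, 4, 5, 4, 3, 5); b <- c(2, 2, 2, 2, 2, 2)
  # differences (1,2,3,2,1,3): t = mean / (sd / sqrt(n))
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(6))
  res <- paired_t(a, b)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 5)

  res2 <- paired_t(a, b, correction_m = 2)
  expect_equal(res2$p, min(res$p_uncorrected * 2, 1))
  res_many <- paired_t(a, b, correction_m = 1000)
  expect_equal(res_many$p, 1)

  eq <- paired_t(a, a)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  expect_true(eq$degenerate)

  # unpaired variant reproduces the classical two-sample test
  un <- paired_t(a, b + rnorm(6, 0, 1e-8), paired = FALSE)
  expect_equal(un$df, 10)
})

test_that("gain-slope regression is exact on 3-point lines", {
  d <- data.frame(subject = rep(1:2, each = 3),
                  gain = rep(c(1, 1.15, 1.3), 2),
                  pha = c(0, 0.15, 0.3, 0.2, 0.2, 0.2))
  sl <- fit_gain_slopes(d)
  expect_equal(sl$slope, c(1, 0), tolerance = 1e-12)
  expect_equal(sl$intercept, c(-1, 0.2), tolerance = 1e-12)

  expect_error(fit_gain_slopes(d[-1, ]), "exactly 3")
})

test_that("slopes are recovered from noisy simulated subjects", {
  set.seed(99)
  n <- 25
  gains <- c(1, 1.15, 1.3)
  d <- do.call(rbind, lapply(seq_len(n), function(s) {
    data.frame(subject = s, gain = gains,
               pha = 0.5 * gains + rnorm(3, 0, 0.2))
  }))
  sl <- fit_gain_slopes(d)
  se <- sd(sl$slope) / sqrt(n)
  expect_lt(abs(mean(sl$slope) - 0.5), 3 * se)
})

test_that("slope tests against zero use the stated tail conventions", {
  expect_true(slopes_vs_zero(rep(0, 5))$degenerate)
  expect_equal(slopes_vs_zero(rep(0, 5))$statistic, 0)

  sl25 <- data.frame(subject = 1:25, slope = rnorm(25, 0.2, 0.5),
                     intercept = 0)
  expect_equal(slopes_vs_zero(sl25)$df, 24)

  res <- slopes_vs_zero(c(0.1, 0.2, 0.3))
  expect_equal(res$statistic, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$statistic, 3.464102, tolerance = 1e-6)
  one <- slopes_vs_zero(c(0.1, 0.2, 0.3), tails = "one")
  two <- slopes_vs_zero(c(0.1, 0.2, 0.3), tails = "two")
  expect_equal(two$p, 2 * one$p, tolerance = 1e-12)
})
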