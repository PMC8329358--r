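test_that("mixed ANOVA matches the linear-model projection oracle", {
  for (sd in 1:30) {
    rd <- random_design(sd)
    m <- tidy(mixed_anova(rd$data, "y", "group", rd$within))
    o <- oracle_mixed_anova(rd$data, "y", "group", rd$within)
    m2 <- m[match(o$effect, m$effect), ]
    expect_equal(m2$statistic, o$statistic, tolerance = 1e-8)
    expect_equal(m2$df_num, o$df_num)
    expect_equal(m2$df_den, o$df_den)
  }
})

test_that("constructed between-effect design gives exact F and null within", {
  d <- tidyr::expand_grid(
    subject_id = sprintf("s%d", 1:8),
    w1 = c("lo", "hi"), w2 = c("lo", "hi")
  )
  d$group <- rep(c("a", "b"), each = 16)
  set.seed(4)
  subj_noise <- rnorm(8, 0, 1)[match(d$subject_id, sprintf("s%d", 1:8))]
  d$y <- ifelse(d$group == "a", 1, 0) + subj_noise
  m <- tidy(mixed_anova(d, "y", "group", c("w1", "w2")))
  o <- oracle_mixed_anova(d, "y", "group", c("w1", "w2"))
  expect_equal(m$statistic[m$effect == "group"],
               o$statistic[o$effect == "group"], tolerance = 1e-10)
  within_f <- m$statistic[m$effect != "group"]
  expect_true(all(within_f < 1e-10))

  # group df: 2 groups, 8 subjects -> (1, 6)
  expect_equal(m$df_num[m$effect == "group"], 1)
  expect_equal(m$df_den[m$effect == "group"], 6)
})

test_that("pure between effect with no residual variance has ges = 1", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:6),
                          w1 = c("lo", "hi"))
  d$group <- rep(c("a", "b"), each = 6)
  d$y <- ifelse(d$group == "a", 1, 0)
  m <- tidy(mixed_anova(d, "y", "group", "w1"))
  expect_equal(m$ges[m$effect == "group"], 1)
})

test_that("degenerate all-equal responses report zero F with a flag", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:6),
                          w1 = c("lo", "hi"))
  d$group <- rep(c("a", "b"), each = 6)
  d$y <- 3
  m <- mixed_anova(d, "y", "group", "w1")
  expect_true(m$degenerate)
  expect_true(all(tidy(m)$statistic == 0))
})

test_that("ges is invariant to affine rescaling of the response", {
  rd <- random_design(12)
  g1 <- tidy(mixed_anova(rd$data, "y", "group", rd$within))$ges
  rd$data$y <- 5.5 * rd$data$y - 2
  g2 <- tidy(mixed_anova(rd$data, "y", "group", rd$within))$ges
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("design validation rejects missing cells and singleton groups", {
  d <- tidyr::expand_grid(subject_id = sprintf("s%d", 1:6),
                          w1 = c("lo", "hi"))
  d$group <- rep(c("a", "b"), each = 6)
  d$y <- rnorm(12)
  expect_error(mixed_anova(d[-1, ], "y", "group", "w1"), "one value per within cell")
  d2 <- d
  d2$group[d2$subject_id == "s1"] <- "c"
  expect_error(mixed_anova(d2, "y", "group", "w1"), "at least 2 subjects")
})

test_that("Welch t matches the textbook formula and is antisymmetric", {
  a <- c(0, 1, 2)
  b <- c(10, 11, 12)
  res <- welch_t(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)

  swapped <- welch_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("Holm adjustment matches its closed form and dominates raw p", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p))  # rank order preserved
  }
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Brown-Forsythe Levene matches a deviation-ANOVA oracle", {
  g1 <- c(1, 2, 3)
  g2 <- c(10, 20, 30)
  res <- levene_median(c(g1, g2), rep(c("a", "b"), each = 3))
  d1 <- abs(g1 - median(g1))   # 1,0,1
  d2 <- abs(g2 - median(g2))   # 10,0,10
  dev <- c(d1, d2)
  grand <- mean(dev)
  ssb <- 3 * ((mean(d1) - grand)^2 + (mean(d2) - grand)^2)
  ssw <- sum((d1 - mean(d1))^2) + sum((d2 - mean(d2))^2)
  w_hand <- (ssb / 1) / (ssw / 4)
  expect_equal(res$statistic, w_hand, tolerance = 1e-12)

  # identical spread pattern: W = 0
  same <- levene_median(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  # location shift leaves W unchanged
  shift <- levene_median(c(g1 + 100, g2), rep(c("a", "b"), each = 3))
  expect_equal(shift$statistic, res$statistic, tolerance = 1e-12)
})

test_that("rank tests behave at the reference points", {
  sep <- rank_tests(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(sep$test, "wilcoxon")
  expect_equal(sep$p_value, 0.1)   # exact two-sided, 3 vs 3, full separation
  expect_true(sep$statistic %in% c(0, 9))

  same <- rank_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(same$p_value, 0.9)

  kw <- rank_tests(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$test, "kruskal")
  expect_lt(kw$statistic, 1e-10)
})

test_that("Spearman matches the 1 - 6*sum(d^2)/(n(n^2-1)) form and cor.test", {
  expect_equal(spearman_cor(1:6, (1:6)^3)$rho, 1)
  res <- spearman_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 1 - 6 * 4 / (4 * 15))   # = 0.6
  rev <- spearman_cor(c(1, 2, 3, 4), -c(2, 1, 4, 3))
  expect_equal(rev$rho, -res$rho)

  set.seed(10)
  x <- rnorm(40)
  y <- x + rnorm(40)
  mine <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)

  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "rank variance")
})
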