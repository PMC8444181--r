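test_that("group standardisation centres, scales and preserves order", {
  set.seed(51)
  values <- c(rnorm(20, 10, 3), rnorm(30, -5, 0.2))
  groups <- rep(c("a", "b"), c(20, 30))
  z <- center_scale(values, groups)
  for (g in c("a", "b")) {
    expect_equal(mean(z[groups == g]), 0, tolerance = 1e-12)
    expect_equal(sd(z[groups == g]), 1, tolerance = 1e-12)
    expect_identical(order(z[groups == g]), order(values[groups == g]))
  }
  expect_error(center_scale(c(1, 1, 1, 2, 3), rep(c("k", "m"), c(3, 2))), "'k'")
})

test_that("KS screen accepts normal and rejects uniform data", {
  set.seed(52)
  z <- center_scale(rnorm(1000), rep("g", 1000))
  expect_gt(ks_normality(z)$p.value, 0.05)
  u <- center_scale(runif(1000), rep("g", 1000))
  expect_lt(ks_normality(u)$p.value, 0.01)
  expect_true(ks_normality(z)$statistic >= 0 && ks_normality(z)$statistic <= 1)
  expect_error(ks_normality(c(1, 2)), ">= 5")
})

test_that("N-way ANOVA separates true effects from null factors", {
  set.seed(53)
  des <- expand.grid(
    genotype = c("wt", "dEx3", "dEx3_SHP2"),
    dose = c(0, 10, 150), rep = 1:4
  )
  y0 <- rnorm(nrow(des))
  null_tab <- anova_nway(y0, des[, c("genotype", "dose")])
  expect_true(all(null_tab$p > 0.05))
  # +3 pooled-sd genotype shift must light up the genotype factor only
  y1 <- y0 + 3 * sd(y0) * (des$genotype == "dEx3")
  alt_tab <- anova_nway(y1, des[, c("genotype", "dose")])
  expect_lt(alt_tab$p[alt_tab$factor == "genotype"], 0.01)
  # balanced design: factor order irrelevant
  swapped <- anova_nway(y1, des[, c("dose", "genotype")])
  expect_equal(
    alt_tab$F[alt_tab$factor == "genotype"],
    swapped$F[swapped$factor == "genotype"]
  )
  expect_error(anova_nway(y0, data.frame(one = rep("x", nrow(des)))), "levels")
})

test_that("two-group one-way ANOVA matches the pooled t-test identity", {
  set.seed(54)
  A <- rnorm(8, 1)
  B <- rnorm(11, 0)
  av <- anova_1way(A, B)
  tt <- t.test(A, B, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(av$p, tt$p.value, tolerance = 1e-12)
  sw <- anova_1way(B, A)
  expect_equal(sw$F, av$F)
  expect_equal(sw$p, av$p)
  same <- anova_1way(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$F, 0)
  expect_identical(same$p, 1)
})

test_that("unbiased Cohen's d reproduces the printed worked example", {
  ef <- cohens_d_unbiased(c(2, 4), c(1, 3))
  expect_identical(ef$m_A, 3)
  expect_identical(ef$m_B, 2)
  expect_identical(ef$SS_A, 2)
  expect_identical(ef$SS_B, 2)
  expect_equal(ef$s_AB, sqrt(2))
  expect_equal(ef$d_unb, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(cohens_d_unbiased(c(1, 2, 3), c(1, 2, 3))$d_unb, 0)
  a <- cohens_d_unbiased(c(5, 9, 7), c(4, 4, 6))
  b <- cohens_d_unbiased(3.7 * c(5, 9, 7), 3.7 * c(4, 4, 6))
  expect_equal(a$d_unb, b$d_unb, tolerance = 1e-12)
  expect_error(cohens_d_unbiased(c(1, 1), c(1, 1)), "zero pooled scale")
})

test_that("effect classification uses exclusive 0.2/0.5/0.8 thresholds", {
  expect_identical(classify_effect(0.85), "large")
  expect_identical(classify_effect(0.6), "medium")
  expect_identical(classify_effect(0.3), "small")
  expect_identical(classify_effect(0.1), "negligible")
  expect_identical(classify_effect(0.2), "negligible")
  expect_identical(classify_effect(-0.9), "large")
  # monotone in |d|
  cats <- factor(
    vapply(seq(0, 2, by = 0.01), classify_effect, character(1)),
    levels = c("negligible", "small", "medium", "large"), ordered = TRUE
  )
  expect_false(is.unsorted(cats))
})

test_that("comparisons are flagged only when p and d both pass", {
  expect_true(significance_decision(0.04, 0.3)$flagged)
  expect_identical(significance_decision(0.04, 0.3)$category, "small")
  expect_false(significance_decision(0.2, 1.0)$flagged)
  expect_false(significance_decision(0.01, 0.15)$flagged)
  expect_true(significance_decision(0.05, -0.25)$flagged)
})

test_that("Pearson correlation on exact and toy data", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2)), 0.5)
  set.seed(55)
  expect_lt(abs(pearson_correlation(rnorm(5000), rnorm(5000))), 0.05)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("replicate correlation comparison returns the mean difference", {
  r_sat <- c(0.73, 0.71, 0.714)
  r_basal <- c(0.47, 0.46, 0.462)
  out <- compare_replicate_correlations(r_sat, r_basal)
  expect_equal(out$beta, mean(r_sat) - mean(r_basal), tolerance = 1e-12)
  # the printed convention: group means 0.718 and 0.464 give beta = 0.254
  lists <- list(A = c(0.718, 0.718), B = c(0.464, 0.464))
  expect_equal(
    compare_replicate_correlations(lists$A + c(-0.01, 0.01), lists$B + c(-0.01, 0.01))$beta,
    0.254,
    tolerance = 1e-12
  )
  # hand-computed pooled t on toy lists
  A <- c(0.7, 0.72, 0.71)
  B <- c(0.46, 0.47, 0.46)
  out2 <- compare_replicate_correlations(A, B)
  sp <- sqrt((sum((A - mean(A))^2) + sum((B - mean(B))^2)) / 4)
  t_hand <- (mean(A) - mean(B)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(out2$t, t_hand, tolerance = 1e-12)
  same <- compare_replicate_correlations(A, A)
  expect_identical(same$beta, 0)
  expect_equal(same$p, 1)
})

test_that("pairwise comparison table covers every group pair", {
  set.seed(56)
  values <- c(rnorm(5, 0), rnorm(5, 0.1), rnorm(5, 5))
  groups <- rep(c("g1", "g2", "g3"), each = 5)
  tab <- pairwise_comparisons(values, groups)
  expect_identical(nrow(tab), 3L)
  row13 <- tab[tab$group_A == "g1" & tab$group_B == "g3", ]
  expect_true(row13$flagged)
})
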