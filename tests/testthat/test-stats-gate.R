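# Frozen external reference values (computed once with an independent
# statistical stack: scipy 1.17.1 / pingouin 0.6.1) for the delegated
# and hand-implemented routines.
REF <- list(
  shapiro_p_12345 = 0.9671739349728582,
  t_stat = -5.0, t_p = 0.0010528257933665399,
  welch_F = 44.92307692307693, welch_df2 = 8.0,
  welch_p = 4.468738195701946e-05,
  gh_p = c("b-a" = 0.5972660921074443, "c-a" = 4.83889999082221e-05,
           "c-b" = 0.00011361366397666384),
  levene_het_F = 26.353558422687193, levene_het_p = 1.2328976856900789e-05,
  pearson_n12_r = 0.995091871174892, pearson_n12_p = 2.2247149936104e-11)

g3 <- list(a = c(1, 2, 3, 4, 5), b = c(2, 3, 4, 5, 6),
           c = c(10, 11, 12, 13, 14))

test_that("two-group gate picks the t-test for normal data and matches the reference", {
  d <- compare_two_groups(c(1, 2, 3, 4, 5), c(6, 7, 8, 9, 10))
  expect_equal(unname(d$normality_p), rep(REF$shapiro_p_12345, 2),
               tolerance = 1e-8)
  expect_identical(d$chosen_test, "t_test")
  expect_equal(d$statistic, REF$t_stat, tolerance = 1e-8)
  expect_equal(d$p_value, REF$t_p, tolerance = 1e-8)
})

test_that("identical groups give p near 1 and skewed data force the rank branch", {
  d <- compare_two_groups(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(d$p_value, 0.99)
  set.seed(5)
  x <- rlnorm(30, sdlog = 1.5)
  y <- rnorm(30, mean = 2)
  expect_lt(shapiro.test(x)$p.value, 0.05)  # gate condition actually holds
  d2 <- compare_two_groups(x, y)
  expect_identical(d2$chosen_test, "mann_whitney")
  expect_error(compare_two_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("k-group Welch branch matches the reference to 1e-6", {
  d <- compare_k_groups(g3, posthoc_family = "games_howell")
  expect_identical(d$chosen_test, "welch_anova_games_howell")
  expect_equal(d$statistic, REF$welch_F, tolerance = 1e-6)
  expect_equal(d$p_value, REF$welch_p, tolerance = 1e-6)
  ph <- d$posthoc
  expect_equal(ph$p_value[match(names(REF$gh_p), ph$comparison)],
               unname(REF$gh_p), tolerance = 1e-6)
  expect_equal(ph$df, rep(8, 3), tolerance = 1e-9)
})

test_that("k-group classic branch runs ANOVA with Tukey", {
  d <- compare_k_groups(g3, posthoc_family = "tukey")
  expect_identical(d$chosen_test, "anova_tukey")
  ref <- summary(aov(y ~ g, data.frame(y = unlist(g3),
                                       g = rep(names(g3), each = 5))))[[1]]
  expect_equal(d$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(nrow(d$posthoc), 3)
})

test_that("three identical groups give F ~ 0 and p ~ 1", {
  d <- compare_k_groups(list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
                             c = c(1, 2, 3, 4, 5)))
  expect_equal(d$statistic, 0, tolerance = 1e-12)
  expect_gt(d$p_value, 0.99)
})

test_that("heteroscedastic groups fail Levene and route to Kruskal-Wallis", {
  a <- c(0.2, -1.1, 0.9, 1.5, -0.7, 0.3)
  b <- c(5, -12, 8, -9, 11, -3)
  cc <- c(0.5, -0.2, 1.1, -0.8, 0.4, 0)
  d <- compare_k_groups(list(a = a, b = b, c = cc))
  expect_equal(d$variance_homogeneity_p, REF$levene_het_p, tolerance = 1e-6)
  expect_identical(d$chosen_test, "kruskal_wallis")
  kw <- kruskal.test(list(a, b, cc))
  expect_equal(d$p_value, kw$p.value, tolerance = 1e-12)
  expect_error(compare_k_groups(list(a, b)), "k >= 3")
})

test_that("Levene statistic itself matches the reference implementation", {
  a <- c(0.2, -1.1, 0.9, 1.5, -0.7, 0.3)
  b <- c(5, -12, 8, -9, 11, -3)
  cc <- c(0.5, -0.2, 1.1, -0.8, 0.4, 0)
  lev <- car::leveneTest(c(a, b, cc),
                         factor(rep(c("a", "b", "c"), each = 6)),
                         center = mean)
  expect_equal(lev[["F value"]][1], REF$levene_het_F, tolerance = 1e-6)
})

test_that("gated correlation picks Pearson for normal pairs and matches scipy", {
  x <- c(10.2, 11.5, 9.8, 12.1, 10.9, 11.2, 9.5, 10, 11.8, 10.6, 11, 10.4)
  y <- c(20.1, 23.4, 19, 24.9, 21.5, 22.8, 18.7, 19.9, 23.9, 21, 22.3, 20.7)
  g <- gated_correlation(x, y)
  expect_identical(g$method, "pearson")
  expect_equal(g$estimate, REF$pearson_n12_r, tolerance = 1e-10)
  expect_equal(g$p_value, REF$pearson_n12_p, tolerance = 1e-6)
})

test_that("gated correlation handles exact monotone relationships", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  g <- gated_correlation(x, 2 * x + 1)
  expect_equal(g$estimate, 1)
  xs <- c(0.1, 0.2, 0.4, 1, 3, 9, 30, 100, 400, 2000)  # heavy-tailed
  g2 <- gated_correlation(xs, 1 / xs)
  expect_identical(g2$method, "spearman")
  expect_equal(g2$estimate, -1)
})

test_that("small-sample Wilcoxon is exact and matches brute-force enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_identical(w$method, "exact")
  expect_equal(w$U, 0)
  expect_equal(w$p_value, 0.1)  # 2 * 1/20

  # independent brute-force oracle over all C(6,3) value assignments
  x <- c(1.3, 2.7, 0.4); y <- c(3.1, 5.5, 2.9)
  vals <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  obs <- u_of(x, y)
  all_u <- apply(combn(6, 3), 2, function(idx)
    u_of(vals[idx], vals[-idx]))
  p_brute <- min(1, 2 * min(mean(all_u <= obs), mean(all_u >= obs)))
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, p_brute)
})

test_that("tied identical groups give the symmetric p = 1", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_identical(w$method, "normal_approx")  # ties disable exactness
  expect_equal(w$p_value, 1)
})

test_that("large-sample Wilcoxon matches the reference normal approximation", {
  set.seed(9)
  x <- rnorm(30); y <- rnorm(25, 0.7)
  w <- wilcoxon_rank_sum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-6)
  expect_equal(w$U, unname(ref$statistic))
  # with ties
  xt <- round(rnorm(30), 1); yt <- round(rnorm(25, 0.5), 1)
  wt <- wilcoxon_rank_sum(xt, yt)
  reft <- wilcox.test(xt, yt, exact = FALSE, correct = TRUE)
  expect_equal(wt$p_value, reft$p.value, tolerance = 1e-6)
})

test_that("exact and approximate Wilcoxon p agree at combined n = 10", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(5); y <- rnorm(5, runif(1, 0, 1))
    pe <- wilcoxon_rank_sum(x, y)$p_value
    pa <- wilcoxon_rank_sum(x, y, exact_max = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("the gate is deterministic: identical input, identical branch", {
  set.seed(13)
  x <- rlnorm(15); y <- rnorm(15)
  d1 <- compare_two_groups(x, y)
  d2 <- compare_two_groups(x, y)
  expect_identical(d1$chosen_test, d2$chosen_test)
  expect_identical(d1$p_value, d2$p_value)
})

test_that("rejection rate is monotone in the location shift", {
  set.seed(17)
  rates <- vapply(c(0, 0.5, 1), function(delta) {
    mean(vapply(1:300, function(i) {
      compare_two_groups(rnorm(20), rnorm(20, delta))$p_value < 0.05
    }, TRUE))
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_lt(rates[1], 0.12)
  expect_gt(rates[3], 0.7)
})
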