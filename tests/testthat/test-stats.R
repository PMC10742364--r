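test_that("the a-priori sample size reproduces the printed design and is monotone", {
  expect_identical(sample_size_oneway(0.5, 0.05, 0.8, 3), 42L)
  # monotonicity in effect size, alpha, power
  expect_lt(sample_size_oneway(1.0, 0.05, 0.8, 3),
            sample_size_oneway(0.5, 0.05, 0.8, 3))
  expect_lte(sample_size_oneway(0.5, 0.10, 0.8, 3),
             sample_size_oneway(0.5, 0.05, 0.8, 3))
  expect_gte(sample_size_oneway(0.5, 0.05, 0.95, 3),
             sample_size_oneway(0.5, 0.05, 0.8, 3))
  expect_error(sample_size_oneway(1e-4, 0.05, 0.8, 3), "1e6")
})

test_that("the returned N achieves the target power in simulation", {
  # one-way ANOVA, k = 3, f = 0.5: means (-d, 0, d) with d = 0.5 * sqrt(3/2)
  N <- sample_size_oneway(0.5, 0.05, 0.8, 3)
  n <- N / 3
  d <- 0.5 * sqrt(3 / 2)
  mu <- c(-d, 0, d)
  set.seed(2024)
  reps <- 20000
  rej <- logical(reps)
  g <- factor(rep(1:3, each = n))
  crit <- qf(0.95, 2, N - 3)
  for (r in seq_len(reps)) {
    y <- rnorm(N, mean = rep(mu, each = n))
    m <- tapply(y, g, mean)
    ssb <- n * sum((m - mean(y))^2)
    ssw <- sum((y - rep(m, each = n))^2)
    rej[r] <- (ssb / 2) / (ssw / (N - 3)) > crit
  }
  expect_gte(mean(rej), 0.8 - 0.02)
})

test_that("the Shapiro-Wilk gate flags capped data and passes normal data", {
  # capped penetration values: mass at the cap at n = 15 per group
  set.seed(101)
  capped <- lapply(1:3, function(i) pmin(7.18, rnorm(15, 6.5, 1.5)))
  names(capped) <- c("a", "b", "c")
  gate <- shapiro_gate(group_study(capped))
  expect_true(gate$nonparametric)

  # large standard-normal samples keep the flag down in >= 90% of seeds
  flags <- vapply(1:100, function(s) {
    set.seed(s)
    shapiro_gate(group_study(list(g1 = rnorm(5000))))$nonparametric
  }, logical(1))
  expect_gte(mean(!flags), 0.9)

  # zero-variance group: warned, treated as non-normal
  expect_warning(
    gate0 <- shapiro_gate(group_study(list(a = rep(7.18, 5), b = rnorm(5)))),
    "zero-variance")
  expect_true(gate0$nonparametric)
  expect_true(is.na(gate0$p_values[["a"]]))

  expect_error(shapiro_gate(group_study(list(a = c(1, 2), b = rnorm(5)))),
               "at least 3")
})

test_that("Kruskal-Wallis reproduces the hand-computed fixture and degenerate cases", {
  kw <- kruskal_wallis(group_study(list(a = 1:3, b = 4:6, c = 7:9)))
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2L)

  # relabeling groups leaves H unchanged
  kw2 <- kruskal_wallis(group_study(list(z = 7:9, y = 1:3, x = 4:6)))
  expect_equal(kw2$statistic, kw$statistic)

  # identical groups
  kw3 <- kruskal_wallis(group_study(list(a = c(2, 2, 2), b = c(2, 2, 2))))
  expect_equal(kw3$statistic, 0)
  expect_equal(kw3$p_value, 1)

  expect_error(kruskal_wallis(group_study(list(a = 1:9))), "2 groups")
  expect_error(kruskal_wallis(group_study(list(a = 1:2, b = 1:2))), "N >= 5")
})

test_that("Dunn-Bonferroni matches a direct-formula oracle on a printed fixture", {
  g <- list(a = c(1.1, 2.3, 3.5, 2.2),
            b = c(2.3, 4.1, 5.0, 3.3),
            c = c(7.7, 8.2, 6.5, 9.9))
  out <- dunn_bonferroni(group_study(g))

  # independent oracle: explicit rank bookkeeping, scalar arithmetic
  all_v <- c(g$a, g$b, g$c)
  rk <- rank(all_v)
  N <- length(all_v)
  ties <- as.numeric(table(all_v))
  sigma2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- c(mean(rk[1:4]), mean(rk[5:8]), mean(rk[9:12]))
  oracle <- function(i, j) {
    z <- (mean_rank[i] - mean_rank[j]) / sqrt(sigma2 * (1 / 4 + 1 / 4))
    min(1, 3 * 2 * pnorm(-abs(z)))
  }
  expect_equal(out$p_adjusted[out$group1 == "a" & out$group2 == "b"],
               oracle(1, 2), tolerance = 1e-12)
  expect_equal(out$p_adjusted[out$group1 == "a" & out$group2 == "c"],
               oracle(1, 3), tolerance = 1e-12)
  expect_equal(out$p_adjusted[out$group1 == "b" & out$group2 == "c"],
               oracle(2, 3), tolerance = 1e-12)

  expect_true(all(out$p_adjusted >= out$p_raw))
})

test_that("Dunn z^2 agrees with the Kruskal-Wallis H for two tie-free groups", {
  set.seed(5)
  g <- list(a = rnorm(8), b = rnorm(9, 1))
  z <- dunn_bonferroni(group_study(g))$z
  H <- kruskal_wallis(group_study(g))$statistic
  expect_equal(z^2, H, tolerance = 1e-10)
})

test_that("two identical groups among three give adjusted p = 1 for that pair", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(9, 10, 11, 12))
  out <- dunn_bonferroni(group_study(g))
  expect_equal(out$p_adjusted[out$group1 == "a" & out$group2 == "b"], 1)
})

test_that("group summaries use the sample standard deviation and carry counts", {
  gs <- group_study(list(a = c(7.18, 7.18), b = c(1, 2, 3)),
                    delaminated_counts = c(a = 2L, b = 0L),
                    complete_penetration_counts = c(a = 2L, b = 0L))
  s <- summarize_groups(gs)
  expect_equal(s$mean[s$group == "a"], 7.18)
  expect_equal(s$sd[s$group == "a"], 0)
  expect_equal(s$mean[s$group == "b"], 2)
  expect_equal(s$sd[s$group == "b"], 1)
  expect_equal(s$delaminated[s$group == "a"], 2L)
  expect_equal(s$n, c(2L, 3L))
})

test_that("Dunn-Bonferroni controls the family-wise error under the complete null", {
  set.seed(77)
  fwe <- vapply(1:10000, function(r) {
    gs <- group_study(list(a = rnorm(15), b = rnorm(15), c = rnorm(15)))
    any(dunn_bonferroni(gs)$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(fwe), 0.06)
})
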