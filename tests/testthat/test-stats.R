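test_that("summary-based Welch tests agree with t.test on exact samples", {
  # identical summaries: no evidence of a difference
  same <- welch_t_summary(3, 1, 10, 3, 1, 10)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # degenerate zero-variance groups
  expect_equal(welch_t_summary(2, 0, 5, 2, 0, 5)$p_value, 1)

  # simulate_from_summary matches the requested moments exactly, so the
  # raw-data Welch test is an independent oracle for the summary formula
  set.seed(11)
  for (i in 1:5) {
    s <- data.frame(group = c("a", "b"),
                    mean = stats::runif(2, 0, 5),
                    sd = stats::runif(2, 0.2, 2),
                    n = sample(5:40, 2))
    d <- simulate_from_summary(s, seed = i)
    ref <- t.test(value ~ group, data = d)
    got <- welch_t_summary(s$mean[1], s$sd[1], s$n[1],
                           s$mean[2], s$sd[2], s$n[2])
    expect_equal(abs(got$statistic), abs(unname(ref$statistic)),
                 tolerance = 1e-6)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-6)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("the published shoot-length gain of the optimized medium is
           significant at the study's threshold", {
  v <- kiwi_validation()
  sl <- v[v$response == "SL" & v$medium %in% c("R", "MS"), ]
  res <- welch_t_summary(sl$mean[1], sl$sd[1], sl$n[1],
                         sl$mean[2], sl$sd[2], sl$n[2])
  expect_lt(res$p_value, 0.001)
  expect_gt(res$statistic, 0)
})

test_that("Tukey letters separate groups exactly when they should", {
  set.seed(21)
  vals <- c(stats::rnorm(20, 0), stats::rnorm(20, 0.05))
  grp <- rep(c("a", "b"), each = 20)
  same <- anova_tukey(vals, grp, alpha = 0.001)
  expect_equal(unname(same$letters["a"]), unname(same$letters["b"]))

  vals2 <- c(stats::rnorm(20, 0, 0.3), stats::rnorm(20, 10, 0.3))
  far <- anova_tukey(vals2, grp, alpha = 0.001)
  expect_false(any(strsplit(far$letters[["a"]], "")[[1]] %in%
                     strsplit(far$letters[["b"]], "")[[1]]))
  expect_error(anova_tukey(stats::rnorm(5), rep("a", 5)), "2 groups")
})

test_that("letter displays from the validation summaries reproduce the
           published shoot-length ordering", {
  v <- kiwi_validation()
  sl <- v[v$response == "SL", ]
  hits <- 0
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    d <- simulate_from_summary(sl, seed = s)
    res <- anova_tukey(d$value, d$group, alpha = 0.001)
    L <- strsplit(res$letters, "")
    shares <- function(a, b) any(L[[a]] %in% L[[b]])
    # St > R > {MS, B5}: St and R separated, R above both standards, and
    # MS/B5 not distinguishable from each other
    if (!shares("St", "R") && !shares("R", "MS") && !shares("R", "B5") &&
        shares("MS", "B5")) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("Kruskal-Wallis matches a brute-force rank computation", {
  expect_equal(kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), 3))$statistic,
               0)
  expect_equal(kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), 3))$p_value, 1)

  vals <- c(1.2, 3.4, 2.2, 5.1, 4.4, 6.0, 0.7, 8.8, 7.3)
  grp <- rep(c("a", "b", "c"), each = 3)
  got <- kruskal_wallis(vals, grp)
  # brute force: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2, no ties here
  r <- rank(vals)
  N <- length(vals)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, grp, function(x) length(x) * (mean(x) - (N + 1) / 2)^2))
  expect_equal(got$statistic, H, tolerance = 1e-12)
  expect_equal(got$df, 2)

  # shifting one group away from the others never decreases H
  H1 <- kruskal_wallis(c(1, 2, 3, 4, 10, 11, 12, 13), rep(c("a", "b"), each = 4))
  H2 <- kruskal_wallis(c(1, 2, 3, 4, 110, 111, 112, 113), rep(c("a", "b"), each = 4))
  expect_gte(H2$statistic, H1$statistic)
})

test_that("group-comparison p-values agree with a permutation oracle", {
  set.seed(31)
  vals <- c(stats::rnorm(8, 0), stats::rnorm(8, 1.2))
  grp <- rep(c("a", "b"), each = 8)
  kw_p <- kruskal_wallis(vals, grp)$p_value
  # permutation distribution of the H statistic
  perm <- replicate(2000, {
    kruskal_wallis(vals, sample(grp))$statistic
  })
  p_perm <- mean(perm >= kruskal_wallis(vals, grp)$statistic - 1e-12)
  expect_lt(abs(kw_p - p_perm), 0.05)
})
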