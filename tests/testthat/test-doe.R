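test_that("candidate grids are full factorials with endpoints", {
  f2 <- data.frame(factor = c("a", "b"), low = c(0, 1), high = c(1, 3))
  g <- candidate_grid(f2, points_per_factor = 3)
  expect_equal(nrow(g), 9L)
  expect_setequal(unique(g$a), c(0, 0.5, 1))
  expect_setequal(unique(g$b), c(1, 2, 3))
  expect_equal(nrow(candidate_grid(points_per_factor = 5)), 5L^5)
  g5 <- candidate_grid(points_per_factor = 4)
  fs <- factor_space()
  for (i in seq_len(nrow(fs))) {
    expect_true(all(c(fs$low[i], fs$high[i]) %in% g5[[fs$factor[i]]]))
  }
  expect_error(candidate_grid(points_per_factor = 50, max_candidates = 100),
               "max_candidates")
})

test_that("exchange search finds the exhaustive optimum on a toy problem", {
  f2 <- data.frame(factor = c("a", "b"), low = c(-1, -1), high = c(1, 1))
  cand <- candidate_grid(f2, points_per_factor = 3)
  des <- d_optimal(cand, "linear", n_runs = 4, seed = 7, factors = f2)
  # brute-force oracle: best det(X'X) over all 4-subsets of the 9 candidates
  best_ld <- -Inf
  for (idx in utils::combn(9, 4, simplify = FALSE)) {
    Fm <- design_model_matrix(cand[idx, ], "linear", f2)
    d <- det(crossprod(Fm))
    if (d > best_ld) best_ld <- d
  }
  Fd <- design_model_matrix(des$runs[, c("a", "b")], "linear", f2)
  expect_equal(det(crossprod(Fd)), best_ld, tolerance = 1e-9)
  # which is the 2^2 full factorial at 100% D-efficiency
  expect_equal(d_efficiency(des$runs[, c("a", "b")], "linear", f2), 100,
               tolerance = 1e-9)
  expect_true(all(abs(des$runs$a) == 1) && all(abs(des$runs$b) == 1))
})

test_that("the exchange determinant trace never decreases", {
  cand <- candidate_grid(points_per_factor = 3)
  des <- d_optimal(cand, "quadratic", n_runs = 25, seed = 3)
  expect_true(all(diff(des$log_det_trace) >= -1e-9))
})

test_that("D-efficiency detects degenerate designs", {
  f2 <- data.frame(factor = c("a", "b"), low = c(-1, -1), high = c(1, 1))
  fact <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  eff_f <- d_efficiency(fact, "linear", f2)
  dup <- fact[c(1, 2, 3, 3), ]   # duplicated corner instead of the fourth
  expect_lt(d_efficiency(dup, "linear", f2), eff_f)
  one_point <- fact[c(1, 1, 1, 1), ]
  expect_warning(e0 <- d_efficiency(one_point, "linear", f2),
                 "rank-deficient")
  expect_equal(e0, 0)
})

test_that("augmentation appends exact replicates and flagged controls", {
  runs <- data.frame(a = c(0.3, 0.8), b = c(1.5, 2.5))
  expect_equal(augment_design(runs)[, c("a", "b")], runs)
  aug <- augment_design(runs, replicate_runs = 2, n_controls = 3,
                        control_point = c(a = 1, b = 1))
  expect_equal(nrow(aug), 6L)
  expect_equal(aug[3, c("a", "b")], runs[2, c("a", "b")],
               ignore_attr = TRUE)
  expect_equal(aug$replicate_of, c(NA, NA, 2L, NA, NA, NA))
  expect_equal(aug$is_control, c(rep(FALSE, 3), rep(TRUE, 3)))
})

test_that("the study-shaped generator matches the published layout", {
  des <- study_design(seed = 11, points_per_factor = 3)
  runs <- des$runs
  expect_equal(nrow(runs), 36L)
  expect_equal(sum(runs$is_control), 3L)
  expect_equal(sum(!is.na(runs$replicate_of)), 3L)
  # controls are the base medium and replicate rows copy their source
  ctrl <- runs[runs$is_control, names(factor_groups())]
  expect_true(all(ctrl == 1))
  for (i in which(!is.na(runs$replicate_of))) {
    expect_equal(runs[i, names(factor_groups())],
                 runs[runs$replicate_of[i], names(factor_groups())],
                 ignore_attr = TRUE)
  }
  # all levels inside the declared bounds
  fs <- factor_space()
  for (k in seq_len(nrow(fs))) {
    expect_true(all(runs[[fs$factor[k]]] >= fs$low[k] - 1e-9))
    expect_true(all(runs[[fs$factor[k]]] <= fs$high[k] + 1e-9))
  }
})

test_that("the optimized design beats random designs of equal size", {
  cand <- candidate_grid(points_per_factor = 3)
  des <- d_optimal(cand, "quadratic", n_runs = 33, seed = 5)
  eff <- d_efficiency(des)
  set.seed(99)
  rand_eff <- replicate(50, {
    idx <- sample(nrow(cand), 33)
    suppressWarnings(d_efficiency(cand[idx, ]))
  })
  expect_true(all(eff >= rand_eff))
})
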