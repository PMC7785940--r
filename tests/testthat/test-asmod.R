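toy_partitions <- function(densities) {
  stats::setNames(lapply(seq_along(densities), function(i) {
    fuzzy_partition(0, 1, densities[i])
  }), names(densities))
}

test_that("tensor bases hit the expected corner and midpoint values", {
  X <- matrix(c(0, 0.5, 1), ncol = 1, dimnames = list(NULL, "a"))
  B <- submodel_basis(X, "a", toy_partitions(c(a = 2)))
  expect_equal(unname(B[1, ]), c(1, 0))
  expect_equal(unname(B[2, ]), c(0.5, 0.5))
  expect_equal(unname(B[3, ]), c(0, 1))

  X2 <- matrix(c(0.5, 0.5), ncol = 2, dimnames = list(NULL, c("a", "b")))
  B2 <- submodel_basis(X2, c("a", "b"), toy_partitions(c(a = 2, b = 2)))
  expect_equal(unname(B2[1, ]), rep(0.25, 4))

  # partition of unity carries through the tensor product
  set.seed(8)
  Xr <- matrix(stats::runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Br <- submodel_basis(Xr, c("a", "b", "c"),
                       toy_partitions(c(a = 2, b = 3, c = 2)))
  expect_equal(rowSums(Br), rep(1, 20), tolerance = 1e-12)
})

test_that("ridge fitting behaves like penalized least squares", {
  set.seed(1)
  B <- cbind(1, matrix(stats::rnorm(40), 20, 2))
  # constant response -> constant predictions whatever the basis
  beta_c <- ridge_fit(B, rep(3, 20), 1e-6)
  expect_equal(drop(B %*% beta_c), rep(3, 20), tolerance = 1e-4)
  # with independent columns and vanishing ridge this is ordinary LS
  y <- stats::rnorm(20)
  expect_equal(ridge_fit(B, y, 1e-10),
               unname(coef(lm(y ~ B - 1))), tolerance = 1e-5)
  # coefficient norm shrinks monotonically in the ridge factor
  norms <- sapply(c(1e-6, 1e-2, 1, 100), function(r)
    sum(ridge_fit(B, y, r)^2))
  expect_true(all(diff(norms) < 0))
})

test_that("the SRM score penalizes capacity and rejects saturated models", {
  expect_equal(srm_score(0, 5, 34), 0)
  # strictly increasing in p at fixed mse, and in mse at fixed p
  scores_p <- sapply(1:16, function(p) srm_score(1, p, 34))
  expect_true(all(diff(scores_p) > 0))
  expect_lt(srm_score(0.5, 4, 34), srm_score(1.0, 4, 34))
  expect_identical(srm_score(1, 34, 34), Inf)
  # matches an independent re-derivation of the documented formula
  n <- 34; p <- 4; C1 <- 0.868; C2 <- 4.8
  eps <- (p * (log(2 * n / p) + 1) - log(1 - C1)) / (C2 * n)
  expect_equal(srm_score(1.0, p, n, C1, C2), 1 / (1 - sqrt(eps)),
               tolerance = 1e-12)
})

test_that("train R-squared follows its defining identity", {
  expect_equal(train_r2(c(1, 2, 3), c(1, 2, 3)), 100)
  y <- c(4, 7, 1, 3)
  expect_equal(train_r2(y, rep(mean(y), 4)), 0)
  # SSE 1 against SST 2
  expect_equal(train_r2(c(1, 2, 3), c(1, 2, 4)), 50)
  expect_error(train_r2(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("model ANOVA reproduces the published critical values", {
  # the published f-critical column equals the F quantile at alpha = 0.001
  # under the df1 = model, df2 = total convention
  published <- data.frame(df1 = c(16, 9, 5, 11, 7),
                          fc = c(3.558, 4.255, 5.382, 3.975, 4.675))
  for (i in seq_len(nrow(published))) {
    av <- model_anova(y = c(stats::rnorm(33), 0), yhat = rep(0.5, 34),
                      df1 = published$df1[i], df2 = 33, alpha = 0.001)
    expect_equal(av$f_critical, published$fc[i], tolerance = 0.01)
  }
  # the ratio follows the R2 identity F = R2/(1-R2) * (df2-df1)/df1
  set.seed(2)
  y <- stats::rnorm(34)
  yhat <- y + stats::rnorm(34, 0, 0.4)
  av <- model_anova(y, yhat, df1 = 11, df2 = 33)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(av$f_ratio,
               sum((yhat - mean(y))^2) / 11 / (sum((y - yhat)^2) / 22))
  expect_identical(av$pass, av$f_ratio > av$f_critical)
  expect_error(model_anova(y, yhat, df1 = 10, df2 = 10), "df")
})

test_that("a single-input truth is recovered and nothing else", {
  X <- study_ion_table()
  set.seed(5)
  # noise-free spline of potassium alone
  part <- fuzzy_partition(min(X[, "K"]), max(X[, "K"]), 3)
  y <- drop(membership(part, X[, "K"]) %*% c(2, 7, 4))
  m <- asmod_fit(X, y)
  expect_equal(sort(unique(unlist(lapply(m$submodels, `[[`, "ions")))), "K")
  expect_gt(train_r2(y, m$fitted), 99.9)
  # deterministic: identical refit
  m2 <- asmod_fit(X, y)
  expect_identical(m$trace, m2$trace)
})

test_that("fitted study models stay within the structural limits", {
  models <- study_nf_models()
  for (m in models) {
    for (s in m$submodels) {
      expect_lte(length(s$ions), 4L)
      expect_true(all(s$densities %in% c(2L, 3L)))
    }
    expect_lte(model_df(m), 16L)
    # predictions on training data reproduce the stored fitted values
    expect_equal(predict(m, study_ion_table()), m$fitted, tolerance = 1e-9)
  }
})

test_that("prediction clamps out-of-domain inputs with a warning", {
  X <- study_ion_table()
  m <- study_nf_models()$SL
  Xout <- X[1:2, , drop = FALSE]
  Xout[1, "K"] <- max(X[, "K"]) * 10
  expect_warning(p <- predict(m, Xout), "clamped")
  Xedge <- X[1:2, , drop = FALSE]
  Xedge[1, "K"] <- max(X[, "K"])
  expect_equal(p, suppressWarnings(predict(m, Xedge)), tolerance = 1e-9)
})

test_that("rule membership degrees match the cell-normalization oracle", {
  X <- study_ion_table()
  # a linear increasing univariate surface gives the two canonical rules
  part <- fuzzy_partition(min(X[, "Na"]), max(X[, "Na"]), 2)
  y <- drop(membership(part, X[, "Na"]) %*% c(1, 5))
  m <- asmod_fit(X, y, output = "toy")
  r <- extract_rules(m)
  r_na <- r[!is.na(r$Na), ]
  expect_equal(r_na$consequent[r_na$Na == "Low"], "Low")
  expect_equal(r_na$consequent[r_na$Na == "High"], "High")
  expect_equal(r_na$MD, c(1, 1), tolerance = 1e-9)

  # every rule of the study models agrees with a brute-force recomputation
  for (m in study_nf_models()) {
    rules <- extract_rules(m)
    expect_true(all(rules$MD >= 0 & rules$MD <= 1))
    for (k in seq_along(m$submodels)) {
      s <- m$submodels[[k]]
      cells <- s$coef
      sc <- (cells - min(cells)) / (max(cells) - min(cells))
      expected_md <- ifelse(sc >= 0.5, sc, 1 - sc)
      got <- rules$MD[rules$submodel == k]
      expect_equal(unname(sort(got)), unname(sort(expected_md)),
                   tolerance = 1e-9)
    }
  }
})

test_that("dominance range reports cover each used ion and tile domains", {
  m <- study_nf_models()$H
  dr <- dominance_ranges(m)
  used <- unique(unlist(lapply(m$submodels, `[[`, "ions")))
  expect_setequal(unique(dr$ion), used)
  for (ion in used) {
    sub <- dr[dr$ion == ion, ]
    expect_equal(sub$lo[1], min(study_ion_table()[, ion]))
    expect_equal(sub$hi[nrow(sub)], max(study_ion_table()[, ion]))
    if (nrow(sub) > 1) expect_equal(sub$lo[-1], sub$hi[-nrow(sub)])
  }
})
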