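#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom
#' computed directly from group means, SDs and sizes, so printed
#' mean +/- SD tables can be tested without the raw data.
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    return(list(statistic = 0, df = n1 + n2 - 2,
                p_value = as.numeric(mean1 == mean2) * 1 +
                  (mean1 != mean2) * 0))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

# compact letter display by insert-and-absorb on a logical "differs" matrix
letter_display <- function(groups, differs) {
  k <- length(groups)
  cols <- list(rep(TRUE, k))    # start with one letter containing everyone
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      if (!differs[i, j]) next
      for (ci in seq_along(cols)) {
        if (cols[[ci]][i] && cols[[ci]][j]) {
          new1 <- cols[[ci]]; new1[j] <- FALSE
          new2 <- cols[[ci]]; new2[i] <- FALSE
          cols[[ci]] <- new1
          dup <- any(vapply(cols, function(cc)
            all(cc == new2), logical(1)))
          if (!dup) cols[[length(cols) + 1]] <- new2
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && keep[a] && keep[b] &&
              all(cols[[a]] <= cols[[b]]) && any(cols[[a]] < cols[[b]])) {
            keep[a] <- FALSE
          }
        }
      }
      cols <- cols[keep]
    }
  }
  ltr <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  stats::setNames(ltr, groups)
}

#' One-way ANOVA with Tukey HSD letters
#'
#' Fits `stats::aov` and runs `stats::TukeyHSD` at the supplied
#' family-wise level, then summarizes the pairwise results as a compact
#' letter display (groups sharing a letter are not significantly
#' different). The default level follows the validation analysis of the
#' study (alpha = 0.001).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param alpha Family-wise significance level.
#' @return List with `f_value`, `df`, `p_value`, `tukey` (the pairwise
#'   table) and `letters`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.001) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  stopifnot(all(table(groups) >= 2))
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  lv <- levels(groups)
  differs <- matrix(FALSE, length(lv), length(lv),
                    dimnames = list(lv, lv))
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pair)) {
    a <- pair[[i]][1]
    b <- pair[[i]][2]
    differs[a, b] <- differs[b, a] <- tk[i, "p adj"] < alpha
  }
  # order letters by decreasing group mean, as printed tables do
  mns <- tapply(values, groups, mean)
  ord <- order(mns, decreasing = TRUE)
  ltr <- letter_display(lv[ord], differs[ord, ord, drop = FALSE])[lv]
  list(f_value = an$`F value`[1], df = an$Df,
       p_value = an$`Pr(>F)`[1], tukey = tk, letters = ltr)
}

#' Kruskal-Wallis rank test
#'
#' Thin wrapper over `stats::kruskal.test` (tie-corrected H statistic with
#' a chi-square p value); all-tied data degenerate to H = 0, p = 1.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(unique(values)) == 1) {
    return(list(statistic = 0, df = nlevels(groups) - 1, p_value = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Simulate raw samples from printed group summaries
#'
#' Draws normal samples with the given mean/SD per group, then re-centers
#' and re-scales each group so its sample mean and SD match the summary
#' exactly. Useful for letter-display checks against tables that print
#' only mean +/- SD.
#'
#' @param summaries Data frame with columns `medium` (or `group`), `mean`,
#'   `sd`, `n`.
#' @param seed Integer seed.
#' @return Data frame with columns `group` and `value`.
#' @export
simulate_from_summary <- function(summaries, seed = 1) {
  g <- if ("medium" %in% names(summaries)) summaries$medium else
    summaries$group
  set.seed(seed)
  out <- lapply(seq_len(nrow(summaries)), function(i) {
    x <- stats::rnorm(summaries$n[i])
    if (summaries$sd[i] > 0 && stats::sd(x) > 0) {
      x <- (x - mean(x)) / stats::sd(x) * summaries$sd[i] + summaries$mean[i]
    } else {
      x <- rep(summaries$mean[i], summaries$n[i])
    }
    data.frame(group = g[i], value = x)
  })
  do.call(rbind, out)
}
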