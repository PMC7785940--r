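#' Candidate point grid for design search
#'
#' Full-factorial grid over each factor's `[low, high]` range, uniformly
#' spaced and including the endpoints.
#'
#' @param factors Data frame with columns `factor`, `low`, `high`
#'   (default the study's five-factor space).
#' @param points_per_factor Grid points per factor (>= 2).
#' @param max_candidates Explicit cap on the grid size.
#' @return Data frame of candidate runs, one column per factor.
#' @export
candidate_grid <- function(factors = factor_space(), points_per_factor = 5,
                           max_candidates = 1e5) {
  stopifnot(points_per_factor >= 2)
  if (points_per_factor ^ nrow(factors) > max_candidates) {
    stop("candidate grid larger than max_candidates (",
         points_per_factor ^ nrow(factors), " > ", max_candidates, ")")
  }
  grid <- expand.grid(lapply(seq_len(nrow(factors)), function(i) {
    seq(factors$low[i], factors$high[i], length.out = points_per_factor)
  }), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- factors$factor
  grid
}

# code factor levels to [-1, 1] using the factor bounds
code_levels <- function(X, factors) {
  X <- as.matrix(X[, factors$factor, drop = FALSE])
  lo <- matrix(factors$low, nrow(X), ncol(X), byrow = TRUE)
  hi <- matrix(factors$high, nrow(X), ncol(X), byrow = TRUE)
  2 * (X - lo) / (hi - lo) - 1
}

#' Model matrix for a design
#'
#' Expands coded `[-1, 1]` factor levels into the regression model matrix
#' for a first-order, two-factor-interaction, or full quadratic model.
#'
#' @param design Data frame/matrix of factor levels (multiplier units).
#' @param model_order `"linear"`, `"interaction"`, or `"quadratic"`.
#' @param factors Factor bounds used for coding.
#' @return Numeric model matrix including the intercept column.
#' @export
design_model_matrix <- function(design, model_order = "quadratic",
                                factors = factor_space()) {
  Z <- code_levels(as.data.frame(design), factors)
  k <- ncol(Z)
  cols <- list(`(Intercept)` = rep(1, nrow(Z)))
  for (i in seq_len(k)) cols[[factors$factor[i]]] <- Z[, i]
  if (model_order %in% c("interaction", "quadratic")) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        cols[[paste0(factors$factor[i], ":", factors$factor[j])]] <-
          Z[, i] * Z[, j]
      }
    }
  }
  if (model_order == "quadratic") {
    for (i in seq_len(k)) {
      cols[[paste0(factors$factor[i], "^2")]] <- Z[, i]^2
    }
  }
  do.call(cbind, cols)
}

#' D-optimal design by Fedorov exchange
#'
#' Seeds a random `n_runs`-point design from the candidate set and then
#' repeatedly exchanges a design point for a candidate whenever the swap
#' increases `det(X'X)` of the model matrix, scanning design points in row
#' order and candidates in index order and taking the first improving
#' exchange (deterministic given the seed). The determinant never
#' decreases across accepted exchanges.
#'
#' @param candidates Candidate runs, as from [candidate_grid()].
#' @param model_order Model whose coefficients the design should estimate.
#' @param n_runs Number of runs (>= number of model terms).
#' @param seed Integer seed for the random start.
#' @param factors Factor bounds (coding + range checks).
#' @param max_passes Cap on full exchange passes.
#' @param n_starts Random starts; the best final design is kept.
#' @return List of class `pm_design`: `runs` (data frame),
#'   `log_det_trace`, `model_order`, plus empty `replicate_of`/`is_control`
#'   columns for [augment_design()] to fill.
#' @export
d_optimal <- function(candidates, model_order = "quadratic", n_runs,
                      seed = 1, factors = factor_space(),
                      max_passes = 50, n_starts = 3) {
  F_all <- design_model_matrix(candidates, model_order, factors)
  p <- ncol(F_all)
  if (n_runs < p) stop("n_runs (", n_runs, ") < model terms (", p, ")")
  set.seed(seed)
  best <- NULL
  for (st in seq_len(n_starts)) {
    idx <- NULL
    for (try in 1:25) {
      cand_idx <- sample(nrow(F_all), n_runs, replace = n_runs > nrow(F_all))
      if (qr(F_all[cand_idx, , drop = FALSE])$rank == p) {
        idx <- cand_idx
        break
      }
    }
    if (is.null(idx)) stop("could not find a non-singular starting design")
    X <- F_all[idx, , drop = FALSE]
    Minv <- solve(crossprod(X) + diag(1e-10, p))
    ld <- determinant(crossprod(X), logarithm = TRUE)$modulus
    trace <- as.numeric(ld)
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (i in seq_len(n_runs)) {
        xi <- X[i, ]
        di <- drop(xi %*% Minv %*% xi)
        V <- F_all %*% Minv            # n_cand x p
        dj <- rowSums(V * F_all)
        dij <- drop(V %*% xi)
        delta <- dj - di - (di * dj - dij^2)
        j <- which(delta > 1e-9)
        if (length(j) == 0) next
        j <- j[1]                       # first improvement in index order
        X[i, ] <- F_all[j, ]
        idx[i] <- j
        M <- crossprod(X)
        Minv <- solve(M + diag(1e-10, p))
        trace <- c(trace,
                   as.numeric(determinant(M, logarithm = TRUE)$modulus))
        improved <- TRUE
      }
      if (!improved) break
    }
    ld_final <- trace[length(trace)]
    if (is.null(best) || ld_final > best$ld) {
      best <- list(idx = idx, trace = trace, ld = ld_final)
    }
  }
  runs <- as.data.frame(candidates[best$idx, , drop = FALSE])
  rownames(runs) <- NULL
  runs$replicate_of <- NA_integer_
  runs$is_control <- FALSE
  structure(list(runs = runs, log_det_trace = best$trace,
                 model_order = model_order, factors = factors),
            class = "pm_design")
}

#' @export
print.pm_design <- function(x, ...) {
  cat(sprintf("<pm_design> %d runs, %s model, log det(X'X) = %.3f\n",
              nrow(x$runs), x$model_order,
              x$log_det_trace[length(x$log_det_trace)]))
  invisible(x)
}

#' D-efficiency of a design (percent)
#'
#' `100 * det(X'X)^(1/p) / n` on coded `[-1, 1]` factors: an orthogonal
#' two-level factorial of a first-order model scores 100.
#'
#' @param design A `pm_design` or data frame of factor levels.
#' @param model_order Model for the efficiency computation.
#' @param factors Factor bounds for coding.
#' @return Efficiency in percent; 0 (with a warning) when the model matrix
#'   is rank deficient.
#' @export
d_efficiency <- function(design, model_order = "quadratic",
                         factors = factor_space()) {
  runs <- if (inherits(design, "pm_design")) design$runs else design
  Fm <- design_model_matrix(runs, model_order, factors)
  p <- ncol(Fm)
  if (qr(Fm)$rank < p) {
    warning("rank-deficient model matrix; D-efficiency 0")
    return(0)
  }
  ld <- as.numeric(determinant(crossprod(Fm), logarithm = TRUE)$modulus)
  100 * exp(ld / p) / nrow(Fm)
}

#' Append replicate and control runs to a design
#'
#' Replicates are exact copies of existing runs (tagged via
#' `replicate_of`); control rows carry `is_control = TRUE`.
#'
#' @param design A `pm_design` or data frame of runs.
#' @param replicate_runs Integer indices of runs to copy once each.
#' @param n_controls Number of control rows to append.
#' @param control_point Named factor levels of the control medium
#'   (default all 1, i.e. the base medium).
#' @return Object of the same kind with the appended rows.
#' @export
augment_design <- function(design, replicate_runs = integer(),
                           n_controls = 0,
                           control_point = NULL) {
  is_obj <- inherits(design, "pm_design")
  runs <- if (is_obj) design$runs else design
  fcols <- setdiff(names(runs), c("replicate_of", "is_control"))
  if (is.null(runs$replicate_of)) runs$replicate_of <- NA_integer_
  if (is.null(runs$is_control)) runs$is_control <- FALSE
  for (r in replicate_runs) {
    stopifnot(r >= 1, r <= nrow(runs))
    new <- runs[r, , drop = FALSE]
    new$replicate_of <- as.integer(r)
    runs <- rbind(runs, new)
  }
  if (n_controls > 0) {
    if (is.null(control_point)) {
      control_point <- stats::setNames(rep(1, length(fcols)), fcols)
    }
    ctrl <- as.data.frame(as.list(control_point[fcols]))
    names(ctrl) <- fcols
    ctrl$replicate_of <- NA_integer_
    ctrl$is_control <- TRUE
    runs <- rbind(runs, ctrl[rep(1, n_controls), , drop = FALSE])
  }
  rownames(runs) <- NULL
  if (is_obj) {
    design$runs <- runs
    design
  } else {
    runs
  }
}

#' Generate the study-shaped design
#'
#' Convenience wrapper reproducing the study configuration: a quadratic
#' model over the five factors, 30 distinct D-optimal runs plus 3
#' within-design replicate pairs (33 runs) and 3 base-medium controls
#' (36 rows).
#'
#' @param seed Seed for the exchange search and replicate choice.
#' @param points_per_factor Candidate grid resolution.
#' @return A `pm_design` with 36 rows.
#' @export
study_design <- function(seed = 1, points_per_factor = 5) {
  cand <- candidate_grid(points_per_factor = points_per_factor)
  des <- d_optimal(cand, "quadratic", n_runs = 30, seed = seed)
  set.seed(seed + 1)
  reps <- sample(nrow(des$runs), 3)
  augment_design(des, replicate_runs = reps, n_controls = 3)
}
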