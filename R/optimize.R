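#' Desirability specification for medium optimization
#'
#' One-sided maximize ramps per response: desirability is 0 at or below the
#' lower anchor, 1 at or above the target, linear between. Weights follow
#' the study's importance scale (0-10). The defaults are the published
#' optimization goals: shoot quality SQ > 4.00 (weight 10), shoot number
#' SN > 4.4 (9), shoot length SL > 1.6 cm (8), leaf area LA > 28 cm^2 (7);
#' quality scores BC and H are not part of the objective.
#'
#' @param targets Named vector of target values (d = 1 at/above).
#' @param lower_anchors Named vector of values at/below which d = 0;
#'   default each response's training minimum must be supplied by the
#'   caller.
#' @param weights Named vector of non-negative importance weights.
#' @return List of class `desirability_spec`.
#' @export
desirability_spec <- function(targets = c(SQ = 4.00, SN = 4.4, SL = 1.6,
                                          LA = 28),
                              lower_anchors,
                              weights = c(SQ = 10, SN = 9, SL = 8, LA = 7)) {
  stopifnot(setequal(names(targets), names(weights)),
            setequal(names(targets), names(lower_anchors)),
            all(weights >= 0), any(weights > 0))
  la <- lower_anchors[names(targets)]
  if (any(la >= targets)) stop("lower_anchor must be below target")
  structure(list(targets = targets, lower_anchors = la,
                 weights = weights[names(targets)]),
            class = "desirability_spec")
}

#' Partial (one-sided) desirability
#'
#' @param yhat Predicted response value(s).
#' @param lower_anchor Value at/below which desirability is 0.
#' @param target Value at/above which desirability is 1.
#' @return Desirability in `[0, 1]`.
#' @export
partial_desirability <- function(yhat, lower_anchor, target) {
  stopifnot(lower_anchor < target)
  pmin(1, pmax(0, (yhat - lower_anchor) / (target - lower_anchor)))
}

#' Overall desirability (weighted geometric mean)
#'
#' Derringer-Suich aggregation `prod(d_i ^ (w_i / sum(w)))`; any response
#' at zero desirability vetoes the candidate. The percentage of agreement
#' with the desired values is `100 * D`.
#'
#' @param d Vector of partial desirabilities.
#' @param weights Non-negative weights, at least one positive.
#' @return Overall desirability in `[0, 1]`.
#' @export
overall_desirability <- function(d, weights) {
  stopifnot(length(d) == length(weights), all(weights >= 0),
            any(weights > 0), all(d >= 0), all(d <= 1))
  if (any(d == 0 & weights > 0)) return(0)
  w <- weights / sum(weights)
  exp(sum(w[weights > 0] * log(d[weights > 0])))
}

#' Genetic algorithm configuration
#'
#' Real-coded GA defaults: population 100, 200 generations, tournament
#' selection of size 3, blend crossover with rate 0.9, bounded Gaussian
#' mutation with rate 0.1 and step 10 percent of each gene's range,
#' elitism 2.
#'
#' @param population,generations,crossover_rate,mutation_rate,elitism,seed
#'   GA settings.
#' @param tournament Tournament size.
#' @param mutation_sd_frac Mutation SD as a fraction of the gene range.
#' @param blend_alpha Blend-crossover expansion factor.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population = 100, generations = 200,
                      crossover_rate = 0.9, mutation_rate = 0.1,
                      elitism = 2, seed = 1, tournament = 3,
                      mutation_sd_frac = 0.1, blend_alpha = 0.5) {
  stopifnot(population >= 10, elitism >= 1)
  structure(as.list(environment()), class = "ga_config")
}

# generic bounded real-coded GA maximizer; fitness takes a matrix of rows
ga_maximize <- function(fitness, lower, upper, config) {
  stopifnot(all(is.finite(lower)), all(is.finite(upper)), all(lower < upper))
  k <- length(lower)
  set.seed(config$seed)
  pop <- matrix(stats::runif(config$population * k), ncol = k)
  pop <- sweep(sweep(pop, 2, upper - lower, "*"), 2, lower, "+")
  fit <- fitness(pop)
  best_trace <- numeric(config$generations)
  for (gen in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[ord[seq_len(config$elitism)], , drop = FALSE]
    # tournament selection
    pick <- function() {
      ids <- sample.int(config$population, config$tournament)
      ids[which.max(fit[ids])]
    }
    children <- matrix(NA_real_, config$population - config$elitism, k)
    i <- 1
    while (i <= nrow(children)) {
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      if (stats::runif(1) < config$crossover_rate) {
        a <- config$blend_alpha
        u <- stats::runif(k, -a, 1 + a)
        c1 <- p1 + u * (p2 - p1)
        c2 <- p2 + u * (p1 - p2)
      } else {
        c1 <- p1
        c2 <- p2
      }
      children[i, ] <- c1
      if (i + 1 <= nrow(children)) children[i + 1, ] <- c2
      i <- i + 2
    }
    mut <- matrix(stats::runif(length(children)) < config$mutation_rate,
                  nrow(children), k)
    noise <- matrix(stats::rnorm(length(children), 0,
                                 rep(config$mutation_sd_frac * (upper - lower),
                                     each = nrow(children))),
                    nrow(children), k)
    children <- children + mut * noise
    children <- pmin(pmax(children, matrix(lower, nrow(children), k,
                                           byrow = TRUE)),
                     matrix(upper, nrow(children), k, byrow = TRUE))
    pop <- rbind(elite, children)
    fit <- fitness(pop)
    best_trace[gen] <- max(fit)
  }
  b <- which.max(fit)
  list(par = pop[b, ], value = fit[b], trace = cummax(best_trace))
}

#' Optimize the medium with a desirability-weighted GA
#'
#' Searches the five factor levels (preserving the salt groupings, so
#' candidate media stay inside the sampled design space), predicts each
#' weighted response with its trained model from the implied 14-salt
#' recipe, and maximizes the overall desirability. A free-salt mode
#' searching all 14 salt concentrations independently is available but off
#' by default, since the models were trained only on group-scaled
#' compositions.
#'
#' @param models Named list of per-response models covering every weighted
#'   response: anything with a `predict` method over the salt matrix, or a
#'   plain function of the salt matrix.
#' @param spec A [desirability_spec()].
#' @param config A [ga_config()].
#' @param base Base recipe scaled by the factor levels.
#' @param factors Factor bounds (gene bounds).
#' @param free_salts If `TRUE`, genes are the 14 salt concentrations
#'   bounded by the factor-scaled ranges instead of the 5 factor levels.
#' @return List of class `optimization_result`: best factor levels, salt
#'   recipe, ion profile, per-response predictions and desirabilities,
#'   overall desirability, agreement percent, and the best-fitness trace.
#' @export
ga_optimize <- function(models, spec, config = ga_config(),
                        base = ms_recipe(), factors = factor_space(),
                        free_salts = FALSE) {
  resp <- names(spec$targets)
  missing_models <- setdiff(resp, names(models))
  if (length(missing_models) > 0) {
    stop("no model for weighted output(s): ",
         paste(missing_models, collapse = ", "))
  }
  groups <- factor_groups()
  salt_names <- names(base$concentrations)
  if (free_salts) {
    fac_of_salt <- rep(NA_character_, length(salt_names))
    for (f in names(groups)) fac_of_salt[salt_names %in% groups[[f]]] <- f
    lo <- base$concentrations *
      factors$low[match(fac_of_salt, factors$factor)]
    hi <- base$concentrations *
      factors$high[match(fac_of_salt, factors$factor)]
    to_salts <- function(P) P
  } else {
    lo <- factors$low
    hi <- factors$high
    to_salts <- function(P) {
      colnames(P) <- factors$factor
      design_to_salt_table(P, base, groups)
    }
  }
  model_predict <- function(model, S) {
    if (is.function(model)) model(S) else suppressWarnings(predict(model, S))
  }
  fitness <- function(P) {
    S <- to_salts(P)
    preds <- vapply(resp, function(r) {
      model_predict(models[[r]], S)
    }, numeric(nrow(S)))
    if (nrow(S) == 1) preds <- matrix(preds, nrow = 1,
                                      dimnames = list(NULL, resp))
    apply(preds, 1, function(yh) {
      d <- partial_desirability(yh, spec$lower_anchors, spec$targets)
      overall_desirability(d, spec$weights)
    })
  }
  res <- ga_maximize(fitness, lo, hi, config)
  if (free_salts) {
    recipe <- medium_recipe(stats::setNames(res$par, salt_names),
                            label = "optimized")
    levels <- NULL
  } else {
    levels <- stats::setNames(res$par, factors$factor)
    recipe <- factors_to_recipe(levels, base, groups, warn_range = FALSE)
    recipe$label <- "optimized"
  }
  S <- matrix(recipe$concentrations, nrow = 1,
              dimnames = list(NULL, salt_names))
  preds <- vapply(resp, function(r) {
    model_predict(models[[r]], S)
  }, numeric(1))
  d <- partial_desirability(preds, spec$lower_anchors, spec$targets)
  structure(list(levels = levels, recipe = recipe,
                 ions = recipe_to_ions(recipe),
                 predictions = preds, desirabilities = d,
                 overall = res$value, agreement = 100 * res$value,
                 trace = res$trace, spec = spec),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> agreement %.1f%%\n", x$agreement))
  if (!is.null(x$levels)) print(round(x$levels, 3))
  print(round(x$predictions, 2))
  invisible(x)
}

#' Compare an optimized medium with the reference media
#'
#' @param result An [ga_optimize()] result.
#' @param media Named list of reference [medium_recipe()]s (default the
#'   bundled standards).
#' @return List with `salts` (mg/L, media as columns) and `ions` (mM)
#'   comparison data frames.
#' @export
result_report <- function(result, media = standard_media()) {
  media <- c(list(optimized = result$recipe), media)
  all_salts <- unique(unlist(lapply(media, function(m)
    names(m$concentrations))))
  salts <- sapply(media, function(m) {
    m$concentrations[all_salts]
  })
  rownames(salts) <- all_salts
  salts[is.na(salts)] <- 0
  ions <- sapply(media, recipe_to_ions)
  list(salts = as.data.frame(salts), ions = as.data.frame(ions),
       predictions = result$predictions)
}
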