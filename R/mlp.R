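#' Multilayer perceptron training configuration
#'
#' One hidden layer of 2-4 sigmoid nodes with a linear output, trained by
#' resilient backpropagation (RPROP) on min-max scaled data. Stopping
#' follows a "smart stop" rule: the blended criterion
#' `(1 - w) * train MSE + w * test MSE` must improve within a patience
#' window (after a minimum number of iterations), with additional stops at
#' a target training MSE and an iteration cap. `auto_weight` and
#' `interaction_overshoot` are accepted for configuration compatibility
#' but are inert.
#'
#' @param hidden_nodes Candidate hidden layer sizes.
#' @param eta_plus,eta_minus RPROP step-size growth/shrink factors.
#' @param delta0,delta_min,delta_max Initial and bounding step sizes.
#' @param max_iterations Training iteration cap.
#' @param target_mse Training MSE at which training stops.
#' @param min_iterations Iterations before smart stop may fire.
#' @param test_error_weighting Weight of the test MSE in the blended
#'   stopping criterion.
#' @param train_fraction Fraction of rows used for training.
#' @param seed Seed for the split and the weight initialization.
#' @param patience Iterations without blended-criterion improvement before
#'   stopping.
#' @param n_restarts Seeded weight re-initializations per architecture in
#'   [select_architecture()]; the restart with the lowest test MSE wins.
#' @param auto_weight,interaction_overshoot Inert compatibility fields.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden_nodes = 2:4, eta_plus = 1.2, eta_minus = 0.5,
                       delta0 = 0.1, delta_min = 1e-6, delta_max = 50,
                       max_iterations = 1000, target_mse = 1e-4,
                       min_iterations = 20, test_error_weighting = 0.1,
                       train_fraction = 0.8, seed = 10000, patience = 50,
                       n_restarts = 20,
                       auto_weight = TRUE, interaction_overshoot = 200) {
  stopifnot(all(hidden_nodes >= 1), train_fraction > 0, train_fraction < 1)
  structure(as.list(environment()), class = "mlp_config")
}

#' Random train/test split
#'
#' Deterministic shuffle given the seed; the train set takes
#' `floor(fraction * n)` rows, the test set the remainder (27/7 at the
#' study's n = 34).
#'
#' @param X Input matrix.
#' @param y Response vector.
#' @param fraction Training fraction.
#' @param seed Integer seed.
#' @return List with `X_train`, `y_train`, `X_test`, `y_test`,
#'   `train_idx`, `test_idx`.
#' @export
split_data <- function(X, y, fraction = 0.8, seed = 10000) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 rows to split")
  stopifnot(length(y) == n)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(fraction * n)
  tr <- sort(perm[seq_len(n_train)])
  te <- sort(perm[-seq_len(n_train)])
  list(X_train = X[tr, , drop = FALSE], y_train = y[tr],
       X_test = X[te, , drop = FALSE], y_test = y[te],
       train_idx = tr, test_idx = te)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

minmax_scaler <- function(M) {
  lo <- apply(M, 2, min)
  hi <- apply(M, 2, max)
  hi[hi <= lo] <- lo[hi <= lo] + 1   # constant columns map to 0
  list(lo = lo, hi = hi)
}

apply_scaler <- function(M, sc, clamp = FALSE) {
  Z <- sweep(sweep(M, 2, sc$lo), 2, sc$hi - sc$lo, "/")
  if (clamp) Z <- pmin(pmax(Z, 0), 1)
  Z
}

mlp_forward <- function(w, Z) {
  H <- sigmoid(sweep(Z %*% w$W1, 2, w$b1, "+"))
  list(H = H, yhat = drop(H %*% w$W2) + w$b2)
}

mlp_gradient <- function(w, Z, t) {
  fw <- mlp_forward(w, Z)
  n <- nrow(Z)
  err <- fw$yhat - t                     # d(MSE)/d(yhat) * n/2
  dW2 <- crossprod(fw$H, err) * 2 / n
  db2 <- mean(err) * 2
  dH <- (err %o% drop(w$W2)) * fw$H * (1 - fw$H)
  dW1 <- crossprod(Z, dH) * 2 / n
  db1 <- colMeans(dH) * 2
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       mse = mean((fw$yhat - t)^2))
}

#' Train a multilayer perceptron with RPROP
#'
#' Full-batch resilient backpropagation on `[0, 1]`-scaled inputs and
#' response. When a test set is supplied the run is monitored with the
#' blended smart-stop criterion and the returned weights are those of the
#' best blended iteration; otherwise training error alone is monitored.
#' With a fixed seed the whole path is reproducible bit for bit.
#'
#' @param X,y Training inputs/response (unscaled).
#' @param config An [mlp_config()]; `hidden_nodes` may be a scalar here.
#' @param X_test,y_test Optional monitoring set.
#' @param hidden Hidden layer size (default first of
#'   `config$hidden_nodes`).
#' @return Object of class `mlp_model`: weights, scalers, per-iteration
#'   train/test error history, and the stopping iteration.
#' @export
train_mlp <- function(X, y, config = mlp_config(), X_test = NULL,
                      y_test = NULL, hidden = config$hidden_nodes[1]) {
  X <- as.matrix(X)
  sx <- minmax_scaler(X)
  sy <- minmax_scaler(matrix(y, ncol = 1))
  Z <- apply_scaler(X, sx)
  t <- drop(apply_scaler(matrix(y, ncol = 1), sy))
  has_test <- !is.null(X_test)
  if (has_test) {
    Zt <- apply_scaler(as.matrix(X_test), sx, clamp = TRUE)
    tt <- drop(apply_scaler(matrix(y_test, ncol = 1), sy, clamp = TRUE))
  }
  k <- ncol(X)
  set.seed(config$seed + hidden)
  w <- list(W1 = matrix(stats::runif(k * hidden, -0.5, 0.5), k, hidden),
            b1 = stats::runif(hidden, -0.5, 0.5),
            W2 = matrix(stats::runif(hidden, -0.5, 0.5), hidden, 1),
            b2 = stats::runif(1, -0.5, 0.5))
  delta <- lapply(w, function(m) m * 0 + config$delta0)
  prev_g <- lapply(w, function(m) m * 0)
  wbl <- config$test_error_weighting
  hist <- matrix(NA_real_, config$max_iterations, 3,
                 dimnames = list(NULL, c("train", "test", "blended")))
  best <- list(crit = Inf, w = w, iter = 0)
  stall <- 0
  for (it in seq_len(config$max_iterations)) {
    g <- mlp_gradient(w, Z, t)
    for (nm in names(w)) {
      s <- sign(g[[nm]]) * sign(prev_g[[nm]])
      delta[[nm]] <- pmin(pmax(
        delta[[nm]] * ifelse(s > 0, config$eta_plus,
                             ifelse(s < 0, config$eta_minus, 1)),
        config$delta_min), config$delta_max)
      gz <- g[[nm]]
      gz[s < 0] <- 0                     # RPROP-: skip update after sign flip
      w[[nm]] <- w[[nm]] - sign(gz) * delta[[nm]]
      prev_g[[nm]] <- gz
    }
    train_mse <- mean((mlp_forward(w, Z)$yhat - t)^2)
    test_mse <- if (has_test) mean((mlp_forward(w, Zt)$yhat - tt)^2) else NA
    crit <- if (has_test) (1 - wbl) * train_mse + wbl * test_mse else train_mse
    hist[it, ] <- c(train_mse, test_mse, crit)
    if (crit < best$crit - 1e-12) {
      best <- list(crit = crit, w = w, iter = it)
      stall <- 0
    } else {
      stall <- stall + 1
    }
    if (train_mse <= config$target_mse && it >= config$min_iterations) break
    if (it >= config$min_iterations && stall >= config$patience) break
  }
  hist <- hist[seq_len(it), , drop = FALSE]
  fitted_s <- unname(mlp_forward(best$w, Z)$yhat)
  structure(list(weights = best$w, hidden = hidden, x_scaler = sx,
                 y_scaler = sy, history = as.data.frame(hist),
                 stop_iter = best$iter, n_iter = it,
                 fitted = unname(sy$lo + fitted_s * (sy$hi - sy$lo)),
                 config = config),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %d-%d-1, stopped at iter %d (of %d run)\n",
              nrow(x$weights$W1), x$hidden, x$stop_iter, x$n_iter))
  invisible(x)
}

#' Predict from a trained MLP
#'
#' @param object An `mlp_model`.
#' @param newdata Input matrix with the training columns; inputs outside
#'   the training hull are clamped to it with a warning.
#' @param ... Unused.
#' @return Predictions on the original response scale.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$weights$W1)) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         nrow(object$weights$W1))
  }
  Z <- apply_scaler(newdata, object$x_scaler)
  if (any(Z < -1e-9 | Z > 1 + 1e-9)) {
    warning("inputs outside the training hull; clamped")
    Z <- pmin(pmax(Z, 0), 1)
  }
  sy <- object$y_scaler
  unname(drop(sy$lo + mlp_forward(object$weights, Z)$yhat *
                (sy$hi - sy$lo)))
}

#' Select the hidden-layer size by test error
#'
#' Splits the data (80/20 by default), trains networks over every
#' candidate hidden size and seeded weight restart, and keeps the one with
#' the lowest test MSE; train and test R-squared are reported for the
#' winner.
#'
#' @param X,y Full data set.
#' @param config An [mlp_config()].
#' @return The winning `mlp_model`, with `split`, `train_r2`, `test_r2`,
#'   `test_mse` and the per-candidate summary attached.
#' @export
select_architecture <- function(X, y, config = mlp_config()) {
  sp <- split_data(X, y, config$train_fraction, config$seed)
  grid <- expand.grid(hidden = config$hidden_nodes,
                      restart = seq_len(max(1, config$n_restarts)) - 1)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 97 * grid$restart[i]
    train_mlp(sp$X_train, sp$y_train, cfg, sp$X_test, sp$y_test,
              hidden = grid$hidden[i])
  })
  test_mse <- vapply(fits, function(f) {
    mean((suppressWarnings(predict(f, sp$X_test)) - sp$y_test)^2)
  }, numeric(1))
  best <- fits[[which.min(test_mse)]]
  best$split <- sp
  best$train_r2 <- train_r2(sp$y_train, predict(best, sp$X_train))
  best$test_r2 <- train_r2(sp$y_test,
                           suppressWarnings(predict(best, sp$X_test)))
  best$test_mse <- min(test_mse)
  best$architectures <- data.frame(grid, test_mse = test_mse)
  best
}
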