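# Hybrid ANFIS learning: exact least squares for the linear consequents,
# batch gradient descent for the Gaussian premise parameters, with an
# adaptive step-length schedule and validation checkpointing.

#' Hybrid-training hyperparameters
#'
#' @param epochs number of premise gradient epochs (>= 0; 0 fits the
#'   consequents once and stops).
#' @param initial_step starting gradient step length.
#' @param step_increase factor (> 1) applied after four consecutive
#'   decreases of the training error.
#' @param step_decrease factor in (0, 1) applied after two consecutive
#'   up-down oscillations of the training error.
#' @param seed RNG seed recorded in the model provenance (training itself
#'   is deterministic).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, initial_step = 0.01,
                         step_increase = 1.1, step_decrease = 0.9,
                         seed = 1L) {
  if (epochs < 0) stopf("epochs must be >= 0")
  if (!(initial_step > 0)) stopf("initial_step must be positive")
  if (!(step_increase > 1)) stopf("step_increase must exceed 1")
  if (!(step_decrease > 0 && step_decrease < 1)) {
    stopf("step_decrease must lie in (0, 1)")
  }
  structure(list(epochs = as.integer(epochs), initial_step = initial_step,
                 step_increase = step_increase, step_decrease = step_decrease,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Global least-squares solve of all rule consequents
#'
#' With the premise parameters held fixed, the crisp output is linear in the
#' consequent coefficients: `y = sum_c wbar_c (p_c . x + r_c)` with
#' normalized firing strengths `wbar_c = w_c / sum w`. All `R * 7`
#' coefficients are therefore solved simultaneously by one linear
#' least-squares problem (minimum-norm solution when rank-deficient), which
#' can never increase the training SSE relative to any other coefficient
#' setting.
#'
#' @param model a `fis_model`.
#' @param x normalized training predictor matrix.
#' @param y numeric targets (class codes 1-4, fitted regression-style).
#' @return the model with refitted consequents.
#' @export
lse_consequents <- function(model, x, y) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stopf("need at least one training row")
  W <- rule_firing(model, x)
  Wbar <- W / rowSums(W)
  R <- n_rules(model)
  constant <- isTRUE(model$meta$constant_consequents)
  if (constant) {
    theta <- minnorm_lstsq(Wbar, y)
    model$consequents[] <- 0
    model$consequents[, ncol(model$consequents)] <- theta
  } else {
    p <- ncol(x) + 1
    A <- matrix(0, nrow(x), R * p)
    for (c in seq_len(R)) {
      A[, (c - 1) * p + seq_len(p)] <- Wbar[, c] * cbind(x, 1)
    }
    theta <- minnorm_lstsq(A, y)
    model$consequents <- matrix(theta, R, p, byrow = TRUE)
  }
  model
}

# Analytic gradient of SSE = sum_i (yhat_i - y_i)^2 with respect to every
# premise center and sigma. Returns list(centers, sigmas) of R x 6 matrices.
premise_gradients <- function(model, x, y) {
  X <- as.matrix(x)
  n <- nrow(X)
  R <- n_rules(model)
  W <- rule_firing(model, X)
  S <- rowSums(W)
  # rows where every firing strength underflowed carry no usable gradient
  dead <- S == 0
  S[dead] <- 1
  F <- consequent_values(model, X)
  yhat <- rowSums(W * F) / S
  err <- ifelse(dead, 0, yhat - y)
  gc <- matrix(0, R, ncol(X))
  gs <- matrix(0, R, ncol(X))
  # dSSE/dw_c = sum_i 2 e_i (F_ic - yhat_i) / S_i; chain through the
  # Gaussian: dw/dmu = w (x - mu) / sigma^2, dw/dsigma = w (x - mu)^2 / sigma^3
  common <- 2 * err * (F - yhat) / S * W # n x R
  for (c in seq_len(R)) {
    Z <- X - matrix(model$centers[c, ], n, ncol(X), byrow = TRUE)
    sig <- matrix(model$sigmas[c, ], n, ncol(X), byrow = TRUE)
    gc[c, ] <- colSums(common[, c] * Z / sig^2)
    gs[c, ] <- colSums(common[, c] * Z^2 / sig^3)
  }
  list(centers = gc, sigmas = gs)
}

#' One batch gradient step on the premise parameters
#'
#' Moves every membership center and width a distance `step` along the
#' negative normalized gradient of the training SSE (the step length, not a
#' raw learning rate, is what the adaptive schedule rescales). Widths are
#' clamped to at least 1e-6.
#'
#' @param model a `fis_model`.
#' @param x normalized training predictor matrix.
#' @param y numeric targets.
#' @param step step length (>= 0; 0 leaves the model unchanged).
#' @return the updated model.
#' @export
premise_gradient_step <- function(model, x, y, step) {
  if (step < 0) stopf("step must be nonnegative")
  if (step == 0) return(model)
  g <- premise_gradients(model, x, y)
  nrm <- sqrt(sum(g$centers^2) + sum(g$sigmas^2))
  if (nrm == 0) return(model)
  model$centers <- model$centers - step * g$centers / nrm
  model$sigmas <- pmax(model$sigmas - step * g$sigmas / nrm, SIGMA_FLOOR)
  model
}

rmse <- function(model, x, y) {
  if (length(y) == 0) return(NA_real_)
  sqrt(mean((evaluate_fis(model, as.matrix(x)) - y)^2))
}

#' Hybrid ANFIS training with validation checkpointing
#'
#' Per epoch: solve the consequents exactly ([lse_consequents()]), record
#' train/validation RMSE, then take one premise gradient step. The step
#' length grows by `step_increase` after four consecutive training-error
#' decreases and shrinks by `step_decrease` after two consecutive up-down
#' oscillations. The returned model is the recorded epoch with minimum
#' validation RMSE (first occurrence on ties); without a validation set the
#' last epoch wins. Fixed data implies a bit-identical history: training is
#' fully deterministic.
#'
#' @param model an initial `fis_model` (from [build_fis()]).
#' @param x,y normalized training predictors and targets.
#' @param xval,yval optional validation predictors and targets.
#' @param config a [train_config()].
#' @return list with `model` (best checkpoint) and `history` (data frame:
#'   epoch, train_rmse, val_rmse, step; attribute `best_epoch`).
#' @export
train_anfis <- function(model, x, y, xval = NULL, yval = NULL,
                        config = train_config()) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stopf("empty training set")
  has_val <- !is.null(xval) && length(yval) > 0
  if (has_val) xval <- as.matrix(xval)
  step <- config$initial_step
  hist <- data.frame(epoch = integer(0), train_rmse = numeric(0),
                     val_rmse = numeric(0), step = numeric(0))
  best <- list(model = NULL, crit = Inf, epoch = NA_integer_)
  dec_run <- 0L
  last_diffs <- numeric(0)
  for (e in 0:config$epochs) {
    model <- lse_consequents(model, x, y)
    tr <- rmse(model, x, y)
    vl <- if (has_val) rmse(model, xval, yval) else NA_real_
    hist <- rbind(hist, data.frame(epoch = e, train_rmse = tr,
                                   val_rmse = vl, step = step))
    crit <- if (has_val) vl else -e # no validation: keep the last epoch
    if (crit < best$crit) {
      best <- list(model = model, crit = crit, epoch = e)
    }
    if (e == config$epochs) break
    model <- premise_gradient_step(model, x, y, step)
    # adaptive step-length schedule on the training-error trace
    ne <- nrow(hist)
    if (ne >= 2) {
      d <- hist$train_rmse[ne] - hist$train_rmse[ne - 1]
      dec_run <- if (d < 0) dec_run + 1L else 0L
      last_diffs <- utils::tail(c(last_diffs, d), 4)
      s <- sign(last_diffs)
      if (dec_run >= 4L) {
        step <- step * config$step_increase
        dec_run <- 0L
      } else if (length(s) == 4 && all(s != 0) &&
                 all(s[-1] * s[-length(s)] < 0)) {
        step <- step * config$step_decrease
        last_diffs <- numeric(0)
      }
    }
  }
  out_model <- best$model
  out_model$meta$epochs_trained <- config$epochs
  out_model$meta$best_epoch <- best$epoch
  attr(hist, "best_epoch") <- best$epoch
  list(model = out_model, history = hist)
}

#' Write a training history as CSV
#'
#' @param history the `history` element of [train_anfis()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
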