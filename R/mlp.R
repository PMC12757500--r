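# Feed-forward binary classifier trained with class-weighted
# cross-entropy, L2 (ridge) regularization and Adam, with early stopping
# on a validation split. Written as plain matrix code so the training
# protocol (weighting, oversampling, early stopping, seeding) is fully
# explicit and deterministic.

#' Hyperparameter bundle for the progression MLP
#'
#' Defaults follow the study protocol: two hidden layers of 64 and 32
#' rectified-linear units with a sigmoid output; binary cross-entropy with
#' a positive-class weight of 3; L2 penalty 0.001; Adam with learning rate
#' 0.001 and canonical momentum constants (0.9, 0.999); mini-batches of
#' 32; at most 100 epochs with early stopping after 10 epochs without
#' validation-loss improvement (best weights restored); a 20% validation
#' carve-out of each training portion; duplication oversampling factor 2
#' for the minority class; seed 42.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param l2_penalty L2 coefficient on weights (not biases).
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment constants.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs), must be < `max_epochs`.
#' @param validation_fraction Fraction of the training portion carved out
#'   for early-stopping monitoring.
#' @param class_weight Loss weight on the positive (progression) class.
#' @param oversample_factor Duplication factor for minority-class rows.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return An object of class `ckd_mlp_config`.
#' @export
mlp_config <- function(hidden_sizes = c(64, 32), l2_penalty = 0.001,
                       learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                       epsilon = 1e-8, batch_size = 32, max_epochs = 100,
                       patience = 10, validation_fraction = 0.2,
                       class_weight = 3, oversample_factor = 2, seed = 42) {
  stopifnot(all(hidden_sizes >= 1), l2_penalty >= 0, learning_rate > 0,
            batch_size >= 1, max_epochs >= 1, patience >= 1,
            validation_fraction > 0, validation_fraction < 1,
            class_weight > 0, oversample_factor >= 1)
  if (patience >= max_epochs) stop("patience must be smaller than max_epochs")
  structure(
    list(hidden_sizes = as.integer(hidden_sizes), l2_penalty = l2_penalty,
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         validation_fraction = validation_fraction, class_weight = class_weight,
         oversample_factor = as.integer(oversample_factor),
         seed = as.integer(seed)),
    class = "ckd_mlp_config"
  )
}

init_params_ <- function(sizes) {
  # Glorot-uniform weights, zero biases
  params <- list()
  for (l in seq_len(length(sizes) - 1)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1]
    lim <- sqrt(6 / (fan_in + fan_out))
    params[[paste0("W", l)]] <- matrix(runif(fan_in * fan_out, -lim, lim),
                                       fan_in, fan_out)
    params[[paste0("b", l)]] <- numeric(fan_out)
  }
  params
}

forward_ <- function(params, x, n_layers) {
  acts <- vector("list", n_layers + 1)
  pre <- vector("list", n_layers)
  acts[[1]] <- x
  for (l in seq_len(n_layers)) {
    z <- acts[[l]] %*% params[[paste0("W", l)]]
    z <- sweep(z, 2, params[[paste0("b", l)]], "+")
    pre[[l]] <- z
    acts[[l + 1]] <- if (l < n_layers) pmax(z, 0) else plogis(z)
  }
  list(acts = acts, pre = pre)
}

bce_ <- function(p, y, w = NULL, eps = 1e-7) {
  p <- pmin(1 - eps, pmax(eps, p))
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(w)) mean(ll) else mean(w * ll)
}

#' Train the progression MLP
#'
#' Minimizes class-weighted binary cross-entropy plus
#' `l2_penalty * sum(W^2)` by Adam over shuffled mini-batches. When a
#' validation set is supplied, training stops once the (unweighted)
#' validation cross-entropy has not improved for `patience` consecutive
#' epochs and the best-epoch weights are restored. Fully deterministic
#' given the data and `config$seed`; exact floating-point reproducibility
#' assumes single-threaded BLAS.
#'
#' @param x Numeric feature matrix (no missing values), columns named.
#' @param y Binary outcome vector; both classes must be present.
#' @param config An [mlp_config()].
#' @param x_val,y_val Optional validation set for early stopping; without
#'   it the model trains for `max_epochs` epochs.
#' @return An object of class `ckd_mlp` holding layer weights, the config,
#'   training metadata (`epochs_run`, `best_val_loss`) and a logit
#'   recalibration shift `recal_delta` (0 until set, see
#'   [recalibrate_model()]).
#' @export
train_mlp <- function(x, y, config = mlp_config(), x_val = NULL, y_val = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (length(unique(y)) < 2) stop("labels contain a single class")
  n <- nrow(x)
  sizes <- c(ncol(x), config$hidden_sizes, 1L)
  n_layers <- length(sizes) - 1
  w_obs <- ifelse(y == 1, config$class_weight, 1)

  with_seed_(config$seed, {
    params <- init_params_(sizes)
    m <- lapply(params, function(p) p * 0)
    v <- lapply(params, function(p) p * 0)
    step <- 0L
    best <- list(loss = Inf, params = params, epoch = 0L)
    stale <- 0L
    epochs_run <- 0L

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        yb <- y[idx]
        wb <- w_obs[idx]
        nb <- length(idx)
        fw <- forward_(params, xb, n_layers)
        p <- fw$acts[[n_layers + 1]]
        if (anyNA(p)) stop("NaN encountered in forward pass (diverged)")
        # gradient of mean weighted BCE wrt output pre-activation
        delta <- matrix(wb * (as.vector(p) - yb) / nb, nb, 1)
        grads <- list()
        for (l in rev(seq_len(n_layers))) {
          Wn <- paste0("W", l); bn <- paste0("b", l)
          grads[[Wn]] <- crossprod(fw$acts[[l]], delta) +
            2 * config$l2_penalty * params[[Wn]]
          grads[[bn]] <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(params[[Wn]])) * (fw$pre[[l - 1]] > 0)
          }
        }
        step <- step + 1L
        lr_t <- config$learning_rate *
          sqrt(1 - config$beta2^step) / (1 - config$beta1^step)
        for (nm in names(params)) {
          m[[nm]] <- config$beta1 * m[[nm]] + (1 - config$beta1) * grads[[nm]]
          v[[nm]] <- config$beta2 * v[[nm]] + (1 - config$beta2) * grads[[nm]]^2
          params[[nm]] <- params[[nm]] - lr_t * m[[nm]] / (sqrt(v[[nm]]) + config$epsilon)
        }
      }
      epochs_run <- epoch
      if (!is.null(x_val)) {
        pv <- forward_(params, as.matrix(x_val), n_layers)$acts[[n_layers + 1]]
        vloss <- bce_(as.vector(pv), as.numeric(y_val))
        if (!is.finite(vloss)) stop("validation loss is not finite (diverged)")
        if (vloss < best$loss - 1e-9) {
          best <- list(loss = vloss, params = params, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= config$patience) break
        }
      }
    }
    if (!is.null(x_val)) params <- best$params
    structure(
      list(params = params, sizes = sizes,
           feature_names = colnames(x), config = config,
           epochs_run = epochs_run,
           best_val_loss = if (is.null(x_val)) NA_real_ else best$loss,
           best_epoch = if (is.null(x_val)) NA_integer_ else best$epoch,
           recal_slope = 1, recal_delta = 0),
      class = "ckd_mlp"
    )
  })
}

#' Predict progression risk
#'
#' Forward pass through a fitted MLP; probabilities in (0, 1). Batch-size
#' invariant: scoring rows one at a time equals scoring them together. Any
#' stored logit recalibration shift (`recal_delta`) is applied.
#'
#' @param model A fitted `ckd_mlp`.
#' @param x Feature matrix whose columns match the training schema.
#' @return Vector of predicted probabilities, named by `x` row names.
#' @export
predict_risk <- function(model, x) {
  stopifnot(inherits(model, "ckd_mlp"))
  x <- as.matrix(x)
  if (is.null(colnames(x)) || !identical(colnames(x), model$feature_names)) {
    stop("feature columns do not match the training schema")
  }
  n_layers <- length(model$sizes) - 1
  p <- as.vector(forward_(model$params, x, n_layers)$acts[[n_layers + 1]])
  slope <- model$recal_slope %||% 1
  if (model$recal_delta != 0 || slope != 1) {
    eps <- 1e-12
    p <- plogis(slope * qlogis(pmin(1 - eps, pmax(eps, p))) + model$recal_delta)
  }
  names(p) <- rownames(x)
  p
}

#' Recalibrate a fitted model to the probability scale of its population
#'
#' Two-step logit-linear (Platt-type) recalibration, fit strictly inside
#' the training fold. First, a calibration slope is estimated by logistic
#' regression of the validation-carve-out outcomes on the raw prediction
#' logits (the carve-out is untouched by gradient updates, so it reflects
#' out-of-sample overconfidence). Second, a constant logit shift is solved
#' (via [calibrate_intercept()]) so the slope-adjusted mean predicted risk
#' over the full (un-oversampled, unweighted) training portion equals that
#' portion's event rate, undoing the systematic upward shift induced by
#' the class-weighted loss and duplication oversampling.
#'
#' @param model A fitted `ckd_mlp`.
#' @param x Training-portion feature matrix.
#' @param target_rate Observed event rate of the same rows.
#' @param x_val,y_val Validation carve-out for the slope step; omitted
#'   (`NULL`) leaves the slope at 1 (intercept-only recalibration).
#' @return The model with `recal_slope` and `recal_delta` set.
#' @export
recalibrate_model <- function(model, x, target_rate,
                              x_val = NULL, y_val = NULL) {
  base <- model
  base$recal_delta <- 0
  base$recal_slope <- 1
  eps <- 1e-12
  clamp_logit <- function(p) qlogis(pmin(1 - eps, pmax(eps, p)))
  slope <- 1
  if (!is.null(x_val)) {
    lp_val <- clamp_logit(predict_risk(base, x_val))
    slope <- tryCatch({
      fit <- glm(as.integer(y_val) ~ lp_val, family = binomial(),
                 control = glm.control(epsilon = 1e-8, maxit = 100))
      s <- unname(coef(fit)[2])
      if (is.finite(s) && s > 0.1 && s < 10) s else 1
    }, error = function(e) 1)
  }
  lp <- slope * clamp_logit(predict_risk(base, x))
  model$recal_slope <- slope
  model$recal_delta <- calibrate_intercept(target_rate, lp)
  model
}

#' Serialize / restore a fitted MLP as JSON
#'
#' Writes layer shapes and row-major weight vectors (full double
#' precision) plus the config and recalibration shift, so a model can be
#' reloaded with numerically identical predictions.
#'
#' @param model A fitted `ckd_mlp`.
#' @param path JSON file path.
#' @return `save_model_json()` returns `path` invisibly;
#'   `load_model_json()` returns the model.
#' @export
save_model_json <- function(model, path) {
  stopifnot(inherits(model, "ckd_mlp"))
  layers <- lapply(seq_len(length(model$sizes) - 1), function(l) {
    W <- model$params[[paste0("W", l)]]
    list(shape = dim(W), weights = as.vector(t(W)),
         bias = model$params[[paste0("b", l)]])
  })
  obj <- list(sizes = model$sizes, feature_names = model$feature_names,
              layers = layers, recal_slope = model$recal_slope %||% 1,
              recal_delta = model$recal_delta,
              epochs_run = model$epochs_run,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- list()
  for (l in seq_along(obj$layers$shape)) {
    shape <- obj$layers$shape[[l]]
    params[[paste0("W", l)]] <- matrix(obj$layers$weights[[l]],
                                       shape[1], shape[2], byrow = TRUE)
    params[[paste0("b", l)]] <- obj$layers$bias[[l]]
  }
  cfg <- obj$config
  config <- mlp_config(hidden_sizes = cfg$hidden_sizes,
                       l2_penalty = cfg$l2_penalty,
                       learning_rate = cfg$learning_rate, beta1 = cfg$beta1,
                       beta2 = cfg$beta2, epsilon = cfg$epsilon,
                       batch_size = cfg$batch_size, max_epochs = cfg$max_epochs,
                       patience = cfg$patience,
                       validation_fraction = cfg$validation_fraction,
                       class_weight = cfg$class_weight,
                       oversample_factor = cfg$oversample_factor,
                       seed = cfg$seed)
  structure(
    list(params = params, sizes = obj$sizes,
         feature_names = obj$feature_names, config = config,
         epochs_run = obj$epochs_run, best_val_loss = NA_real_,
         best_epoch = NA_integer_, recal_slope = obj$recal_slope %||% 1,
         recal_delta = obj$recal_delta),
    class = "ckd_mlp"
  )
}
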