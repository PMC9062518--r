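# The divnn fitting function and its S3 methods.

#' Fit a diversity regression network
#'
#' Trains a fully connected network (ReLU hidden layers with optional
#' dropout, softplus output) on 0-1 scaled features and scaled diversity
#' labels, by minibatch Adam on the mean absolute error. Validation loss
#' is evaluated every epoch with dropout disabled; the weights at the best
#' validation epoch are kept alongside the final weights. Training is
#' fully reproducible given `config$seed`.
#'
#' @param x numeric feature matrix (rows = sites) or a `feature_table`.
#' @param y numeric labels on the original diversity scale.
#' @param config a [divnn_config()].
#' @param validation optional list `list(x =, y =)` on the same scales.
#' @param epochs number of epochs; defaults to `config$max_epochs`. `0` is
#'   allowed and returns the initialized, untrained network.
#' @return object of class `divnn` with the final and best-validation
#'   weights, the per-epoch training/validation MAE history (scaled-label
#'   units), and the configuration.
#' @seealso [predict.divnn()], [select_epoch()], [grid_search()],
#'   [divnn_ensemble()]
#' @export
#' @examples
#' x <- matrix(runif(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- 5 + 10 * x[, 1]
#' fit <- divnn(x, y, divnn_config("gamma", "subset6", hidden = c(8L),
#'                                 seed = 1), epochs = 20)
#' fit
divnn <- function(x, y, config = divnn_config(), validation = NULL,
                  epochs = config$max_epochs) {
  if (inherits(x, "feature_table")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop_divnn("x rows and y length differ")
  if (!nrow(x)) stop_divnn("empty training set")
  ys <- scale_labels(y, config$label_scale)
  val <- NULL
  if (!is.null(validation)) {
    vx <- if (inherits(validation$x, "feature_table")) validation$x$values
          else as.matrix(validation$x)
    val <- list(x = vx, y = scale_labels(validation$y, config$label_scale))
    if (!nrow(val$x)) stop_divnn("empty validation set")
  }

  with_seed(config$seed, {
    layers <- nn_init(ncol(x), config$hidden)
    state <- adam_init(layers)
    history <- data.frame(epoch = integer(0), train_mae = numeric(0),
                          val_mae = numeric(0))
    best <- list(layers = layers, val = Inf, epoch = 0L)
    n <- nrow(x)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        fwd <- nn_forward(layers, x[idx, , drop = FALSE],
                          dropout = config$dropout, training = TRUE)
        loss <- mean(abs(fwd$output - ys[idx]))
        if (!is.finite(loss)) {
          stop_divnn("training diverged: non-finite loss at epoch %d", epoch)
        }
        batch_losses <- c(batch_losses, loss)
        grads <- nn_backward(layers, fwd, ys[idx])
        upd <- adam_step(layers, grads, state, lr = config$learning_rate)
        layers <- upd$layers
        state <- upd$state
      }
      val_mae <- if (is.null(val)) NA_real_ else nn_mae(layers, val$x, val$y)
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_mae = mean(batch_losses),
                                           val_mae = val_mae))
      if (!is.null(val) && val_mae < best$val) {
        best <- list(layers = layers, val = val_mae, epoch = epoch)
      }
    }
    structure(list(layers = layers,
                   best_layers = if (is.null(val)) NULL else best$layers,
                   best_epoch = if (is.null(val)) NA_integer_ else best$epoch,
                   history = history, config = config,
                   feature_names = colnames(x), n_features = ncol(x),
                   n_train = n,
                   train_x = x, train_y = y),
              class = "divnn")
  })
}

#' Predict from a fitted diversity network
#'
#' @param object a [divnn()] fit.
#' @param newdata feature matrix or `feature_table` with the columns the
#'   model was fitted on.
#' @param weights `"final"` (weights after the last epoch; production
#'   models trained exactly to their chosen epoch) or `"best"` (snapshot
#'   at the best validation epoch).
#' @param scale `"response"` returns predictions on the diversity scale;
#'   `"scaled"` returns the network's raw scaled-label output.
#' @param ... unused.
#' @return numeric vector of predictions (strictly positive).
#' @export
predict.divnn <- function(object, newdata, weights = c("final", "best"),
                          scale = c("response", "scaled"), ...) {
  weights <- match.arg(weights)
  scale <- match.arg(scale)
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  newdata <- as.matrix(newdata)
  n_feat <- object$n_features %||% nrow(object$layers[[1]]$W)
  if (ncol(newdata) != n_feat) {
    stop_divnn("newdata has %d columns; model expects %d (%s)",
               ncol(newdata), n_feat,
               paste(object$feature_names, collapse = ", "))
  }
  layers <- if (weights == "best" && !is.null(object$best_layers)) {
    object$best_layers
  } else object$layers
  out <- nn_forward(layers, newdata)$output
  if (scale == "response") unscale_labels(out, object$config$label_scale)
  else out
}

#' @export
print.divnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "divnn fit (%s, %s): %s -> 1, dropout %.2g, %d epochs, %d parameters\n",
    cfg$metric, cfg$feature_set,
    paste(c(length(x$feature_names), cfg$hidden), collapse = " -> "),
    cfg$dropout, nrow(x$history), nn_param_count(x$layers)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final train MAE %.4g (scaled labels)", last$train_mae))
    if (is.finite(last$val_mae)) {
      cat(sprintf("; best val MAE %.4g at epoch %d",
                  min(x$history$val_mae), x$best_epoch))
    }
    cat("\n")
  } else {
    cat("  untrained (initialization only)\n")
  }
  invisible(x)
}

#' @export
summary.divnn <- function(object, ...) {
  h <- object$history
  structure(list(config = object$config,
                 n_parameters = nn_param_count(object$layers),
                 n_train = object$n_train,
                 epochs = nrow(h),
                 final_train_mae = if (nrow(h)) h$train_mae[nrow(h)] else NA,
                 best_val_mae = if (nrow(h) && any(is.finite(h$val_mae)))
                   min(h$val_mae, na.rm = TRUE) else NA,
                 best_epoch = object$best_epoch,
                 chosen_epoch = if (nrow(h) && any(is.finite(h$val_mae)))
                   select_epoch(h) else NA),
            class = "summary.divnn")
}

#' @export
print.summary.divnn <- function(x, ...) {
  cat(sprintf("diversity network (%s, %s)\n", x$config$metric,
              x$config$feature_set))
  cat(sprintf("  architecture : hidden %s, dropout %.2g, softplus output\n",
              paste(x$config$hidden, collapse = ", "), x$config$dropout))
  cat(sprintf("  parameters   : %d\n", x$n_parameters))
  cat(sprintf("  training     : %d instances, %d epochs, batch %d, MAE loss\n",
              x$n_train, x$epochs, x$config$batch_size))
  cat(sprintf("  label scale  : %.6g\n", x$config$label_scale))
  if (is.finite(x$best_val_mae %||% NA)) {
    cat(sprintf("  validation   : best MAE %.4g at epoch %d (use epoch %d)\n",
                x$best_val_mae, x$best_epoch, x$chosen_epoch))
  }
  invisible(x)
}

#' @export
coef.divnn <- function(object, ...) {
  lapply(object$layers, function(l) list(W = l$W, b = l$b))
}

#' @export
fitted.divnn <- function(object, ...) {
  predict(object, object$train_x)
}

#' Residuals of a diversity network
#'
#' @param object a [divnn()] fit.
#' @param newdata optional feature matrix or `feature_table`; defaults to
#'   the training data.
#' @param y true labels on the diversity scale (required with `newdata`).
#' @param ... unused.
#' @return numeric vector `y - prediction`.
#' @export
residuals.divnn <- function(object, newdata = NULL, y = NULL, ...) {
  if (is.null(newdata)) {
    object$train_y - fitted(object)
  } else {
    if (is.null(y)) stop_divnn("supply y alongside newdata")
    y - predict(object, newdata)
  }
}

#' Plot training and validation loss curves
#'
#' @param x a [divnn()] fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.divnn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop_divnn("no training history to plot")
  graphics::matplot(h$epoch, cbind(h$train_mae, h$val_mae), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "MAE (scaled labels)", ...)
  graphics::legend("topright", legend = c("training", "validation"),
                   col = c("black", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
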