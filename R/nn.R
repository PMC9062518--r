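# Fully connected network internals: initialization, forward/backward
# passes, and Adam updates. Written against plain matrices; networks here
# are small (tens of nodes), so dense base-R linear algebra is the whole
# implementation.

#' Model configuration for a diversity network
#'
#' Captures architecture and training protocol: hidden layers with ReLU
#' activation and optional dropout, a single softplus output (predictions
#' strictly positive), mean-absolute-error loss on scaled labels, and
#' minibatch training. Labels are multiplied by `label_scale` before
#' training; the conventional factors are 1/100 for alpha, 1/800 for
#' gamma, and 1 for beta (already in \[0, 1\]).
#'
#' @param metric `"alpha"`, `"beta"`, or `"gamma"` — selects the default
#'   label scale and maximum epochs.
#' @param feature_set `"full27"`, `"subset8"`, or `"subset6"`.
#' @param hidden integer vector of hidden-layer widths; the candidate
#'   architectures of the model-selection grid are `30`, `30,5`,
#'   `30,15,5`, and `30,20,10,5`.
#' @param dropout dropout fraction in \[0, 1) applied after each hidden
#'   layer during training; candidates are 0, 0.1, 0.3.
#' @param label_scale multiplier applied to labels before training;
#'   `NULL` selects the metric default.
#' @param batch_size minibatch size (default 40).
#' @param max_epochs training-epoch budget; `NULL` selects the metric
#'   default (2000 for alpha/gamma, 1000 for beta).
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization, batching, and dropout.
#' @return a `divnn_config` list.
#' @export
divnn_config <- function(metric = c("gamma", "alpha", "beta"),
                         feature_set = c("full27", "subset8", "subset6"),
                         hidden = c(30L, 15L, 5L),
                         dropout = 0,
                         label_scale = NULL,
                         batch_size = 40L,
                         max_epochs = NULL,
                         learning_rate = 1e-3,
                         seed = 1L) {
  metric <- match.arg(metric)
  feature_set <- match.arg(feature_set)
  if (dropout < 0 || dropout >= 1) stop_divnn("dropout must be in [0, 1)")
  if (any(hidden <= 0)) stop_divnn("hidden layer widths must be positive")
  label_scale <- label_scale %||%
    switch(metric, alpha = 1 / 100, gamma = 1 / 800, beta = 1)
  if (label_scale <= 0) stop_divnn("label_scale must be positive")
  max_epochs <- max_epochs %||%
    switch(metric, alpha = 2000L, gamma = 2000L, beta = 1000L)
  structure(list(metric = metric, feature_set = feature_set,
                 hidden = as.integer(hidden), dropout = dropout,
                 label_scale = label_scale,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "divnn_config")
}

#' Scale or unscale diversity labels
#'
#' Training labels are multiplied by a metric-specific factor so they fall
#' roughly in \[0, 1\]; predictions are divided by the same factor to
#' return to the diversity scale. The round trip is exact to machine
#' precision.
#'
#' @param values numeric vector of labels or predictions.
#' @param label_scale positive multiplier.
#' @return scaled (or unscaled) numeric vector.
#' @export
#' @examples
#' scale_labels(100, 1 / 100)   # 1
#' unscale_labels(1, 1 / 800)   # 800
scale_labels <- function(values, label_scale) {
  if (label_scale <= 0) stop_divnn("label_scale must be positive")
  values * label_scale
}

#' @rdname scale_labels
#' @export
unscale_labels <- function(values, label_scale) {
  if (label_scale <= 0) stop_divnn("label_scale must be positive")
  values / label_scale
}

# Seeded uniform fan-in initialization: W ~ U(-1/sqrt(fan_in), +),
# biases zero. Returns list of layers (W, b).
nn_init <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  lapply(seq_len(length(sizes) - 1L), function(l) {
    lim <- 1 / sqrt(sizes[l])
    list(W = matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                    sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

nn_param_count <- function(layers) {
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

# Forward pass. X: n x p matrix. In training mode, inverted dropout masks
# are drawn from the current RNG stream and cached for backprop.
nn_forward <- function(layers, X, dropout = 0, training = FALSE) {
  L <- length(layers)
  pre <- acts <- masks <- vector("list", L)
  A <- X
  for (l in seq_len(L)) {
    Z <- A %*% layers[[l]]$W
    Z <- sweep(Z, 2, layers[[l]]$b, "+")
    pre[[l]] <- Z
    if (l < L) {
      A <- Z * (Z > 0)  # ReLU
      if (training && dropout > 0) {
        m <- matrix(stats::rbinom(length(A), 1L, 1 - dropout),
                    nrow(A)) / (1 - dropout)
        A <- A * m
        masks[[l]] <- m
      }
    } else {
      A <- softplus(Z)
    }
    acts[[l]] <- A
  }
  list(output = acts[[L]][, 1L], pre = pre, acts = acts, masks = masks,
       input = X)
}

# Gradients of mean absolute error wrt all parameters, given a cached
# forward pass and scaled targets y.
nn_backward <- function(layers, fwd, y) {
  L <- length(layers)
  n <- length(y)
  grads <- vector("list", L)
  # d MAE / d output, then through softplus
  dZ <- matrix(sign(fwd$output - y) / n, ncol = 1L) * sigmoid(fwd$pre[[L]])
  for (l in rev(seq_len(L))) {
    A_prev <- if (l == 1L) fwd$input else fwd$acts[[l - 1L]]
    grads[[l]] <- list(W = crossprod(A_prev, dZ), b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% t(layers[[l]]$W)
      if (!is.null(fwd$masks[[l - 1L]])) dA <- dA * fwd$masks[[l - 1L]]
      dZ <- dA * (fwd$pre[[l - 1L]] > 0)
    }
  }
  grads
}

adam_init <- function(layers) {
  list(t = 0L,
       m = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0)))
}

adam_step <- function(layers, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / bc1
      vhat <- state$v[[l]][[p]] / bc2
      layers[[l]][[p]] <- layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

nn_mae <- function(layers, X, y) {
  mean(abs(nn_forward(layers, X)$output - y))
}
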