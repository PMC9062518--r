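# Production ensembles: independently seeded retrains of the selected
# configuration on the full dataset, serialized together with the feature
# scaler and label scale.

#' Train a production ensemble
#'
#' Retrains the selected configuration on the full dataset (no held-out
#' split) for exactly `epochs` epochs, `n_members` times with seeds
#' `base_seed + 1 ... base_seed + n_members`. The feature scaler fitted on
#' the supplied table is stored so prediction grids can be normalized
#' identically.
#'
#' @param table an unscaled `feature_table` covering all training sites
#'   (it is scaled internally on all rows), or an already-scaled table
#'   whose scaler is reused.
#' @param labels diversity labels on the original scale.
#' @param config the selected [divnn_config()].
#' @param epochs chosen training epoch (a positive multiple of 50 from
#'   [select_epoch()]).
#' @param n_members ensemble size (default 50).
#' @param base_seed base seed for member seeding.
#' @param verbose print one line per member.
#' @return object of class `divnn_ensemble`: members (list of [divnn()]
#'   fits), `config`, `epochs`, `scaler`, `feature_names`.
#' @export
divnn_ensemble <- function(table, labels, config, epochs,
                           n_members = 50L, base_seed = config$seed,
                           verbose = FALSE) {
  if (epochs <= 0) stop_divnn("epochs must be positive")
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$scaler)) table <- scale_features(table)
  members <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    cfg <- config
    cfg$seed <- as.integer(base_seed + k)
    members[[k]] <- divnn(table$values, labels, cfg, epochs = epochs)
    # drop per-member training copies; the ensemble carries shared metadata
    members[[k]]$train_x <- NULL
    members[[k]]$train_y <- NULL
    if (verbose) {
      cat(sprintf("member %d/%d trained (seed %d)\n", k, n_members, cfg$seed))
    }
  }
  structure(list(members = members, config = config,
                 epochs = as.integer(epochs), scaler = table$scaler,
                 feature_names = colnames(table$values),
                 n_members = as.integer(n_members),
                 base_seed = as.integer(base_seed)),
            class = "divnn_ensemble")
}

#' @export
print.divnn_ensemble <- function(x, ...) {
  cat(sprintf(
    "divnn_ensemble (%s, %s): %d members, %d epochs each, seeds %d..%d\n",
    x$config$metric, x$config$feature_set, x$n_members, x$epochs,
    x$base_seed + 1L, x$base_seed + x$n_members))
  invisible(x)
}

#' Per-member ensemble predictions
#'
#' @param object a [divnn_ensemble()].
#' @param newdata feature matrix or `feature_table`, already scaled with
#'   the ensemble's scaler.
#' @param ... unused.
#' @return numeric matrix, rows = sites, one column per member, on the
#'   diversity scale.
#' @export
predict.divnn_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$values
  sapply(object$members, function(m) predict(m, newdata))
}

#' Save / load a trained ensemble bundle
#'
#' The bundle directory holds the model configuration, scaler, and member
#' weights as JSON, plus each member's training history as CSV — a
#' portable text-only serialization.
#'
#' @param ensemble a [divnn_ensemble()].
#' @param dir bundle directory.
#' @return `dir` (save) or the restored ensemble (load).
#' @export
save_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "divnn_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config = unclass(ensemble$config),
               epochs = ensemble$epochs,
               n_members = ensemble$n_members,
               base_seed = ensemble$base_seed,
               feature_names = ensemble$feature_names,
               scaler = ensemble$scaler)
  jsonlite::write_json(meta, file.path(dir, "ensemble.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # weights stored flat (column-major) with explicit dims for a
  # simplification-proof round trip
  weights <- lapply(ensemble$members, function(m) {
    lapply(m$layers, function(l) {
      list(dim = dim(l$W), W = as.vector(l$W), b = l$b)
    })
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  invisible(dir)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "ensemble.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(divnn_config, meta$config[c("metric", "feature_set",
                                             "hidden", "dropout",
                                             "label_scale", "batch_size",
                                             "max_epochs", "learning_rate",
                                             "seed")])
  weights <- jsonlite::read_json(file.path(dir, "weights.json"),
                                 simplifyVector = FALSE)
  members <- lapply(weights, function(w) {
    layers <- lapply(w, function(l) {
      d <- unlist(l$dim)
      list(W = matrix(unlist(l$W), d[1], d[2]), b = as.numeric(unlist(l$b)))
    })
    structure(list(layers = layers, best_layers = NULL,
                   best_epoch = NA_integer_,
                   history = data.frame(epoch = integer(0),
                                        train_mae = numeric(0),
                                        val_mae = numeric(0)),
                   config = cfg, feature_names = meta$feature_names,
                   n_train = NA_integer_),
              class = "divnn")
  })
  structure(list(members = members, config = cfg,
                 epochs = as.integer(meta$epochs),
                 scaler = as.data.frame(meta$scaler),
                 feature_names = meta$feature_names,
                 n_members = as.integer(meta$n_members),
                 base_seed = as.integer(meta$base_seed)),
            class = "divnn_ensemble")
}
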