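# Data splitting, error metrics, epoch selection, and the model-selection
# grid.

#' Split instances into train/validation/test sets
#'
#' A uniformly random permutation under `seed` is cut into a test set of
#' `floor(0.2 n)`, a validation set of `floor(0.2 n)`, and a training set
#' of the remainder (about 60%). With 7,896 instances this gives
#' 1,579 / 1,579 / 4,738.
#'
#' @param n number of instances (>= 5).
#' @param seed integer seed.
#' @return list of integer index vectors `train`, `validation`, `test`
#'   (disjoint, union `1:n`).
#' @export
split_data <- function(n, seed = 1L) {
  if (n < 5) stop_divnn("need at least 5 instances to split, have %d", n)
  n_test <- floor(0.2 * n)
  n_val <- floor(0.2 * n)
  if (n_test < 1 || n - n_test - n_val < 1) {
    stop_divnn("n = %d too small for non-empty partitions", n)
  }
  with_seed(seed, {
    perm <- sample.int(n)
    list(test = sort(perm[seq_len(n_test)]),
         validation = sort(perm[n_test + seq_len(n_val)]),
         train = sort(perm[(n_test + n_val + 1L):n]))
  })
}

#' Mean absolute percentage error
#'
#' `100 * mean(|pred - truth| / truth)`, computed on the original
#' diversity scale. Instances with `truth == 0` (possible for beta at
#' fully identical neighbourhoods) are excluded; their count is attached
#' as attribute `n_zero_truth`. MAPE is invariant to a common positive
#' rescaling of predictions and truth.
#'
#' @param predictions,truth numeric vectors of equal length.
#' @return percentage (e.g. `10` means 10%), with attribute
#'   `n_zero_truth`.
#' @export
#' @examples
#' mape(110, 100)  # 10
mape <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop_divnn("predictions and truth lengths differ")
  }
  keep <- truth != 0
  if (!any(keep)) stop_divnn("MAPE undefined: all truth values are zero")
  out <- 100 * mean(abs(predictions[keep] - truth[keep]) / truth[keep])
  attr(out, "n_zero_truth") <- sum(!keep)
  out
}

#' Select the training epoch from a validation history
#'
#' The epoch minimising validation MAE, rounded half-up to the nearest
#' multiple of 50 with a floor of 50. Ties in the validation minimum are
#' broken toward the earlier epoch.
#'
#' @param history data.frame with columns `epoch` and `val_mae` (a
#'   [divnn()] `history`).
#' @return integer, a positive multiple of 50.
#' @export
#' @examples
#' select_epoch(data.frame(epoch = 1:100, val_mae = c(51:75, 1, 74:1)))
select_epoch <- function(history) {
  stopifnot(is.data.frame(history), all(c("epoch", "val_mae") %in%
                                          names(history)))
  ok <- which(is.finite(history$val_mae))
  if (!length(ok)) stop_divnn("history has no validation losses")
  best <- history$epoch[ok[which.min(history$val_mae[ok])]]
  max(50L, as.integer(floor(best / 50 + 0.5)) * 50L)
}

#' Enumerate the model-selection grid
#'
#' The full grid crosses the three feature sets with four architectures
#' (`30`, `30,5`, `30,15,5`, `30,20,10,5`) and three dropout fractions
#' (0, 0.1, 0.3): 36 configurations in total, 12 per feature set.
#'
#' @param feature_sets character vector of feature-set names.
#' @param architectures list of integer vectors of hidden-layer widths.
#' @param dropouts numeric vector of dropout fractions.
#' @return data.frame with columns `feature_set`, `nodes` (comma-joined
#'   label), `dropout`, and a list column `hidden`.
#' @export
grid_configs <- function(feature_sets = c("full27", "subset8", "subset6"),
                         architectures = list(30L, c(30L, 5L),
                                              c(30L, 15L, 5L),
                                              c(30L, 20L, 10L, 5L)),
                         dropouts = c(0, 0.1, 0.3)) {
  combos <- expand.grid(arch = seq_along(architectures),
                        dropout = dropouts,
                        feature_set = feature_sets,
                        stringsAsFactors = FALSE)
  # order: feature set outer, then architecture, then dropout
  combos <- combos[order(match(combos$feature_set, feature_sets),
                         combos$arch, combos$dropout), ]
  out <- data.frame(
    feature_set = combos$feature_set,
    nodes = vapply(architectures[combos$arch], paste, character(1),
                   collapse = ","),
    dropout = combos$dropout,
    stringsAsFactors = FALSE
  )
  out$hidden <- architectures[combos$arch]
  rownames(out) <- NULL
  out
}

#' Model selection over the configuration grid
#'
#' Trains one network per grid row (feature set x architecture x dropout)
#' for up to `max_epochs`, evaluates the mean absolute percentage error of
#' its best-validation-epoch weights on the held-out test set, and returns
#' the grid ranked by test MAPE (ascending; the first row is the selected
#' configuration). Feature scalers are fitted on the training rows only.
#'
#' @param features named list of unscaled `feature_table`s, one per
#'   feature set appearing in `configs`.
#' @param labels numeric vector of diversity labels (original scale) for
#'   all sites.
#' @param split a [split_data()] result.
#' @param metric `"alpha"`, `"beta"`, or `"gamma"` (sets the label scale).
#' @param configs grid rows, from [grid_configs()]; pass a subset for a
#'   reduced search.
#' @param max_epochs epoch budget per candidate; `NULL` = metric default.
#' @param seed base seed; candidate i trains with `seed + i`.
#' @param verbose print one line per candidate.
#' @return `configs` with added columns `mape`, `chosen_epoch`, and
#'   `val_mae`, sorted by `mape`; attribute `best_fit` holds the winning
#'   [divnn()] object.
#' @export
grid_search <- function(features, labels, split,
                        metric = c("gamma", "alpha", "beta"),
                        configs = grid_configs(),
                        max_epochs = NULL, seed = 1L, verbose = FALSE) {
  metric <- match.arg(metric)
  need_sets <- unique(configs$feature_set)
  miss <- setdiff(need_sets, names(features))
  if (length(miss)) {
    stop_divnn("feature table(s) missing for set(s): %s",
               paste(miss, collapse = ", "))
  }
  scaled <- lapply(features[need_sets], scale_features,
                   fit_rows = split$train)

  results <- configs
  results$mape <- NA_real_
  results$chosen_epoch <- NA_integer_
  results$val_mae <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(configs))) {
    ft <- scaled[[configs$feature_set[i]]]
    cfg <- divnn_config(metric = metric,
                        feature_set = configs$feature_set[i],
                        hidden = configs$hidden[[i]],
                        dropout = configs$dropout[i],
                        max_epochs = max_epochs,
                        seed = seed + i)
    fit <- divnn(ft$values[split$train, , drop = FALSE], labels[split$train],
                 cfg,
                 validation = list(x = ft$values[split$validation, ,
                                                 drop = FALSE],
                                   y = labels[split$validation]))
    pred <- predict(fit, ft$values[split$test, , drop = FALSE],
                    weights = "best")
    results$mape[i] <- as.numeric(mape(pred, labels[split$test]))
    results$chosen_epoch[i] <- select_epoch(fit$history)
    results$val_mae[i] <- min(fit$history$val_mae, na.rm = TRUE)
    if (is.null(best) || results$mape[i] < best$mape) {
      best <- list(fit = fit, mape = results$mape[i], row = i)
    }
    if (verbose) {
      cat(sprintf("[%2d/%d] %s | %s | dropout %.2g -> MAPE %.2f%%\n",
                  i, nrow(configs), configs$feature_set[i], configs$nodes[i],
                  configs$dropout[i], results$mape[i]))
    }
  }
  results <- results[order(results$mape), ]
  rownames(results) <- NULL
  attr(results, "best_fit") <- best$fit
  attr(results, "metric") <- metric
  results
}
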