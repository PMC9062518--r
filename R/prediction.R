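# Gridded ensemble prediction: regular equal-area grids, grid feature
# tables with constant plot-size/radius columns, ensemble mean / sd /
# coefficient of variation, the median-CV uncertainty mask, and
# per-region summaries.

#' Centroids of a regular prediction grid
#'
#' Lays square cells of side `cell_size` from the extent's lower-left
#' corner; only cells that fit entirely inside the extent are kept (their
#' centroids are returned). Optionally restricted to cells whose centroid
#' carries data in a land-mask raster.
#'
#' @param extent named vector `xmin, xmax, ymin, ymax` in metres.
#' @param cell_size cell side in metres (default 10,000 m = 10 km cells).
#' @param land_mask optional [raster_layer()]; centroids on `NA` cells are
#'   dropped.
#' @return data.frame with columns `x`, `y` (cell centroids).
#' @export
#' @examples
#' nrow(make_grid(c(xmin = 0, xmax = 1e5, ymin = 0, ymax = 1e5)))  # 100
make_grid <- function(extent, cell_size = 10000, land_mask = NULL) {
  extent <- extent[c("xmin", "xmax", "ymin", "ymax")]
  if (anyNA(extent)) stop_divnn("extent must name xmin, xmax, ymin, ymax")
  if (cell_size <= 0) stop_divnn("cell_size must be positive")
  nx <- floor((extent["xmax"] - extent["xmin"]) / cell_size)
  ny <- floor((extent["ymax"] - extent["ymin"]) / cell_size)
  if (nx < 1 || ny < 1) stop_divnn("extent too small for any %g m cell",
                                   cell_size)
  grid <- expand.grid(
    x = unname(extent["xmin"]) + (seq_len(nx) - 0.5) * cell_size,
    y = unname(extent["ymin"]) + (seq_len(ny) - 0.5) * cell_size
  )
  if (!is.null(land_mask)) {
    vals <- extract_raster_values(land_mask, grid)[[1]]
    grid <- grid[!is.na(vals), , drop = FALSE]
    if (!nrow(grid)) stop_divnn("land mask excludes every grid cell")
  }
  rownames(grid) <- NULL
  grid
}

#' Feature table for a prediction grid
#'
#' Builds the same features as [assemble_features()] at grid centroids,
#' with the plot-size and radius features held constant: predictions then
#' read as the diversity expected for a plot of `plot_size` m2 (alpha) or
#' within a neighbourhood of radius `radius` m (beta/gamma) at each cell.
#' Values are normalized with the training scaler; a warning is emitted if
#' the constant plot size or radius falls outside the scaler's fitted
#' (training) range, since the networks should not be extrapolated.
#'
#' @param centroids data.frame `x, y` from [make_grid()].
#' @param layers named list of [raster_layer()] objects.
#' @param occurrences filtered occurrence table (needed for `full27`).
#' @param scaler training scaler (`feature, min, max`), e.g. from an
#'   ensemble bundle.
#' @param feature_set feature-set name.
#' @param plot_size constant plot-size feature, m2 (default 500).
#' @param radius constant neighbourhood-radius feature, m (default 5,000).
#' @param window_side sampling-effort window side, m.
#' @return scaled `feature_table` for the grid (out-of-range cell count in
#'   `n_out_of_range`).
#' @export
grid_features <- function(centroids, layers, occurrences = NULL, scaler,
                          feature_set = c("full27", "subset8", "subset6"),
                          plot_size = 500, radius = 5000,
                          window_side = 10000) {
  feature_set <- match.arg(feature_set)
  for (f in c(plot_size = "plot_size", radius = "radius")) {
    s <- scaler[scaler$feature == f, ]
    val <- if (f == "plot_size") plot_size else radius
    if (nrow(s) && (val < s$min || val > s$max)) {
      warn_divnn(
        "prediction %s %g is outside the training range [%g, %g]; %s",
        f, val, s$min, s$max,
        "predictions extrapolate beyond the fitted species-area signal")
    }
  }
  ids <- sprintf("cell_%06d", seq_len(nrow(centroids)))
  plots <- data.frame(plot_id = ids, x = centroids$x, y = centroids$y,
                      area = plot_size)
  sites <- data.frame(plot_id = ids, radius = radius)
  ft <- assemble_features(sites, plots, occurrences, layers, feature_set,
                          window_side = window_side)
  apply_scaler(ft, scaler)
}

#' Ensemble prediction surface with uncertainty
#'
#' Runs every ensemble member on the grid features, inverse-scales to the
#' diversity scale, and summarizes per cell: ensemble mean, population
#' standard deviation (divisor n — the members are the whole population),
#' coefficient of variation `CV = sd / mean`, and the uncertainty mask.
#' A cell is masked (high uncertainty) exactly when its CV is strictly
#' greater than the median CV across all cells of the run; cells at or
#' below the median are retained. Cells with mean 0 get CV 0 and are
#' flagged in `zero_mean` (softplus outputs make this a numerical
#' safeguard only).
#'
#' @param ensemble a [divnn_ensemble()].
#' @param features scaled grid `feature_table` from [grid_features()]
#'   (or a matrix).
#' @param centroids optional data.frame `x, y` carried into the result.
#' @return data.frame of class `prediction_grid`: `x, y` (if supplied),
#'   `mean, sd, cv, masked, zero_mean`, one row per cell.
#' @export
predict_ensemble <- function(ensemble, features, centroids = NULL) {
  stopifnot(inherits(ensemble, "divnn_ensemble"))
  preds <- predict(ensemble, features)  # cells x members
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  mu <- rowMeans(preds)
  sdev <- sqrt(rowMeans((preds - mu)^2))  # population sd
  zero <- mu == 0
  cv <- ifelse(zero, 0, sdev / ifelse(zero, 1, mu))
  masked <- cv > stats::median(cv)
  out <- data.frame(mean = mu, sd = sdev, cv = cv, masked = masked,
                    zero_mean = zero)
  if (!is.null(centroids)) out <- cbind(centroids[, c("x", "y")], out)
  class(out) <- c("prediction_grid", "data.frame")
  attr(out, "metric") <- ensemble$config$metric
  attr(out, "median_cv") <- stats::median(cv)
  out
}

#' @export
print.prediction_grid <- function(x, ...) {
  cat(sprintf(
    "prediction_grid (%s): %d cells, mean %.3g (sd of means %.3g), %s\n",
    attr(x, "metric") %||% "?", nrow(x), mean(x$mean), stats::sd(x$mean),
    sprintf("median CV %.3g, %d cells masked", attr(x, "median_cv"),
            sum(x$masked))))
  invisible(x)
}

#' Summarize predictions by region
#'
#' Aggregates a prediction grid over regions (e.g. biomes or ecoregions):
#' per region, the cell counts and the mean and quantiles of the
#' predicted diversity over unmasked (low-uncertainty) cells only. A
#' region whose cells are all masked is reported with `n_unmasked = 0` and
#' `NA` statistics.
#'
#' @param grid a [predict_ensemble()] result containing `x, y`.
#' @param regions either a category [raster_layer()] (cell values are
#'   region codes; `NA` = outside) or a data.frame `x, y, region` aligned
#'   with the grid; or a vector of region labels parallel to `grid` rows.
#' @param region_names optional named vector mapping codes to labels.
#' @return data.frame: `region, n_cells, n_unmasked, mean, q05, q25,
#'   median, q75, q95`.
#' @export
summarize_by_region <- function(grid, regions, region_names = NULL) {
  stopifnot(inherits(grid, "prediction_grid"))
  if (inherits(regions, "raster_layer")) {
    if (!all(c("x", "y") %in% names(grid))) {
      stop_divnn("grid lacks coordinates; cannot overlay a region raster")
    }
    codes <- extract_raster_values(regions, grid[, c("x", "y")])[[1]]
  } else if (is.data.frame(regions)) {
    key <- paste(grid$x, grid$y)
    codes <- regions$region[match(key, paste(regions$x, regions$y))]
  } else {
    if (length(regions) != nrow(grid)) {
      stop_divnn("region vector length differs from grid")
    }
    codes <- regions
  }
  if (all(is.na(codes))) stop_divnn("regions do not overlap the grid")
  if (!is.null(region_names)) codes <- region_names[as.character(codes)]
  keep <- !is.na(codes)
  g <- grid[keep, , drop = FALSE]
  codes <- codes[keep]
  res <- lapply(split(seq_along(codes), codes), function(idx) {
    vals <- g$mean[idx][!g$masked[idx]]
    qs <- if (length(vals)) stats::quantile(vals, c(.05, .25, .5, .75, .95))
          else rep(NA_real_, 5)
    data.frame(n_cells = length(idx), n_unmasked = length(vals),
               mean = if (length(vals)) mean(vals) else NA_real_,
               q05 = qs[1], q25 = qs[2], median = qs[3], q75 = qs[4],
               q95 = qs[5], row.names = NULL)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(region = names(res), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Rasterize a prediction-grid column
#'
#' Turns one column of a [predict_ensemble()] result (with coordinates)
#' back into a [raster_layer()] on the prediction grid, for export as an
#' ASCII grid.
#'
#' @param grid a `prediction_grid` with `x, y`.
#' @param column column to rasterize (`"mean"`, `"sd"`, `"cv"`,
#'   `"masked"`).
#' @param cell_size grid cell size in metres.
#' @return a [raster_layer()].
#' @export
grid_to_raster <- function(grid, column = "mean", cell_size = 10000) {
  stopifnot(all(c("x", "y", column) %in% names(grid)))
  xs <- sort(unique(grid$x))
  ys <- sort(unique(grid$y), decreasing = TRUE)  # row 1 = north
  m <- matrix(NA_real_, length(ys), length(xs))
  m[cbind(match(grid$y, ys), match(grid$x, xs))] <- as.numeric(grid[[column]])
  raster_layer(m, xll = min(xs) - cell_size / 2, yll = min(grid$y) -
                 cell_size / 2, cellsize = cell_size, name = column)
}
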