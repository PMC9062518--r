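# Per-site feature tables: occurrence filtering, sampling-effort window
# counts, raster extraction, plot-size and neighbourhood-radius features,
# named feature subsets, and 0-1 min-max rescaling.

# The full feature catalogue, in table order. `source` says where each
# column comes from; `layer` names the raster for raster-sourced features.
feature_catalog <- function() {
  bio_names <- sprintf("bio%02d", 1:19)
  data.frame(
    feature = c("longitude", "latitude", "sampling_effort",
                "sampled_species", "human_footprint", "elevation",
                bio_names, "plot_size", "radius"),
    source = c("coordinate", "coordinate", "occurrence", "occurrence",
               "raster", "raster", rep("raster", 19), "plot", "site"),
    layer = c(NA, NA, NA, NA, "human_footprint", "elevation",
              bio_names, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Names of a feature set
#'
#' Three named feature sets are supported: `full27` (all 27 features),
#' `subset8` (longitude, latitude, human footprint, elevation, bio01,
#' bio12, plot size, radius), and `subset6` (`subset8` without the two
#' coordinate features).
#'
#' @param feature_set one of `"full27"`, `"subset8"`, `"subset6"`.
#' @return character vector of feature names in canonical order.
#' @export
#' @examples
#' length(feature_set_names("full27"))  # 27
#' setdiff(feature_set_names("subset8"), feature_set_names("subset6"))
feature_set_names <- function(feature_set = c("full27", "subset8", "subset6")) {
  feature_set <- match.arg(feature_set)
  cat27 <- feature_catalog()$feature
  sub8 <- c("longitude", "latitude", "human_footprint", "elevation",
            "bio01", "bio12", "plot_size", "radius")
  switch(feature_set,
         full27 = cat27,
         subset8 = cat27[cat27 %in% sub8],
         subset6 = cat27[cat27 %in% setdiff(sub8, c("longitude", "latitude"))])
}

#' Filter occurrence records for feature generation
#'
#' Keeps records that are (1) not fossils, (2) based on human observation,
#' (3) free of geospatial issue flags, (4) carry a binomial name (exactly
#' two whitespace-separated tokens), and (5) whose normalized name appears
#' in the accepted-name checklist. Applying the filter twice is a no-op.
#'
#' @param occurrences data.frame with columns `species, x, y,
#'   basis_of_record, issue_flags, is_fossil`.
#' @param checklist data.frame with column `accepted_name` (non-empty).
#' @return the surviving subset of `occurrences` (possibly zero rows).
#' @export
filter_occurrences <- function(occurrences, checklist) {
  stopifnot(is.data.frame(occurrences))
  if (!is.data.frame(checklist) || !"accepted_name" %in% names(checklist) ||
      !nrow(checklist)) {
    stop_divnn("checklist must be a non-empty table with column 'accepted_name'")
  }
  nm <- normalize_names(occurrences$species)
  accepted <- unique(normalize_names(checklist$accepted_name))
  n_tokens <- lengths(strsplit(nm, " ", fixed = TRUE))
  flags <- occurrences$issue_flags
  flags[is.na(flags)] <- ""
  keep <- !occurrences$is_fossil &
    occurrences$basis_of_record == "HUMAN_OBSERVATION" &
    trimws(flags) == "" &
    n_tokens == 2L &
    nm %in% accepted
  occurrences[keep, , drop = FALSE]
}

#' Occurrence and species counts in a square window
#'
#' Counts occurrence records, and the distinct species among them, inside
#' a square window of side `window_side` centred on `center`. Membership
#' is half-open on the maximum edges (`[c - s/2, c + s/2)` on both axes),
#' so adjacent windows tile the plane without double counting.
#'
#' @param occurrences data.frame with columns `species, x, y` (projected
#'   metres); normally the output of [filter_occurrences()].
#' @param center numeric length-2 `(x, y)` in metres.
#' @param window_side window edge length in metres (default 10,000 m, the
#'   operational 10 km sampling-effort window).
#' @return named integer vector `c(n_records, n_species)`.
#' @export
window_counts <- function(occurrences, center, window_side = 10000) {
  if (window_side <= 0) stop_divnn("window_side must be positive")
  h <- window_side / 2
  inside <- occurrences$x >= center[1] - h & occurrences$x < center[1] + h &
    occurrences$y >= center[2] - h & occurrences$y < center[2] + h
  c(n_records = sum(inside),
    n_species = length(unique(normalize_names(occurrences$species[inside]))))
}

#' Assemble the per-site feature table
#'
#' Builds the model input matrix for a set of labelled sites: coordinates,
#' occurrence-based sampling effort and sampled-species counts in a square
#' window, raster-extracted climatic/anthropogenic values, vegetation plot
#' size, and the neighbourhood radius. Columns follow the canonical order
#' of the requested feature set.
#'
#' @param sites a [label_sites()] result (or any data.frame with
#'   `plot_id` and `radius`).
#' @param plots data.frame with `plot_id, x, y, area`.
#' @param occurrences filtered occurrence table (projected metres); only
#'   needed for `full27`.
#' @param layers named list of [raster_layer()] objects; must cover the
#'   raster features of the requested set.
#' @param feature_set `"full27"`, `"subset8"`, or `"subset6"`.
#' @param window_side sampling-effort window side in metres.
#' @return object of class `feature_table`: list with `site_id`, numeric
#'   matrix `values` (sites x features), `feature_set`, and `scaler`
#'   (`NULL` until [scale_features()] is applied).
#' @export
assemble_features <- function(sites, plots, occurrences = NULL, layers,
                              feature_set = c("full27", "subset8", "subset6"),
                              window_side = 10000) {
  feature_set <- match.arg(feature_set)
  wanted <- feature_set_names(feature_set)
  cat <- feature_catalog()
  cat <- cat[match(wanted, cat$feature), ]

  idx <- match(sites$plot_id, plots$plot_id)
  if (anyNA(idx)) stop_divnn("site id(s) missing from plots table")
  pts <- data.frame(x = plots$x[idx], y = plots$y[idx])

  need_layers <- cat$layer[cat$source == "raster"]
  miss <- setdiff(need_layers, names(layers))
  if (length(miss)) {
    stop_divnn("missing raster layer(s) for requested features: %s",
               paste(miss, collapse = ", "))
  }
  rast_vals <- if (length(need_layers)) {
    extract_raster_values(layers[need_layers], pts)
  } else NULL

  if (any(cat$source == "occurrence")) {
    if (is.null(occurrences)) {
      stop_divnn("feature set '%s' needs an occurrence table", feature_set)
    }
    wc <- t(vapply(seq_len(nrow(pts)), function(i) {
      window_counts(occurrences, c(pts$x[i], pts$y[i]), window_side)
    }, c(n_records = 0, n_species = 0)))
  }

  values <- matrix(NA_real_, nrow(pts), nrow(cat),
                   dimnames = list(sites$plot_id, cat$feature))
  for (k in seq_len(nrow(cat))) {
    f <- cat$feature[k]
    values[, k] <- switch(cat$source[k],
      coordinate = if (f == "longitude") pts$x else pts$y,
      occurrence = if (f == "sampling_effort") wc[, "n_records"]
                   else wc[, "n_species"],
      raster = rast_vals[[cat$layer[k]]],
      plot = plots$area[idx],
      site = sites$radius)
  }
  structure(list(site_id = as.character(sites$plot_id), values = values,
                 feature_set = feature_set, scaler = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d sites x %d features (%s), %s\n",
              nrow(x$values), ncol(x$values), x$feature_set,
              if (is.null(x$scaler)) "unscaled" else "scaled to training 0-1"))
  invisible(x)
}

#' Fit and apply 0-1 min-max scaling to a feature table
#'
#' Per-feature min-max scaling fitted on the designated rows (normally the
#' training split) and applied to all rows. Fitted-range rows map into
#' \[0, 1\]; other rows are deliberately not clipped and may fall outside
#' it — the number of such cells is stored as `n_out_of_range`. A feature
#' constant on the fit rows maps to 0 everywhere.
#'
#' @param table a [assemble_features()] result.
#' @param fit_rows integer indices of rows used to fit the scaler
#'   (default: all rows).
#' @return the feature table with `values` scaled and `scaler` set (a
#'   data.frame `feature, min, max`), plus `n_out_of_range`.
#' @export
scale_features <- function(table, fit_rows = seq_len(nrow(table$values))) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  mins <- apply(v[fit_rows, , drop = FALSE], 2, min)
  maxs <- apply(v[fit_rows, , drop = FALSE], 2, max)
  table$scaler <- data.frame(feature = colnames(v), min = mins, max = maxs,
                             row.names = NULL)
  apply_scaler(table, table$scaler)
}

#' Apply a previously fitted feature scaler
#'
#' Used for prediction grids: grid features are normalized with the
#' training min/max so that model inputs are on the scale the network was
#' trained on. Values outside the fitted range are not clipped.
#'
#' @param table a [assemble_features()] result (unscaled values).
#' @param scaler data.frame `feature, min, max` as stored by
#'   [scale_features()].
#' @return scaled feature table with `n_out_of_range` set.
#' @export
apply_scaler <- function(table, scaler) {
  stopifnot(inherits(table, "feature_table"))
  if (!all(colnames(table$values) %in% scaler$feature)) {
    stop_divnn("scaler does not cover feature(s): %s",
               paste(setdiff(colnames(table$values), scaler$feature),
                     collapse = ", "))
  }
  v <- table$values
  for (k in seq_len(ncol(v))) {
    s <- scaler[scaler$feature == colnames(v)[k], ]
    rng <- s$max - s$min
    v[, k] <- if (rng <= 0) 0 else (v[, k] - s$min) / rng
  }
  table$values <- v
  table$scaler <- scaler
  table$n_out_of_range <- sum(v < 0 | v > 1, na.rm = TRUE)
  table
}
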