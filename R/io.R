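# Readers and writers for the interchange formats: delimited plot /
# occurrence / checklist tables (comma- or tab-separated), diversity-label
# tables, feature tables, and run manifests. Coordinates on disk are
# longitude/latitude; readers project them to equal-area metres.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop_divnn("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (!length(first)) stop_divnn("file is empty: %s", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "")
}

require_columns <- function(d, cols, what, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss)) {
    stop_divnn("%s file %s missing column(s): %s", what, path,
               paste(miss, collapse = ", "))
  }
}

check_coords <- function(lon, lat, what, path) {
  bad <- which(!is.finite(lon) | !is.finite(lat) | abs(lat) > 90 |
                 abs(lon) > 360)
  if (length(bad)) {
    stop_divnn("%s file %s: unparseable coordinates at data row(s) %s",
               what, path, paste(utils::head(bad, 5), collapse = ", "))
  }
}

#' Read a vegetation-plot table
#'
#' Accepts two layouts: wide — one row per plot with columns `plot_id,
#' lon, lat, area_m2, species` where `species` is a `;`- or `|`-delimited
#' list — or long — one row per plot/species pair with the same columns
#' and a single name in `species` (plot rows repeat). The layout is
#' detected from duplicated plot ids. Coordinates are projected to
#' equal-area metres.
#'
#' @param path CSV or TSV file.
#' @param standard_parallel projection parallel passed to [cea_project()].
#' @return data.frame `plot_id, lon, lat, x, y, area` with a list column
#'   `species`.
#' @export
read_plots <- function(path, standard_parallel = -30) {
  d <- read_delim_auto(path)
  require_columns(d, c("plot_id", "lon", "lat", "area_m2", "species"),
                  "plots", path)
  if (!nrow(d)) stop_divnn("plots file %s has no data rows", path)
  d$lon <- suppressWarnings(as.numeric(d$lon))
  d$lat <- suppressWarnings(as.numeric(d$lat))
  check_coords(d$lon, d$lat, "plots", path)
  d$plot_id <- as.character(d$plot_id)
  long <- anyDuplicated(d$plot_id) > 0
  if (long) {
    sp <- split(as.character(d$species), d$plot_id)
    firsts <- d[!duplicated(d$plot_id), ]
    species <- unname(lapply(sp[firsts$plot_id],
                             function(s) sort(unique(trimws(s)))))
    d <- firsts
  } else {
    species <- lapply(strsplit(as.character(d$species), "[;|]"),
                      function(s) sort(unique(trimws(s))))
  }
  xy <- cea_project(d$lon, d$lat, standard_parallel)
  out <- data.frame(plot_id = d$plot_id, lon = d$lon, lat = d$lat,
                    x = xy$x, y = xy$y,
                    area = suppressWarnings(as.numeric(d$area_m2)))
  if (anyNA(out$area)) {
    stop_divnn("plots file %s: unparseable area_m2 at data row(s) %s", path,
               paste(utils::head(which(is.na(out$area)), 5), collapse = ", "))
  }
  out$species <- species
  out
}

#' Read an occurrence table
#'
#' Expects columns `species, lon, lat, basis_of_record, issue_flags`
#' (empty string = no geospatial issues) and optionally `is_fossil`
#' (defaults to `FALSE`). Coordinates are projected to equal-area metres.
#'
#' @inheritParams read_plots
#' @return data.frame `species, lon, lat, x, y, basis_of_record,
#'   issue_flags, is_fossil`.
#' @export
read_occurrences <- function(path, standard_parallel = -30) {
  d <- read_delim_auto(path)
  require_columns(d, c("species", "lon", "lat", "basis_of_record",
                       "issue_flags"), "occurrences", path)
  d$lon <- suppressWarnings(as.numeric(d$lon))
  d$lat <- suppressWarnings(as.numeric(d$lat))
  check_coords(d$lon, d$lat, "occurrences", path)
  xy <- cea_project(d$lon, d$lat, standard_parallel)
  flags <- as.character(d$issue_flags)
  flags[is.na(flags)] <- ""
  data.frame(species = as.character(d$species), lon = d$lon, lat = d$lat,
             x = xy$x, y = xy$y,
             basis_of_record = as.character(d$basis_of_record),
             issue_flags = flags,
             is_fossil = if ("is_fossil" %in% names(d))
               as.logical(d$is_fossil) else FALSE,
             stringsAsFactors = FALSE)
}

#' Read an accepted-name checklist
#'
#' @inheritParams read_plots
#' @return data.frame with column `accepted_name`.
#' @export
read_checklist <- function(path) {
  d <- read_delim_auto(path)
  require_columns(d, "accepted_name", "checklist", path)
  if (!nrow(d)) stop_divnn("checklist file %s has no data rows", path)
  data.frame(accepted_name = as.character(d$accepted_name),
             stringsAsFactors = FALSE)
}

#' Read all rasters in a directory
#'
#' @param dir directory containing `.asc` ESRI ASCII grids.
#' @return named list of [raster_layer()] objects.
#' @export
read_raster_dir <- function(dir) {
  paths <- list.files(dir, pattern = "\\.asc$", full.names = TRUE)
  if (!length(paths)) stop_divnn("no .asc rasters found in %s", dir)
  layers <- lapply(paths, read_raster)
  names(layers) <- vapply(layers, function(l) l$name, character(1))
  layers
}

#' Write a feature table
#'
#' @param table a `feature_table`.
#' @param path output CSV path; the scaler (if fitted) is written next to
#'   it as `<path>.scaler.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  d <- data.frame(site_id = table$site_id, table$values, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  if (!is.null(table$scaler)) {
    jsonlite::write_json(table$scaler, paste0(path, ".scaler.json"),
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @param feature_set the set the columns belong to.
#' @return a `feature_table` (scaler restored if the sidecar JSON exists).
#' @export
read_feature_table <- function(path, feature_set = "full27") {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(d)) {
    stop_divnn("feature table %s missing column: site_id", path)
  }
  vals <- as.matrix(d[, setdiff(names(d), "site_id"), drop = FALSE])
  rownames(vals) <- d$site_id
  scaler_path <- paste0(path, ".scaler.json")
  scaler <- if (file.exists(scaler_path)) {
    as.data.frame(jsonlite::read_json(scaler_path, simplifyVector = TRUE))
  } else NULL
  structure(list(site_id = as.character(d$site_id), values = vals,
                 feature_set = feature_set, scaler = scaler),
            class = "feature_table")
}

#' Write a machine-readable run manifest
#'
#' Every pipeline stage records its configuration, seeds, package version,
#' and any extrapolation warnings (count of scaled feature values outside
#' the fitted 0-1 range), so a run can be reproduced from the manifest
#' alone.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param params named list of parameters/seeds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, stage, params) {
  jsonlite::write_json(
    list(stage = stage,
         package = "divnn",
         version = as.character(utils::packageVersion("divnn")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         params = params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
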