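# Synthetic landscapes with a known diversity-environment relationship.
#
# The generator emulates the structure of the package's intended inputs:
# sPlotOpen-like vegetation plots (areas 50-10,000 m2, 1-115 species,
# spatially clustered sites), occurrence points with spatially uneven
# sampling density, smooth autocorrelated environmental surfaces, and an
# accepted-name checklist. Expected plot richness is a deterministic
# increasing function of one designated environmental layer ("bio01") and
# of plot area (a power-law species-area relationship), so downstream
# models have a recoverable signal. Species composition is drawn by
# distance-decaying sampling from a pool with spatially varying
# availability, which induces non-trivial beta diversity and
# distance-decay of similarity.

# Layer names in feature-table order; "bio01" is the designated richness
# driver.
ENV_LAYER_NAMES <- c("human_footprint", "elevation", sprintf("bio%02d", 1:19))

# Plausible value ranges per layer (only cosmetic: features are min-max
# scaled before modelling).
env_layer_range <- function(name) {
  switch(name,
    human_footprint = c(0, 50),
    elevation = c(0, 1500),
    bio12 = , bio13 = , bio14 = , bio15 = , bio16 = , bio17 = ,
    bio18 = , bio19 = c(100, 2000),
    c(5, 30)  # temperature-like layers
  )
}

#' Configuration for a synthetic landscape
#'
#' @param seed integer seed; the whole landscape is a deterministic
#'   function of the configuration including this seed.
#' @param extent named numeric vector `xmin, xmax, ymin, ymax` in projected
#'   metres (equal-area).
#' @param n_plots number of vegetation plots (>= 2).
#' @param n_species_pool size of the regional species pool.
#' @param plot_area_range min/max plot area in m2; the default 50-10,000 m2
#'   matches the plot sizes the models are intended to be trained on.
#' @param richness_gradient_strength non-negative; log-scale effect of the
#'   designated environmental layer on expected richness (0 = area-only).
#' @param occurrence_density_bias non-negative; strength of spatial
#'   unevenness in occurrence sampling density (0 = spatially uniform).
#' @param n_env_layers number of environmental raster layers (1-21); layers
#'   are taken in the order human footprint, elevation, bio01..bio19.
#' @param n_occurrences number of occurrence records to simulate.
#' @param checklist_noise fraction of extra never-used names added to the
#'   checklist, to exercise name filtering.
#' @param cellsize raster cell size in metres.
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(seed = 1L,
                             extent = c(xmin = 0, xmax = 1e5,
                                        ymin = 0, ymax = 1e5),
                             n_plots = 400L,
                             n_species_pool = 400L,
                             plot_area_range = c(50, 10000),
                             richness_gradient_strength = 2,
                             occurrence_density_bias = 1.5,
                             n_env_layers = 21L,
                             n_occurrences = 5000L,
                             checklist_noise = 0.1,
                             cellsize = 1000) {
  extent <- extent[c("xmin", "xmax", "ymin", "ymax")]
  if (anyNA(extent)) stop_divnn("extent must name xmin, xmax, ymin, ymax")
  if (extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"]) {
    stop_divnn("degenerate extent: max must exceed min on both axes")
  }
  if (n_plots < 2) stop_divnn("n_plots must be at least 2")
  if (length(plot_area_range) != 2 || plot_area_range[1] <= 0 ||
      diff(plot_area_range) < 0) {
    stop_divnn("plot_area_range must be an increasing positive pair")
  }
  if (richness_gradient_strength < 0 || occurrence_density_bias < 0) {
    stop_divnn("gradient strength and density bias must be non-negative")
  }
  if (n_env_layers < 1 || n_env_layers > length(ENV_LAYER_NAMES)) {
    stop_divnn("n_env_layers must be between 1 and %d", length(ENV_LAYER_NAMES))
  }
  structure(list(
    seed = as.integer(seed), extent = extent,
    n_plots = as.integer(n_plots),
    n_species_pool = as.integer(n_species_pool),
    plot_area_range = plot_area_range,
    richness_gradient_strength = richness_gradient_strength,
    occurrence_density_bias = occurrence_density_bias,
    n_env_layers = as.integer(n_env_layers),
    n_occurrences = as.integer(n_occurrences),
    checklist_noise = checklist_noise,
    cellsize = cellsize
  ), class = "landscape_config")
}

# Smooth random field as a sum of low-frequency sinusoids. Returns the
# component parameters; evaluate with field_eval().
field_params <- function(n_components = 5L, wavelength = c(3e4, 1.5e5)) {
  data.frame(
    amp = runif(n_components, 0.5, 1),
    theta = runif(n_components, 0, pi),
    wavelength = exp(runif(n_components, log(wavelength[1]),
                           log(wavelength[2]))),
    phase = runif(n_components, 0, 2 * pi)
  )
}

field_eval <- function(params, x, y) {
  v <- 0
  for (k in seq_len(nrow(params))) {
    p <- params[k, ]
    v <- v + p$amp * sin(2 * pi / p$wavelength *
                           (x * cos(p$theta) + y * sin(p$theta)) + p$phase)
  }
  v
}

# Expected plot richness: power-law species-area relationship modulated by
# the designated environmental driver (on the 0-1 scale).
expected_richness <- function(env01, area, strength, z = 0.25, base = 15) {
  base * (area / 500)^z * exp(strength * (env01 - 0.5))
}

#' Generate a synthetic landscape
#'
#' Produces environmental rasters, clustered vegetation plots with realized
#' species sets, spatially biased occurrence records, an accepted-name
#' checklist (with a fraction of unused noise names), and the per-plot
#' expected richness used during generation (`truth`). Reproducible: the
#' same configuration yields an identical landscape.
#'
#' Realized per-plot richness is Poisson around the deterministic
#' expectation (truncated to at least 1 and at most the pool size); species
#' identities are drawn without replacement with probabilities proportional
#' to a per-species spatial availability kernel, so nearby plots share
#' species.
#'
#' @param config a [landscape_config()].
#' @return object of class `synthetic_landscape`: list with elements
#'   `config`, `layers` (named list of [raster_layer()]), `plots`
#'   (data.frame `plot_id, x, y, area, species` with a list column of
#'   species names), `occurrences`, `checklist`, and `truth`.
#' @export
generate_landscape <- function(config = landscape_config()) {
  stopifnot(inherits(config, "landscape_config"))
  with_seed(config$seed, {
    ext <- config$extent
    width <- ext["xmax"] - ext["xmin"]
    height <- ext["ymax"] - ext["ymin"]

    ## --- environmental layers -------------------------------------------
    layer_names <- ENV_LAYER_NAMES[seq_len(config$n_env_layers)]
    # richness driver must exist even in minimal configurations
    if (!"bio01" %in% layer_names) layer_names[length(layer_names)] <- "bio01"
    fields <- lapply(layer_names, function(nm) field_params())
    names(fields) <- layer_names

    nx <- max(2L, floor(width / config$cellsize))
    ny <- max(2L, floor(height / config$cellsize))
    cx <- ext["xmin"] + (seq_len(nx) - 0.5) * config$cellsize
    cy <- ext["ymin"] + (seq_len(ny) - 0.5) * config$cellsize
    gx <- rep(cx, each = ny)
    gy <- rep(rev(cy), times = nx)  # row 1 = north

    norms <- list()
    layers <- list()
    for (nm in layer_names) {
      raw <- field_eval(fields[[nm]], gx, gy)
      norms[[nm]] <- c(min = min(raw), max = max(raw))
      v01 <- (raw - norms[[nm]]["min"]) /
        max(norms[[nm]]["max"] - norms[[nm]]["min"], .Machine$double.eps)
      rng <- env_layer_range(nm)
      vals <- matrix(rng[1] + v01 * (rng[2] - rng[1]), nrow = ny, ncol = nx)
      layers[[nm]] <- raster_layer(vals, ext["xmin"], ext["ymin"],
                                   config$cellsize, name = nm)
    }
    env01_at <- function(x, y) {
      raw <- field_eval(fields[["bio01"]], x, y)
      n <- norms[["bio01"]]
      pmin(pmax((raw - n["min"]) / max(n["max"] - n["min"],
                                       .Machine$double.eps), 0), 1)
    }

    ## --- species pool with spatial availability -------------------------
    n_sp <- config$n_species_pool
    pool <- sprintf("genus%03d species%03d",
                    sample.int(max(40L, n_sp %/% 8L), n_sp, replace = TRUE),
                    seq_len(n_sp))
    sp_cx <- runif(n_sp, ext["xmin"], ext["xmax"])
    sp_cy <- runif(n_sp, ext["ymin"], ext["ymax"])
    sp_sigma <- runif(n_sp, 0.15, 0.5) * width
    availability <- function(x, y) {
      d2 <- outer(x, sp_cx, "-")^2 + outer(y, sp_cy, "-")^2
      exp(-d2 / (2 * rep(sp_sigma^2, each = length(x)))) + 0.005
    }

    ## --- vegetation plots (clustered) -----------------------------------
    n_clusters <- max(3L, config$n_plots %/% 25L)
    ccx <- runif(n_clusters, ext["xmin"], ext["xmax"])
    ccy <- runif(n_clusters, ext["ymin"], ext["ymax"])
    cl <- sample.int(n_clusters, config$n_plots, replace = TRUE)
    px <- rnorm(config$n_plots, ccx[cl], 0.02 * width)
    py <- rnorm(config$n_plots, ccy[cl], 0.02 * height)
    px <- pmin(pmax(px, ext["xmin"]), ext["xmax"] - 1e-6)
    py <- pmin(pmax(py, ext["ymin"]), ext["ymax"] - 1e-6)
    area <- exp(runif(config$n_plots, log(config$plot_area_range[1]),
                      log(config$plot_area_range[2])))

    env01 <- env01_at(px, py)
    mu <- expected_richness(env01, area, config$richness_gradient_strength)
    alpha <- pmin(pmax(rpois(config$n_plots, mu), 1L), min(115L, n_sp))

    avail <- availability(px, py)
    species <- lapply(seq_len(config$n_plots), function(i) {
      sort(pool[sample.int(n_sp, alpha[i], prob = avail[i, ])])
    })

    plots <- data.frame(
      plot_id = sprintf("plot_%04d", seq_len(config$n_plots)),
      x = px, y = py, area = area
    )
    plots$species <- species

    ## --- occurrence records with spatially uneven density ---------------
    bias_field <- field_params()
    amp_total <- sum(bias_field$amp)
    n_occ <- config$n_occurrences
    ox <- oy <- numeric(0)
    if (n_occ > 0) {
      # rejection sampling against exp(bias * field01); field01 uses the
      # global amplitude bound so acceptance is batch-independent
      while (length(ox) < n_occ) {
        m <- max(2L * (n_occ - length(ox)), 100L)
        candx <- runif(m, ext["xmin"], ext["xmax"])
        candy <- runif(m, ext["ymin"], ext["ymax"])
        raw <- field_eval(bias_field, candx, candy)
        f01 <- (raw + amp_total) / (2 * amp_total)
        keep <- runif(m) < exp(config$occurrence_density_bias * (f01 - 1))
        ox <- c(ox, candx[keep])
        oy <- c(oy, candy[keep])
      }
      ox <- ox[seq_len(n_occ)]
      oy <- oy[seq_len(n_occ)]
      occ_avail <- availability(ox, oy)
      osp <- pool[vapply(seq_len(n_occ), function(i) {
        sample.int(n_sp, 1L, prob = occ_avail[i, ])
      }, integer(1))]
    } else {
      osp <- character(0)
    }

    basis <- ifelse(runif(n_occ) < 0.9, "HUMAN_OBSERVATION",
                    "PRESERVED_SPECIMEN")
    issues <- ifelse(runif(n_occ) < 0.05, "COORDINATE_ROUNDED", "")
    fossil <- runif(n_occ) < 0.02
    # inject dirty names: non-binomial and unmatched binomials
    dirty <- which(runif(n_occ) < 0.04)
    if (length(dirty)) {
      half <- dirty[seq_len(length(dirty) %/% 2L)]
      osp[half] <- sprintf("indetgenus%03d", seq_along(half))
      rest <- setdiff(dirty, half)
      osp[rest] <- sprintf("nomatchgenus%03d species001", seq_along(rest))
    }
    occurrences <- data.frame(
      species = osp, x = ox, y = oy,
      basis_of_record = basis, issue_flags = issues, is_fossil = fossil,
      stringsAsFactors = FALSE
    )

    ## --- checklist -------------------------------------------------------
    n_noise <- ceiling(config$checklist_noise * n_sp)
    checklist <- data.frame(
      accepted_name = c(pool,
                        sprintf("unusedgenus%03d species001", seq_len(n_noise))),
      stringsAsFactors = FALSE
    )

    truth <- data.frame(plot_id = plots$plot_id,
                        expected_richness = mu, env01 = env01,
                        realized_alpha = alpha)

    structure(list(config = config, layers = layers, plots = plots,
                   occurrences = occurrences, checklist = checklist,
                   truth = truth),
              class = "synthetic_landscape")
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat(sprintf(
    paste0("synthetic_landscape: %d plots, %d occurrence records, ",
           "%d env layers, pool of %d species\n"),
    nrow(x$plots), nrow(x$occurrences), length(x$layers),
    x$config$n_species_pool))
  invisible(x)
}

#' Write a landscape to disk as plain-text fixtures
#'
#' Writes `plots.csv` (wide layout: `plot_id, lon, lat, area_m2, species`
#' with a semicolon-joined species list), `occurrences.csv`,
#' `checklist.csv`, `truth.csv`, and one ESRI ASCII grid per environmental
#' layer under `rasters/`. Coordinates are stored as longitude/latitude
#' (inverse equal-area projection), matching the reader contract.
#'
#' @param landscape a [generate_landscape()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  if (!nrow(landscape$plots)) stop_divnn("landscape has no plots to write")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_divnn("cannot create output directory: %s", dir)

  ll <- cea_inverse(landscape$plots$x, landscape$plots$y)
  plots_out <- data.frame(
    plot_id = landscape$plots$plot_id,
    lon = sprintf("%.10f", ll$lon), lat = sprintf("%.10f", ll$lat),
    area_m2 = sprintf("%.6f", landscape$plots$area),
    species = vapply(landscape$plots$species, paste, character(1),
                     collapse = ";")
  )
  utils::write.csv(plots_out, file.path(dir, "plots.csv"), row.names = FALSE)

  oll <- cea_inverse(landscape$occurrences$x, landscape$occurrences$y)
  occ_out <- data.frame(
    species = landscape$occurrences$species,
    lon = sprintf("%.10f", oll$lon), lat = sprintf("%.10f", oll$lat),
    basis_of_record = landscape$occurrences$basis_of_record,
    issue_flags = landscape$occurrences$issue_flags,
    is_fossil = landscape$occurrences$is_fossil
  )
  utils::write.csv(occ_out, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(landscape$checklist, file.path(dir, "checklist.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(plot_id = landscape$truth$plot_id,
               expected_richness = sprintf("%.8f",
                                           landscape$truth$expected_richness),
               env01 = sprintf("%.8f", landscape$truth$env01),
               realized_alpha = landscape$truth$realized_alpha),
    file.path(dir, "truth.csv"), row.names = FALSE)

  rdir <- file.path(dir, "rasters")
  dir.create(rdir, showWarnings = FALSE)
  for (nm in names(landscape$layers)) {
    write_raster(landscape$layers[[nm]], file.path(rdir, paste0(nm, ".asc")))
  }
  invisible(dir)
}
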