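test_that("equal-area projection maps the origin and round-trips", {
  o <- cea_project(0, 0)
  expect_equal(c(o$x, o$y), c(0, 0))
  withr::with_seed(7, {
    lon <- runif(100, -180, 180)
    lat <- runif(100, -89, 89)
    xy <- cea_project(lon, lat)
    back <- cea_inverse(xy$x, xy$y)
    expect_equal(back$lon, lon, tolerance = 1e-9)
    expect_equal(back$lat, lat, tolerance = 1e-9)
  })
  expect_error(cea_project(0, 95), "latitude")
})

test_that("projected cell area matches spherical area at the standard parallel", {
  R <- 6371007.2
  for (parallel in c(-30, 0, 45)) {
    # 1 x 1 degree cell straddling the standard parallel
    lat1 <- parallel - 0.5
    lat2 <- parallel + 0.5
    corners <- cea_project(c(10, 11), c(lat1, lat2), parallel)
    proj_area <- abs(diff(corners$x)) * abs(diff(corners$y))
    # spherical area by numerical integration of R^2 cos(phi) dphi dlambda
    phi <- seq(lat1, lat2, length.out = 2001) * pi / 180
    sphere_area <- R^2 * (pi / 180) * sum(cos(phi)) * mean(diff(phi))
    expect_lt(abs(proj_area - sphere_area) / sphere_area, 0.005)
  }
})

test_that("occurrence filtering applies every stated rule", {
  checklist <- data.frame(accepted_name = c("acacia dealbata",
                                            "eucalyptus regnans"))
  occ <- data.frame(
    species = c("Acacia dealbata",      # kept
                "Eucalyptus",           # non-binomial
                "Acacia dealbata",      # fossil
                "Eucalyptus regnans",   # preserved specimen
                "Acacia dealbata",      # flagged
                "Banksia serrata"),     # not in checklist
    x = 1:6, y = 1:6,
    basis_of_record = c("HUMAN_OBSERVATION", "HUMAN_OBSERVATION",
                        "HUMAN_OBSERVATION", "PRESERVED_SPECIMEN",
                        "HUMAN_OBSERVATION", "HUMAN_OBSERVATION"),
    issue_flags = c("", "", "", "", "COORDINATE_ROUNDED", ""),
    is_fossil = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  kept <- filter_occurrences(occ, checklist)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$x, 1)
})

test_that("filtering matches an independent row-by-row predicate on random tables", {
  withr::with_seed(11, {
    pool <- sprintf("genus%02d species%02d", 1:20, 1:20)
    n <- 100
    occ <- data.frame(
      species = sample(c(pool, "solo", "bad name here",
                         "unknown species99"), n, replace = TRUE),
      x = runif(n), y = runif(n),
      basis_of_record = sample(c("HUMAN_OBSERVATION", "PRESERVED_SPECIMEN"),
                               n, TRUE),
      issue_flags = sample(c("", "", "", "ZERO_COORDINATE"), n, TRUE),
      is_fossil = runif(n) < 0.1)
    checklist <- data.frame(accepted_name = pool)
    kept <- filter_occurrences(occ, checklist)
    oracle <- vapply(seq_len(n), function(i) {
      nm <- tolower(trimws(occ$species[i]))
      !occ$is_fossil[i] &&
        occ$basis_of_record[i] == "HUMAN_OBSERVATION" &&
        occ$issue_flags[i] == "" &&
        length(strsplit(nm, " +")[[1]]) == 2 &&
        nm %in% tolower(pool)
    }, logical(1))
    expect_equal(nrow(kept), sum(oracle))
    # subset + idempotence
    expect_true(all(rownames(kept) %in% rownames(occ)))
    expect_identical(filter_occurrences(kept, checklist), kept)
  })
})

test_that("window counts respect half-open membership and count distinct species", {
  occ <- data.frame(species = c("a a", "a a", "b b", "c c", "a a", "d d", "e e"),
                    x = c(0, 1, -1, 4.999, -5, 5, 0),
                    y = c(0, 2, -2, 0, 0, 0, -5.0001))
  wc <- window_counts(occ, c(0, 0), window_side = 10)
  # inside: rows 1-4 and row 5 (x = -5 on the min edge, included);
  # excluded: x = +5 (max edge, half-open) and y just past the min edge
  expect_equal(unname(wc["n_records"]), 5)
  expect_equal(unname(wc["n_species"]), 3)  # a, b, c
  expect_error(window_counts(occ, c(0, 0), 0), "positive")
})

test_that("window counts equal an exhaustive scan and are translation-equivariant", {
  withr::with_seed(13, {
    occ <- data.frame(
      species = sample(sprintf("sp%02d", 1:25), 500, replace = TRUE),
      x = runif(500, -2e4, 2e4), y = runif(500, -2e4, 2e4))
    for (rep in 1:5) {
      center <- runif(2, -1e4, 1e4)
      expect_equal(window_counts(occ, center, 10000),
                   window_oracle(occ, center, 10000))
    }
    shift <- c(1234.5, -987.6)
    shifted <- occ
    shifted$x <- occ$x + shift[1]
    shifted$y <- occ$y + shift[2]
    center <- c(500, -300)
    expect_equal(window_counts(occ, center, 10000),
                 window_counts(shifted, center + shift, 10000))
  })
})

test_that("raster extraction is nearest-cell with nodata propagation", {
  r <- demo_raster()  # 4 x 5 cells of 10 m, values 1..20 row-wise from north
  # cell centres: top-left cell value 1 at (5, 35); bottom-left 16 at (5, 5)
  expect_equal(extract_raster_values(r, data.frame(x = 5, y = 35))$demo, 1)
  expect_equal(extract_raster_values(r, data.frame(x = 5, y = 5))$demo, 16)
  # anywhere within a cell hits that cell (x band 2, second row from north)
  expect_equal(extract_raster_values(r, data.frame(x = 19.99, y = 25))$demo, 7)
  # constant raster -> constant column
  const <- raster_layer(matrix(7, 3, 3), 0, 0, 10, name = "c7")
  pts <- data.frame(x = runif(10, 0, 29.9), y = runif(10, 0, 29.9))
  expect_true(all(extract_raster_values(const, pts)$c7 == 7))
  # nodata -> NA
  vals <- matrix(1:9, 3, 3)
  vals[2, 2] <- NA
  rna <- raster_layer(vals, 0, 0, 10, name = "na")
  expect_true(is.na(extract_raster_values(rna, data.frame(x = 15, y = 15))$na))
  # outside the extent errors and names the point
  expect_error(extract_raster_values(r, data.frame(x = 999, y = 5)),
               "x=999.*demo")
})

test_that("raster extraction matches floor index arithmetic on random points", {
  withr::with_seed(19, {
    r <- demo_raster(nrows = 8, ncols = 6, xll = -30, yll = 100, cs = 7)
    pts <- data.frame(x = runif(50, -30, -30 + 6 * 7 - 1e-9),
                      y = runif(50, 100, 100 + 8 * 7 - 1e-9))
    got <- extract_raster_values(r, pts)[[1]]
    oracle <- vapply(seq_len(50), function(i) {
      col <- floor((pts$x[i] - (-30)) / 7) + 1
      row_bottom <- floor((pts$y[i] - 100) / 7) + 1
      r$values[8 - row_bottom + 1, col]
    }, numeric(1))
    expect_equal(got, oracle)
  })
})

test_that("feature sets have the documented cardinalities and contents", {
  expect_length(feature_set_names("full27"), 27)
  expect_length(feature_set_names("subset8"), 8)
  expect_length(feature_set_names("subset6"), 6)
  expect_setequal(setdiff(feature_set_names("subset8"),
                          feature_set_names("subset6")),
                  c("longitude", "latitude"))
  expect_true(all(feature_set_names("subset6") %in%
                    feature_set_names("subset8")))
  expect_true(all(feature_set_names("subset8") %in%
                    feature_set_names("full27")))
})

test_that("assemble_features builds the expected columns from all sources", {
  land <- tiny_landscape(seed = 23, n_plots = 40)
  labels <- label_sites(land$plots, n = 6L)
  occ <- filter_occurrences(land$occurrences, land$checklist)

  full <- assemble_features(labels, land$plots, occ, land$layers, "full27")
  expect_identical(colnames(full$values), feature_set_names("full27"))
  expect_equal(unname(full$values[, "plot_size"]), land$plots$area)
  expect_equal(unname(full$values[, "radius"]), labels$radius)
  expect_equal(unname(full$values[, "longitude"]), land$plots$x)
  # sampling effort equals a direct window count at each site
  i <- 7
  wc <- window_counts(occ, c(land$plots$x[i], land$plots$y[i]), 10000)
  expect_equal(unname(full$values[i, "sampling_effort"]),
               unname(wc["n_records"]))
  expect_equal(unname(full$values[i, "sampled_species"]),
               unname(wc["n_species"]))

  sub6 <- assemble_features(labels, land$plots, NULL, land$layers, "subset6")
  expect_identical(colnames(sub6$values), feature_set_names("subset6"))
  expect_false(any(c("longitude", "latitude") %in% colnames(sub6$values)))

  # determinism / stable order
  again <- assemble_features(labels, land$plots, occ, land$layers, "full27")
  expect_identical(full$values, again$values)

  # missing raster layer errors by name
  expect_error(assemble_features(labels, land$plots, occ,
                                 land$layers[c("bio01", "elevation")],
                                 "subset6"),
               "human_footprint")
  expect_error(assemble_features(labels, land$plots, NULL, land$layers,
                                 "full27"), "occurrence")
})

test_that("min-max scaling fits on designated rows and flags out-of-range values", {
  ft <- structure(list(site_id = as.character(1:3),
                       values = matrix(c(0, 5, 10, 3, 3, 3), 3, 2,
                                       dimnames = list(NULL, c("a", "b"))),
                       feature_set = "subset6", scaler = NULL),
                  class = "feature_table")
  sc <- scale_features(ft)
  expect_equal(unname(sc$values[, "a"]), c(0, 0.5, 1))
  # constant column maps to 0
  expect_equal(unname(sc$values[, "b"]), c(0, 0, 0))
  expect_equal(sc$n_out_of_range, 0)

  # values outside the fitted range are not clipped and are counted
  ft2 <- ft
  ft2$values[3, "a"] <- 12
  sc2 <- apply_scaler(ft2, sc$scaler)
  expect_equal(unname(sc2$values[3, "a"]), 1.2)
  expect_equal(sc2$n_out_of_range, 1)

  # affine and order-preserving
  withr::with_seed(5, {
    v <- runif(20, -3, 9)
    ftr <- structure(list(site_id = as.character(1:20),
                          values = matrix(v, dimnames = list(NULL, "f")),
                          feature_set = "subset6", scaler = NULL),
                     class = "feature_table")
    scr <- scale_features(ftr)
    expect_equal(order(scr$values[, 1]), order(v))
    # affine: scaled = (v - min) / range exactly
    expect_equal(unname(scr$values[, 1]), (v - min(v)) / diff(range(v)),
                 tolerance = 1e-14)
  })
})
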