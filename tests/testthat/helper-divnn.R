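# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route (literal set arithmetic, exhaustive scans)
# than the implementation they check.

tiny_landscape <- function(seed = 11, n_plots = 120, n_occurrences = 800,
                           ...) {
  generate_landscape(landscape_config(seed = seed, n_plots = n_plots,
                                      n_occurrences = n_occurrences, ...))
}

# Random multi-site instance: list(focal =, neighbors = list of sets).
random_sets_instance <- function(n_sites = NULL, pool_size = 30) {
  pool <- sprintf("sp%02d", seq_len(pool_size))
  n_sites <- n_sites %||% sample(2:20, 1)
  sets <- replicate(n_sites, {
    sample(pool, sample.int(pool_size, 1))
  }, simplify = FALSE)
  list(focal = sets[[1]], neighbors = sets[-1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Literal set-arithmetic re-derivation of the multiple-site Sorensen
# dissimilarity: pairs between each neighbour i and the focal j = N+1.
beta_oracle <- function(focal, neighbors) {
  focal <- unique(focal)
  neighbors <- lapply(neighbors, unique)
  A <- B <- 0
  for (nb in neighbors) {
    b_ij <- length(setdiff(nb, focal))
    b_ji <- length(setdiff(focal, nb))
    A <- A + min(b_ij, b_ji)
    B <- B + max(b_ij, b_ji)
  }
  all_sites <- c(neighbors, list(focal))
  sum_S <- sum(vapply(all_sites, length, integer(1)))
  S_T <- length(Reduce(union, all_sites))
  (A + B) / (2 * (sum_S - S_T) + A + B)
}

# Exhaustive-scan window count oracle.
window_oracle <- function(occ, center, side) {
  n <- 0L
  sp <- character(0)
  for (i in seq_len(nrow(occ))) {
    if (occ$x[i] >= center[1] - side / 2 && occ$x[i] < center[1] + side / 2 &&
        occ$y[i] >= center[2] - side / 2 && occ$y[i] < center[2] + side / 2) {
      n <- n + 1L
      sp <- c(sp, tolower(trimws(occ$species[i])))
    }
  }
  c(n_records = n, n_species = length(unique(sp)))
}

# Ensemble with constant member outputs: member k always predicts
# values[k]. Single softplus layer with zero weights and a bias solving
# softplus(b) = value.
fake_ensemble <- function(values, n_features = 3L, label_scale = 1) {
  cfg <- divnn_config("beta", "subset6", hidden = 5L,
                      label_scale = label_scale)
  members <- lapply(values, function(v) {
    b <- log(expm1(v * label_scale))
    structure(list(
      layers = list(list(W = matrix(0, n_features, 1L), b = b)),
      best_layers = NULL, best_epoch = NA_integer_,
      history = data.frame(epoch = integer(0), train_mae = numeric(0),
                           val_mae = numeric(0)),
      config = cfg, feature_names = paste0("f", seq_len(n_features)),
      n_train = NA_integer_), class = "divnn")
  })
  structure(list(members = members, config = cfg,
                 epochs = 1L,
                 scaler = data.frame(feature = paste0("f", seq_len(n_features)),
                                     min = 0, max = 1),
                 feature_names = paste0("f", seq_len(n_features)),
                 n_members = length(values), base_seed = 0L),
            class = "divnn_ensemble")
}

# Small raster with known values for extraction tests.
demo_raster <- function(nrows = 4, ncols = 5, xll = 0, yll = 0, cs = 10,
                        name = "demo") {
  raster_layer(matrix(seq_len(nrows * ncols), nrows, ncols, byrow = TRUE),
               xll, yll, cs, name = name)
}
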