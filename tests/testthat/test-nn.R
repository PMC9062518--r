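test_that("split_data cuts 20/20/60 with disjoint exhaustive partitions", {
  sp <- split_data(7896, seed = 1)
  expect_length(sp$test, 1579)
  expect_length(sp$validation, 1579)
  expect_length(sp$train, 4738)

  sp10 <- split_data(10, seed = 2)
  expect_equal(lengths(sp10)[c("test", "validation", "train")],
               c(test = 2L, validation = 2L, train = 6L))

  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation, sp$test), 1:7896)

  sp_b <- split_data(7896, seed = 99)
  expect_false(identical(sp$test, sp_b$test))
  expect_equal(lengths(sp_b), lengths(sp))
  # same seed reproduces the same split
  expect_identical(split_data(7896, seed = 1), sp)
  expect_error(split_data(4), "at least 5")
})

test_that("label scaling multiplies, inverts exactly, and rejects bad scales", {
  expect_equal(scale_labels(100, 1 / 100), 1)
  expect_equal(scale_labels(800, 1 / 800), 1)
  expect_equal(scale_labels(0.42, 1), 0.42)
  v <- c(3.1, 57, 804.2)
  expect_equal(unscale_labels(scale_labels(v, 1 / 800), 1 / 800), v,
               tolerance = 1e-14)
  expect_error(scale_labels(1, 0), "positive")
  # metric defaults wired into the configuration
  expect_equal(divnn_config("alpha")$label_scale, 1 / 100)
  expect_equal(divnn_config("gamma")$label_scale, 1 / 800)
  expect_equal(divnn_config("beta")$label_scale, 1)
})

test_that("the network has the documented shape, parameter count, and positive outputs", {
  expect_equal(softplus(0), log(2))
  cfg <- divnn_config("gamma", "subset8", hidden = c(30L, 5L), seed = 3)
  x <- matrix(runif(80), 10, 8)
  fit <- divnn(x, rep(1, 10), cfg, epochs = 0)
  # 8*30+30 + 30*5+5 + 5*1+1 = 431 parameters
  expect_equal(sum(vapply(coef(fit), function(l) length(l$W) + length(l$b),
                          numeric(1))), 431)
  expect_equal(nrow(fit$history), 0)  # untrained at initialization
  preds <- predict(fit, matrix(rnorm(80, sd = 5), 10, 8))
  expect_true(all(preds > 0))
})

test_that("training is deterministic under a fixed seed, including dropout", {
  x <- matrix(runif(60), 20, 3)
  y <- 2 + 3 * x[, 1]
  for (dr in c(0, 0.3)) {
    cfg <- divnn_config("beta", "subset6", hidden = 8L, dropout = dr,
                        seed = 11)
    f1 <- divnn(x, y, cfg, validation = list(x = x, y = y), epochs = 15)
    f2 <- divnn(x, y, cfg, validation = list(x = x, y = y), epochs = 15)
    expect_identical(f1$history, f2$history)
    expect_identical(predict(f1, x), predict(f2, x))
  }
  # different seeds give different trajectories
  cfgb <- divnn_config("beta", "subset6", hidden = 8L, seed = 12)
  f3 <- divnn(x, y, cfgb, epochs = 15)
  expect_false(identical(
    divnn(x, y, divnn_config("beta", "subset6", hidden = 8L, seed = 11),
          epochs = 15)$history$train_mae,
    f3$history$train_mae))
})

test_that("a memorizable 5-instance set is fit to near-zero training loss", {
  x <- matrix(c(0.1, 0.3, 0.5, 0.7, 0.9,
                0.9, 0.7, 0.5, 0.3, 0.1), 5, 2)
  y <- c(120, 260, 380, 530, 710)  # gamma-scale labels
  cfg <- divnn_config("gamma", "subset6", hidden = c(30L, 5L), seed = 5,
                      learning_rate = 5e-3)
  fit <- divnn(x, y, cfg, epochs = 1500)
  expect_lt(fit$history$train_mae[1500], 0.01)  # scaled-label units
})

test_that("select_epoch rounds half-up to multiples of 50 with a floor", {
  h <- function(best, n = 2000) {
    data.frame(epoch = 1:n, val_mae = replace(rep(1, n), best, 0.1))
  }
  expect_equal(select_epoch(h(1483)), 1500)
  expect_equal(select_epoch(h(24)), 50)
  expect_equal(select_epoch(h(75)), 100)
  expect_equal(select_epoch(h(50)), 50)
  # ties break toward the earlier epoch
  tied <- data.frame(epoch = 1:300, val_mae = rep(1, 300))
  tied$val_mae[c(120, 280)] <- 0.2
  expect_equal(select_epoch(tied), 100)
  # always a positive multiple of 50
  withr::with_seed(3, {
    for (rep in 1:20) {
      hh <- data.frame(epoch = 1:500, val_mae = runif(500))
      e <- select_epoch(hh)
      expect_true(e >= 50 && e %% 50 == 0)
    }
  })
})

test_that("mape matches hand arithmetic and is scale-invariant", {
  expect_equal(as.numeric(mape(110, 100)), 10)
  expect_equal(as.numeric(mape(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(as.numeric(mape(c(1, 3), c(2, 2))), 50)
  m <- mape(c(1, 3, 9), c(2, 2, 0))
  expect_equal(as.numeric(m), 50)
  expect_equal(attr(m, "n_zero_truth"), 1)
  expect_error(mape(c(1, 2), c(0, 0)), "zero")
  # ratio invariance: scaled and unscaled labels give the same MAPE
  withr::with_seed(9, {
    truth <- runif(30, 10, 700)
    pred <- truth * runif(30, 0.5, 1.5)
    expect_equal(as.numeric(mape(pred, truth)),
                 as.numeric(mape(pred / 800, truth / 800)))
  })
})

test_that("the model-selection grid enumerates 3 x 4 x 3 configurations", {
  grid <- grid_configs()
  expect_equal(nrow(grid), 36)
  expect_equal(as.integer(table(grid$feature_set)), rep(12L, 3))
  # the 12 (nodes, dropout) combinations are identical per feature set
  combos <- split(paste(grid$nodes, grid$dropout), grid$feature_set)
  expect_true(all(vapply(combos, function(cmb) {
    setequal(cmb, combos[[1]]) && length(cmb) == 12
  }, logical(1))))
  expect_setequal(unique(grid$nodes),
                  c("30", "30,5", "30,15,5", "30,20,10,5"))
  expect_setequal(unique(grid$dropout), c(0, 0.1, 0.3))
})

test_that("a reduced grid search ranks by test MAPE and is reproducible", {
  land <- tiny_landscape(seed = 31, n_plots = 120)
  labels <- label_sites(land$plots, n = 8L)
  ft6 <- assemble_features(labels, land$plots, NULL, land$layers, "subset6")
  split <- split_data(nrow(labels), seed = 4)
  configs <- grid_configs(feature_sets = "subset6",
                          architectures = list(10L, c(10L, 5L)),
                          dropouts = 0)
  r1 <- grid_search(list(subset6 = ft6), labels$gamma, split, "gamma",
                    configs = configs, max_epochs = 40, seed = 8)
  expect_equal(nrow(r1), 2)
  expect_true(!is.unsorted(r1$mape))
  expect_true(all(r1$chosen_epoch %% 50 == 0 & r1$chosen_epoch >= 50))
  r2 <- grid_search(list(subset6 = ft6), labels$gamma, split, "gamma",
                    configs = configs, max_epochs = 40, seed = 8)
  expect_equal(r1$mape, r2$mape)
  best <- attr(r1, "best_fit")
  expect_s3_class(best, "divnn")
  expect_equal(min(r1$mape),
               as.numeric(mape(predict(best,
                                       scale_features(ft6, split$train)$values[
                                         split$test, , drop = FALSE],
                                       weights = "best"),
                               labels$gamma[split$test])))
})

test_that("ensembles train distinct, reproducible, positive members", {
  x <- matrix(runif(90), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 100 + 200 * x[, 1]
  ft <- structure(list(site_id = as.character(1:30), values = x,
                       feature_set = "subset6", scaler = NULL),
                  class = "feature_table")
  cfg <- divnn_config("gamma", "subset6", hidden = 8L, seed = 2)
  ens <- divnn_ensemble(ft, y, cfg, epochs = 30, n_members = 3,
                        base_seed = 100)
  expect_equal(ens$n_members, 3)
  w1 <- ens$members[[1]]$layers[[1]]$W
  w2 <- ens$members[[2]]$layers[[1]]$W
  expect_false(identical(w1, w2))
  preds <- predict(ens, scale_features(ft)$values)
  expect_equal(dim(preds), c(30, 3))
  expect_true(all(preds > 0))
  # reproducible member-by-member
  ens2 <- divnn_ensemble(ft, y, cfg, epochs = 30, n_members = 3,
                         base_seed = 100)
  expect_identical(ens$members[[2]]$layers, ens2$members[[2]]$layers)
  expect_error(divnn_ensemble(ft, y, cfg, epochs = 0), "positive")
})

test_that("ensemble bundles round-trip through the text serialization", {
  x <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- runif(10, 50, 500)
  ft <- structure(list(site_id = as.character(1:10), values = x,
                       feature_set = "subset6", scaler = NULL),
                  class = "feature_table")
  cfg <- divnn_config("gamma", "subset6", hidden = c(6L, 3L), dropout = 0.1,
                      seed = 7)
  ens <- divnn_ensemble(ft, y, cfg, epochs = 10, n_members = 2)
  dir <- file.path(tempdir(), "bundle")
  save_ensemble(ens, dir)
  back <- load_ensemble(dir)
  expect_equal(back$config$hidden, cfg$hidden)
  expect_equal(back$config$label_scale, cfg$label_scale)
  expect_equal(back$scaler, ens$scaler)
  newx <- matrix(runif(15), 5, 3)
  expect_equal(predict(back, newx), predict(ens, newx), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
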