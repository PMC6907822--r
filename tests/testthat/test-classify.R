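# Small deterministic fixture: smoothed-ish curves for a one-year scene
toy_samples <- function(n_per_class = 50, seed = 5) {
  set.seed(seed)
  doys <- seq(1, by = 8, length.out = 46)
  flat <- rep(1000, 46)
  bimodal <- 1500 + 5000 * exp(-(doys - 115)^2 / (2 * 22^2)) +
    4500 * exp(-(doys - 224)^2 / (2 * 18^2))
  mk <- function(curve, code, jitter) {
    X <- t(replicate(n_per_class, curve + rnorm(46, 0, jitter)))
    colnames(X) <- paste0("node", 1:46)
    cbind(data.frame(class = code, year = 2016,
                     row = seq_len(n_per_class), col = code), X)
  }
  rbind(mk(bimodal, 1L, 100), mk(flat, 4L, 100))
}

test_that("grid allocation tiles the extent and stratifies per class", {
  # 100 km x 100 km at 250 m = 400 x 400 pixels; 50 km grid -> 4 tiles
  set.seed(1)
  labels <- matrix(sample.int(5L, 400 * 400, replace = TRUE), 400, 400)
  tm <- class_map(labels, year = 2016)
  pts <- grid_allocate(tm, grid_size_m = 50000, per_class_per_tile = 5, seed = 2)
  expect_equal(length(unique(pts$tile)), 4)
  # 4 tiles x 5 classes x 5 points
  expect_equal(nrow(pts), 100)
  expect_true(all(table(pts$tile, pts$class) == 5))
  expect_identical(pts$class, tm$labels[cbind(pts$row, pts$col)])

  # determinism and seed sensitivity
  pts2 <- grid_allocate(tm, grid_size_m = 50000, per_class_per_tile = 5, seed = 2)
  expect_identical(pts, pts2)

  # single-class truth: all labels identical
  tm1 <- class_map(matrix(3L, 20, 20), year = 2016)
  p1 <- grid_allocate(tm1, grid_size_m = 2500, seed = 1)
  expect_true(all(p1$class == 3L))
  expect_error(grid_allocate(tm, grid_size_m = -1), "positive")
})

test_that("class signatures report per-node mean and sample SD", {
  s <- toy_samples(n_per_class = 2)
  s[grep("^node", names(s))] <- 0
  s[1, "node1"] <- 4000; s[2, "node1"] <- 6000
  s <- s[s$class == 1L | s$class == 4L, ]
  sig <- class_signatures(s)
  wm <- sig[["1"]]
  expect_equal(unname(wm$mean_curve["node1"]), 5000)
  expect_equal(unname(wm$sd_curve["node1"]), sd(c(4000, 6000)))  # 1414.2, sample SD
  expect_true(all(sig[["4"]]$sd_curve == 0))

  # synthetic wheat-maize signature peaks inside the wheat DOY window
  sc <- small_scene(seed = 41, cloud_prob = 0, n = 16)
  st <- interleave_stacks(sc$stack_a, sc$stack_b)
  samp <- build_samples(st, sc$truth, 2004, grid_size_m = 2000, seed = 4)
  sig <- class_signatures(samp)
  node_peak <- which.max(sig[["1"]]$mean_curve)
  peak_doy <- st$calendar$doy[node_peak]
  expect_true(peak_doy >= 60 && peak_doy <= 170)
})

test_that("random forest trains on bootstrap trees with sqrt feature sampling", {
  s <- toy_samples()
  m <- train_classifier(s, seed = 9)
  expect_equal(m$mtry, 6)  # floor(sqrt(46))
  expect_equal(m$n_trees, 100)
  # linearly separable toy: perfect vote accuracy on the training set
  X <- as.matrix(s[grep("^node", names(s))])
  pred <- doublecrop:::predict_codes(m, X)
  expect_equal(pred, s$class)
  expect_error(train_classifier(s[s$class == 1L, ]), "single class")
})

test_that("training is invariant to sample order and duplicates never hurt recall", {
  s <- toy_samples()
  m1 <- train_classifier(s, seed = 7)
  m2 <- train_classifier(s[sample(nrow(s)), ], seed = 7)
  X <- as.matrix(s[grep("^node", names(s))])
  expect_identical(doublecrop:::predict_codes(m1, X),
                   doublecrop:::predict_codes(m2, X))

  dup <- rbind(s, s[s$class == 1L, ][1:20, ])
  m3 <- train_classifier(dup, seed = 7)
  recall <- function(m) mean(doublecrop:::predict_codes(m, X[s$class == 1L, ]) == 1L)
  expect_gte(recall(m3), recall(m1))
})

test_that("predict_map labels whole scenes with deterministic tie-breaks", {
  # constant-water scene classifies as all water
  sc <- generate_scene(scene_spec(
    n_rows = 10, n_cols = 10, years = c(2016, 2016), seed = 3,
    cloud_prob = 0,
    class_fractions = c(wheat_maize = 0, one_season = 0, forest_grass = 0,
                        water = 1, built_up = 0)))
  st <- interleave_stacks(sc$stack_a, sc$stack_b)
  s <- toy_samples()
  m <- train_classifier(s, seed = 2)
  mp <- predict_map(m, st, 2016)
  expect_true(all(mp$labels == 4L))
  expect_equal(mp$year, 2016L)
  expect_error(predict_map(m, st, 2015), "2015")
})

test_that("held-out accuracy on a default synthetic scene is high", {
  sc <- small_scene(seed = 55, cloud_prob = 0.1, years = c(2016, 2016), n = 32)
  st <- interleave_stacks(sc$stack_a, sc$stack_b)
  sm <- hants_stack(fill_stack(st))
  samp <- build_samples(sm, sc$truth, 2016, grid_size_m = 2000,
                        per_class_per_tile = 4, seed = 6)
  m <- train_classifier(samp, seed = 6)
  mp <- predict_map(m, sm, 2016)
  rep <- accuracy_summary(confusion(mp, sc$reference_points))
  expect_gte(rep$overall_accuracy, 90)
})
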