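# Texture features, balanced subsampling, decision-tree training.

test_that("constant image yields zero entropy, std and range everywhere", {
  tf <- compute_texture_features(matrix(37, 64, 64))
  expect_true(all(tf$entropy == 0))
  expect_true(all(tf$std == 0))
  expect_true(all(tf$range == 0))
})

test_that("checkerboard range filter and Gaussian mass conservation", {
  M <- 12
  chk <- M * outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  tf <- compute_texture_features(chk, range_window = 3)
  # every 3x3 window of a checkerboard contains both levels
  expect_true(all(tf$range == M))
  # unit impulse: sigma = 5 smoothing conserves mass away from borders
  imp <- matrix(0, 64, 64); imp[32, 32] <- 1
  tfi <- compute_texture_features(imp, sigma = 5)
  expect_equal(sum(tfi$gaussian), 1, tolerance = 1e-10)
})

test_that("features are translation-equivariant away from borders", {
  # two crops of one image, offset by (5, 7); interior features must agree
  # exactly.  Values span the full 0..255 range in both crops so the entropy
  # quantization grid is identical.
  set.seed(42)
  big <- matrix(sample(0:255, 120 * 120, replace = TRUE), 120, 120)
  big[40, 40] <- 0; big[41, 41] <- 255
  a <- big[1:96, 1:96]
  b <- big[6:101, 8:103]
  f1 <- compute_texture_features(a)
  f2 <- compute_texture_features(b)
  inner_r <- 28:70; inner_c <- 30:70   # >= 21 px from every crop border
  for (feat in c("entropy", "std", "range", "gaussian"))
    expect_equal(f2[[feat]][inner_r - 5, inner_c - 7],
                 f1[[feat]][inner_r, inner_c], tolerance = 1e-10,
                 label = feat)
})

test_that("balanced subsampling honors the per-image budget and class balance", {
  # reference-geometry budget: floor(0.025 * 1024 * 1344) = 34406
  lab <- matrix(0L, 1024, 1344)
  lab[1:200, ] <- 3L
  feats <- structure(list(entropy = matrix(0, 1024, 1344),
                          std = matrix(0, 1024, 1344),
                          range = matrix(0, 1024, 1344),
                          gaussian = matrix(0, 1024, 1344),
                          params = list()), class = "texture_features")
  ts <- subsample_balanced(feats, lab, fraction = 0.025, seed = 1)
  expect_equal(nrow(ts$x), 34406L)
  expect_lte(abs(sum(ts$y == 0L) - sum(ts$y == 3L)), 1L)

  # 90/10 prevalence, budget 1000 -> 500 from each class
  set.seed(2)
  lab2 <- matrix(ifelse(runif(100 * 100) < 0.9, 0L, 3L), 100, 100)
  f2 <- structure(list(entropy = matrix(rnorm(1e4), 100),
                       std = matrix(rnorm(1e4), 100),
                       range = matrix(rnorm(1e4), 100),
                       gaussian = matrix(rnorm(1e4), 100),
                       params = list()), class = "texture_features")
  ts2 <- subsample_balanced(f2, lab2, fraction = 0.1, seed = 3)
  expect_equal(unname(ts2$counts[1, ]), c(500L, 500L))

  # exhausted class is sampled fully with recorded shortfall
  lab3 <- lab2; lab3[] <- 0L; lab3[1:10] <- 3L
  ts3 <- subsample_balanced(f2, lab3, fraction = 0.1, seed = 3)
  expect_equal(unname(ts3$counts[1, "3"]), 10L)
  expect_equal(unname(ts3$shortfall[1, "3"]), 490L)

  # determinism
  ts2b <- subsample_balanced(f2, lab2, fraction = 0.1, seed = 3)
  expect_identical(ts2$x, ts2b$x)
  expect_error(subsample_balanced(f2, matrix(0L, 100, 100), 0.1, 1),
               "two classes")
})

test_that("tree training separates a linearly separable toy set perfectly", {
  set.seed(5)
  n <- 400
  x <- cbind(entropy = runif(n), std = runif(n), range = runif(n),
             gaussian = runif(n))
  y <- ifelse(x[, "std"] > 0.5, 3L, 0L)
  ts <- structure(list(x = x, y = y, classes = c(0L, 3L),
                       feature_names = colnames(x), fraction = 1, seed = 1L),
                  class = "pixel_training_set")
  model <- train_pixel_classifier(ts, seed = 1)
  expect_equal(model$training_accuracy, 1)
  expect_identical(predict(model, x), y)
  # same data and seed -> identical tree and predictions
  model2 <- train_pixel_classifier(ts, seed = 1)
  expect_identical(model$tree, model2$tree)
  expect_error(train_pixel_classifier(
    structure(list(x = x, y = rep(0L, n), classes = 0L,
                   feature_names = colnames(x)),
              class = "pixel_training_set")), "class")
})

test_that("synthetic training reaches high accuracy and models round-trip", {
  model <- fixture_model()
  expect_gte(model$training_accuracy, 0.95)
  p <- withr::local_tempfile(fileext = ".json")
  save_pixel_classifier(model, p)
  back <- load_pixel_classifier(p)
  sc <- fixture_train_scenes()[[1]]
  tf <- compute_texture_features(sc$alpha_actinin)
  expect_identical(classify_foreground(model, tf),
                   classify_foreground(back, tf))
  # feature-name mismatch is an error
  bad <- feature_matrix_for_test <- tf$entropy
  x <- cbind(a = as.vector(tf$entropy), b = 1, c = 2, d = 3)
  expect_error(predict(model, x), "feature names")
})

test_that("blank field classifies almost entirely as background", {
  model <- fixture_model()
  blank <- generate_scene(scene_spec(cells = list(), seed = 12))
  tf <- compute_texture_features(blank$alpha_actinin)
  lab <- classify_foreground(model, tf)
  expect_gte(mean(lab == 0L), 0.99)
  expect_true(all(lab %in% c(0L, 3L)))
})

test_that("foreground IoU on held-out scenes reaches 0.8 at SNR 5", {
  model <- fixture_model()
  ws <- generate_wellset(2, 0.5, cells_per_well = 8, base_seed = 200,
                         other_fraction = 0.3)
  for (sc in ws$scenes) {
    tf <- compute_texture_features(sc$alpha_actinin)
    fg <- classify_foreground(model, tf) != 0
    truth <- sc$truth_class != 0
    expect_gte(sum(fg & truth) / sum(fg | truth), 0.8)
  }
})
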