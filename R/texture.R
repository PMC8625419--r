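# Background/foreground pixel classification of alpha-actinin images:
# four texture features (local entropy, local standard deviation, local
# range, Gaussian-smoothed intensity with sigma = 5) feed a CART decision
# tree whose depth/leaf-size hyperparameters are chosen by seeded k-fold
# cross-validated grid search.

TEXTURE_FEATURES <- c("entropy", "std", "range", "gaussian")

#' Compute per-pixel texture features
#'
#' Produces the four feature planes used by the pixel classifier: local
#' entropy (on 8-bit-quantized intensities, 256 bins), local standard
#' deviation, local range, and the Gaussian-filtered image (`sigma = 5` by
#' default).  Borders are handled by reflection padding.  Features are
#' computed on the raw intensities: per-image z-scoring (`standardize =
#' TRUE`) makes a blank field indistinguishable from a dim one, inflating
#' noise into the foreground range, so it is off by default and available
#' only for exposure-mismatched acquisitions.
#'
#' @param img [channel_image] or numeric matrix.
#' @param entropy_window,std_window,range_window odd window sizes.
#' @param sigma Gaussian smoothing SD.
#' @param standardize z-score the image before filtering (see above).
#' @return Object of class `texture_features`: a list of four same-shape
#'   matrices plus the parameters.
#' @export
compute_texture_features <- function(img, entropy_window = 9, std_window = 5,
                                     range_window = 5, sigma = 5,
                                     standardize = FALSE) {
  m <- if (inherits(img, "channel_image")) img$pixels else as.matrix(img)
  for (w in c(entropy_window, std_window, range_window)) {
    if (w %% 2 == 0) stop("window sizes must be odd")
    if (w > min(dim(m))) stop("window larger than image")
  }
  if (standardize) {
    s <- sd(m)
    m <- if (s > 0) (m - mean(m)) / s else m * 0
  }
  rngv <- range(m)
  if (diff(rngv) > 0) {
    q <- matrix(as.integer(pmin(floor((m - rngv[1]) / diff(rngv) * 256), 255)),
                nrow(m), ncol(m))
  } else {
    q <- matrix(0L, nrow(m), ncol(m))
  }
  ent <- cpp_local_entropy(q, as.integer(entropy_window), 256L)
  st <- cpp_local_stats(m, as.integer(std_window))$std
  rg <- cpp_local_stats(m, as.integer(range_window))$range
  ga <- cpp_gaussian_blur(m, sigma)
  structure(list(entropy = ent, std = st, range = rg, gaussian = ga,
                 params = list(entropy_window = entropy_window,
                               std_window = std_window,
                               range_window = range_window, sigma = sigma,
                               standardize = standardize)),
            class = "texture_features")
}

#' @export
dim.texture_features <- function(x) dim(x$entropy)

# flatten a texture_features object into an n_pixels x 4 matrix
feature_matrix <- function(tf) {
  stopifnot(inherits(tf, "texture_features"))
  cbind(entropy = as.vector(tf$entropy), std = as.vector(tf$std),
        range = as.vector(tf$range), gaussian = as.vector(tf$gaussian))
}

#' Balanced subsampling of labeled pixels
#'
#' Draws a per-image budget of `floor(fraction * n_pixels)` pixels, split
#' equally across classes (counts differ by at most one); a class with fewer
#' pixels than its share is sampled exhaustively and the shortfall recorded.
#' For the reference 1024 x 1344 image at the default 2.5% this budget is
#' 34406 pixels.
#'
#' @param features a `texture_features` object or list of them (one per
#'   image).
#' @param labels integer class-label matrix or list of matrices.
#' @param fraction per-image sampling fraction in `(0, 1]`.
#' @param seed RNG seed; identical seeds select identical pixels.
#' @return Object of class `pixel_training_set` with fields `x` (n x 4
#'   feature matrix), `y` (integer class codes), `classes`, `counts`,
#'   `shortfall`, `fraction`, `seed`.
#' @export
subsample_balanced <- function(features, labels, fraction = 0.025, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (inherits(features, "texture_features")) features <- list(features)
  if (is.matrix(labels)) labels <- list(labels)
  stopifnot(length(features) == length(labels))
  classes <- sort(unique(unlist(lapply(labels, function(l) unique(as.vector(l))))))
  if (length(classes) < 2)
    stop("labels must cover at least two classes")
  k <- length(classes)
  xs <- list(); ys <- list()
  counts <- matrix(0L, length(features), k,
                   dimnames = list(NULL, as.character(classes)))
  shortfall <- counts
  with_seed(seed, {
    for (i in seq_along(features)) {
      lab <- as.vector(labels[[i]])
      fm <- feature_matrix(features[[i]])
      stopifnot(nrow(fm) == length(lab))
      budget <- floor(fraction * length(lab))
      share <- rep(budget %/% k, k) + as.integer(seq_len(k) <= budget %% k)
      sel <- integer(0)
      for (j in seq_len(k)) {
        pool <- which(lab == classes[j])
        take <- min(share[j], length(pool))
        shortfall[i, j] <- share[j] - take
        if (take > 0) {
          pick <- if (length(pool) == take) pool else sample(pool, take)
          sel <- c(sel, pick)
          counts[i, j] <- take
        }
      }
      xs[[i]] <- fm[sel, , drop = FALSE]
      ys[[i]] <- lab[sel]
    }
  })
  structure(list(x = do.call(rbind, xs), y = unlist(ys),
                 classes = classes, counts = counts, shortfall = shortfall,
                 fraction = fraction, seed = as.integer(seed),
                 feature_names = TEXTURE_FEATURES),
            class = "pixel_training_set")
}

#' @export
print.pixel_training_set <- function(x, ...) {
  cat(sprintf("<pixel_training_set> %d pixels, classes {%s}, fraction %.3g\n",
              nrow(x$x), paste(x$classes, collapse = ", "), x$fraction))
  invisible(x)
}

cart_accuracy <- function(tree, x, y01) mean(cpp_cart_predict(tree, x) == y01)

#' Train the pixel classifier
#'
#' Fits a CART decision tree to a balanced training set.  The automatic
#' hyperparameter optimization of the original workflow is stood in for by a
#' seeded k-fold cross-validated grid search over tree depth and minimum leaf
#' size; the chosen tree is refit on the full training set and its training
#' accuracy stored.
#'
#' @param training_set a [subsample_balanced()] result.
#' @param search named list with `max_depth` and `min_leaf` candidate vectors.
#' @param k_folds folds for cross-validation.
#' @param seed RNG seed for fold assignment.
#' @return Object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(training_set,
                                   search = list(max_depth = c(4, 6, 8, 12, 16),
                                                 min_leaf = c(1, 5, 20, 100)),
                                   k_folds = 5, seed = 1L) {
  stopifnot(inherits(training_set, "pixel_training_set"))
  classes <- training_set$classes
  if (length(classes) < 2) stop("degenerate single-class training set")
  x <- training_set$x
  y01 <- match(training_set$y, classes) - 1L
  n <- nrow(x)
  grid <- expand.grid(max_depth = search$max_depth, min_leaf = search$min_leaf)
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  cv_acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    accs <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      tree <- cpp_cart_train(x[tr, , drop = FALSE], y01[tr], length(classes),
                             grid$max_depth[g], grid$min_leaf[g])
      cart_accuracy(tree, x[!tr, , drop = FALSE], y01[!tr])
    }, 0)
    cv_acc[g] <- mean(accs)
  }
  best <- which.max(cv_acc)
  tree <- cpp_cart_train(x, y01, length(classes),
                         grid$max_depth[best], grid$min_leaf[best])
  structure(list(tree = lapply(tree, as.vector),
                 classes = classes,
                 feature_names = training_set$feature_names,
                 hyper = list(max_depth = grid$max_depth[best],
                              min_leaf = grid$min_leaf[best]),
                 cv_accuracy = cv_acc[best],
                 training_accuracy = cart_accuracy(tree, x, y01),
                 seed = as.integer(seed)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf(paste0("<pixel_classifier> CART, depth<=%d, min leaf %d, ",
                     "training accuracy %.4f\n"),
              x$hyper$max_depth, x$hyper$min_leaf, x$training_accuracy))
  invisible(x)
}

#' @param object a `pixel_classifier`.
#' @param newdata `texture_features` object or n x 4 feature matrix with
#'   matching column names.
#' @param ... unused.
#' @return Integer class codes (matrix if `newdata` is a feature stack).
#' @rdname train_pixel_classifier
#' @export
predict.pixel_classifier <- function(object, newdata, ...) {
  as_stack <- inherits(newdata, "texture_features")
  fm <- if (as_stack) feature_matrix(newdata) else as.matrix(newdata)
  if (!identical(colnames(fm), object$feature_names))
    stop("feature names do not match the model: expected ",
         paste(object$feature_names, collapse = ", "))
  pred <- object$classes[cpp_cart_predict(object$tree, fm) + 1L]
  if (as_stack) matrix(as.integer(pred), nrow(newdata$entropy),
                       ncol(newdata$entropy))
  else as.integer(pred)
}

#' Classify image foreground
#'
#' Applies the pixel classifier to a feature stack and collapses every
#' non-background prediction to the Foreground-unresolved code; resolution
#' into Striated Myocyte vs Other is structural and happens in
#' [classify_striated_superpixels()].
#'
#' @param model a `pixel_classifier`.
#' @param features `texture_features` of the alpha-actinin image.
#' @return Integer label map with codes `{0, 3}` (Background /
#'   Foreground-unresolved).
#' @export
classify_foreground <- function(model, features) {
  pred <- predict(model, features)
  codes <- class_codes()
  out <- matrix(codes[["background"]], nrow(pred), ncol(pred))
  out[pred != codes[["background"]]] <- codes[["foreground"]]
  storage.mode(out) <- "integer"
  out
}

#' Serialize / restore a pixel classifier
#'
#' JSON round trip preserving exact split thresholds, so a reloaded model
#' yields identical predictions.
#'
#' @param model a `pixel_classifier`.
#' @param path JSON file path.
#' @export
save_pixel_classifier <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_pixel_classifier
#' @export
load_pixel_classifier <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  obj$tree <- lapply(obj$tree, as.vector)
  obj$hyper <- lapply(obj$hyper, as.vector)
  obj$classes <- as.integer(obj$classes)
  obj$feature_names <- as.character(obj$feature_names)
  structure(obj, class = "pixel_classifier")
}

#' Train a texture model from synthetic scenes
#'
#' Convenience wrapper: computes features for each alpha-actinin image,
#' collapses truth labels to Background vs Foreground, balanced-samples and
#' trains the classifier.
#'
#' @param scenes list of [generate_scene()] outputs.
#' @param fraction,seed see [subsample_balanced()].
#' @param config parameter list, see [myotype_config()].
#' @return A `pixel_classifier`.
#' @export
train_texture_model <- function(scenes, fraction = 0.025, seed = 1L,
                                config = myotype_config()) {
  feats <- lapply(scenes, function(s)
    compute_texture_features(s$alpha_actinin,
                             entropy_window = config$entropy_window,
                             std_window = config$std_window,
                             range_window = config$range_window,
                             sigma = config$feature_sigma))
  labs <- lapply(scenes, function(s) {
    l <- matrix(class_codes()[["background"]], nrow(s$truth_class),
                ncol(s$truth_class))
    l[s$truth_class != 0L] <- class_codes()[["foreground"]]
    storage.mode(l) <- "integer"
    l
  })
  ts <- subsample_balanced(feats, labs, fraction = fraction, seed = seed)
  train_pixel_classifier(ts, search = config$tree_search,
                         k_folds = config$cv_folds, seed = seed)
}
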