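#' Allocate training/validation points on a coarse spatial grid
#'
#' Tiles the map extent into square grid cells (default 50 km, i.e.
#' 50,000 m x 50,000 m) and samples a fixed number of labelled points per
#' class within every cell that contains that class. Stratifying by a
#' coarse grid spreads the training set across regional growing-condition
#' gradients instead of letting one subregion dominate.
#'
#' @param truth A [class_map()] supplying the labels (a reference map for
#'   real use, the known truth for synthetic scenes).
#' @param grid_size_m Grid cell side in metres (default 50,000).
#' @param per_class_per_tile Points sampled per class per tile (default 5);
#'   tiles holding fewer pixels of a class contribute what they have.
#' @param seed Integer seed; sampling is deterministic given it.
#' @return Data frame of sample points: `row`, `col`, `x`, `y`, `class`
#'   (integer code), `tile`.
#' @export
grid_allocate <- function(truth, grid_size_m = 50000, per_class_per_tile = 5,
                          seed = 1L) {
  stopifnot(inherits(truth, "class_map"))
  if (grid_size_m <= 0) stop("grid_size_m must be positive")
  nr <- nrow(truth$labels); nc <- ncol(truth$labels)
  if (nr == 0 || nc == 0) stop("empty map extent")
  px <- truth$pixel_size_m
  cells_per_tile <- max(1L, as.integer(round(grid_size_m / px)))
  tile_row <- ceiling(seq_len(nr) / cells_per_tile)
  tile_col <- ceiling(seq_len(nc) / cells_per_tile)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  idx$tile <- paste(tile_row[idx$row], tile_col[idx$col], sep = "_")
  idx$class <- truth$labels[cbind(idx$row, idx$col)]
  picked <- do.call(rbind, lapply(split(idx, idx[c("tile", "class")], drop = TRUE),
    function(g) g[sample.int(nrow(g), min(per_class_per_tile, nrow(g))), ]))
  picked <- picked[order(picked$tile, picked$class, picked$row, picked$col), ]
  rownames(picked) <- NULL
  xy <- pixel_xy(truth$geotransform, picked$row, picked$col)
  data.frame(row = picked$row, col = picked$col, x = xy$x, y = xy$y,
             class = picked$class, tile = picked$tile,
             stringsAsFactors = FALSE)
}

# Feature matrix: one row per point, columns = that year's nodes.
extract_features <- function(stack, points, year) {
  idx <- which(stack$calendar$year == year)
  if (length(idx) == 0) stop("stack has no nodes for year ", year)
  d <- dim(stack$values)
  V <- matrix(stack$values[idx, , ], length(idx), d[2] * d[3])
  pix <- (points$col - 1L) * d[2] + points$row
  X <- t(V[, pix, drop = FALSE])
  colnames(X) <- paste0("node", seq_along(idx))
  X
}

#' Build labelled phenology samples over one or more years
#'
#' Combines [grid_allocate()] locations with per-year smoothed curves: each
#' sample carries the full vector of that year's nodes as its feature
#' vector, so samples from different years are pooled by relative node
#' position.
#'
#' @param stack Smoothed [ndvi_stack()].
#' @param truth Per-year list of [class_map()]s (or a single map reused for
#'   every year).
#' @param years Years to sample from.
#' @param ... Passed to [grid_allocate()].
#' @return Data frame with `class`, `year`, location columns and
#'   `node1..nodeK` feature columns.
#' @export
build_samples <- function(stack, truth, years, ...) {
  out <- lapply(years, function(y) {
    tm <- if (inherits(truth, "class_map")) truth else truth[[as.character(y)]]
    pts <- grid_allocate(tm, ...)
    X <- extract_features(stack, pts, y)
    cbind(data.frame(class = pts$class, year = y, row = pts$row,
                     col = pts$col, x = pts$x, y_coord = pts$y), X)
  })
  do.call(rbind, out)
}

#' Per-class mean and standard-deviation phenology signatures
#'
#' The per-node mean curve of a class is its interpretation key: the
#' double-cropping rotation shows the characteristic bimodal curve, and the
#' per-node sample standard deviation quantifies how stable the signature
#' is across the landscape.
#'
#' @param samples Data frame from [build_samples()] (needs `class` and
#'   `node*` columns).
#' @return List of signatures, one per class present: each has
#'   `class_label`, `n`, `mean_curve` and `sd_curve` (sample SD).
#' @export
class_signatures <- function(samples) {
  node_cols <- grep("^node", names(samples), value = TRUE)
  if (length(node_cols) == 0) stop("samples carry no node feature columns")
  out <- lapply(split(samples, samples$class), function(g) {
    if (nrow(g) < 2) {
      warning("class ", g$class[1], " has fewer than 2 samples; SD undefined")
    }
    X <- as.matrix(g[node_cols])
    list(class_label = crop_classes()[g$class[1]], n = nrow(g),
         mean_curve = colMeans(X),
         sd_curve = apply(X, 2, stats::sd))
  })
  structure(out, class = "class_signatures")
}

#' @export
print.class_signatures <- function(x, ...) {
  for (s in x) {
    cat(sprintf("%-12s n=%4d  mean NDVI peak %5.0f at node %d\n",
                s$class_label, s$n, max(s$mean_curve),
                which.max(s$mean_curve)))
  }
  invisible(x)
}

#' Train the random-forest phenology classifier
#'
#' An ensemble of decision trees, each grown on a bootstrap sample of the
#' training points with `floor(sqrt(n_features))` candidate features per
#' split, predicting by majority vote. Defaults: 100 trees over the 46-node
#' annual curve (6 candidate features per split).
#'
#' @param samples Data frame from [build_samples()].
#' @param n_trees Number of trees (default 100).
#' @param seed Integer seed for reproducible tree growing.
#' @return A `crop_classifier` wrapping the fitted forest.
#' @export
train_classifier <- function(samples, n_trees = 100L, seed = 1L) {
  node_cols <- grep("^node", names(samples), value = TRUE)
  # canonical sample order: predictions are invariant to the order the
  # caller assembled the training set in
  key_cols <- intersect(c("class", "year", "row", "col"), names(samples))
  samples <- samples[do.call(order, samples[key_cols]), , drop = FALSE]
  classes <- sort(unique(samples$class))
  if (length(classes) < 2) stop("training set has a single class; need >= 2")
  X <- as.matrix(samples[node_cols])
  y <- factor(samples$class, levels = seq_along(crop_classes()))
  y <- droplevels(y)
  mtry <- max(1L, floor(sqrt(length(node_cols))))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  forest <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                       mtry = mtry)
  structure(list(forest = forest, node_cols = node_cols, mtry = mtry,
                 n_trees = n_trees, classes = as.integer(levels(y))),
            class = "crop_classifier")
}

#' @export
print.crop_classifier <- function(x, ...) {
  cat(sprintf("<crop_classifier> %d trees, %d features, mtry=%d, classes: %s\n",
              x$n_trees, length(x$node_cols), x$mtry,
              paste(crop_classes()[x$classes], collapse = ", ")))
  invisible(x)
}

# Vote-based prediction with deterministic tie-break: among tied top vote
# counts the lowest class code wins.
predict_codes <- function(model, X) {
  votes <- stats::predict(model$forest, X, type = "vote", norm.votes = FALSE)
  top <- max.col(votes, ties.method = "first")
  model$classes[top]
}

#' Classify every pixel of one year into the five classes
#'
#' Applies the trained forest to each pixel's smoothed annual curve.
#' Vote ties are broken deterministically towards the lowest class code.
#'
#' @param model A [train_classifier()] model.
#' @param stack Smoothed [ndvi_stack()] covering the year's nodes.
#' @param year Year to classify.
#' @return A [class_map()] for that year.
#' @export
predict_map <- function(model, stack, year) {
  idx <- which(stack$calendar$year == year)
  if (length(idx) != length(model$node_cols)) {
    stop("stack provides ", length(idx), " nodes for year ", year,
         " but the model expects ", length(model$node_cols))
  }
  d <- dim(stack$values)
  X <- t(matrix(stack$values[idx, , ], length(idx), d[2] * d[3]))
  colnames(X) <- model$node_cols
  codes <- rep(NA_integer_, nrow(X))
  ok <- stats::complete.cases(X)
  if (any(ok)) codes[ok] <- predict_codes(model, X[ok, , drop = FALSE])
  class_map(matrix(codes, d[2], d[3]), crop_classes(), year,
            stack$geotransform, stack$pixel_size_m)
}
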