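#' Confusion matrix of a class map against reference points
#'
#' Tallies (mapped, reference) class pairs at the reference locations.
#' Rows are the mapped class, columns the reference class, so user's
#' accuracy is a row quantity and producer's accuracy a column quantity.
#' Points outside the map extent are an error (listed, never silently
#' dropped).
#'
#' @param pred A [class_map()].
#' @param ref_points Data frame with `row`, `col` and `class` columns
#'   (reference class codes).
#' @return A `confusion_matrix`: a k x k integer matrix with class names
#'   on both dimensions.
#' @export
confusion <- function(pred, ref_points) {
  stopifnot(inherits(pred, "class_map"))
  nr <- nrow(pred$labels); nc <- ncol(pred$labels)
  outside <- ref_points$row < 1 | ref_points$row > nr |
    ref_points$col < 1 | ref_points$col > nc
  if (any(outside)) {
    stop(sum(outside), " reference point(s) outside the map extent, rows: ",
         paste(utils::head(which(outside), 10), collapse = ", "))
  }
  k <- length(pred$legend)
  mapped <- pred$labels[cbind(ref_points$row, ref_points$col)]
  cm <- table(factor(mapped, levels = seq_len(k)),
              factor(ref_points$class, levels = seq_len(k)))
  cm <- matrix(as.integer(cm), k, k,
               dimnames = list(mapped = pred$legend, reference = pred$legend))
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = mapped, cols = reference):\n")
  print(unclass(x))
  invisible(x)
}

#' Accuracy report from a confusion matrix
#'
#' Overall accuracy is the diagonal fraction (in percent); user's accuracy
#' of a class is its diagonal cell over its row total (complement of
#' commission error), producer's accuracy over its column total (complement
#' of omission error); kappa is the chance-corrected agreement
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum(row_i * col_i) / total^2`.
#' Classes absent from the map (empty row) or the reference (empty column)
#' get `NA` for the undefined rate.
#'
#' @param cm A [confusion()] matrix (any square count matrix works).
#' @return An `accuracy_report` list: `overall_accuracy` (%), `kappa`,
#'   `users_accuracy` (%, per class), `producers_accuracy` (%, per class),
#'   `n` (total points).
#' @export
accuracy_summary <- function(cm) {
  cm <- unclass(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  rs <- rowSums(cm); cs <- colSums(cm)
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rs * cs) / total^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  ua <- ifelse(rs > 0, diag(cm) / rs * 100, NA_real_)
  pa <- ifelse(cs > 0, diag(cm) / cs * 100, NA_real_)
  structure(list(overall_accuracy = p_o * 100, kappa = kappa,
                 users_accuracy = ua, producers_accuracy = pa, n = total),
            class = "accuracy_report")
}

#' @export
summary.confusion_matrix <- function(object, ...) accuracy_summary(object)

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("overall accuracy %.2f%%   kappa %.3f   (n = %d)\n",
              x$overall_accuracy, x$kappa, x$n))
  tab <- data.frame(users_pct = round(x$users_accuracy, 2),
                    producers_pct = round(x$producers_accuracy, 2))
  print(tab)
  invisible(x)
}

#' Consistency index between extracted and statistical area
#'
#' `c = (1 - |x - y| / y) * 100`, where `x` is the remote-sensing extracted
#' area and `y` the statistical (reference) area. 100 means exact
#' agreement, 0 means the discrepancy equals the reference area, and values
#' go negative (unclamped) when `x > 2y`. The index is invariant to a
#' common rescaling of both areas.
#'
#' @param extracted_area Extracted area `x` (any unit).
#' @param statistical_area Reference area `y`, same unit; must be positive.
#' @return The consistency index in percent.
#' @export
consistency_index <- function(extracted_area, statistical_area) {
  if (any(statistical_area <= 0)) stop("statistical area must be positive")
  (1 - abs(extracted_area - statistical_area) / statistical_area) * 100
}

#' Bin consistency indices into the standard report bins
#'
#' Bins: `> 80` (i.e. (80, 100]), `60-80` = [60, 80), `40-60` = [40, 60),
#' `20-40` = [20, 40), `< 20` (including negative values). Lower-closed,
#' upper-open except the top bin.
#'
#' @param indices Numeric vector of consistency indices (percent).
#' @return Named integer vector of counts per bin, summing to
#'   `length(indices)`.
#' @export
consistency_binning <- function(indices) {
  out <- c(">80" = sum(indices > 80),
           "60-80" = sum(indices >= 60 & indices <= 80),
           "40-60" = sum(indices >= 40 & indices < 60),
           "20-40" = sum(indices >= 20 & indices < 40),
           "<20" = sum(indices < 20))
  as.integer(out) |> stats::setNames(names(out))
}

#' Regression of extracted areas on statistical areas
#'
#' Ordinary least squares of the remote-sensing extracted area on the
#' statistical reference area, with a free intercept. A slope near 1 with
#' high R-squared indicates the extraction tracks the reference totals.
#'
#' @param extracted Numeric vector of extracted areas.
#' @param statistical Numeric vector of reference areas, same length.
#' @return List with `slope`, `intercept`, `r_squared` and the underlying
#'   `lm` fit.
#' @export
area_regression <- function(extracted, statistical) {
  if (length(extracted) != length(statistical)) stop("length mismatch")
  if (length(extracted) < 3) stop("need at least 3 area pairs")
  if (stats::var(statistical) == 0) stop("statistical areas have zero variance")
  fit <- stats::lm(extracted ~ statistical)
  r2 <- if (stats::var(extracted) == 0) 0 else summary(fit)$r.squared
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       fit = fit)
}
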