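#' Control parameters for Harmonic Analysis of Time Series
#'
#' HANTS fits a truncated Fourier series to a vegetation-index time series
#' by iterated least squares, rejecting outliers on one side of the curve
#' between refits. The four classical controls are the valid data range,
#' the number of frequencies, the fit error tolerance (FET) and the degree
#' of overdeterminedness (DoD). Defaults follow common practice for
#' x10,000-scaled NDVI: valid range -2,000 to 9,000, 3 frequencies,
#' FET 1,000, DoD 8.
#'
#' @param valid_min,valid_max Valid scaled-NDVI range; values outside are
#'   pre-rejected before the first fit.
#' @param n_freq Number of harmonic frequencies above the mean term
#'   (integer multiples 1..n_freq of the base frequency).
#' @param fit_error_tolerance Maximum tolerated residual (scaled NDVI) on
#'   the suppression side before a point is rejected.
#' @param dod Degree of overdeterminedness: the fit keeps at least
#'   `2 * n_freq + 1 + dod` points (15 with the defaults).
#' @param suppression Which side of the curve outliers are rejected from:
#'   `"low"` (default; clouds and snow depress NDVI, so low values are the
#'   suspect ones), `"high"`, or `"none"` (two-sided).
#' @param base_period_nodes Nodes in one base period; the Fourier period is
#'   `base_period_nodes * 8` days (46 nodes = 368 days, one nominal year).
#' @param max_iter Maximum reject-refit iterations.
#' @return An object of class `hants_params`.
#' @export
hants_params <- function(valid_min = -2000, valid_max = 9000, n_freq = 3L,
                         fit_error_tolerance = 1000, dod = 8L,
                         suppression = c("low", "high", "none"),
                         base_period_nodes = 46L, max_iter = 50L) {
  suppression <- match.arg(suppression)
  if (n_freq < 1L) stop("n_freq must be >= 1")
  if (dod < 0L) stop("dod must be >= 0")
  if (valid_min >= valid_max) stop("valid_min must be below valid_max")
  structure(list(valid_min = valid_min, valid_max = valid_max,
                 n_freq = as.integer(n_freq),
                 fit_error_tolerance = fit_error_tolerance,
                 dod = as.integer(dod), suppression = suppression,
                 base_period_nodes = as.integer(base_period_nodes),
                 max_iter = as.integer(max_iter)),
            class = "hants_params")
}

min_points <- function(params) 2L * params$n_freq + 1L + params$dod

# Fourier design matrix at positions t (days) for period T (days)
hants_design <- function(t, params) {
  T <- params$base_period_nodes * 8
  A <- matrix(1, length(t), 1L)
  for (i in seq_len(params$n_freq)) {
    A <- cbind(A, cos(2 * pi * i * t / T), sin(2 * pi * i * t / T))
  }
  colnames(A) <- c("a0", as.vector(rbind(paste0("a", seq_len(params$n_freq)),
                                         paste0("b", seq_len(params$n_freq)))))
  A
}

# Core iterative fit given a precomputed design matrix. Returns NULL-free
# list; errors if too few usable points.
hants_core <- function(y, A, params) {
  n <- length(y)
  mp <- min_points(params)
  acc <- !is.na(y) & y >= params$valid_min & y <= params$valid_max
  if (sum(acc) < mp) {
    stop("only ", sum(acc), " in-range points; HANTS needs at least ", mp)
  }
  fet <- params$fit_error_tolerance
  converged <- FALSE
  iter <- 0L
  coefs <- NULL
  fit <- NULL
  while (iter < params$max_iter) {
    iter <- iter + 1L
    coefs <- qr.solve(A[acc, , drop = FALSE], y[acc])
    fit <- drop(A %*% coefs)
    res <- y - fit
    viol <- switch(params$suppression,
                   low = -res > fet,   # observation more than FET below curve
                   high = res > fet,
                   none = abs(res) > fet)
    viol <- viol & acc
    if (!any(viol)) { converged <- TRUE; break }
    if (sum(acc) - 1L < mp) break     # would drop below overdeterminedness floor
    worst <- which.max(ifelse(viol, abs(res), -Inf))
    acc[worst] <- FALSE
  }
  list(coefficients = coefs, fitted = fit, accepted = acc,
       converged = converged, iterations = iter)
}

#' Fit HANTS to one vegetation-index series
#'
#' Fits `y(t) = a0 + sum_{i=1..n_freq} [a_i cos(2 pi i t / T) +
#' b_i sin(2 pi i t / T)]` with `T = base_period_nodes * 8` days by least
#' squares over the currently accepted points, then iterates: the single
#' worst point whose residual exceeds the fit error tolerance on the
#' suppression side is rejected and the curve refitted, until no residual
#' violates the tolerance, the accepted count would fall below
#' `2 n_freq + 1 + dod`, or `max_iter` is reached. Out-of-range values are
#' pre-rejected before the first fit.
#'
#' @param y Numeric vector of scaled NDVI at the nodes.
#' @param doys Node positions in days (e.g. day of year for one annual
#'   window). Defaults to the 8-day dual-sensor grid `1, 9, 17, ...`.
#' @param params A [hants_params()].
#' @return An object of class `hants` with components `coefficients`
#'   (`a0, a1, b1, ..., a_nf, b_nf`), `fitted` (the smoothed series),
#'   `y`, `doys`, `rejected_mask`, `converged` and `iterations`. Supports
#'   `print()`, `coef()`, `fitted()`, `residuals()`, `predict()` and
#'   `plot()`.
#' @examples
#' doys <- seq(1, 361, by = 8)
#' clean <- 4000 + 2000 * cos(2 * pi * doys / 368 - pi)
#' f <- hants(clean, doys)
#' max(abs(fitted(f) - clean)) < 1e-6
#' @export
hants <- function(y, doys = seq(1, by = 8, length.out = length(y)),
                  params = hants_params()) {
  stopifnot(inherits(params, "hants_params"))
  if (length(y) != length(doys)) stop("y and doys lengths differ")
  if (length(y) < min_points(params)) {
    stop("series of length ", length(y), " is shorter than the minimum ",
         min_points(params), " points")
  }
  if (is.unsorted(doys, strictly = TRUE)) stop("doys must be strictly increasing")
  A <- hants_design(doys, params)
  core <- hants_core(as.numeric(y), A, params)
  structure(list(coefficients = core$coefficients,
                 fitted = core$fitted,
                 y = as.numeric(y), doys = doys,
                 rejected_mask = !core$accepted,
                 converged = core$converged,
                 iterations = core$iterations,
                 params = params),
            class = "hants")
}

#' @export
print.hants <- function(x, ...) {
  cat(sprintf("<hants fit> %d nodes, %d rejected, %s after %d iteration(s)\n",
              length(x$y), sum(x$rejected_mask),
              if (x$converged) "converged" else "not converged", x$iterations))
  cat("coefficients:\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' @export
fitted.hants <- function(object, ...) object$fitted

#' @export
residuals.hants <- function(object, ...) object$y - object$fitted

#' @export
coef.hants <- function(object, ...) object$coefficients

#' Evaluate a fitted HANTS curve at arbitrary days
#' @param object A fitted [hants()] object.
#' @param doys Days at which to evaluate (default: the fitted nodes).
#' @param ... Unused.
#' @export
predict.hants <- function(object, doys = object$doys, ...) {
  drop(hants_design(doys, object$params) %*% object$coefficients)
}

#' @export
plot.hants <- function(x, ...) {
  plot(x$doys, x$y, pch = ifelse(x$rejected_mask, 4, 1),
       xlab = "day of year", ylab = "scaled NDVI",
       main = "HANTS fit (x = rejected)", ...)
  dd <- seq(min(x$doys), max(x$doys), length.out = 200)
  graphics::lines(dd, predict(x, dd), col = "forestgreen", lwd = 2)
  invisible(x)
}

#' Smooth every pixel of a stack with HANTS
#'
#' Applies [hants()] per pixel, by default independently within each
#' calendar year (phenology is annual; a year of the dual-sensor series has
#' 46 nodes, comfortably above the 15-point floor of the default
#' parameters). With `per_year = FALSE` one harmonic model with an annual
#' base period is fitted through the whole multi-year series. Pixels whose
#' fit fails (too few in-range points) or does not converge keep their
#' input (typically gap-filled) values, so the output never contains new
#' missing values; their count is recorded in the `n_fallback` attribute.
#'
#' @param stack An [ndvi_stack()], normally gap-filled first.
#' @param params A [hants_params()].
#' @param per_year Fit each calendar year separately (default `TRUE`).
#' @return An `ndvi_stack` of smoothed values with the original
#'   reliability cube, plus attribute `n_fallback`.
#' @export
hants_stack <- function(stack, params = hants_params(), per_year = TRUE) {
  stopifnot(inherits(stack, "ndvi_stack"))
  cal <- stack$calendar
  d <- dim(stack$values)
  npix <- d[2] * d[3]
  Y_all <- matrix(as.numeric(stack$values), d[1], npix)
  out <- Y_all
  n_fallback <- 0L
  fet <- params$fit_error_tolerance

  windows <- if (per_year) split(seq_len(d[1]), cal$year) else
    list(all = seq_len(d[1]))
  for (w in windows) {
    t_w <- if (per_year) cal$doy[w] else calendar_axis(cal)[w]
    if (length(w) < min_points(params)) {
      stop("window of ", length(w), " nodes is below the minimum ",
           min_points(params), " points per fit")
    }
    A <- hants_design(t_w, params)
    Y <- Y_all[w, , drop = FALSE]
    in_range <- !is.na(Y) & Y >= params$valid_min & Y <= params$valid_max
    full <- colSums(in_range) == length(w)
    # fast path: one batch least-squares fit for pixels with all points
    # accepted and no violating residual afterwards
    if (any(full)) {
      AtA <- crossprod(A)
      C <- solve(AtA, crossprod(A, Y[, full, drop = FALSE]))
      Fit <- A %*% C
      R <- Y[, full, drop = FALSE] - Fit
      viol <- switch(params$suppression,
                     low = -R > fet, high = R > fet, none = abs(R) > fet)
      clean <- colSums(viol) == 0L
      done <- which(full)[clean]
      out[w, done] <- Fit[, clean]
    } else {
      done <- integer(0)
    }
    rest <- setdiff(seq_len(npix), done)
    for (j in rest) {
      res <- tryCatch(hants_core(Y[, j], A, params), error = function(e) NULL)
      if (is.null(res) || !res$converged) n_fallback <- n_fallback + 1L
      if (!is.null(res) && res$converged) out[w, j] <- res$fitted
      # fallback: keep the (gap-filled) input values already in `out`
    }
  }
  out <- pmin(pmax(out, -10000), 10000)
  sm <- ndvi_stack(array(as.integer(round(out)), d), stack$reliability,
                   cal, stack$geotransform, stack$pixel_size_m)
  attr(sm, "n_fallback") <- n_fallback
  sm
}
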