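#' Replace cloud/snow-flagged values by linear temporal interpolation
#'
#' Nodes flagged snow/ice (2), cloud (3) or fill (255) are replaced by
#' linear interpolation, in node-index time, between the nearest usable
#' neighbours — nodes flagged good (0) or marginal (1). Good and marginal
#' values (and their flags) are retained untouched. Flagged runs at the
#' start or end of the series take the nearest usable value (constant
#' extension, no extrapolation). Because composite nodes are equally spaced
#' (8 days in the merged series), index-time and calendar-time
#' interpolation coincide; across the December-January boundary index time
#' is used, treating the multi-year series as one continuous record.
#'
#' @param values Numeric vector of scaled NDVI over consecutive nodes.
#' @param reliability Integer vector of quality codes, same length.
#' @param flag_codes Codes treated as unusable (default `c(2, 3, 255)`).
#' @return A list: `values` (filled series, integer) and `filled_mask`
#'   (logical, `TRUE` where a value was replaced).
#' @examples
#' fill_series(c(5000, 0, 7000), c(0, 3, 0))$values  # 5000 6000 7000
#' @export
fill_series <- function(values, reliability, flag_codes = c(2L, 3L, 255L)) {
  n <- length(values)
  if (n < 2L) stop("series must have at least 2 nodes")
  if (length(reliability) != n) stop("values and reliability lengths differ")
  bad <- reliability %in% flag_codes
  if (all(bad)) stop("all ", n, " nodes are flagged; series unusable")
  if (!any(bad)) {
    return(list(values = as.integer(values), filled_mask = logical(n)))
  }
  good <- which(!bad)
  filled <- values
  if (length(good) == 1L) {
    filled[bad] <- values[good]  # one usable anchor: constant series
  } else {
    # rule = 2: constant extension from nearest good node at the edges
    filled[bad] <- stats::approx(good, values[good], xout = which(bad),
                                 method = "linear", rule = 2)$y
  }
  list(values = as.integer(round(filled)), filled_mask = bad)
}

#' Gap-fill every pixel of a time-series stack
#'
#' Applies [fill_series()] independently to each pixel's series. The
#' reliability cube is returned unchanged, so downstream stages still see
#' which nodes were originally contaminated. Pixels whose series is flagged
#' at every node cannot be filled; they are set to `NA` and counted in the
#' `n_masked_pixels` attribute rather than raising an error.
#'
#' @param stack An [ndvi_stack()].
#' @param flag_codes Codes treated as unusable (default `c(2, 3, 255)`).
#' @return The gap-filled `ndvi_stack`, with attributes `filled_mask`
#'   (logical cube of replaced nodes) and `n_masked_pixels`.
#' @export
fill_stack <- function(stack, flag_codes = c(2L, 3L, 255L)) {
  stopifnot(inherits(stack, "ndvi_stack"))
  d <- dim(stack$values)
  vmat <- matrix(stack$values, d[1], d[2] * d[3])
  rmat <- matrix(stack$reliability, d[1], d[2] * d[3])
  bad <- matrix(rmat %in% flag_codes, d[1], d[2] * d[3])
  all_bad <- colSums(bad) == d[1]
  out <- vmat
  for (j in which(!all_bad & colSums(bad) > 0)) {
    out[, j] <- fill_series(vmat[, j], rmat[, j], flag_codes)$values
  }
  out[, all_bad] <- NA_integer_
  filled <- ndvi_stack(array(out, d), stack$reliability, stack$calendar,
                       stack$geotransform, stack$pixel_size_m)
  attr(filled, "filled_mask") <- array(bad & !rep(all_bad, each = d[1]), d)
  attr(filled, "n_masked_pixels") <- sum(all_bad)
  if (any(all_bad)) {
    message(sum(all_bad), " pixel(s) flagged at every node were masked out")
  }
  filled
}
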