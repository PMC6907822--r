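#' NDVI time-series raster stack
#'
#' Container for a per-pixel NDVI time series over a regular raster grid.
#' Values are integers on the common scaled-NDVI convention (true NDVI
#' multiplied by 10,000, so the physical range [-1, 1] maps to
#' [-10000, 10000]). A parallel reliability cube carries per-pixel,
#' per-node quality codes: 0 good, 1 marginal, 2 snow/ice, 3 cloud,
#' 255 fill.
#'
#' @param values Integer array of dimension `n_nodes x n_rows x n_cols`.
#' @param reliability Integer array of the same dimension with codes in
#'   `{0, 1, 2, 3, 255}`.
#' @param calendar A [build_calendar()] calendar with one entry per node.
#' @param geotransform Numeric length-6 affine georeferencing vector
#'   `(x_origin, pixel_width, 0, y_origin, 0, -pixel_height)` in map units.
#' @param pixel_size_m Ground pixel size in metres (default 250).
#' @return An object of class `ndvi_stack`.
#' @export
ndvi_stack <- function(values, reliability, calendar,
                       geotransform = c(0, 250, 0, 0, 0, -250),
                       pixel_size_m = 250) {
  validate_calendar(calendar)
  if (length(dim(values)) != 3L) stop("`values` must be a 3-D array")
  if (!identical(dim(values), dim(reliability))) {
    stop("`values` and `reliability` must share dimensions")
  }
  if (dim(values)[1] != nrow(calendar)) {
    stop("stack has ", dim(values)[1], " bands but calendar has ",
         nrow(calendar), " nodes")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1] < -10000 || rng[2] > 10000) {
    stop("scaled NDVI values must lie within [-10000, 10000]")
  }
  if (!all(reliability %in% c(0L, 1L, 2L, 3L, 255L) | is.na(reliability))) {
    stop("reliability codes must be in {0, 1, 2, 3, 255}")
  }
  if (length(geotransform) != 6L) stop("`geotransform` must have length 6")
  structure(list(values = values,
                 reliability = reliability,
                 calendar = calendar,
                 geotransform = as.numeric(geotransform),
                 pixel_size_m = pixel_size_m),
            class = "ndvi_stack")
}

#' @export
print.ndvi_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ndvi_stack> %d nodes x %d rows x %d cols (%g m pixels)\n",
              d[1], d[2], d[3], x$pixel_size_m))
  cat(sprintf("  years %d-%d, %d nodes/year\n",
              min(x$calendar$year), max(x$calendar$year),
              attr(x$calendar, "nodes_per_year")))
  flagged <- mean(x$reliability %in% c(2L, 3L, 255L)) * 100
  cat(sprintf("  value range [%d, %d]; %.1f%% nodes flagged cloud/snow/fill\n",
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE), flagged))
  invisible(x)
}

#' Interleave two single-sensor stacks into one 8-day-cadence stack
#'
#' Merges the 16-day composites of sensors A and B — offset by half a
#' compositing period ("half-synthetic period dislocation") — by sorting all
#' nodes on (year, day-of-year). Values and reliability codes pass through
#' untouched; only the node order changes.
#'
#' @param stack_a,stack_b `ndvi_stack`s on the identical grid covering the
#'   same years, with sensor-A and sensor-B calendars respectively.
#' @return A dual-sensor `ndvi_stack` with 46 nodes per year.
#' @export
interleave_stacks <- function(stack_a, stack_b) {
  stopifnot(inherits(stack_a, "ndvi_stack"), inherits(stack_b, "ndvi_stack"))
  if (!identical(dim(stack_a$values)[2:3], dim(stack_b$values)[2:3]) ||
      !isTRUE(all.equal(stack_a$geotransform, stack_b$geotransform))) {
    stop("sensor A and B stacks must share grid and georeferencing")
  }
  ya <- sort(unique(stack_a$calendar$year))
  yb <- sort(unique(stack_b$calendar$year))
  if (!identical(ya, yb)) stop("sensor A and B stacks must cover the same years")
  cal_a <- stack_a$calendar
  cal_b <- stack_b$calendar
  key_a <- paste(cal_a$year, cal_a$doy)
  key_b <- paste(cal_b$year, cal_b$doy)
  if (length(intersect(key_a, key_b)) > 0) {
    stop("overlapping (year, doy) nodes between sensors; expected an 8-day offset")
  }
  merged <- rbind(as.data.frame(cal_a), as.data.frame(cal_b))
  src <- c(rep(1L, nrow(cal_a)), rep(2L, nrow(cal_b)))
  idx <- c(seq_len(nrow(cal_a)), seq_len(nrow(cal_b)))
  o <- order(merged$year, merged$doy)
  merged <- merged[o, ]
  rownames(merged) <- NULL
  src <- src[o]
  idx <- idx[o]

  d <- dim(stack_a$values)
  n <- nrow(merged)
  values <- array(NA_integer_, c(n, d[2], d[3]))
  reliability <- array(NA_integer_, c(n, d[2], d[3]))
  for (k in seq_len(n)) {
    s <- if (src[k] == 1L) stack_a else stack_b
    values[k, , ] <- s$values[idx[k], , ]
    reliability[k, , ] <- s$reliability[idx[k], , ]
  }
  cal <- structure(merged, nodes_per_year = 46L,
                   class = c("node_calendar", "data.frame"))
  ndvi_stack(values, reliability, cal, stack_a$geotransform,
             stack_a$pixel_size_m)
}

# 16-bit offset encoding: exact round trip for integers in [-32768, 32767]
encode16 <- function(m) (m + 32768) / 65535
decode16 <- function(m) as.integer(round(m * 65535 - 32768))

write_bands <- function(arr, path) {
  bands <- lapply(seq_len(dim(arr)[1]), function(k) encode16(arr[k, , , drop = TRUE]))
  bands <- lapply(bands, function(b) matrix(b, dim(arr)[2], dim(arr)[3]))
  tiff::writeTIFF(bands, path, bits.per.sample = 16L, compression = "none")
}

read_bands <- function(path) {
  bands <- tiff::readTIFF(path, all = TRUE)
  arr <- array(NA_integer_, c(length(bands), nrow(bands[[1]]), ncol(bands[[1]])))
  for (k in seq_along(bands)) arr[k, , ] <- decode16(bands[[k]])
  arr
}

#' Write / read an NDVI stack as multi-band TIFF plus JSON sidecar
#'
#' `write_stack()` writes three files under a common base path: the value
#' cube (`<base>_values.tif`, one 16-bit band per node), the reliability
#' cube (`<base>_reliability.tif`) and a JSON sidecar (`<base>.json`)
#' carrying the node calendar, affine geotransform and pixel size.
#' `read_stack()` reverses the operation; the round trip is bit-exact on
#' values, reliability and calendar metadata.
#'
#' @param stack An `ndvi_stack`.
#' @param base_path Path prefix (without extension) for the three files.
#' @return `write_stack()` returns the three file paths invisibly;
#'   `read_stack()` returns the reconstructed `ndvi_stack`.
#' @export
write_stack <- function(stack, base_path) {
  stopifnot(inherits(stack, "ndvi_stack"))
  paths <- stack_paths(base_path)
  write_bands(stack$values, paths$values)
  write_bands(stack$reliability, paths$reliability)
  sidecar <- list(
    calendar = as.data.frame(stack$calendar),
    nodes_per_year = attr(stack$calendar, "nodes_per_year"),
    geotransform = stack$geotransform,
    pixel_size_m = stack$pixel_size_m
  )
  jsonlite::write_json(sidecar, paths$sidecar, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_stack
#' @export
read_stack <- function(base_path) {
  paths <- stack_paths(base_path)
  for (nm in c("values", "reliability", "sidecar")) {
    if (!file.exists(paths[[nm]])) {
      stop("missing stack component: ", paths[[nm]])
    }
  }
  side <- jsonlite::read_json(paths$sidecar, simplifyVector = TRUE)
  cal <- structure(as.data.frame(side$calendar),
                   nodes_per_year = as.integer(side$nodes_per_year),
                   class = c("node_calendar", "data.frame"))
  values <- read_bands(paths$values)
  if (dim(values)[1] != nrow(cal)) {
    stop("band count (", dim(values)[1], ") does not match calendar length (",
         nrow(cal), ")")
  }
  reliability <- read_bands(paths$reliability)
  ndvi_stack(values, reliability, cal,
             as.numeric(side$geotransform), side$pixel_size_m)
}

stack_paths <- function(base_path) {
  list(values = paste0(base_path, "_values.tif"),
       reliability = paste0(base_path, "_reliability.tif"),
       sidecar = paste0(base_path, ".json"))
}

# Map coordinates of pixel centres (row 1 = top). Used for sample points.
pixel_xy <- function(gt, row, col) {
  list(x = gt[1] + (col - 0.5) * gt[2],
       y = gt[4] + (row - 0.5) * gt[6])
}

#' Read a table of statistical sown areas
#'
#' Reads a CSV with columns `unit_name`, `year`, `area_mha` (administrative
#' unit, calendar year, sown area in million hectares) and checks it for
#' duplicate (unit, year) rows and negative areas.
#'
#' @param path CSV file path.
#' @return A data frame with the three validated columns.
#' @export
read_area_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_name", "year", "area_mha")
  if (!all(need %in% names(tab))) {
    stop("area table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab[c("unit_name", "year")])) {
    stop("duplicate (unit_name, year) rows in area table")
  }
  if (any(tab$area_mha < 0)) stop("areas must be non-negative")
  tab
}
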