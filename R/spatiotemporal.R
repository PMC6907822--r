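#' Mapped area of one class, in million hectares
#'
#' One 250 m pixel covers 6.25 ha, so 160,000 pixels make 1 Mha.
#'
#' @param map A [class_map()].
#' @param target_class Class code or name.
#' @param pixel_size_m Pixel size in metres (defaults to the map's).
#' @return Area in Mha.
#' @export
class_area <- function(map, target_class = "wheat_maize",
                       pixel_size_m = map$pixel_size_m) {
  stopifnot(inherits(map, "class_map"))
  if (pixel_size_m <= 0) stop("pixel_size_m must be positive")
  code <- resolve_class(target_class, map$legend)
  n <- sum(map$labels == code, na.rm = TRUE)
  n * pixel_size_m^2 / 1e10  # m^2 -> Mha (1 Mha = 1e10 m^2)
}

resolve_class <- function(target_class, legend) {
  if (is.character(target_class)) {
    code <- match(target_class, legend)
    if (is.na(code)) stop("unknown class: ", target_class)
  } else {
    code <- as.integer(target_class)
    if (code < 1 || code > length(legend)) stop("unknown class code: ", code)
  }
  code
}

#' Annual area series with year-on-year growth rates
#'
#' Growth in year t is `(A_t - A_{t-1}) / A_{t-1} * 100`; an average growth
#' rate over a span is the arithmetic mean of the annual rates in it.
#'
#' @param areas Named numeric vector of areas (names = years) or data
#'   frame with `year` and `area_mha`.
#' @return Data frame `year`, `area_mha`, `growth_pct` (`NA` for the first
#'   year), of class `area_series`.
#' @export
growth_rates <- function(areas) {
  if (is.data.frame(areas)) {
    years <- areas$year; a <- areas$area_mha
  } else {
    years <- as.integer(names(areas)); a <- as.numeric(areas)
  }
  if (length(a) < 2) stop("need at least 2 years")
  o <- order(years); years <- years[o]; a <- a[o]
  prev <- a[-length(a)]
  if (any(prev == 0)) stop("zero prior-year area; growth rate undefined")
  rate <- c(NA_real_, diff(a) / prev * 100)
  structure(data.frame(year = years, area_mha = a, growth_pct = rate),
            class = c("area_series", "data.frame"))
}

#' Change map of a target class between two dates
#'
#' Per pixel: `stable` = target at both dates, `gain` = target only at the
#' second, `loss` = target only at the first, `absent` = neither.
#'
#' @param map_t1,map_t2 [class_map()]s on the same grid.
#' @param target_class Class code or name.
#' @return A `change_map`: list with a character matrix `change` over
#'   `{"stable","gain","loss","absent"}` plus the grid metadata.
#' @export
change_map <- function(map_t1, map_t2, target_class = "wheat_maize") {
  stopifnot(inherits(map_t1, "class_map"), inherits(map_t2, "class_map"))
  if (!identical(dim(map_t1$labels), dim(map_t2$labels))) {
    stop("maps are on different grids")
  }
  code <- resolve_class(target_class, map_t1$legend)
  t1 <- map_t1$labels == code
  t2 <- map_t2$labels == code
  ch <- matrix("absent", nrow(t1), ncol(t1))
  ch[t1 & t2] <- "stable"
  ch[t1 & !t2] <- "loss"
  ch[!t1 & t2] <- "gain"
  structure(list(change = ch, year_t1 = map_t1$year, year_t2 = map_t2$year,
                 geotransform = map_t1$geotransform,
                 pixel_size_m = map_t1$pixel_size_m),
            class = "change_map")
}

#' @export
print.change_map <- function(x, ...) {
  cat(sprintf("<change_map> %s -> %s\n", x$year_t1, x$year_t2))
  print(table(factor(x$change, levels = c("stable", "gain", "loss", "absent"))))
  invisible(x)
}

#' Planting-frequency (planting-probability) raster
#'
#' Per pixel, the percentage of study years in which it was mapped as the
#' target class: `100 * k / n_years` with `k` the per-pixel count, equal to
#' the mean of the per-year target indicators times 100.
#'
#' @param maps List of per-year [class_map()]s on a common grid.
#' @param target_class Class code or name.
#' @return A `frequency_raster`: list with `values` (percent matrix),
#'   `n_years` and grid metadata.
#' @export
planting_frequency <- function(maps, target_class = "wheat_maize") {
  if (length(maps) < 1) stop("need at least one map")
  dims <- lapply(maps, function(m) dim(m$labels))
  if (length(unique(dims)) != 1) stop("maps are on different grids")
  code <- resolve_class(target_class, maps[[1]]$legend)
  k <- Reduce(`+`, lapply(maps, function(m) (m$labels == code) * 1L))
  structure(list(values = 100 * k / length(maps), n_years = length(maps),
                 geotransform = maps[[1]]$geotransform,
                 pixel_size_m = maps[[1]]$pixel_size_m),
            class = "frequency_raster")
}

#' Area per planting-frequency bin
#'
#' Companion histogram to [planting_frequency()]: the mapped area (Mha)
#' falling in each frequency band. Default bands: exactly 100%, then
#' [80,100), [60,80), [40,60), [20,40), (0,20], and never planted (0%).
#'
#' @param freq A `frequency_raster`.
#' @param breaks Interior band edges in percent, ascending, within (0, 100).
#' @return Data frame `bin`, `area_mha`; areas sum to the full raster area.
#' @export
frequency_histogram <- function(freq, breaks = c(20, 40, 60, 80)) {
  stopifnot(inherits(freq, "frequency_raster"))
  v <- as.vector(freq$values)
  px_mha <- freq$pixel_size_m^2 / 1e10
  edges <- c(0, breaks, 100)
  # "0" and "100" stand alone; interior bands are lower-closed [lo, hi)
  bands <- c("0",
             paste0("(0,", edges[2], ")"),
             if (length(breaks) > 1)
               paste0("[", breaks[-length(breaks)], ",", breaks[-1], ")"),
             paste0("[", breaks[length(breaks)], ",100)"),
             "100")
  counts <- c(sum(v == 0),
              sum(v > 0 & v < edges[2]),
              if (length(breaks) > 1)
                vapply(seq_len(length(breaks) - 1), function(i)
                  sum(v >= breaks[i] & v < breaks[i + 1]), 0L),
              sum(v >= breaks[length(breaks)] & v < 100),
              sum(v == 100))
  data.frame(bin = bands, area_mha = counts * px_mha)
}

#' Peak value and timing of a smoothed curve inside a phenology window
#'
#' Scans the nodes whose day-of-year falls inside the window and returns
#' the maximum smoothed value and its node DOY (node resolution, i.e. the
#' 8-day merged grid; no sub-node interpolation). Default windows: winter
#' wheat DOY 60-170, summer maize DOY 180-270.
#'
#' @param values Numeric vector of smoothed scaled NDVI for one year.
#' @param doys Matching node DOYs.
#' @param window Length-2 `(doy_lo, doy_hi)` inclusive window.
#' @return List with `peak_value` and `peak_doy`.
#' @export
peak_metrics <- function(values, doys, window = c(60, 170)) {
  if (length(values) != length(doys)) stop("values and doys lengths differ")
  sel <- doys >= window[1] & doys <= window[2]
  if (!any(sel)) stop("no nodes inside the window [", window[1], ", ",
                      window[2], "]")
  i <- which(sel)[which.max(values[sel])]
  list(peak_value = values[i], peak_doy = doys[i])
}
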