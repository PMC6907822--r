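#' Land-cover classes used throughout the package
#'
#' The mapping problem distinguishes five classes: the target double-cropping
#' rotation (winter wheat followed by summer maize), single-season cropland,
#' forest/grassland, water, and built-up land. Class codes are the positions
#' in this vector.
#'
#' @return Character vector of the five class labels, in code order.
#' @export
crop_classes <- function() {
  c("wheat_maize", "one_season", "forest_grass", "water", "built_up")
}

#' Categorical class-map raster
#'
#' @param labels Integer matrix of class codes (row 1 = top of the map).
#' @param legend Character vector mapping code (position) to class name.
#' @param year Calendar year the map refers to.
#' @param geotransform Affine georeferencing vector of length 6.
#' @param pixel_size_m Ground pixel size in metres.
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, legend = crop_classes(), year = NA_integer_,
                      geotransform = c(0, 250, 0, 0, 0, -250),
                      pixel_size_m = 250) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  codes <- unique(as.vector(labels))
  codes <- codes[!is.na(codes)]
  if (!all(codes %in% seq_along(legend))) {
    stop("label codes outside legend: ",
         paste(setdiff(codes, seq_along(legend)), collapse = ", "))
  }
  structure(list(labels = labels, legend = legend, year = as.integer(year),
                 geotransform = as.numeric(geotransform),
                 pixel_size_m = pixel_size_m),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d x %d pixels (%g m), year %s\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_m,
              ifelse(is.na(x$year), "?", x$year)))
  tab <- table(factor(x$legend[x$labels], levels = x$legend))
  print(tab)
  invisible(x)
}

#' Write / read a class map as single-band TIFF plus JSON sidecar
#'
#' @param map A `class_map`.
#' @param base_path Path prefix for `<base>.tif` and `<base>.json`.
#' @return `write_class_map()` returns the paths invisibly;
#'   `read_class_map()` the reconstructed `class_map`.
#' @export
write_class_map <- function(map, base_path) {
  stopifnot(inherits(map, "class_map"))
  tif <- paste0(base_path, ".tif")
  js <- paste0(base_path, ".json")
  tiff::writeTIFF(encode16(map$labels), tif, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(legend = map$legend, year = map$year,
                            geotransform = map$geotransform,
                            pixel_size_m = map$pixel_size_m),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(list(tif = tif, sidecar = js))
}

#' @rdname write_class_map
#' @export
read_class_map <- function(base_path) {
  tif <- paste0(base_path, ".tif")
  js <- paste0(base_path, ".json")
  if (!file.exists(tif) || !file.exists(js)) {
    stop("missing class map component under base path: ", base_path)
  }
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  img <- tiff::readTIFF(tif)
  labels <- matrix(decode16(img), nrow = nrow(img))
  class_map(labels, side$legend, side$year,
            as.numeric(side$geotransform), side$pixel_size_m)
}
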