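#' Parametric annual phenology curve for one land-cover class
#'
#' The seasonal NDVI trajectory of each class is modelled as a baseline plus
#' a sum of Gaussian bumps, one per green-up peak, with additive Gaussian
#' observation noise. The double-cropping rotation is bimodal: the winter
#' wheat peak falls in DOY 60-170 (default draw window 108-123) and the
#' summer maize peak in DOY 180-270 (default window 221-228). True NDVI is
#' clipped to [-0.2, 0.9] before the x10,000 integer scaling.
#'
#' @param class_label One of [crop_classes()].
#' @param baseline_ndvi Off-season NDVI level (unscaled).
#' @param peaks List of peaks, each `list(peak_doy, peak_ndvi, width_days)`
#'   where `peak_ndvi` is the bump amplitude above baseline and `width_days`
#'   the Gaussian sigma in days.
#' @param noise_sd Standard deviation of additive noise (unscaled NDVI).
#' @param peak_doy_ranges Optional list of `c(lo, hi)` windows, one per peak,
#'   from which per-pixel peak DOYs are drawn by [generate_scene()].
#' @return An object of class `phenology_model`.
#' @export
phenology_model <- function(class_label, baseline_ndvi, peaks = list(),
                            noise_sd = 0.02, peak_doy_ranges = NULL) {
  class_label <- match.arg(class_label, crop_classes())
  if (class_label == "wheat_maize") {
    if (length(peaks) != 2L) stop("wheat_maize phenology must have exactly 2 peaks")
    d1 <- peaks[[1]]$peak_doy
    d2 <- peaks[[2]]$peak_doy
    if (d1 < 60 || d1 > 170) stop("first (wheat) peak DOY must lie in [60, 170]")
    if (d2 < 180 || d2 > 270) stop("second (maize) peak DOY must lie in [180, 270]")
  }
  structure(list(class_label = class_label, baseline_ndvi = baseline_ndvi,
                 peaks = peaks, noise_sd = noise_sd,
                 peak_doy_ranges = peak_doy_ranges),
            class = "phenology_model")
}

#' Default phenology models for the five classes
#'
#' Baselines, peak timings, amplitudes and widths chosen to reproduce the
#' qualitative class signatures of temperate double-cropping landscapes:
#' a bimodal wheat-maize curve, a unimodal summer curve for single-season
#' crops, a broad forest/grassland summer plateau, negative NDVI over water
#' and a weak vegetated signal over built-up land.
#'
#' @return Named list of [phenology_model()]s, one per class.
#' @export
default_phenology_models <- function() {
  list(
    wheat_maize = phenology_model(
      "wheat_maize", baseline_ndvi = 0.18,
      peaks = list(list(peak_doy = 115L, peak_ndvi = 0.55, width_days = 22),
                   list(peak_doy = 224L, peak_ndvi = 0.52, width_days = 18)),
      noise_sd = 0.02,
      peak_doy_ranges = list(c(108L, 123L), c(221L, 228L))),
    one_season = phenology_model(
      "one_season", baseline_ndvi = 0.18,
      peaks = list(list(peak_doy = 200L, peak_ndvi = 0.52, width_days = 32)),
      noise_sd = 0.02,
      peak_doy_ranges = list(c(190L, 212L))),
    forest_grass = phenology_model(
      "forest_grass", baseline_ndvi = 0.28,
      peaks = list(list(peak_doy = 195L, peak_ndvi = 0.40, width_days = 58)),
      noise_sd = 0.02,
      peak_doy_ranges = list(c(185L, 205L))),
    water = phenology_model(
      "water", baseline_ndvi = -0.10, peaks = list(), noise_sd = 0.01),
    built_up = phenology_model(
      "built_up", baseline_ndvi = 0.12,
      peaks = list(list(peak_doy = 200L, peak_ndvi = 0.08, width_days = 60)),
      noise_sd = 0.02,
      peak_doy_ranges = list(c(180L, 220L)))
  )
}

# Clean (noise-free, unscaled) curve value at given DOYs.
curve_true <- function(model, doys) {
  v <- rep(model$baseline_ndvi, length(doys))
  for (p in model$peaks) {
    v <- v + p$peak_ndvi * exp(-(doys - p$peak_doy)^2 / (2 * p$width_days^2))
  }
  v
}

#' Evaluate a phenology model at a day of year
#'
#' Returns the scaled-NDVI integer (true NDVI x 10,000) at `doy`: the
#' class's baseline plus its Gaussian peaks, plus one draw of Gaussian
#' observation noise, clipped to the generative range [-0.2, 0.9].
#'
#' @param model A [phenology_model()].
#' @param doy Day(s) of year, each in 1-366.
#' @return Integer vector of scaled NDVI values.
#' @export
curve_at <- function(model, doy) {
  if (any(doy < 1 | doy > 366)) stop("doy must lie in [1, 366]")
  v <- curve_true(model, doy)
  if (model$noise_sd > 0) v <- v + stats::rnorm(length(doy), 0, model$noise_sd)
  as.integer(round(pmin(pmax(v, -0.2), 0.9) * 10000))
}

#' Specification of a synthetic multi-year scene
#'
#' @param n_rows,n_cols Raster dimensions in pixels.
#' @param class_fractions Named fractions over [crop_classes()]; must sum
#'   to 1.
#' @param patch_scale_px Side length of the square patches the class map is
#'   tiled from (1 = i.i.d. pixels).
#' @param years Length-2 vector `(start_year, end_year)`.
#' @param cloud_prob Per-node probability of cloud contamination.
#' @param snow_prob_winter Per-node probability of snow contamination,
#'   applied only at winter nodes (DOY < 60 or > 330).
#' @param marginal_prob Probability that an uncontaminated node is flagged
#'   marginal (code 1) rather than good (code 0).
#' @param n_ref_per_year Validation reference points drawn per year.
#' @param seed Integer seed; the whole scene is reproducible from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 64, n_cols = 64,
                       class_fractions = c(wheat_maize = 0.45, one_season = 0.20,
                                           forest_grass = 0.15, water = 0.10,
                                           built_up = 0.10),
                       patch_scale_px = 4,
                       years = c(2004, 2016),
                       cloud_prob = 0.10,
                       snow_prob_winter = 0.15,
                       marginal_prob = 0.10,
                       n_ref_per_year = 150,
                       seed = 1L) {
  if (!setequal(names(class_fractions), crop_classes())) {
    stop("class_fractions must be named by all five classes")
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    stop("class_fractions must sum to 1 (got ", sum(class_fractions), ")")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 class_fractions = class_fractions[crop_classes()],
                 patch_scale_px = patch_scale_px, years = years,
                 cloud_prob = cloud_prob, snow_prob_winter = snow_prob_winter,
                 marginal_prob = marginal_prob,
                 n_ref_per_year = n_ref_per_year, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Generate a synthetic dual-sensor scene with known truth
#'
#' Builds a patchy five-class land-cover map, evaluates each pixel's class
#' phenology (with per-pixel peak-DOY draws from the model windows) at every
#' composite node of both sensors, adds observation noise, then contaminates
#' random nodes: contaminated values are depressed by a draw from
#' U(0.2, 0.6) x 10,000 — clouds and snow only ever lower NDVI — and flagged
#' cloud (code 3) or, at winter nodes, snow (code 2). Clean nodes carry code
#' 0, or 1 (marginal) with the spec's marginal probability. Everything is
#' drawn from a single RNG stream seeded once, so the scene is bit-identical
#' across runs with the same spec.
#'
#' @param spec A [scene_spec()].
#' @param models Named list of [phenology_model()]s (default
#'   [default_phenology_models()]).
#' @param change Optional `list(year, mask, class)`: from `year` onward the
#'   truth map pixels where `mask` is `TRUE` switch to class code `class`.
#' @return A list with `stack_a`, `stack_b` (single-sensor [ndvi_stack()]s),
#'   `truth` (list of per-year [class_map()]s), `reference_points` (data
#'   frame `x, y, row, col, year, class`), `clean_a`, `clean_b` (noise- and
#'   contamination-free scaled value cubes), and `peak_doy` (per-pixel
#'   matrices of the drawn peak DOYs per class peak).
#' @export
generate_scene <- function(spec, models = default_phenology_models(),
                           change = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (!setequal(names(models), crop_classes())) {
    stop("models must cover all five classes")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  nr <- spec$n_rows; nc <- spec$n_cols; npix <- nr * nc
  legend <- crop_classes()
  gt <- c(0, spec$pixel_size_m %||% 250, 0, 0, 0, -(spec$pixel_size_m %||% 250))

  # patchy class map: one multinomial draw per patch
  ps <- spec$patch_scale_px
  pr <- ceiling(nr / ps); pc <- ceiling(nc / ps)
  patch_class <- matrix(
    sample.int(5L, pr * pc, replace = TRUE, prob = spec$class_fractions),
    pr, pc)
  labels <- patch_class[ceiling(seq_len(nr) / ps), ceiling(seq_len(nc) / ps),
                        drop = FALSE]

  # per-pixel peak DOY draws within each class's windows
  peak_doy <- list()
  for (cls in legend) {
    m <- models[[cls]]
    if (length(m$peaks) == 0) next
    per_peak <- list()
    for (j in seq_along(m$peaks)) {
      rng <- if (!is.null(m$peak_doy_ranges)) m$peak_doy_ranges[[j]] else
        rep(m$peaks[[j]]$peak_doy, 2)
      vals <- seq.int(rng[1], rng[2])
      per_peak[[j]] <- matrix(
        vals[sample.int(length(vals), npix, replace = TRUE)], nr, nc)
    }
    peak_doy[[cls]] <- per_peak
  }

  years <- seq.int(spec$years[1], spec$years[2])
  truth <- lapply(years, function(y) {
    lab <- labels
    if (!is.null(change) && y >= change$year) lab[change$mask] <- change$class
    class_map(lab, legend, y, gt, spec$pixel_size_m %||% 250)
  })
  names(truth) <- years

  build_sensor <- function(sensor) {
    cal <- build_calendar(spec$years[1], spec$years[2], dual = FALSE)
    if (sensor == "B") {
      cal$doy <- cal$doy + 8L
      cal$sensor <- "B"
    }
    n_nodes <- nrow(cal)
    values <- array(NA_integer_, c(n_nodes, nr, nc))
    clean <- array(NA_integer_, c(n_nodes, nr, nc))
    reliability <- array(NA_integer_, c(n_nodes, nr, nc))
    for (k in seq_len(n_nodes)) {
      doy <- cal$doy[k]
      yr <- as.character(cal$year[k])
      lab <- truth[[yr]]$labels
      v <- matrix(NA_real_, nr, nc)
      for (ci in seq_along(legend)) {
        idx <- lab == ci
        if (!any(idx)) next
        m <- models[[legend[ci]]]
        vv <- rep(m$baseline_ndvi, sum(idx))
        for (j in seq_along(m$peaks)) {
          p <- m$peaks[[j]]
          d <- peak_doy[[legend[ci]]][[j]][idx]
          vv <- vv + p$peak_ndvi * exp(-(doy - d)^2 / (2 * p$width_days^2))
        }
        v[idx] <- vv
      }
      cl <- as.integer(round(pmin(pmax(v, -0.2), 0.9) * 10000))
      noise_sd <- matrix(vapply(models, function(m) m$noise_sd, 0)[lab], nr, nc)
      obs <- v + stats::rnorm(npix, 0, 1) * noise_sd
      obs <- pmin(pmax(obs, -0.2), 0.9)

      winter <- doy < 60 || doy > 330
      snow <- winter & (matrix(stats::runif(npix), nr, nc) < spec$snow_prob_winter)
      cloud <- !snow & (matrix(stats::runif(npix), nr, nc) < spec$cloud_prob)
      contaminated <- snow | cloud
      depress <- matrix(stats::runif(npix, 0.2, 0.6), nr, nc)
      # depression acts on (at most) the clean level, so contamination can
      # only ever lower the stored value relative to the clean curve
      clipped <- pmin(pmax(v, -0.2), 0.9)
      obs[contaminated] <- pmin(obs, clipped)[contaminated] - depress[contaminated]
      obs <- pmax(obs, -1)
      rel <- matrix(0L, nr, nc)
      rel[matrix(stats::runif(npix), nr, nc) < spec$marginal_prob] <- 1L
      rel[cloud] <- 3L
      rel[snow] <- 2L
      values[k, , ] <- as.integer(round(obs * 10000))
      clean[k, , ] <- cl
      reliability[k, , ] <- rel
    }
    list(stack = ndvi_stack(values, reliability, cal, gt,
                            spec$pixel_size_m %||% 250),
         clean = clean)
  }

  sa <- build_sensor("A")
  sb <- build_sensor("B")

  ref <- do.call(rbind, lapply(years, function(y) {
    i <- sample.int(npix, min(spec$n_ref_per_year, npix))
    row <- ((i - 1) %% nr) + 1
    col <- ((i - 1) %/% nr) + 1
    xy <- pixel_xy(gt, row, col)
    data.frame(x = xy$x, y = xy$y, row = row, col = col, year = y,
               class = truth[[as.character(y)]]$labels[cbind(row, col)])
  }))

  list(stack_a = sa$stack, stack_b = sb$stack,
       truth = truth, reference_points = ref,
       clean_a = sa$clean, clean_b = sb$clean,
       peak_doy = peak_doy, models = models, spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
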