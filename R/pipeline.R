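#' Run the full mapping pipeline on a synthetic scene
#'
#' Convenience driver chaining every stage: synthetic scene generation,
#' dual-sensor interleaving, cloud/snow gap-filling, per-year HANTS
#' smoothing, grid-stratified sampling and random-forest training on the
#' first year, per-year classification, confusion-matrix accuracy against
#' held-out reference points, area/growth series, epoch change map,
#' planting-frequency raster and wheat-peak metrics.
#'
#' @param spec A [scene_spec()] describing the scene.
#' @param models Phenology models (default [default_phenology_models()]).
#' @param hparams HANTS parameters (default [hants_params()]).
#' @param grid_size_m Sampling grid size in metres passed to
#'   [build_samples()].
#' @param per_class_per_tile Training points per class per tile.
#' @param training_years Years whose samples are pooled for training
#'   (default: all years of the scene).
#' @param n_trees Random-forest size (default 100).
#' @param seed Seed for sampling and tree growing (scene generation uses
#'   `spec$seed`).
#' @return List with all intermediate and final products: `scene`,
#'   `stack` (interleaved), `filled`, `smoothed`, `samples`, `model`,
#'   `maps`, `report` (accuracy on the scene's reference points, pooled
#'   over years), `areas`, `frequency`, `change`.
#' @export
run_pipeline <- function(spec = scene_spec(), models = default_phenology_models(),
                         hparams = hants_params(), grid_size_m = 4000,
                         per_class_per_tile = 5, training_years = NULL,
                         n_trees = 100L, seed = 1L) {
  scene <- generate_scene(spec, models)
  stack <- interleave_stacks(scene$stack_a, scene$stack_b)
  filled <- fill_stack(stack)
  smoothed <- hants_stack(filled, hparams, per_year = TRUE)

  years <- sort(unique(stack$calendar$year))
  if (is.null(training_years)) training_years <- years
  samples <- build_samples(smoothed, scene$truth, training_years,
                           grid_size_m = grid_size_m,
                           per_class_per_tile = per_class_per_tile,
                           seed = seed)
  model <- train_classifier(samples, n_trees = n_trees, seed = seed)

  maps <- lapply(years, function(y) predict_map(model, smoothed, y))
  names(maps) <- years

  cms <- lapply(years, function(y) {
    pts <- scene$reference_points[scene$reference_points$year == y, ]
    confusion(maps[[as.character(y)]], pts)
  })
  cm_total <- Reduce(`+`, lapply(cms, unclass))
  class(cm_total) <- c("confusion_matrix", class(cm_total))
  report <- accuracy_summary(cm_total)

  areas <- growth_rates(stats::setNames(
    vapply(maps, class_area, 0, target_class = "wheat_maize"), years))
  freq <- planting_frequency(maps, "wheat_maize")
  chg <- change_map(maps[[1]], maps[[length(maps)]], "wheat_maize")

  list(scene = scene, stack = stack, filled = filled, smoothed = smoothed,
       samples = samples, model = model, maps = maps,
       confusions = cms, confusion_total = cm_total, report = report,
       areas = areas, frequency = freq, change = chg)
}
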