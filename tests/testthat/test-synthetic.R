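test_that("class curves have the designed shapes", {
  m <- noise_free_models()
  # water stays negative at any day
  expect_true(all(curve_at(m$water, c(1, 100, 200, 366)) < 0))
  # noise-free wheat-maize curve peaks at the model's first peak DOY
  doys <- 60:170
  v <- curve_at(m$wheat_maize, doys)
  expect_equal(doys[which.max(v)], m$wheat_maize$peaks[[1]]$peak_doy)
  expect_error(curve_at(m$wheat_maize, 0), "doy")
  expect_error(curve_at(m$wheat_maize, 367), "doy")
})

test_that("wheat-maize curve is bimodal: dense scan finds exactly 2 peaks", {
  m <- noise_free_models()$wheat_maize
  v <- curve_at(m, 1:366) / 10000
  # independent brute-force scan for interior local maxima above baseline+0.1
  is_max <- which(diff(sign(diff(v))) == -2) + 1
  prominent <- is_max[v[is_max] > m$baseline_ndvi + 0.1]
  expect_length(prominent, 2)
  expect_true(prominent[1] >= 60 && prominent[1] <= 170)
  expect_true(prominent[2] >= 180 && prominent[2] <= 270)
})

test_that("wheat-maize model enforces its peak windows", {
  expect_error(phenology_model("wheat_maize", 0.2,
    peaks = list(list(peak_doy = 40, peak_ndvi = 0.5, width_days = 20),
                 list(peak_doy = 224, peak_ndvi = 0.5, width_days = 20))),
    "\\[60, 170\\]")
  expect_error(phenology_model("wheat_maize", 0.2,
    peaks = list(list(peak_doy = 115, peak_ndvi = 0.5, width_days = 20))),
    "exactly 2 peaks")
})

test_that("scenes are bit-reproducible from the seed", {
  s1 <- small_scene(seed = 21)
  s2 <- small_scene(seed = 21)
  expect_identical(s1$stack_a$values, s2$stack_a$values)
  expect_identical(s1$stack_b$reliability, s2$stack_b$reliability)
  expect_identical(s1$truth[["2004"]]$labels, s2$truth[["2004"]]$labels)
  expect_identical(s1$reference_points, s2$reference_points)
  s3 <- small_scene(seed = 22)
  expect_false(identical(s1$stack_a$values, s3$stack_a$values))
})

test_that("contamination flags and value depression behave as designed", {
  clean <- generate_scene(scene_spec(n_rows = 8, n_cols = 8, cloud_prob = 0,
                                     snow_prob_winter = 0,
                                     years = c(2010, 2010), seed = 4))
  expect_true(all(clean$stack_a$reliability %in% c(0L, 1L)))

  sc <- small_scene(seed = 9, cloud_prob = 0.25)
  rel <- sc$stack_a$reliability
  expect_true(any(rel == 3L))
  expect_true(any(rel == 2L))
  # snow only at winter nodes
  doy <- sc$stack_a$calendar$doy
  snow_nodes <- apply(rel == 2L, 1, any)
  expect_true(all(doy[snow_nodes] < 60 | doy[snow_nodes] > 330))
  # contamination only ever lowers the stored value relative to the clean curve
  contaminated <- rel %in% c(2L, 3L)
  expect_true(all(sc$stack_a$values[contaminated] <
                    sc$clean_a[contaminated]))
})

test_that("requested class fractions are recovered within multinomial CI", {
  fr <- c(wheat_maize = 0.45, one_season = 0.2, forest_grass = 0.15,
          water = 0.1, built_up = 0.1)
  sc <- generate_scene(scene_spec(n_rows = 64, n_cols = 64,
                                  class_fractions = fr, patch_scale_px = 1,
                                  years = c(2010, 2010), seed = 31))
  counts <- tabulate(sc$truth[["2010"]]$labels, 5)
  n <- sum(counts)
  for (i in 1:5) {
    # 99% normal-approximation CI of a multinomial count
    half <- qnorm(0.995) * sqrt(n * fr[i] * (1 - fr[i]))
    expect_lt(abs(counts[i] - n * fr[i]), half + 1)
  }
  # degenerate single-class scene
  one <- generate_scene(scene_spec(
    n_rows = 8, n_cols = 8, years = c(2010, 2010), seed = 5,
    class_fractions = c(wheat_maize = 1, one_season = 0, forest_grass = 0,
                        water = 0, built_up = 0)))
  expect_true(all(one$truth[["2010"]]$labels == 1L))
  expect_error(scene_spec(class_fractions = fr * 0.9), "sum to 1")
})

test_that("mean wheat-maize curve peaks globally in the wheat window", {
  sc <- generate_scene(scene_spec(n_rows = 16, n_cols = 16, cloud_prob = 0,
                                  snow_prob_winter = 0, years = c(2010, 2010),
                                  seed = 12),
                       models = noise_free_models())
  st <- interleave_stacks(sc$stack_a, sc$stack_b)
  wm <- sc$truth[["2010"]]$labels == 1L
  mean_curve <- apply(st$values, 1, function(m) mean(m[wm]))
  peak_doy <- st$calendar$doy[which.max(mean_curve)]
  expect_true(peak_doy >= 60 && peak_doy <= 170)
})

test_that("an optional change mask flips the truth from the given year", {
  mask <- matrix(FALSE, 8, 8); mask[1:3, 1:3] <- TRUE
  sc <- generate_scene(scene_spec(n_rows = 8, n_cols = 8, years = c(2004, 2006),
                                  seed = 6),
                       change = list(year = 2005, mask = mask, class = 4L))
  expect_false(all(sc$truth[["2004"]]$labels[mask] == 4L))
  expect_true(all(sc$truth[["2005"]]$labels[mask] == 4L))
  expect_true(all(sc$truth[["2006"]]$labels[mask] == 4L))
  same <- !mask
  expect_identical(sc$truth[["2004"]]$labels[same], sc$truth[["2006"]]$labels[same])
})
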