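# Shared fixtures. Everything is generated in code under fixed seeds; the
# larger multi-year scene pipeline is computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

small_scene <- function(seed = 11, cloud_prob = 0.2, years = c(2004, 2006),
                        n = 20) {
  generate_scene(scene_spec(n_rows = n, n_cols = n, years = years,
                            cloud_prob = cloud_prob, seed = seed,
                            n_ref_per_year = 60))
}

# Noise-free models: deterministic curves, fixed (non-drawn) peak DOYs
noise_free_models <- function() {
  m <- default_phenology_models()
  for (i in seq_along(m)) {
    m[[i]]$noise_sd <- 0
    if (!is.null(m[[i]]$peak_doy_ranges)) {
      m[[i]]$peak_doy_ranges <- lapply(m[[i]]$peaks,
                                       function(p) rep(p$peak_doy, 2))
    }
  }
  m
}

# 64 x 64, 13-year, cloud_prob 0.2 end-to-end pipeline run (cached)
full_pipeline_run <- function(seed = 2026) {
  key <- paste0("pipe_", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  spec <- scene_spec(n_rows = 64, n_cols = 64, years = c(2004, 2016),
                     cloud_prob = 0.2, seed = seed)
  res <- run_pipeline(spec, grid_size_m = 4000, per_class_per_tile = 2,
                      training_years = c(2004, 2010, 2016), seed = seed)
  .fixture_env[[key]] <- res
  res
}

# Independent piecewise-linear interpolation oracle: for each flagged index
# walk outward to the nearest good neighbours and interpolate by hand.
oracle_fill <- function(values, reliability, flag_codes = c(2, 3, 255)) {
  n <- length(values)
  bad <- reliability %in% flag_codes
  out <- values
  for (i in which(bad)) {
    lo <- i - 1L
    while (lo >= 1L && bad[lo]) lo <- lo - 1L
    hi <- i + 1L
    while (hi <= n && bad[hi]) hi <- hi + 1L
    out[i] <- if (lo < 1L) values[hi]
    else if (hi > n) values[lo]
    else values[lo] + (values[hi] - values[lo]) * (i - lo) / (hi - lo)
  }
  as.integer(round(out))
}

# Independent normal-equations least-squares oracle for the harmonic model
oracle_harmonic_fit <- function(y, doys, n_freq = 3, period = 368) {
  A <- matrix(1, length(doys), 1)
  for (i in seq_len(n_freq)) {
    A <- cbind(A, cos(2 * pi * i * doys / period),
               sin(2 * pi * i * doys / period))
  }
  solve(t(A) %*% A, t(A) %*% y)[, 1]
}
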