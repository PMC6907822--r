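doys46 <- seq(1, by = 8, length.out = 46)
band_limited <- function(doys, a0 = 4000, a1 = -2500, b1 = 500, a2 = 800,
                         b2 = -300, T = 368) {
  a0 + a1 * cos(2 * pi * doys / T) + b1 * sin(2 * pi * doys / T) +
    a2 * cos(4 * pi * doys / T) + b2 * sin(4 * pi * doys / T)
}

test_that("signals inside the harmonic span are recovered exactly", {
  y <- band_limited(doys46)
  f <- hants(y, doys46)
  expect_true(f$converged)
  expect_false(any(f$rejected_mask))
  expect_lt(max(abs(fitted(f) - y)), 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-6)

  const <- hants(rep(5000, 46), doys46)
  expect_equal(unname(coef(const)["a0"]), 5000)
  expect_lt(max(abs(coef(const)[-1])), 1e-8)
})

test_that("cloud-like depressions are rejected and the clean curve restored", {
  y <- band_limited(doys46)
  hit <- c(3, 11, 24, 30, 42)
  y2 <- y
  y2[hit] <- y2[hit] - 3000
  f <- hants(y2, doys46)
  expect_true(f$converged)
  expect_true(all(f$rejected_mask[hit]))
  expect_false(any(f$rejected_mask[-hit]))
  # smoothed within the fit error tolerance of the clean signal everywhere
  expect_lt(max(abs(fitted(f) - y)), 1000)
  # coefficients match an independent normal-equations solve on the
  # accepted (clean) subset
  oracle <- oracle_harmonic_fit(y2[-hit], doys46[-hit])
  expect_lt(max(abs(coef(f) - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("out-of-range values are pre-rejected and scarcity errors carry counts", {
  y <- band_limited(doys46)
  y[5] <- 9990  # above the default valid range
  f <- hants(y, doys46)
  expect_true(f$rejected_mask[5])
  short <- band_limited(doys46[1:20])
  short[1:8] <- -5000  # leaves 12 in-range points, below the floor of 15
  expect_error(hants(short, doys46[1:20]), "12 in-range.*15")
  expect_error(hants(band_limited(doys46[1:10]), doys46[1:10]), "minimum")
})

test_that("suppression sides behave as documented", {
  set.seed(42)
  y <- band_limited(doys46) + rnorm(46, 0, 150)
  low <- hants(y, doys46, hants_params(suppression = "low"))
  expect_true(low$converged)
  acc <- !low$rejected_mask
  expect_true(all(fitted(low)[acc] >= y[acc] - 1000))

  none <- hants(y, doys46, hants_params(suppression = "none"))
  expect_true(none$converged)
  acc <- !none$rejected_mask
  # plain least squares on symmetric noise is unbiased: mean residual ~ 0
  expect_lt(abs(mean(y[acc] - fitted(none)[acc])), 3 * 150 / sqrt(46))
})

test_that("iteration terminates with monotonically shrinking accepted set", {
  set.seed(8)
  for (i in 1:20) {
    y <- band_limited(doys46) + rnorm(46, 0, 400) -
      3000 * rbinom(46, 1, 0.15)
    f <- hants(y, doys46)
    expect_lte(f$iterations, f$params$max_iter)
    expect_gte(sum(!f$rejected_mask), 15)  # 2*3 + 1 + 8
    if (f$converged) {
      # one rejection per iteration except the final accepting pass
      expect_equal(sum(f$rejected_mask[y >= -2000 & y <= 9000]),
                   f$iterations - 1L)
    }
  }
})

test_that("predict() evaluates the harmonic model at arbitrary days", {
  y <- band_limited(doys46)
  f <- hants(y, doys46)
  dd <- c(4.5, 100, 250.25)
  expect_equal(predict(f, dd), band_limited(dd), tolerance = 1e-8)
})

test_that("hants_stack smooths per year, keeps length, and falls back gracefully", {
  sc <- generate_scene(scene_spec(n_rows = 8, n_cols = 8, cloud_prob = 0,
                                  snow_prob_winter = 0, years = c(2004, 2016),
                                  seed = 23))
  st <- interleave_stacks(sc$stack_a, sc$stack_b)
  sm <- hants_stack(fill_stack(st))
  expect_equal(dim(sm$values), dim(st$values))
  expect_equal(dim(sm$values)[1], 598)
  expect_identical(sm$reliability, st$reliability)

  # contamination-free scene: for classes whose annual curve is within
  # reach of 3 harmonics (everything except the bimodal rotation), the
  # per-pixel RMSE of smoothed vs clean truth stays below the generator
  # noise level (noise_sd x 10,000)
  cal_a <- sc$stack_a$calendar
  ka <- match(paste(cal_a$year, cal_a$doy),
              paste(st$calendar$year, st$calendar$doy))
  clean <- array(NA_integer_, dim(st$values))
  clean[ka, , ] <- sc$clean_a
  clean[setdiff(seq_len(598), ka), , ] <- sc$clean_b
  lab <- sc$truth[["2004"]]$labels
  rmse <- sqrt(apply((sm$values - clean)^2, c(2, 3), mean))
  expect_lt(max(rmse[lab != 1L]), 0.02 * 10000)

  # the bimodal wheat-maize curve exceeds the 3-harmonic span (its floor is
  # the harmonic truncation error, not the noise level), but the smoothing
  # must preserve the phenological signal it exists to expose: the wheat
  # peak node survives to within one node (8 days)
  doys <- st$calendar$doy[1:46]
  for (p in which(lab == 1L)[1:5]) {
    r <- ((p - 1) %% nrow(lab)) + 1; c <- ((p - 1) %/% nrow(lab)) + 1
    for (yr in c(1, 13)) {
      idx <- (yr - 1) * 46 + 1:46
      pk_sm <- peak_metrics(sm$values[idx, r, c], doys, c(60, 170))
      pk_cl <- peak_metrics(clean[idx, r, c], doys, c(60, 170))
      expect_lte(abs(pk_sm$peak_doy - pk_cl$peak_doy), 8)
    }
  }

  # whole-series mode also preserves shape
  sm2 <- hants_stack(fill_stack(st), per_year = FALSE)
  expect_equal(dim(sm2$values), dim(st$values))
})
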