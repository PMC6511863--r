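test_that("harmonic bias on a flat profile gives the analytic Gaussian", {
  prof <- flat_profile()
  spec <- window_spec(0.1, k = 210000, n_samples = 20000, burnin = 0,
                      seed = 99)
  w <- sample_window(prof, spec)
  sigma <- sqrt(1 / k_internal(210000))   # ~0.0350 A at 310 K
  expect_equal(sigma, 0.035, tolerance = 0.01)
  expect_lt(abs(mean(w$retained) - 0.1), 3 * sigma / sqrt(20000))
  expect_lt(abs(sd(w$retained) - sigma), 0.03 * sigma)
})

test_that("a linear profile shifts the window mean by -slope/k", {
  slope <- 30    # kBT/A, strong enough to see against sampling noise
  prof <- linear_profile(slope)
  spec <- window_spec(0, k = 210000, n_samples = 20000, burnin = 0, seed = 5)
  w <- sample_window(prof, spec)
  k_int <- k_internal(210000)
  shift <- -slope / k_int
  expect_equal(mean(w$retained), shift,
               tolerance = 4 * sqrt(1 / k_int) / sqrt(20000))
})

test_that("sampled draws match the discretized biased density (KS test)", {
  prof <- packaged_profile("rATP", "cognate")
  spec <- window_spec(-0.3, k = 210000, n_samples = 10000, burnin = 0,
                      seed = 314)
  w <- sample_window(prof, spec)
  k_int <- k_internal(spec$k)
  sigma <- sqrt(1 / k_int)
  lo <- max(prof$domain[1], spec$center - 6 * sigma)
  hi <- min(prof$domain[2], spec$center + 6 * sigma)
  grid <- seq(lo, hi, length.out = 2001)
  dens <- exp(-(profile_eval(prof, grid) +
                  0.5 * k_int * (grid - spec$center)^2))
  dx <- diff(grid)
  cdf <- c(0, cumsum((dens[-1] + dens[-length(dens)]) / 2 * dx))
  cdf <- cdf / cdf[length(cdf)]
  cdf_fun <- approxfun(grid, cdf, rule = 2)
  ks <- suppressWarnings(ks.test(w$samples, cdf_fun))
  expect_gt(ks$p.value, 0.01)
})

test_that("sampling is reproducible and burn-in is flagged", {
  prof <- flat_profile()
  spec <- window_spec(0, n_samples = 1000, burnin = 0.25, seed = 17)
  w1 <- sample_window(prof, spec)
  w2 <- sample_window(prof, spec)
  expect_identical(w1$samples, w2$samples)
  expect_equal(w1$n_burnin, 250)
  expect_equal(length(w1$retained), 750)
  expect_identical(w1$retained, w1$samples[-(1:250)])
  w3 <- sample_window(prof, window_spec(0, n_samples = 1000, burnin = 0.25,
                                        seed = 18))
  expect_false(identical(w1$samples, w3$samples))
})

test_that("window validation rejects invalid specs and centers", {
  expect_error(window_spec(0, k = -1), "k must be")
  expect_error(window_spec(0, n_samples = 5), ">= 10")
  expect_error(window_spec(0, burnin = 0.95), "burn-in")
  expect_error(sample_window(flat_profile(), window_spec(5)),
               "outside profile domain")
})

test_that("window layouts reproduce the standard window counts", {
  expect_length(window_layout(-1.3, 1.3), 27)
  expect_length(window_layout(-2.2, 2.2), 45)
  expect_length(window_layout(-2.6, 2.6), 53)
  lay <- window_layout(-1.3, 1.3, seed = 1)
  expect_equal(vapply(lay, function(s) s$center, numeric(1)),
               seq(-1.3, 1.3, by = 0.1))
  # graded pattern: 3 stiff central windows, 2 soft terminal windows
  gr <- window_layout(-1.3, 1.3, k_pattern = "graded")
  ks <- vapply(gr, function(s) s$k, numeric(1))
  expect_equal(sum(ks == 2.1e6), 3)
  expect_equal(ks[c(1, 27)], rep(2.1e4, 2))
  expect_equal(sum(ks == 2.1e5), 22)
  # per-window seeds are distinct and stable
  s1 <- vapply(window_layout(-1.3, 1.3, seed = 7), function(s) s$seed,
               integer(1))
  s2 <- vapply(window_layout(-1.3, 1.3, seed = 7), function(s) s$seed,
               integer(1))
  expect_identical(s1, s2)
  expect_equal(anyDuplicated(s1), 0L)
})
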