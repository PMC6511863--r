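# minimal window object accepted by the WHAM functions
make_window <- function(center, values, k = 210000) {
  structure(list(spec = list(center = center, k = k), retained = values),
            class = "window_series")
}

test_that("a single window on a flat landscape unbiases to a flat PMF", {
  set.seed(11)
  k <- 26000                      # sigma = 0.1 A
  sigma <- sqrt(1 / k_internal(k))
  w <- make_window(0, rnorm(2e5, 0, sigma), k = k)
  pmf <- wham_reconstruct(list(w), bin_width = 0.02, zero = "global-min")
  core <- is.finite(pmf$G) & abs(pmf$grid) < 2 * sigma
  expect_lt(diff(range(pmf$G[core])), 0.1)
})

test_that("duplicating a window leaves the reconstruction unchanged", {
  set.seed(12)
  vals <- rnorm(5000, 0.05, 0.1)
  w <- make_window(0, vals, k = 26000)
  p1 <- wham_reconstruct(list(w), bin_width = 0.02)
  p2 <- wham_reconstruct(list(w, w), bin_width = 0.02)
  expect_equal(p1$G, p2$G, tolerance = 1e-6)
})

test_that("WHAM matches an independent maximum-likelihood oracle", {
  set.seed(13)
  k <- 26000
  sigma <- sqrt(1 / k_internal(k))
  centers <- c(-0.15, 0, 0.15)
  # biased draws from a quadratic landscape G(x) = 40 x^2 (kBT)
  windows <- lapply(centers, function(c0) {
    prec <- 80 + 1 / sigma^2              # quadratic G adds precision 2*40
    mu <- (c0 / sigma^2) / prec
    make_window(c0, rnorm(400, mu, sqrt(1 / prec)), k = k)
  })
  pmf <- wham_reconstruct(windows, bin_width = 0.05, tol = 1e-13,
                          zero = "none")
  oracle <- wham_oracle(windows, bin_width = 0.05)
  expect_equal(pmf$grid, oracle$grid)
  occ <- is.finite(pmf$G) & is.finite(oracle$G)
  d <- pmf$G[occ] - oracle$G[occ]
  expect_lt(max(abs(d - mean(d))), 1e-6)
})

test_that("dense windows recover a known profile up to a constant", {
  prof <- peak_profile()            # anchors (-0.5,0), (0,2), (0.5,-1)
  layout <- window_layout(-0.5, 0.5, by = 0.05, k = 26000,
                          n_samples = 4000, burnin = 0, seed = 77)
  windows <- sample_windows(prof, layout)
  pmf <- wham_reconstruct(windows, bin_width = 0.02, zero = "none")
  occ <- is.finite(pmf$G)
  truth <- profile_eval(prof, pmf$grid[occ])
  d <- pmf$G[occ] - truth
  expect_lt(sqrt(mean((d - mean(d))^2)), 0.15)
})

test_that("disconnected window chains are rejected with the gap named", {
  set.seed(14)
  w1 <- make_window(0, rnorm(1000, 0, 0.035))
  w2 <- make_window(2, rnorm(1000, 2, 0.035))
  expect_error(wham_reconstruct(list(w1, w2)), "connected chain")
  expect_error(wham_reconstruct(list(w1, w2)), "0 and 2")
})

test_that("input validation rejects short or non-finite windows", {
  expect_error(wham_reconstruct(list()), "at least one window")
  expect_error(wham_reconstruct(list(make_window(0, c(1, 2, 3)))),
               ">= 10 finite")
  expect_error(wham_reconstruct(list(make_window(0, c(rnorm(20), NA)))),
               ">= 10 finite")
})

test_that("zero conventions shift but do not reshape the PMF", {
  set.seed(15)
  w <- make_window(0, rnorm(5000, 0, 0.1), k = 26000)
  p_none <- wham_reconstruct(list(w), zero = "none")
  p_min <- wham_reconstruct(list(w), zero = "global-min")
  occ <- is.finite(p_min$G)
  expect_equal(min(p_min$G[occ]), 0)
  expect_equal(diff(p_min$G[occ]), diff(p_none$G[occ]), tolerance = 1e-12)
})

test_that("bootstrap sigma is zero for a degenerate single-bin window", {
  w <- make_window(0, rep(0.01, 50))
  pmf <- bootstrap_pmf(list(w), n_boot = 20, seed = 2)
  expect_equal(pmf$sigma[is.finite(pmf$G)], 0)
  expect_equal(attr(pmf, "n_boot_failed"), 0L)
})

test_that("bootstrap sigma shrinks roughly as 1/sqrt(n)", {
  prof <- peak_profile()
  sig_at <- function(n) {
    layout <- window_layout(-0.5, 0.5, by = 0.1, k = 26000,
                            n_samples = n, burnin = 0, seed = 21)
    windows <- sample_windows(prof, layout)
    pmf <- bootstrap_pmf(windows, n_boot = 60, seed = 5)
    stats::median(pmf$sigma[is.finite(pmf$G)])
  }
  r <- sig_at(400) / sig_at(6400)
  expect_gt(r, 2)    # ideal ratio 4
  expect_lt(r, 8)
})

test_that("barrier extraction reports the stationary points and summaries", {
  # noiseless PMF built directly: double-well with barrier
  grid <- seq(-1, 1, by = 0.02)
  G <- 3 * (grid^2 - 0.5)^2 - grid   # minima near -0.6 / +0.66, max near 0
  pmf <- structure(list(grid = grid, G = G - min(G),
                        sigma = rep(NA_real_, length(G)),
                        n_samples = rep(100L, length(G)),
                        bin_width = 0.02, zero = "none",
                        f = 0, iterations = 1L, residual = 0,
                        windows = list(centers = 0, k = 210000)),
                   class = "pmf_profile")
  b <- extract_barriers(pmf)
  expect_false(b$monotone)
  i_pre <- which.min(abs(grid - b$pre_min["coord"]))
  expect_equal(unname(b$dE_in), max(G[grid > -0.3 & grid < 0.3]) -
                 min(G[grid < -0.3]), tolerance = 1e-12)
  expect_equal(unname(b$dG_end + b$dE_rev), unname(b$dE_in), tolerance = 1e-12)
  # monotone profile: barriers are zero and flagged
  pmf$G <- grid + 1
  bm <- extract_barriers(pmf)
  expect_true(bm$monotone)
  expect_equal(bm$dE_in, 0)
  expect_error(extract_barriers(pmf, pre_region = c(0, 1),
                                ins_region = c(-1, 0)), "disjoint")
})
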