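#' @title PMF reconstruction by the weighted histogram analysis method
#' @description
#' Umbrella windows bias the sampled coordinate with harmonic restraints;
#' WHAM recovers the unbiased probability P(x), and hence the potential of
#' mean force G(x) = -kBT ln P(x), by self-consistent iteration of the
#' window free-energy shifts f_i:
#'
#'   P(x_b) = sum_i H_ib / sum_i n_i exp(f_i) exp(-w_i(x_b))
#'   exp(-f_i) = sum_b P(x_b) exp(-w_i(x_b))
#'
#' with w_i(x) = k_i/2 (x - x0_i)^2 the restraint potential in kBT.
#' @name wham
NULL

# Core self-consistent solver on pre-binned data.  H: windows x bins count
# matrix; bias: windows x bins matrix of exp(-w_i(x_b)); f0: starting shifts.
# The plain self-consistent update converges only linearly (slowly when
# window overlap is thin), so once the iteration is in the basin the root of
# update(f) - f = 0 is polished by Newton steps on the gauge-reduced system
# (f_1 fixed at 0), with a finite-difference Jacobian; every Newton step is
# validated against the plain update and rejected if it does not reduce the
# residual.
wham_core <- function(H, bias, tol = 1e-8, max_iter = 1e5, f0 = NULL) {
  n_i <- rowSums(H)
  H_b <- colSums(H)
  occ <- H_b > 0
  nw <- nrow(H)
  f <- if (is.null(f0)) numeric(nw) else f0 - f0[1]
  tb <- t(bias)
  update <- function(f) {
    denom <- as.vector(tb %*% (n_i * exp(f)))
    P <- ifelse(occ, H_b / denom, 0)
    f_new <- -log(as.vector(bias %*% P))
    f_new - f_new[1]
  }
  iter <- 0L
  res <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    f_new <- update(f)
    res <- max(abs(f_new - f))
    f <- f_new
    if (res < tol) break
    if (nw > 1 && res < 0.5 && iter %% 5 == 0) {
      # Newton polish on r(f) = update(f) - f, free coordinates f[-1]
      r0 <- update(f) - f
      eps <- 1e-7
      J <- matrix(0, nw - 1, nw - 1)
      for (j in 2:nw) {
        fp <- f; fp[j] <- fp[j] + eps
        J[, j - 1] <- ((update(fp) - fp) - r0)[-1] / eps
      }
      step <- tryCatch(solve(J, -r0[-1]), error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        f_try <- f
        f_try[-1] <- f_try[-1] + step
        r_try <- max(abs(update(f_try) - f_try))
        if (r_try < res) { f <- f_try; res <- r_try }
        if (res < tol) break
      }
    }
  }
  denom <- as.vector(tb %*% (n_i * exp(f)))
  P <- ifelse(occ, H_b / denom, 0)
  P <- P / sum(P)
  list(P = P, f = f, iterations = iter, residual = res,
       converged = res < tol, occupied = occ, n_bin = H_b)
}

bin_windows <- function(windows, bin_width) {
  values <- lapply(windows, function(w) w$retained)
  rng <- range(unlist(values))
  # bin edges aligned on multiples of the bin width
  lo <- floor(rng[1] / bin_width) * bin_width
  hi <- ceiling(rng[2] / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  H <- t(vapply(values, function(v) {
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                length(centers))
    tabulate(idx, nbins = length(centers))
  }, integer(length(centers))))
  list(H = H, centers = centers, edges = edges)
}

bias_matrix <- function(windows, centers) {
  t(vapply(windows, function(w) {
    k_int <- k_to_kbt_a2(w$spec$k)
    wpot <- 0.5 * k_int * (centers - w$spec$center)^2
    exp(-wpot)
  }, numeric(length(centers))))
}

check_overlap <- function(H, window_centers) {
  nw <- nrow(H)
  if (nw == 1) return(invisible(TRUE))
  ord <- order(window_centers)
  occ <- H[ord, , drop = FALSE] > 0
  # connectivity of windows through shared occupied bins
  comp <- seq_len(nw)
  for (i in seq_len(nw - 1)) {
    for (j in seq(i + 1, nw)) {
      if (any(occ[i, ] & occ[j, ])) comp[comp == comp[j]] <- comp[i]
    }
  }
  if (length(unique(comp)) > 1) {
    first_gap <- which(diff(match(comp, unique(comp))) != 0)[1]
    stop("umbrella windows do not form a connected chain: no occupied bin ",
         "is shared across the gap between window centers ",
         window_centers[ord][first_gap], " and ",
         window_centers[ord][first_gap + 1], " A")
  }
  adj <- vapply(seq_len(nw - 1), function(i) any(occ[i, ] & occ[i + 1, ]),
                logical(1))
  if (!all(adj))
    warning("adjacent windows at centers ",
            paste(round(window_centers[ord][which(!adj)], 3), collapse = ", "),
            " A share no occupied bin with their right neighbour")
  invisible(TRUE)
}

apply_zero <- function(G, centers, zero) {
  occ <- is.finite(G)
  ref <- switch(zero,
                "pre-min" = {
                  left <- occ & centers <= stats::median(range(centers[occ]))
                  min(G[left])
                },
                "global-min" = min(G[occ]),
                "none" = 0)
  G - ref
}

#' Reconstruct a PMF from umbrella windows
#'
#' @param windows list of [`window_series`][sample_window] objects (or
#'   anything with `$spec$center`, `$spec$k` and `$retained`)
#' @param bin_width histogram bin width in Angstrom; the default 0.02 A gives
#'   five bins per 0.1 A window spacing
#' @param tol convergence tolerance on the maximum absolute change of the
#'   window shifts (kBT)
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual
#' @param zero zero-of-energy convention: `"pre-min"` (G = 0 at the minimum
#'   of the left half of the covered range, i.e. the pre-insertion minimum),
#'   `"global-min"`, or `"none"`
#' @return object of class `pmf_profile`: `grid` (bin centers, A), `G` (kBT,
#'   `NA` on unoccupied bins), `n_samples` per bin, `sigma` (filled by
#'   [bootstrap_pmf()]), window shifts `f`, and convergence metadata
#' @seealso [bootstrap_pmf()], [extract_barriers()]
#' @export
wham_reconstruct <- function(windows, bin_width = 0.02, tol = 1e-8,
                             max_iter = 1e5,
                             zero = c("pre-min", "global-min", "none")) {
  zero <- match.arg(zero)
  if (length(windows) < 1) stop("need at least one window")
  for (w in windows)
    if (length(w$retained) < 10 || !all(is.finite(w$retained)))
      stop("every window needs >= 10 finite retained samples")
  bw <- bin_windows(windows, bin_width)
  wc <- vapply(windows, function(w) w$spec$center, numeric(1))
  check_overlap(bw$H, wc)
  bias <- bias_matrix(windows, bw$centers)
  sol <- wham_core(bw$H, bias, tol = tol, max_iter = max_iter)
  if (!sol$converged)
    stop("WHAM did not converge in ", max_iter, " iterations (residual ",
         format(sol$residual), " kBT)")
  G <- ifelse(sol$occupied, -log(sol$P), NA_real_)
  G <- apply_zero(G, bw$centers, zero)
  structure(list(grid = bw$centers, G = G, sigma = rep(NA_real_, length(G)),
                 n_samples = sol$n_bin, f = sol$f,
                 bin_width = bin_width, zero = zero,
                 iterations = sol$iterations, residual = sol$residual,
                 windows = list(centers = wc,
                                k = vapply(windows, function(w) w$spec$k,
                                           numeric(1)))),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- is.finite(x$G)
  cat(sprintf("<pmf_profile> %d bins of %.3g A over [%.2f, %.2f] A, %d windows\n",
              length(x$grid), x$bin_width, min(x$grid), max(x$grid),
              length(x$windows$centers)))
  cat(sprintf("  G range [%.2f, %.2f] kBT (zero: %s); converged in %d iterations (residual %.2e)\n",
              min(x$G[occ]), max(x$G[occ]), x$zero, x$iterations, x$residual))
  if (any(is.finite(x$sigma)))
    cat(sprintf("  bootstrap sigma: median %.3f kBT\n",
                stats::median(x$sigma[is.finite(x$sigma)])))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, show_sigma = TRUE, ...) {
  graphics::plot(x$grid, x$G, type = "l",
                 xlab = expression(paste(delta, "rmsd (", ring(A), ")")),
                 ylab = expression(G ~ (k[B] * T)), ...)
  if (show_sigma && any(is.finite(x$sigma))) {
    ok <- is.finite(x$G) & is.finite(x$sigma)
    graphics::arrows(x$grid[ok], x$G[ok] - x$sigma[ok],
                     x$grid[ok], x$G[ok] + x$sigma[ok],
                     length = 0.01, angle = 90, code = 3,
                     col = "grey60")
  }
  invisible(x)
}

#' @export
as.data.frame.pmf_profile <- function(x, ...) {
  data.frame(coord_A = x$grid, G_kBT = x$G, sigma_kBT = x$sigma,
             n_samples = x$n_samples)
}

#' Bootstrap uncertainty of a WHAM PMF
#'
#' Resamples each window's retained coordinate values with replacement,
#' recomputes the WHAM reconstruction for every replicate (re-anchored to
#' the same zero convention), and returns the pointwise standard deviation
#' over replicates, sigma_PMF(x) = sd over the N bootstrapped G_b(x).
#' Because WHAM only consumes the per-window histograms, resampling a
#' window's values with replacement is performed as a multinomial redraw of
#' its histogram counts, which is distributionally identical.
#'
#' @param windows list of `window_series` (same input as [wham_reconstruct()])
#' @param n_boot number of bootstrap replicates (default 200)
#' @param seed RNG seed for the resampling
#' @param bin_width,tol,max_iter,zero as in [wham_reconstruct()]
#' @return the base `pmf_profile` with `sigma` filled in, plus attributes
#'   `n_boot_used` (converged replicates) and `n_boot_failed`
#' @export
bootstrap_pmf <- function(windows, n_boot = 200, seed = 20190327,
                          bin_width = 0.02, tol = 1e-8, max_iter = 1e5,
                          zero = c("pre-min", "global-min", "none")) {
  zero <- match.arg(zero)
  if (n_boot < 2) stop("need at least 2 bootstrap replicates")
  base <- wham_reconstruct(windows, bin_width = bin_width, tol = tol,
                           max_iter = max_iter, zero = zero)
  bw <- bin_windows(windows, bin_width)
  bias <- bias_matrix(windows, bw$centers)
  n_i <- rowSums(bw$H)
  nb <- ncol(bw$H)
  G_rep <- matrix(NA_real_, nrow = n_boot, ncol = nb)
  failed <- 0L
  set.seed(seed)
  for (r in seq_len(n_boot)) {
    Hr <- t(vapply(seq_len(nrow(bw$H)), function(i)
      as.integer(stats::rmultinom(1, n_i[i], bw$H[i, ] / n_i[i])),
      integer(nb)))
    sol <- wham_core(Hr, bias, tol = tol, max_iter = max_iter, f0 = base$f)
    if (!sol$converged) { failed <- failed + 1L; next }
    G <- ifelse(sol$occupied, -log(sol$P), NA_real_)
    G_rep[r, ] <- apply_zero(G, bw$centers, zero)
  }
  if (failed > 0.1 * n_boot)
    stop(failed, " of ", n_boot, " bootstrap replicates failed to converge")
  base$sigma <- apply(G_rep, 2, stats::sd, na.rm = TRUE)
  base$sigma[!is.finite(base$G)] <- NA_real_
  attr(base, "n_boot_used") <- n_boot - failed
  attr(base, "n_boot_failed") <- failed
  base
}

#' Extract barrier and end-state summaries from a PMF
#'
#' Locates the pre-insertion minimum (lowest bin in `pre_region`), the
#' insertion minimum (lowest bin in `ins_region`) and the transition maximum
#' (highest bin strictly between the two minima), and reports the forward
#' insertion barrier dE_in = G(max) - G(pre min), the reverse barrier
#' dE_rev = G(max) - G(ins min), and the end-state difference
#' dG_end = G(ins min) - G(pre min).
#'
#' @param pmf a `pmf_profile`
#' @param pre_region,ins_region disjoint coordinate intervals (length-2
#'   numeric) searched for the two minima; default to the left and right
#'   thirds of the covered range
#' @return object of class `barrier_summary`; if no interior maximum exists
#'   (monotone profile) barriers are 0 with `monotone = TRUE`
#' @export
extract_barriers <- function(pmf, pre_region = NULL, ins_region = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  occ <- is.finite(pmf$G)
  rng <- range(pmf$grid[occ])
  third <- diff(rng) / 3
  if (is.null(pre_region)) pre_region <- c(rng[1], rng[1] + third)
  if (is.null(ins_region)) ins_region <- c(rng[2] - third, rng[2])
  if (max(pre_region) > min(ins_region))
    stop("pre_region and ins_region must be disjoint, pre_region first")
  in_pre <- occ & pmf$grid >= pre_region[1] & pmf$grid <= pre_region[2]
  in_ins <- occ & pmf$grid >= ins_region[1] & pmf$grid <= ins_region[2]
  if (!any(in_pre) || !any(in_ins)) stop("empty search region")
  i_pre <- which(in_pre)[which.min(pmf$G[in_pre])]
  i_ins <- which(in_ins)[which.min(pmf$G[in_ins])]
  between <- occ & seq_along(pmf$G) > i_pre & seq_along(pmf$G) < i_ins
  monotone <- FALSE
  if (any(between)) {
    i_ts <- which(between)[which.max(pmf$G[between])]
    if (pmf$G[i_ts] <= max(pmf$G[i_pre], pmf$G[i_ins])) monotone <- TRUE
  } else {
    monotone <- TRUE
    i_ts <- NA_integer_
  }
  if (monotone) {
    dE_in <- 0; dE_rev <- 0
    ts <- c(coord = NA_real_, G = NA_real_)
  } else {
    dE_in <- pmf$G[i_ts] - pmf$G[i_pre]
    dE_rev <- pmf$G[i_ts] - pmf$G[i_ins]
    ts <- c(coord = pmf$grid[i_ts], G = pmf$G[i_ts])
  }
  sig <- function(i) if (!is.na(i) && is.finite(pmf$sigma[i])) pmf$sigma[i] else NA_real_
  structure(list(pre_min = c(coord = pmf$grid[i_pre], G = pmf$G[i_pre]),
                 ts_max = ts,
                 ins_min = c(coord = pmf$grid[i_ins], G = pmf$G[i_ins]),
                 dE_in = dE_in, dE_rev = dE_rev,
                 dG_end = pmf$G[i_ins] - pmf$G[i_pre],
                 sigma = c(pre_min = sig(i_pre),
                           ts_max = if (monotone) NA_real_ else sig(i_ts),
                           ins_min = sig(i_ins)),
                 monotone = monotone),
            class = "barrier_summary")
}

#' @export
print.barrier_summary <- function(x, ...) {
  cat("<barrier_summary>\n")
  cat(sprintf("  pre-insertion min: G = %.2f kBT at %.2f A\n",
              x$pre_min["G"], x$pre_min["coord"]))
  if (!x$monotone)
    cat(sprintf("  transition max:    G = %.2f kBT at %.2f A\n",
                x$ts_max["G"], x$ts_max["coord"]))
  cat(sprintf("  insertion min:     G = %.2f kBT at %.2f A\n",
              x$ins_min["G"], x$ins_min["coord"]))
  cat(sprintf("  dE_in = %.2f, dE_rev = %.2f, dG_end = %.2f kBT%s\n",
              x$dE_in, x$dE_rev, x$dG_end,
              if (x$monotone) "  [monotone profile: no interior maximum]" else ""))
  invisible(x)
}
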