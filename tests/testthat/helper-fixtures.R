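# shared test fixtures, built in code

# flat reference profile on [-1, 1]
flat_profile <- function(domain = c(-1, 1)) {
  build_reference_profile(cbind(seq(domain[1], domain[2], length.out = 5), 0),
                          domain = domain)
}

# linear profile G = slope * x
linear_profile <- function(slope, domain = c(-1, 1)) {
  x <- seq(domain[1], domain[2], length.out = 5)
  build_reference_profile(cbind(x, slope * x), domain = domain)
}

# small peaked profile for quick WHAM recovery checks
peak_profile <- function() {
  build_reference_profile(cbind(c(-0.5, 0, 0.5), c(0, 2, -1)),
                          domain = c(-0.5, 0.5))
}

# Gaussian bidirectional samples consistent with Crooks for a single pair
planted_pair <- function(dg, sigma = 0.5, n = 5000, seed = 1) {
  set.seed(seed)
  list(w_f = rnorm(n, dg + sigma^2 / 2, sigma),
       w_r = rnorm(n, -dg + sigma^2 / 2, sigma))
}

# harmonic-bias internal force constant (kBT/A^2) for a spec in kJ/mol/nm^2
k_internal <- function(k) k_to_kbt_a2(k)

# independent WHAM oracle: maximize the binned multinomial log-likelihood
# over softmax-parameterized bin probabilities with stats::optim (BFGS,
# analytic gradient); shares no code with the package's self-consistent
# iteration.  Returns G = -log(p) up to an additive constant.
wham_oracle <- function(windows, bin_width) {
  values <- lapply(windows, function(w) w$retained)
  rng <- range(unlist(values))
  lo <- floor(rng[1] / bin_width) * bin_width
  hi <- ceiling(rng[2] / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  H <- t(sapply(values, function(v) {
    idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                length(centers))
    tabulate(idx, nbins = length(centers))
  }))
  C <- t(sapply(windows, function(w) {
    exp(-0.5 * k_internal(w$spec$k) * (centers - w$spec$center)^2)
  }))
  n_i <- rowSums(H)
  H_b <- colSums(H)
  occ <- H_b > 0
  Cocc <- C[, occ, drop = FALSE]
  Hocc <- H_b[occ]
  nb <- sum(occ)
  nll <- function(theta) {
    p <- exp(theta - max(theta)); p <- p / sum(p)
    z <- as.vector(Cocc %*% p)
    -(sum(Hocc * log(p)) - sum(n_i * log(z)))
  }
  grad <- function(theta) {
    p <- exp(theta - max(theta)); p <- p / sum(p)
    z <- as.vector(Cocc %*% p)
    gp <- Hocc / p - as.vector(t(Cocc) %*% (n_i / z))
    # softmax chain rule
    -(p * (gp - sum(gp * p)))
  }
  fit <- optim(rep(0, nb), nll, grad, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  # Newton polish with a finite-difference Hessian of the analytic gradient
  # (the softmax gauge direction is pinned at theta[1]); BFGS alone stops
  # with a gradient around 1e-6, too loose for the equivalence check
  for (it in 1:50) {
    g <- grad(fit$par)
    if (max(abs(g)) < 1e-11) break
    eps <- 1e-6
    Hm <- vapply(seq_len(nb), function(j) {
      tp <- fit$par; tp[j] <- tp[j] + eps
      (grad(tp) - g) / eps
    }, numeric(nb))
    Hm <- (Hm + t(Hm)) / 2
    step <- tryCatch(solve(Hm[-1, -1], -g[-1]), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cand <- fit$par
    cand[-1] <- cand[-1] + step
    if (max(abs(grad(cand))) < max(abs(g))) fit$par <- cand else break
  }
  p <- exp(fit$par - max(fit$par)); p <- p / sum(p)
  G <- rep(NA_real_, length(centers))
  G[occ] <- -log(p)
  list(grid = centers, G = G, convergence = fit$convergence)
}
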