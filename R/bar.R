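#' @title Bennett acceptance ratio free-energy estimation
#' @description
#' Bidirectional alchemical perturbation samples are combined per adjacent
#' lambda pair with the Bennett acceptance ratio (BAR), the minimum-variance
#' estimator for two-state free-energy differences; legs are summed and the
#' relative binding free energy follows from the thermodynamic cycle
#' ddGb = dGa(protein) - dGa(solution).
#' @name alchemy
NULL

fermi <- function(x) 1 / (1 + exp(x))

# Bennett self-consistency residual at trial dG (kBT units):
#   sum_F fermi(M + wF - dG) - sum_R fermi(-M + wR + dG)
bar_residual <- function(dG, w_f, w_r, M) {
  sum(fermi(M + w_f - dG)) - sum(fermi(-M + w_r + dG))
}

#' BAR estimate for one lambda pair
#'
#' Solves the Bennett self-consistency equation for the free-energy
#' difference dG (kBT) given forward perturbation energies `w_f` (sampled in
#' the A ensemble, evaluated toward B) and backward energies `w_r` (sampled
#' in B toward A).  Unequal sample sizes are handled through the standard
#' offset M = ln(n_f/n_r).  The root is isolated by geometric expansion of
#' the bracket from [-50, 50] kBT and refined by bisection.
#'
#' @param w_f,w_r forward / backward perturbation energies (kBT), >= 2 each
#' @param tol bisection tolerance (kBT)
#' @return list with `dG` and asymptotic standard error `se` (kBT)
#' @export
bar_pair <- function(w_f, w_r, tol = 1e-10) {
  if (length(w_f) < 2 || length(w_r) < 2)
    stop("need at least 2 samples in each direction")
  if (!all(is.finite(w_f)) || !all(is.finite(w_r)))
    stop("perturbation energies must be finite")
  n_f <- length(w_f); n_r <- length(w_r)
  M <- log(n_f / n_r)
  lo <- -50; hi <- 50
  f_lo <- bar_residual(lo, w_f, w_r, M)
  f_hi <- bar_residual(hi, w_f, w_r, M)
  tries <- 0
  while (f_lo * f_hi > 0 && tries < 30) {
    lo <- lo * 2; hi <- hi * 2
    f_lo <- bar_residual(lo, w_f, w_r, M)
    f_hi <- bar_residual(hi, w_f, w_r, M)
    tries <- tries + 1
  }
  if (f_lo * f_hi > 0)
    stop("no overlap between forward and backward distributions: the ",
         "Bennett equation has no bracketable root; use more lambda states")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- bar_residual(mid, w_f, w_r, M)
    if (f_lo * f_mid <= 0) { hi <- mid } else { lo <- mid; f_lo <- f_mid }
  }
  dG <- (lo + hi) / 2
  # Bennett asymptotic variance from the Fermi weights at the solution
  ff <- fermi(M + w_f - dG)
  fr <- fermi(-M + w_r + dG)
  var_est <- (mean(ff^2) / mean(ff)^2 - 1) / n_f +
             (mean(fr^2) / mean(fr)^2 - 1) / n_r
  list(dG = dG, se = sqrt(max(var_est, 0)))
}

# one-sided exponential-averaging (FEP) estimates, used as a hysteresis
# diagnostic only
fep_forward <- function(w_f) -log(mean(exp(-w_f)))
fep_backward <- function(w_r) log(mean(exp(-w_r)))

#' Total free-energy change along one alchemical leg
#'
#' Sums per-pair BAR estimates over the full lambda schedule; standard errors
#' combine in quadrature (pairs use disjoint samples).  The hysteresis
#' diagnostic is the absolute difference between the summed forward-only and
#' backward-only exponential-averaging (FEP) estimates.
#'
#' @param leg an [`alch_leg`][sample_alchemical]
#' @param tol per-pair BAR tolerance (kBT)
#' @return object of class `leg_result`: `dG`, `se`, `hysteresis`, and a
#'   per-pair data.frame
#' @export
leg_total <- function(leg, tol = 1e-10) {
  stopifnot(inherits(leg, "alch_leg"))
  n_pair <- length(leg$lambdas) - 1
  if (length(leg$forward) != n_pair || length(leg$backward) != n_pair)
    stop("leg must cover every adjacent lambda pair")
  est <- lapply(seq_len(n_pair), function(i)
    bar_pair(leg$forward[[i]], leg$backward[[i]], tol = tol))
  dG_pair <- vapply(est, `[[`, numeric(1), "dG")
  se_pair <- vapply(est, `[[`, numeric(1), "se")
  fwd <- vapply(leg$forward, fep_forward, numeric(1))
  bwd <- vapply(leg$backward, fep_backward, numeric(1))
  structure(list(dG = sum(dG_pair), se = sqrt(sum(se_pair^2)),
                 hysteresis = abs(sum(fwd) - sum(bwd)),
                 environment = leg$environment,
                 pairs = data.frame(lambda_from = leg$lambdas[-(n_pair + 1)],
                                    lambda_to = leg$lambdas[-1],
                                    dG_kBT = dG_pair, se_kBT = se_pair,
                                    fep_fwd_kBT = fwd, fep_bwd_kBT = bwd)),
            class = "leg_result")
}

#' @export
print.leg_result <- function(x, ...) {
  cat(sprintf("<leg_result> %s leg: dG = %.3f +/- %.3f kBT (FEP hysteresis %.3f kBT)\n",
              x$environment, x$dG, x$se, x$hysteresis))
  invisible(x)
}

#' Relative binding free energy through the thermodynamic cycle
#'
#' ddGb = dGb(non-cognate) - dGb(cognate) = dGa(protein) - dGa(solution):
#' the alchemical transformation of the cognate into the non-cognate
#' nucleotide, performed in the protein complex and in free solution, closes
#' the cycle for the relative binding free energy at the pre-insertion site.
#'
#' @param leg_pro,leg_sol [`alch_leg`][sample_alchemical] objects for the
#'   protein-complex and free-solution legs (same lambda schedule)
#' @param tol per-pair BAR tolerance (kBT)
#' @return object of class `cycle_result` with `ddG_b`, `se`, and both
#'   `leg_result`s
#' @export
compute_cycle <- function(leg_pro, leg_sol, tol = 1e-10) {
  stopifnot(inherits(leg_pro, "alch_leg"), inherits(leg_sol, "alch_leg"))
  if (length(leg_pro$lambdas) != length(leg_sol$lambdas) ||
      any(abs(leg_pro$lambdas - leg_sol$lambdas) > 1e-12))
    stop("protein and solution legs must share the same lambda schedule")
  pro <- leg_total(leg_pro, tol = tol)
  sol <- leg_total(leg_sol, tol = tol)
  structure(list(ddG_b = pro$dG - sol$dG,
                 se = sqrt(pro$se^2 + sol$se^2),
                 dG_pro = pro$dG, dG_sol = sol$dG,
                 protein = pro, solution = sol),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("<cycle_result> ddG_b = %.3f +/- %.3f kBT\n", x$ddG_b, x$se))
  cat(sprintf("  protein leg  %.3f +/- %.3f kBT\n", x$dG_pro, x$protein$se))
  cat(sprintf("  solution leg %.3f +/- %.3f kBT\n", x$dG_sol, x$solution$se))
  invisible(x)
}
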