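#' @title Branched five-state master equation for elongation fidelity
#' @description
#' The nucleotide addition cycle is modelled as
#' I (pre-translocation) <-> II (post-translocation) <-> III (pre-insertion)
#' <-> IV (insertion) <-> V (product) <-> I', with the cognate and
#' non-cognate species tracked on parallel branches downstream of II.  Four
#' kinetic checkpoints discriminate the species, each by a selection
#' strength eta = exp(Delta/kBT) applied to one rate of the non-cognate
#' branch.  The steady-state elongation error rate is the non-cognate share
#' of the total completion flux, Err = J_nc / (J_c + J_nc).
#' @name cme
NULL

RATE_NAMES <- c("k_I_plus", "k_II_minus", "k_II_plus", "k_III_minus",
                "k_III_plus", "k_IV_minus", "k_IV_plus", "k_V_minus",
                "k_V_plus", "k_I_minus")

#' Packaged baseline rate constants
#'
#' @param file rates fixture file; defaults to the packaged set (see
#'   `inst/extdata/baseline_rates.cfg` for the calibration note)
#' @return named numeric vector of the ten rate constants (s^-1)
#' @export
packaged_rates <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "baseline_rates.cfg", package = "polfid",
                        mustWork = TRUE)
  cfg <- read_kv_config(file)
  r <- vapply(RATE_NAMES, function(nm) as.numeric(cfg$baseline[[nm]]),
              numeric(1))
  names(r) <- RATE_NAMES
  r
}

zero_selection <- function() selection_energetics(0, 0, 0, 0)

#' Construct a kinetic scheme
#'
#' A baseline scheme has identical cognate and non-cognate branches
#' (no selection); [apply_selection()] attaches the checkpoint selection
#' energetics.
#'
#' @param rates named numeric vector of the ten baseline rate constants
#'   (s^-1); see [packaged_rates()]
#' @param ntp_ratio non-cognate : cognate NTP availability ratio, scaling
#'   the non-cognate binding rate (default 1: error rate per competing pair)
#' @return object of class `kinetic_scheme` (unselected)
#' @export
kinetic_scheme <- function(rates = packaged_rates(), ntp_ratio = 1) {
  if (!all(RATE_NAMES %in% names(rates)))
    stop("rates must contain: ", paste(RATE_NAMES, collapse = ", "))
  rates <- rates[RATE_NAMES]
  if (any(!is.finite(rates)) || any(rates < 0)) stop("all rates must be >= 0 and finite")
  if (ntp_ratio <= 0) stop("ntp_ratio must be > 0")
  structure(list(rates = rates, ntp_ratio = ntp_ratio,
                 sel = zero_selection(), sel_on = NULL, mode = "lumped"),
            class = "kinetic_scheme")
}

#' Apply checkpoint selection energetics to a baseline scheme
#'
#' The four selection strengths scale the non-cognate branch rates:
#' rejection at pre-insertion speeds non-cognate dissociation
#' (`k_III_minus * exp(delta_b_minus)`), insertion inhibition slows
#' non-cognate insertion (`k_III_plus * exp(-delta_in_plus)`), insertion
#' destabilization speeds reverse insertion
#' (`k_IV_minus * exp(delta_in_minus)`), and catalytic inhibition slows
#' non-cognate catalysis (`k_IV_plus * exp(-delta_c_plus)`).  An `NA`
#' catalytic selection is treated as 0 (no catalytic discrimination).
#'
#' In `mode = "split"` the non-cognate pre-insertion state is resolved into
#' on-path and off-path sub-states entered with the quasi-equilibrium
#' fractions `sel$f_on` / `sel$f_off` (no direct interconversion): `sel`
#' then describes the off-path branch and `sel_on` the on-path branch
#' (default: no selection, i.e. cognate-like).  Both sub-branches share the
#' insertion state IV and the catalytic checkpoint.
#'
#' @param baseline a [kinetic_scheme()] with identical branches
#' @param sel a [`selection_energetics`][selection_energetics] object
#' @param sel_on optional on-path selection energetics (split mode)
#' @param mode `"lumped"` (single non-cognate pre-insertion state) or
#'   `"split"`
#' @return a `kinetic_scheme` carrying the selection
#' @export
apply_selection <- function(baseline, sel, sel_on = NULL,
                            mode = c("lumped", "split")) {
  stopifnot(inherits(baseline, "kinetic_scheme"),
            inherits(sel, "selection_energetics"))
  mode <- match.arg(mode)
  if (!is.null(sel_on)) stopifnot(inherits(sel_on, "selection_energetics"))
  if (mode == "split" && is.null(sel_on)) {
    sel_on <- zero_selection()
    sel_on$f_on <- sel$f_on; sel_on$f_off <- sel$f_off
  }
  out <- baseline
  out$sel <- sel
  out$sel_on <- sel_on
  out$mode <- mode
  out
}

dc <- function(sel) if (is.na(sel$delta_c_plus)) 0 else sel$delta_c_plus

# State layout and transition edges for a scheme at a given error-rate
# closure.  States: I, II, IIIc, IVc, Vc, then one or two non-cognate
# pre-insertion states, IVnc, Vnc.
scheme_edges <- function(scheme, err) {
  r <- scheme$rates
  sel <- scheme$sel
  if (scheme$mode == "lumped") {
    states <- c("I", "II", "IIIc", "IVc", "Vc", "IIInc", "IVnc", "Vnc")
    e <- rbind(
      c("I", "II", r["k_I_plus"]),
      c("II", "I", r["k_II_minus"]),
      c("II", "IIIc", r["k_II_plus"]),
      c("IIIc", "II", r["k_III_minus"]),
      c("IIIc", "IVc", r["k_III_plus"]),
      c("IVc", "IIIc", r["k_IV_minus"]),
      c("IVc", "Vc", r["k_IV_plus"]),
      c("Vc", "IVc", r["k_V_minus"]),
      c("II", "IIInc", scheme$ntp_ratio * r["k_II_plus"]),
      c("IIInc", "II", exp(sel$delta_b_minus) * r["k_III_minus"]),
      c("IIInc", "IVnc", exp(-sel$delta_in_plus) * r["k_III_plus"]),
      c("IVnc", "IIInc", exp(sel$delta_in_minus) * r["k_IV_minus"]),
      c("IVnc", "Vnc", exp(-dc(sel)) * r["k_IV_plus"]),
      c("Vnc", "IVnc", r["k_V_minus"]),
      c("Vc", "I", r["k_V_plus"]),
      c("Vnc", "I", r["k_V_plus"]),
      c("I", "Vc", (1 - err) * r["k_I_minus"]),
      c("I", "Vnc", err * r["k_I_minus"]))
  } else {
    son <- scheme$sel_on
    f_on <- sel$f_on; f_off <- sel$f_off
    states <- c("I", "II", "IIIc", "IVc", "Vc", "IIIon", "IIIoff", "IVnc",
                "Vnc")
    e <- rbind(
      c("I", "II", r["k_I_plus"]),
      c("II", "I", r["k_II_minus"]),
      c("II", "IIIc", r["k_II_plus"]),
      c("IIIc", "II", r["k_III_minus"]),
      c("IIIc", "IVc", r["k_III_plus"]),
      c("IVc", "IIIc", r["k_IV_minus"]),
      c("IVc", "Vc", r["k_IV_plus"]),
      c("Vc", "IVc", r["k_V_minus"]),
      c("II", "IIIon", f_on * scheme$ntp_ratio * r["k_II_plus"]),
      c("IIIon", "II", exp(son$delta_b_minus) * r["k_III_minus"]),
      c("IIIon", "IVnc", exp(-son$delta_in_plus) * r["k_III_plus"]),
      # reversal re-partitions between sub-paths in proportion to their
      # entry weights, so zero selection reproduces the lumped branch exactly
      c("IVnc", "IIIon", f_on * exp(son$delta_in_minus) * r["k_IV_minus"]),
      c("II", "IIIoff", f_off * scheme$ntp_ratio * r["k_II_plus"]),
      c("IIIoff", "II", exp(sel$delta_b_minus) * r["k_III_minus"]),
      c("IIIoff", "IVnc", exp(-sel$delta_in_plus) * r["k_III_plus"]),
      c("IVnc", "IIIoff", f_off * exp(sel$delta_in_minus) * r["k_IV_minus"]),
      c("IVnc", "Vnc", exp(-dc(sel)) * r["k_IV_plus"]),
      c("Vnc", "IVnc", r["k_V_minus"]),
      c("Vc", "I", r["k_V_plus"]),
      c("Vnc", "I", r["k_V_plus"]),
      c("I", "Vc", (1 - err) * r["k_I_minus"]),
      c("I", "Vnc", err * r["k_I_minus"]))
  }
  list(states = states,
       from = match(e[, 1], states), to = match(e[, 2], states),
       rate = as.numeric(e[, 3]),
       from_name = e[, 1], to_name = e[, 2])
}

check_irreducible <- function(ed) {
  n <- length(ed$states)
  pos <- ed$rate > 0
  reach <- function(from, to) {
    seen <- rep(FALSE, n); seen[1] <- TRUE
    repeat {
      new <- unique(to[pos & seen[from]])
      new <- new[!seen[new]]
      if (!length(new)) break
      seen[new] <- TRUE
    }
    seen
  }
  fwd <- reach(ed$from, ed$to)
  bwd <- reach(ed$to, ed$from)
  if (!all(fwd & bwd))
    stop("scheme is reducible: state(s) ",
         paste(ed$states[!(fwd & bwd)], collapse = ", "),
         " not strongly connected to state I")
}

# Stationary distribution by Grassmann-Taksar-Heyman state elimination.
# The algorithm is subtraction-free, so it remains accurate even when the
# selection strengths spread the rates over many orders of magnitude (a
# direct linear solve loses the small populations to cancellation there).
solve_populations <- function(ed) {
  n <- length(ed$states)
  R <- matrix(0, n, n)
  for (i in seq_along(ed$rate))
    R[ed$from[i], ed$to[i]] <- R[ed$from[i], ed$to[i]] + ed$rate[i]
  diag(R) <- 0
  S <- numeric(n)
  for (m in n:2) {
    below <- seq_len(m - 1)
    S[m] <- sum(R[m, below])
    if (S[m] <= 0)
      stop("singular stationary system: state ", ed$states[m],
           " cannot reach the remaining states")
    for (i in below) {
      if (R[i, m] > 0)
        R[i, below] <- R[i, below] + R[i, m] * R[m, below] / S[m]
    }
  }
  p <- numeric(n)
  p[1] <- 1
  for (m in seq_len(n)[-1])
    p[m] <- sum(p[seq_len(m - 1)] * R[seq_len(m - 1), m]) / S[m]
  stats::setNames(p / sum(p), ed$states)
}

#' Steady-state populations, fluxes and error rate
#'
#' Solves the stationary master equation of the branched cycle.  The cyclic
#' closure identifies I' with I, with the reverse PPi-binding flux
#' partitioned between the branches by the error rate itself
#' (`J_nc = P_Vnc k_V_plus - Err P_I k_I_minus`, and analogously for the
#' cognate branch); the resulting self-consistency in Err is solved by
#' fixed-point iteration (Err is a fraction in [0, 1], so the iteration
#' contracts).
#'
#' @param scheme a [kinetic_scheme()], usually after [apply_selection()]
#' @param tol convergence tolerance on Err
#' @param max_iter iteration cap for the closure
#' @return object of class `fidelity_result`: `populations`, fluxes `J_c`,
#'   `J_nc`, `J` (s^-1), `err`, and closure iterations
#' @export
steady_state <- function(scheme, tol = 1e-10, max_iter = 500) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  err <- 0.5
  p <- NULL
  for (it in seq_len(max_iter)) {
    ed <- scheme_edges(scheme, err)
    if (it == 1) check_irreducible(ed)
    p <- solve_populations(ed)
    kvp <- scheme$rates["k_V_plus"]; kim <- scheme$rates["k_I_minus"]
    J_nc <- p["Vnc"] * kvp - err * p["I"] * kim
    J_c <- p["Vc"] * kvp - (1 - err) * p["I"] * kim
    J <- J_c + J_nc
    if (J <= 0) stop("non-positive total flux at steady state")
    err_new <- as.numeric(J_nc / J)
    if (abs(err_new - err) < tol) { err <- err_new; break }
    err <- err_new
  }
  ed <- scheme_edges(scheme, err)
  p <- solve_populations(ed)
  kvp <- scheme$rates["k_V_plus"]; kim <- scheme$rates["k_I_minus"]
  J_nc <- as.numeric(p["Vnc"] * kvp - err * p["I"] * kim)
  J_c <- as.numeric(p["Vc"] * kvp - (1 - err) * p["I"] * kim)
  structure(list(populations = p, J_c = J_c, J_nc = J_nc, J = J_c + J_nc,
                 err = err, iterations = it, mode = scheme$mode),
            class = "fidelity_result")
}

#' @export
print.fidelity_result <- function(x, ...) {
  cat("<fidelity_result>\n")
  cat(sprintf("  elongation rate J = %.3g s^-1 (J_c %.3g, J_nc %.3g)\n",
              x$J, x$J_c, x$J_nc))
  cat(sprintf("  error rate Err = %.3e\n", x$err))
  cat("  populations:\n")
  print(round(x$populations, 6))
  invisible(x)
}

#' Stochastic validation of the steady-state solver
#'
#' Exact (Gillespie) stochastic simulation of the branched cycle for a
#' single enzyme.  At state I the reverse PPi-binding step re-forms the
#' product state of the most recently added nucleotide, which realizes the
#' cyclic closure without the mean-field error-rate partition.  The
#' empirical error rate is the non-cognate fraction of net completed
#' additions.
#'
#' @param scheme a `kinetic_scheme`
#' @param n_cycles number of completed additions to accumulate (>= 100)
#' @param seed RNG seed
#' @return list with empirical `err`, `rate` (additions per unit time),
#'   counts and simulated time
#' @export
gillespie_validate <- function(scheme, n_cycles = 10000, seed = 1) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (n_cycles < 100) stop("need n_cycles >= 100")
  ed <- scheme_edges(scheme, err = 0.5)   # closure edges replaced below
  check_irreducible(ed)
  states <- ed$states
  n <- length(states)
  i_I <- match("I", states); i_Vc <- match("Vc", states)
  i_Vnc <- match("Vnc", states)
  # per-state outgoing edges, excluding the mean-field closure edges I->V*
  closure <- ed$from_name == "I" & ed$to_name %in% c("Vc", "Vnc")
  out_to <- lapply(seq_len(n), function(s) ed$to[ed$from == s & !closure])
  out_rate <- lapply(seq_len(n), function(s) ed$rate[ed$from == s & !closure])
  kim <- as.numeric(scheme$rates["k_I_minus"])
  set.seed(seed)
  state <- i_I
  last <- NA_integer_                 # branch of the last completed addition
  n_c <- 0L; n_nc <- 0L
  t_sim <- 0
  while (n_c + n_nc < n_cycles) {
    rates <- out_rate[[state]]
    targets <- out_to[[state]]
    if (state == i_I && !is.na(last)) {
      rates <- c(rates, kim)
      targets <- c(targets, if (last == 1L) i_Vc else i_Vnc)
    }
    tot <- sum(rates)
    t_sim <- t_sim + stats::rexp(1, tot)
    nxt <- targets[sample.int(length(rates), 1L, prob = rates)]
    if (state == i_Vc && nxt == i_I) { n_c <- n_c + 1L; last <- 1L }
    else if (state == i_Vnc && nxt == i_I) { n_nc <- n_nc + 1L; last <- 2L }
    else if (state == i_I && nxt == i_Vc) { n_c <- n_c - 1L; last <- NA_integer_ }
    else if (state == i_I && nxt == i_Vnc) { n_nc <- n_nc - 1L; last <- NA_integer_ }
    state <- nxt
  }
  total <- n_c + n_nc
  list(err = n_nc / total, rate = total / t_sim,
       n_c = n_c, n_nc = n_nc, time = t_sim)
}

#' Infer the catalytic selection free energy from a target error rate
#'
#' Err is monotone non-increasing in the catalytic selection free energy
#' delta_c_plus, so the value reproducing a target steady-state error rate
#' is found by bisection.
#'
#' @param scheme a selected `kinetic_scheme`; its current catalytic
#'   selection is ignored and refit
#' @param target_err target steady-state error rate, strictly between the
#'   error rates at `delta_c_plus = upper` and at `delta_c_plus = 0`
#' @param upper upper search bound (kBT)
#' @param tol bisection tolerance (kBT)
#' @return fitted delta_c_plus (kBT), with attribute `err` (achieved error
#'   rate)
#' @export
fit_catalytic_selection <- function(scheme, target_err, upper = 40,
                                    tol = 1e-3) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  err_at <- function(d) {
    s <- scheme
    s$sel$delta_c_plus <- d
    steady_state(s)$err
  }
  e0 <- err_at(0)
  e_inf <- err_at(upper)
  if (target_err >= e0) {
    if (abs(target_err - e0) <= .Machine$double.eps * 8) return(structure(0, err = e0))
    stop(sprintf("target error %.3g not achievable: range [%.3g, %.3g] over delta_c_plus in [0, %g] kBT",
                 target_err, e_inf, e0, upper))
  }
  if (target_err <= e_inf)
    stop(sprintf("target error %.3g not achievable: range [%.3g, %.3g] over delta_c_plus in [0, %g] kBT",
                 target_err, e_inf, e0, upper))
  lo <- 0; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (err_at(mid) > target_err) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2
  structure(d, err = err_at(d))
}

#' Scan error rate over allocations of a fixed total selection energy
#'
#' Distributes a total selection free energy across the four checkpoints and
#' reports the steady-state error rate for each allocation, quantifying the
#' advantage of early over late selection.
#'
#' @param total_delta total selection free energy (kBT, >= 0)
#' @param splits 4-column matrix of allocations
#'   (delta_b_minus, delta_in_plus, delta_in_minus, delta_c_plus), each row
#'   summing to `total_delta`; default enumerates all quarter-step
#'   allocations
#' @param baseline baseline [kinetic_scheme()]
#' @param step allocation grid step for the default enumeration (kBT)
#' @return data.frame of allocations and their error rates
#' @export
checkpoint_placement_scan <- function(total_delta, splits = NULL,
                                      baseline = kinetic_scheme(),
                                      step = total_delta / 4) {
  if (total_delta < 0) stop("total_delta must be >= 0")
  if (is.null(splits)) {
    if (total_delta == 0) {
      splits <- matrix(0, 1, 4)
    } else {
      m <- round(total_delta / step)
      grid <- expand.grid(a = 0:m, b = 0:m, c = 0:m)
      grid <- grid[grid$a + grid$b + grid$c <= m, ]
      splits <- cbind(grid$a, grid$b, grid$c,
                      m - grid$a - grid$b - grid$c) * step
    }
  }
  splits <- as.matrix(splits)
  if (ncol(splits) != 4) stop("splits must have 4 columns")
  if (any(abs(rowSums(splits) - total_delta) > 1e-9))
    stop("every allocation must sum to total_delta")
  err <- apply(splits, 1, function(a) {
    sel <- selection_energetics(a[1], a[2], a[3], a[4])
    steady_state(apply_selection(baseline, sel))$err
  })
  data.frame(delta_b_minus = splits[, 1], delta_in_plus = splits[, 2],
             delta_in_minus = splits[, 3], delta_c_plus = splits[, 4],
             err = err)
}
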