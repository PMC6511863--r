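#' Standard window layouts per species/path case
#'
#' Window centers are spaced 0.1 A apart: 27 windows over -1.3..1.3 A for
#' the cognate and on-path cases, 45 over -2.2..2.2 A (rGTP off-path) and 53
#' over -2.6..2.6 A (dATP off-path).
#'
#' @param species,path species and path labels as in [packaged_profile()]
#' @return named list with `from` and `to` (Angstrom)
#' @export
standard_layout <- function(species, path) {
  key <- paste(species, path, sep = "/")
  tab <- list("rATP/cognate" = c(-1.3, 1.3),
              "rGTP/on" = c(-1.3, 1.3),
              "rGTP/off" = c(-2.2, 2.2),
              "dATP/on" = c(-1.3, 1.3),
              "dATP/off" = c(-2.6, 2.6))
  if (!key %in% names(tab)) stop("no standard layout for ", key)
  list(from = tab[[key]][1], to = tab[[key]][2])
}

#' Run the umbrella-sampling recovery chain for one species/path case
#'
#' Samples the standard window layout from the packaged reference profile,
#' reconstructs the PMF by WHAM (optionally with bootstrap uncertainties)
#' and extracts the barrier summary.
#'
#' @param species,path case labels (see [packaged_profile()])
#' @param seed master seed for the window sampling
#' @param n_retained retained samples per window after burn-in
#' @param n_boot bootstrap replicates (0 to skip the bootstrap)
#' @param bin_width WHAM bin width (Angstrom)
#' @param k force constant (kJ mol^-1 nm^-2), uniform across windows
#' @param burnin burn-in fraction
#' @return list with `profile`, `windows`, `pmf` and `barriers`
#' @export
recover_case <- function(species, path, seed = 20190327, n_retained = 2000,
                         n_boot = 0, bin_width = 0.02, k = 210000,
                         burnin = 0.25) {
  prof <- packaged_profile(species, path)
  lay <- standard_layout(species, path)
  n_samp <- ceiling(n_retained / (1 - burnin))
  layout <- window_layout(lay$from, lay$to, by = 0.1, k = k,
                          n_samples = n_samp, burnin = burnin, seed = seed)
  windows <- sample_windows(prof, layout)
  pmf <- if (n_boot >= 2)
    bootstrap_pmf(windows, n_boot = n_boot, seed = derive_seed(seed, 777L),
                  bin_width = bin_width)
  else wham_reconstruct(windows, bin_width = bin_width)
  list(profile = prof, windows = windows, pmf = pmf,
       barriers = extract_barriers(pmf))
}

#' Packaged rGTP fidelity fixture
#'
#' The branched scheme for rGTP versus rATP: off-path rejection at
#' pre-insertion (4 kBT) and insertion inhibition (4 kBT), on-path branch
#' cognate-like beyond its binding offset, on/off entry fractions from the
#' two-state Boltzmann weight of the 5.3 kBT on-path offset.
#'
#' @param baseline baseline [kinetic_scheme()]
#' @param delta_c_plus catalytic selection free energy (kBT; default 0)
#' @param on_offset on-path pre-insertion offset (kBT) setting the entry
#'   fractions
#' @return a selected `kinetic_scheme` in split mode
#' @export
rgtp_scheme <- function(baseline = kinetic_scheme(), delta_c_plus = 0,
                        on_offset = packaged_constants()$on_path_offset_rGTP) {
  konst <- packaged_constants()
  fr <- path_populations(on_offset)
  f_on <- unname(fr["f_on"]); f_off <- unname(fr["f_off"])
  sel_off <- selection_energetics(konst$dE_d_c - konst$dE_d_off, 4, 0,
                                  delta_c_plus, f_on = f_on, f_off = f_off)
  sel_on <- selection_energetics(konst$dE_d_c - konst$dE_d_on, 0, 0,
                                 delta_c_plus, f_on = f_on, f_off = f_off)
  apply_selection(baseline, sel_off, sel_on = sel_on, mode = "split")
}

#' Packaged dATP fidelity fixture
#'
#' dATP binds on-path and off-path with about equal probability; the
#' on-path branch is inhibited during insertion (3 kBT) while the off-path
#' branch is rejected at pre-insertion (4 kBT) with a mild insertion
#' inhibition (1 kBT).  No catalytic selection is applied by default.
#'
#' @param baseline baseline [kinetic_scheme()]
#' @param delta_c_plus catalytic selection free energy (kBT; default 0)
#' @return a selected `kinetic_scheme` in split mode
#' @export
datp_scheme <- function(baseline = kinetic_scheme(), delta_c_plus = 0) {
  konst <- packaged_constants()
  sel_off <- selection_energetics(konst$dE_d_c - konst$dE_d_off, 1, 0,
                                  delta_c_plus, f_on = 0.5, f_off = 0.5)
  sel_on <- selection_energetics(konst$dE_d_c - konst$dE_d_on, 3, 0,
                                 delta_c_plus, f_on = 0.5, f_off = 0.5)
  apply_selection(baseline, sel_off, sel_on = sel_on, mode = "split")
}

#' One-shot reproduction pipeline
#'
#' Runs the full chain - synthetic umbrella sampling, WHAM reconstruction,
#' barrier extraction, alchemical BAR cycles, path populations, and the
#' master-equation fidelity analysis - for all five species/path cases, and
#' returns (optionally writes) a single report.
#'
#' @param seed master seed for every stochastic stage
#' @param n_retained retained samples per umbrella window
#' @param n_boot bootstrap replicates per PMF (0 skips bootstrap)
#' @param n_per_pair alchemical samples per direction per lambda pair
#' @param sigma alchemical work spread (kBT)
#' @param target_err error-rate target for the catalytic-selection fit
#' @param out_dir if non-NULL, JSON/TSV outputs are written there
#' @return report list with per-case barrier summaries, cycle results, path
#'   populations, fidelity results and the fitted catalytic selection
#' @export
reproduce_pipeline <- function(seed = 20190327, n_retained = 2000,
                               n_boot = 0, n_per_pair = 5000, sigma = 0.5,
                               target_err = 1e-4, out_dir = NULL) {
  cases <- list(c("rATP", "cognate"), c("rGTP", "on"), c("rGTP", "off"),
                c("dATP", "on"), c("dATP", "off"))
  barriers <- list()
  for (cs in cases) {
    key <- paste(cs[1], cs[2], sep = "/")
    rec <- recover_case(cs[1], cs[2], seed = derive_seed(seed, match(key,
             vapply(cases, function(x) paste(x[1], x[2], sep = "/"),
                    character(1)))),
             n_retained = n_retained, n_boot = n_boot)
    barriers[[key]] <- rec$barriers
  }
  cycles <- list(
    rGTP = {
      legs <- sample_cycle("rGTP", sigma = sigma, n_per_pair = n_per_pair,
                           seed = derive_seed(seed, 41L))
      compute_cycle(legs$protein, legs$solution)
    },
    dATP = {
      legs <- sample_cycle("dATP", sigma = sigma, n_per_pair = n_per_pair,
                           seed = derive_seed(seed, 42L))
      compute_cycle(legs$protein, legs$solution)
    })
  konst <- packaged_constants()
  pops <- path_populations(konst$on_path_offset_rGTP)
  fid_rgtp <- steady_state(rgtp_scheme())
  fid_datp <- steady_state(datp_scheme())
  dc_fit <- fit_catalytic_selection(rgtp_scheme(), target_err)
  report <- list(seed = seed,
                 barriers = barriers, cycles = cycles,
                 path_populations = as.list(pops),
                 fidelity = list(rGTP = fid_rgtp, dATP = fid_datp),
                 delta_c_plus_fit = as.numeric(dc_fit),
                 delta_c_plus_fit_err = attr(dc_fit, "err"),
                 target_err = target_err)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (key in names(barriers))
      write_result_json(barriers[[key]],
                        file.path(out_dir, paste0("barriers_",
                                  gsub("/", "_", key), ".json")))
    for (key in names(cycles))
      write_result_json(cycles[[key]],
                        file.path(out_dir, paste0("cycle_", key, ".json")))
    write_result_json(report$path_populations,
                      file.path(out_dir, "path_populations.json"))
    write_result_json(fid_rgtp, file.path(out_dir, "fidelity_rGTP.json"))
    write_result_json(fid_datp, file.path(out_dir, "fidelity_dATP.json"))
    write_result_json(list(delta_c_plus = report$delta_c_plus_fit,
                           achieved_err = report$delta_c_plus_fit_err,
                           target_err = target_err),
                      file.path(out_dir, "catalytic_fit.json"))
  }
  report
}
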