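#' @title Composite selection landscapes and stepwise selection energetics
#' @description
#' Individual PMFs are defined only up to an additive constant; to read off
#' selection energetics the cognate, on-path and off-path profiles must be
#' placed on one energy axis.  The on-path non-cognate profile is raised by
#' the alchemically determined relative binding free energy ddGb at
#' pre-insertion, and the off-path profile is anchored through its final
#' insertion configuration (config 5), which is structurally shared with the
#' on-path insertion state.
#' @name energetics
NULL

#' Packaged dissociation barriers and offsets
#'
#' @param file fixture file; defaults to the packaged constants
#' @return list with `dE_d_c`, `dE_d_on`, `dE_d_off`,
#'   `on_path_offset_rGTP`, `datp_offpath_baseline` (all kBT)
#' @export
packaged_constants <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "selection_constants.cfg",
                        package = "polfid", mustWork = TRUE)
  cfg <- read_kv_config(file)
  list(dE_d_c = as.numeric(cfg$dissociation$dE_d_c),
       dE_d_on = as.numeric(cfg$dissociation$dE_d_on),
       dE_d_off = as.numeric(cfg$dissociation$dE_d_off),
       on_path_offset_rGTP = as.numeric(cfg$offsets$on_path_offset_rGTP),
       datp_offpath_baseline = as.numeric(cfg$offsets$datp_offpath_baseline))
}

profile_anchor_summary <- function(pmf, summary = NULL) {
  if (is.null(summary)) summary <- extract_barriers(pmf)
  summary
}

#' Align cognate, on-path and off-path PMFs into one landscape
#'
#' Applies additive offsets only (profiles are never rescaled): the cognate
#' pre-insertion minimum defines the global zero; the on-path non-cognate
#' pre-insertion minimum is placed at ddGb above it; the off-path profile is
#' shifted so its final insertion configuration (config 5) either coincides
#' with the on-path config 5 (`merge_rule = "equal_config5"`, the rGTP case)
#' or lies between the on-path config-4 and config-5 levels
#' (`merge_rule = "between_config4_and_5"`, the dATP case; the config-4
#' level is read from the aligned on-path profile midway between its
#' transition maximum and insertion minimum, and `fraction` interpolates
#' between config 5 at 0 and config 4 at 1, default midpoint).
#'
#' @param cognate,on_path,off_path `pmf_profile` objects
#' @param ddG_b relative binding free energy of the on-path non-cognate
#'   versus cognate nucleotide at pre-insertion (kBT)
#' @param merge_rule `"equal_config5"` or `"between_config4_and_5"`
#' @param fraction interpolation fraction for the dATP merge rule
#' @param summaries optional named list of precomputed
#'   [`barrier_summary`][extract_barriers] objects (`cognate`, `on`, `off`)
#' @return object of class `composite_landscape` with the three profiles,
#'   the applied offsets, and the aligned anchor levels
#' @export
align_landscape <- function(cognate, on_path, off_path, ddG_b,
                            merge_rule = c("equal_config5",
                                           "between_config4_and_5"),
                            fraction = 0.5, summaries = NULL) {
  merge_rule <- match.arg(merge_rule)
  if (!is.finite(ddG_b)) stop("ddG_b must be finite")
  sc <- profile_anchor_summary(cognate, summaries$cognate)
  son <- profile_anchor_summary(on_path, summaries$on)
  soff <- profile_anchor_summary(off_path, summaries$off)
  if (soff$monotone && merge_rule == "between_config4_and_5") {
    # semi-insertion endpoint: use the rightmost bin as config 5
  }
  off_c <- -sc$pre_min["G"]
  off_on <- ddG_b - son$pre_min["G"]
  on_cfg5 <- son$ins_min["G"] + off_on
  target <- if (merge_rule == "equal_config5") {
    on_cfg5
  } else {
    # config-4 level: aligned on-path G midway between transition maximum
    # and insertion minimum
    mid_coord <- (son$ts_max["coord"] + son$ins_min["coord"]) / 2
    i_mid <- which.min(abs(on_path$grid - mid_coord))
    on_cfg4 <- on_path$G[i_mid] + off_on
    on_cfg5 + fraction * (on_cfg4 - on_cfg5)
  }
  off_off <- target - soff$ins_min["G"]
  offsets <- c(cognate = unname(off_c), on = unname(off_on),
               off = unname(off_off))
  structure(list(profiles = list(cognate = cognate, on = on_path,
                                 off = off_path),
                 summaries = list(cognate = sc, on = son, off = soff),
                 offsets = offsets, ddG_b = ddG_b,
                 merge_rule = merge_rule, fraction = fraction,
                 anchors = data.frame(
                   path = c("cognate", "on", "off"),
                   pre_insertion = c(sc$pre_min["G"] + off_c,
                                     son$pre_min["G"] + off_on,
                                     soff$pre_min["G"] + off_off),
                   transition = c(sc$ts_max["G"] + off_c,
                                  son$ts_max["G"] + off_on,
                                  soff$ts_max["G"] + off_off),
                   insertion = c(sc$ins_min["G"] + off_c,
                                 son$ins_min["G"] + off_on,
                                 soff$ins_min["G"] + off_off))),
            class = "composite_landscape")
}

#' @export
print.composite_landscape <- function(x, ...) {
  cat(sprintf("<composite_landscape> ddG_b = %.2f kBT, merge rule %s\n",
              x$ddG_b, x$merge_rule))
  print(x$anchors, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.composite_landscape <- function(x, col = c("black", "firebrick",
                                                "steelblue"), ...) {
  xs <- lapply(names(x$profiles), function(nm) x$profiles[[nm]]$grid)
  ys <- lapply(seq_along(x$profiles),
               function(i) x$profiles[[i]]$G + x$offsets[i])
  graphics::plot(NA, xlim = range(unlist(xs)), ylim = range(unlist(ys),
                                                            na.rm = TRUE),
                 xlab = expression(paste(delta, "rmsd (", ring(A), ")")),
                 ylab = expression(G ~ (k[B] * T)), ...)
  for (i in seq_along(ys)) graphics::lines(xs[[i]], ys[[i]], col = col[i])
  graphics::legend("topright", legend = names(x$profiles), col = col,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Quasi-equilibrium on/off path populations
#'
#' Two-state Boltzmann weights of the on- versus off-path pre-insertion
#' configurations: f_on = exp(-dG) / (1 + exp(-dG)), with dG the free-energy
#' offset (kBT) of the on-path relative to the off-path configuration.
#' Saturates smoothly at the extremes.
#'
#' @param dG_on_offset on-path offset in kBT (positive = on-path less
#'   accessible)
#' @return named numeric: `f_on`, `f_off` (sum to 1)
#' @examples
#' path_populations(5.3)   # ~0.5% on-path, 99.5% off-path
#' path_populations(0)     # 50/50
#' @export
path_populations <- function(dG_on_offset) {
  stopifnot(is.numeric(dG_on_offset), length(dG_on_offset) == 1,
            !is.na(dG_on_offset))
  f_on <- stats::plogis(-dG_on_offset)
  c(f_on = f_on, f_off = 1 - f_on)
}

#' Derive the stepwise selection free energies
#'
#' The four kinetic-checkpoint selection free energies are barrier
#' differences between the non-cognate and cognate species:
#' \itemize{
#'   \item rejection at pre-insertion: `delta_b_minus = dE_d_c - dE_d_nc`
#'     (dissociation barriers, packaged constants);
#'   \item insertion inhibition: `delta_in_plus = dE_in_nc - dE_in_c`;
#'   \item insertion-state destabilization:
#'     `delta_in_minus = dE_rev_c - dE_rev_nc`;
#'   \item catalytic inhibition `delta_c_plus`: not observable from the
#'     insertion PMFs, left `NA` here and inferred by
#'     [fit_catalytic_selection()].
#' }
#'
#' @param cognate [`barrier_summary`][extract_barriers] of the cognate PMF
#' @param noncognate `barrier_summary` of the chosen non-cognate path
#' @param dE_d_c,dE_d_nc dissociation barriers at pre-insertion (kBT); see
#'   [packaged_constants()]
#' @param fractions optional on/off path populations from
#'   [path_populations()]
#' @return object of class `selection_energetics`
#' @export
derive_selection_energies <- function(cognate, noncognate,
                                      dE_d_c = packaged_constants()$dE_d_c,
                                      dE_d_nc = NULL,
                                      fractions = c(f_on = 1, f_off = 0)) {
  stopifnot(inherits(cognate, "barrier_summary"),
            inherits(noncognate, "barrier_summary"))
  if (is.null(dE_d_nc) || !is.finite(dE_d_c) || !is.finite(dE_d_nc))
    stop("dissociation barriers dE_d_c and dE_d_nc are required")
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("path fractions must be non-negative and sum to 1")
  structure(list(delta_b_minus = dE_d_c - dE_d_nc,
                 delta_in_plus = noncognate$dE_in - cognate$dE_in,
                 delta_in_minus = cognate$dE_rev - noncognate$dE_rev,
                 delta_c_plus = NA_real_,
                 f_on = unname(fractions[1]), f_off = unname(fractions[2])),
            class = "selection_energetics")
}

#' Construct selection energetics directly
#'
#' Convenience constructor when the selection free energies are known
#' numbers rather than derived from PMFs.
#'
#' @param delta_b_minus,delta_in_plus,delta_in_minus,delta_c_plus selection
#'   free energies (kBT); `delta_c_plus` may be `NA`
#' @param f_on,f_off on/off path fractions (sum to 1)
#' @return object of class `selection_energetics`
#' @export
selection_energetics <- function(delta_b_minus = 0, delta_in_plus = 0,
                                 delta_in_minus = 0, delta_c_plus = NA_real_,
                                 f_on = 1, f_off = 1 - f_on) {
  vals <- c(delta_b_minus, delta_in_plus, delta_in_minus)
  if (!all(is.finite(vals))) stop("pre-catalytic selection energies must be finite")
  if (f_on < 0 || f_off < 0 || abs(f_on + f_off - 1) > 1e-9)
    stop("path fractions must be non-negative and sum to 1")
  structure(list(delta_b_minus = delta_b_minus,
                 delta_in_plus = delta_in_plus,
                 delta_in_minus = delta_in_minus,
                 delta_c_plus = delta_c_plus,
                 f_on = f_on, f_off = f_off),
            class = "selection_energetics")
}

#' @export
print.selection_energetics <- function(x, ...) {
  cat("<selection_energetics> (kBT)\n")
  cat(sprintf("  delta_b_minus  (pre-insertion rejection)     %.3f\n", x$delta_b_minus))
  cat(sprintf("  delta_in_plus  (insertion inhibition)        %.3f\n", x$delta_in_plus))
  cat(sprintf("  delta_in_minus (insertion destabilization)   %.3f\n", x$delta_in_minus))
  cat(sprintf("  delta_c_plus   (catalytic inhibition)        %s\n",
              if (is.na(x$delta_c_plus)) "NA (to be inferred)" else
                sprintf("%.3f", x$delta_c_plus)))
  cat(sprintf("  path fractions on/off: %.4f / %.4f\n", x$f_on, x$f_off))
  invisible(x)
}
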