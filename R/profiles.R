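#' Build a reference free-energy profile
#'
#' A reference profile is the ground-truth free-energy curve G(delta_rmsd)
#' from which the synthetic umbrella sampler draws.  It is a monotone
#' piecewise-cubic (Fritsch-Carlson) interpolant through a small set of
#' anchor knots, so it passes through every anchor exactly and introduces no
#' spurious extrema between monotone neighbours.
#'
#' @param anchors two-column matrix or data.frame: coordinate (Angstrom,
#'   strictly increasing) and free energy (kBT at 310 K)
#' @param domain length-2 numeric, the coordinate interval on which the
#'   profile is defined; defaults to the anchor range
#' @param species optional species label (`"rATP"`, `"rGTP"`, `"dATP"`)
#' @param path optional path label (`"cognate"`, `"on"`, `"off"`)
#' @return an object of class `ref_profile`; call it like a function, or use
#'   `profile_eval()`, to evaluate G at coordinates
#' @examples
#' p <- build_reference_profile(cbind(c(-1.3, 0, 1.3), c(0, 3, -3)))
#' profile_eval(p, 0)   # exactly 3
#' @export
build_reference_profile <- function(anchors, domain = NULL,
                                    species = NULL, path = NULL) {
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 2) stop("anchors must have two columns: coordinate, energy")
  if (nrow(anchors) < 3) stop("need at least 3 anchors")
  x <- anchors[, 1]; g <- anchors[, 2]
  if (!all(is.finite(x)) || !all(is.finite(g))) stop("anchors must be finite")
  if (anyDuplicated(x)) stop("duplicate anchor coordinates")
  if (is.unsorted(x, strictly = TRUE)) stop("anchor coordinates must be strictly increasing")
  if (is.null(domain)) domain <- range(x)
  domain <- sort(as.numeric(domain))
  if (length(domain) != 2) stop("domain must have length 2")
  if (any(x < domain[1] | x > domain[2])) stop("anchors outside domain")
  fun <- stats::splinefun(x, g, method = "monoH.FC")
  structure(list(fun = fun, anchors = cbind(coord = x, energy = g),
                 domain = domain, species = species, path = path),
            class = "ref_profile")
}

#' Evaluate a reference profile
#' @param profile a `ref_profile`
#' @param x coordinates (Angstrom) inside the profile domain
#' @return free energy in kBT
#' @export
profile_eval <- function(profile, x) {
  stopifnot(inherits(profile, "ref_profile"))
  if (any(x < profile$domain[1] - 1e-9 | x > profile$domain[2] + 1e-9))
    stop("evaluation outside profile domain [", profile$domain[1], ", ",
         profile$domain[2], "]")
  profile$fun(x)
}

#' @export
print.ref_profile <- function(x, ...) {
  cat("<ref_profile>",
      if (!is.null(x$species)) paste0(x$species, "/", x$path) else "",
      sprintf(" domain [%g, %g] A, %d anchors\n",
              x$domain[1], x$domain[2], nrow(x$anchors)))
  print(as.data.frame(x$anchors), row.names = FALSE)
  invisible(x)
}

#' @export
plot.ref_profile <- function(x, n = 401, ...) {
  xx <- seq(x$domain[1], x$domain[2], length.out = n)
  graphics::plot(xx, x$fun(xx), type = "l",
                 xlab = expression(paste(delta, "rmsd (", ring(A), ")")),
                 ylab = expression(G ~ (k[B] * T)), ...)
  graphics::points(x$anchors[, 1], x$anchors[, 2], pch = 19)
  invisible(x)
}

#' Packaged reference free-energy profiles
#'
#' Loads one of the five ground-truth insertion profiles shipped with the
#' package (synthetic fixtures encoding the reported activation barriers and
#' end-state stabilities): cognate rATP, on-/off-path rGTP, on-/off-path
#' dATP.  Anchor energies follow the reported values; anchor coordinates
#' place the pre-insertion minimum at the most negative window center, the
#' transition maximum at delta_rmsd = 0, and the insertion minimum at the
#' most positive center.
#'
#' @param species `"rATP"`, `"rGTP"` or `"dATP"`
#' @param path `"cognate"`, `"on"` or `"off"`
#' @param file profile fixture file (key-value text); defaults to the
#'   packaged file
#' @return a `ref_profile`
#' @export
packaged_profile <- function(species = c("rATP", "rGTP", "dATP"),
                             path = c("cognate", "on", "off"),
                             file = NULL) {
  species <- match.arg(species)
  path <- match.arg(path)
  if (is.null(file))
    file <- system.file("extdata", "reference_profiles.cfg", package = "polfid",
                        mustWork = TRUE)
  profs <- read_profile_config(file)
  key <- paste(species, path, sep = "/")
  if (!key %in% names(profs))
    stop("no packaged profile for ", key, "; available: ",
         paste(names(profs), collapse = ", "))
  profs[[key]]
}
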