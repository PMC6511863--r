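#' Construct a coordinate frame
#'
#' A coordinate frame is an ordered set of atom positions (Angstrom) used to
#' evaluate the difference-RMSD reaction coordinate.  Frames compared by RMSD
#' must contain the same atoms in the same order.
#'
#' @param xyz numeric matrix with 3 columns (x, y, z in Angstrom), one row per
#'   atom, or a length-3k vector that is reshaped row-wise
#' @param label optional character label
#' @return an object of class `coordinate_frame`
#' @export
coordinate_frame <- function(xyz, label = NULL) {
  if (is.vector(xyz) && is.numeric(xyz)) {
    if (length(xyz) %% 3 != 0) stop("coordinate vector length must be a multiple of 3")
    xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  }
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1) stop("a coordinate frame needs at least one atom")
  if (ncol(xyz) != 3) stop("coordinates must have 3 columns (x, y, z)")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  structure(list(xyz = unname(xyz), label = label), class = "coordinate_frame")
}

#' @export
print.coordinate_frame <- function(x, ...) {
  cat("<coordinate_frame>", if (!is.null(x$label)) x$label else "", "-",
      nrow(x$xyz), "atoms\n")
  invisible(x)
}

as_frame <- function(x) {
  if (inherits(x, "coordinate_frame")) x else coordinate_frame(x)
}

check_paired <- function(a, b) {
  if (nrow(a$xyz) != nrow(b$xyz))
    stop("frames have different atom counts (", nrow(a$xyz), " vs ",
         nrow(b$xyz), ")")
}

# Kabsch least-squares rotation of `mob` onto `ref` (both centred).
kabsch_rotate <- function(mob, ref) {
  s <- svd(crossprod(mob, ref))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  mob %*% t(rot)
}

#' Root-mean-square deviation between two frames
#'
#' By default the RMSD is evaluated on the coordinates as given, without
#' re-superposition: the reaction coordinate is defined on restrained,
#' pre-aligned structures, so the restraint-style RMSD is the primitive.
#' `superpose = TRUE` applies optimal (Kabsch) superposition first, for
#' general use on unaligned structures.
#'
#' @param x,ref `coordinate_frame` objects (or coercible matrices) with equal
#'   atom counts and identical atom ordering
#' @param superpose logical; optimally superpose `x` onto `ref` first
#' @return RMSD in Angstrom
#' @export
rmsd <- function(x, ref, superpose = FALSE) {
  x <- as_frame(x); ref <- as_frame(ref)
  check_paired(x, ref)
  a <- x$xyz; b <- ref$xyz
  if (superpose) {
    a <- sweep(a, 2, colMeans(a))
    b <- sweep(b, 2, colMeans(b))
    a <- kabsch_rotate(a, b)
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Difference-RMSD reaction coordinate
#'
#' The collective reaction coordinate for nucleotide insertion:
#' `delta_rmsd = rmsd(X, X_init) - rmsd(X, X_final)`, negative near the
#' pre-insertion reference and positive near the insertion reference.
#'
#' @param x instantaneous frame
#' @param x_init pre-insertion reference frame
#' @param x_final insertion reference frame
#' @param superpose logical; superpose before each RMSD (off by default, see
#'   [rmsd()])
#' @return delta-RMSD in Angstrom
#' @export
delta_rmsd <- function(x, x_init, x_final, superpose = FALSE) {
  x <- as_frame(x); x_init <- as_frame(x_init); x_final <- as_frame(x_final)
  check_paired(x, x_init)
  check_paired(x, x_final)
  rmsd(x, x_init, superpose = superpose) - rmsd(x, x_final, superpose = superpose)
}
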