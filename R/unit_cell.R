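#' Unit cell
#'
#' A triclinic unit cell described by its six lattice parameters. Lengths are
#' in Angstrom, angles in degrees. Internally all geometry goes through the
#' column-basis matrix returned by [cell_matrix()], with the fixed convention
#' that `a` lies along Cartesian x and `b` in the x-y plane.
#'
#' @param a,b,c cell edge lengths (Angstrom), all > 0.
#' @param alpha,beta,gamma cell angles (degrees), each in (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' cell <- unit_cell(3.55, 9.7, 16.3, beta = 96)
#' cell_volume(cell)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a = a, b = b, c = c)
  ang <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit_cell: lengths must be positive and finite", call. = FALSE)
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit_cell: angles must lie in (0, 180) degrees", call. = FALSE)
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (cell_volume(cell) <= 0)
    stop("unit_cell: angles do not define a positive cell volume", call. = FALSE)
  cell
}

#' Cartesian basis matrix of a cell
#'
#' Columns are the lattice vectors a, b, c in Cartesian coordinates
#' (Angstrom), with a along x and b in the x-y plane. Fractional coordinates
#' (as rows) convert to Cartesian via `frac %*% t(cell_matrix(cell))`.
#'
#' @param cell a [unit_cell()].
#' @return 3x3 numeric matrix.
#' @export
cell_matrix <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  av <- c(cell$a, 0, 0)
  bv <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cell$c * cb
  cy <- cell$c * (ca - cb * cg) / sg
  cz2 <- cell$c^2 - cx^2 - cy^2
  if (cz2 <= 0)
    stop("unit_cell: degenerate cell (non-positive volume)", call. = FALSE)
  cv <- c(cx, cy, sqrt(cz2))
  cbind(a = av, b = bv, c = cv)
}

#' Cell volume in cubic Angstrom
#' @inheritParams cell_matrix
#' @return numeric scalar.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta  * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  cell$a * cell$b * cell$c * sqrt(arg)
}

#' Convert fractional to Cartesian coordinates
#' @param cell a [unit_cell()].
#' @param frac numeric vector of length 3 or an n x 3 matrix of fractional
#'   coordinates (rows).
#' @return matching vector or n x 3 matrix of Cartesian coordinates (Angstrom).
#' @export
frac_to_cart <- function(cell, frac) {
  M <- cell_matrix(cell)
  if (is.matrix(frac)) frac %*% t(M) else as.numeric(M %*% frac)
}

#' Convert Cartesian to fractional coordinates
#' @inheritParams frac_to_cart
#' @param cart numeric vector of length 3 or an n x 3 matrix (rows Cartesian).
#' @export
cart_to_frac <- function(cell, cart) {
  Mi <- solve(cell_matrix(cell))
  if (is.matrix(cart)) cart %*% t(Mi) else as.numeric(Mi %*% cart)
}

#' Miller index
#'
#' @param h,k,l integers, not all zero.
#' @return object of class `miller_index` (named integer vector).
#' @export
miller_index <- function(h, k, l) {
  hkl <- c(h = as.integer(h), k = as.integer(k), l = as.integer(l))
  if (any(is.na(hkl))) stop("miller_index: non-integer input", call. = FALSE)
  if (all(hkl == 0L)) stop("miller_index: (0,0,0) is not a valid plane", call. = FALSE)
  structure(hkl, class = "miller_index")
}

#' Interplanar d-spacing
#'
#' d(hkl) = 1 / |h a* + k b* + l c*|, computed from the general triclinic
#' reciprocal basis, so any cell metric is handled.
#'
#' @param cell a [unit_cell()].
#' @param hkl a [miller_index()] or length-3 integer vector (not all zero).
#' @return d-spacing in Angstrom.
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 0, 0))  # 10
#' @export
d_spacing <- function(cell, hkl) {
  hkl <- as.numeric(hkl)
  if (length(hkl) != 3 || all(hkl == 0))
    stop("d_spacing: hkl must be a nonzero length-3 index", call. = FALSE)
  B <- reciprocal_matrix(cell)
  g <- as.numeric(B %*% hkl)
  1 / sqrt(sum(g^2))
}

#' Reciprocal basis matrix
#'
#' Columns are the reciprocal lattice vectors a*, b*, c* (crystallographic
#' convention, no 2*pi factor) in the same Cartesian frame as [cell_matrix()].
#'
#' @inheritParams cell_matrix
#' @return 3x3 numeric matrix.
#' @export
reciprocal_matrix <- function(cell) {
  M <- cell_matrix(cell)
  t(solve(M))
}
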