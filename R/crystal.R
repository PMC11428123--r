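#' Crystal structures
#'
#' A molecular crystal: unit cell, space-group operations, the asymmetric
#' unit (a list of molecule placements in fractional coordinates) and the
#' symmetry-expanded molecule list for one unit cell. Molecules keep their
#' template atom ordering through symmetry expansion, which the interaction
#' classifier relies on.
#'
#' @param cell a [unit_cell()].
#' @param symops list of [parse_symop()] operations; must contain the
#'   identity.
#' @param asym list of molecule placements. Each is a list with elements
#'   `species`, `tautomer`, `elements`, `frac` (n x 3 fractional coordinates)
#'   and optionally `scaffold` (named indices as in [molecule_template()]).
#' @return object of class `crystal_structure` with fields `cell`, `symops`,
#'   `asym`, `molecules` (expanded), `Z`.
#' @export
crystal_structure <- function(cell, symops, asym) {
  stopifnot(inherits(cell, "unit_cell"), length(asym) >= 1)
  if (!any(vapply(symops, .is_identity_symop, logical(1))))
    stop("crystal_structure: identity operation missing from symops", call. = FALSE)
  asym <- lapply(asym, .validate_molecule)
  molecules <- .expand_symmetry(cell, symops, asym)
  structure(list(cell = cell, symops = symops, asym = asym,
                 molecules = molecules, Z = length(molecules)),
            class = "crystal_structure")
}

.validate_molecule <- function(m) {
  m$frac <- as.matrix(m$frac)
  if (ncol(m$frac) != 3) stop("molecule frac coordinates must be n x 3", call. = FALSE)
  if (is.null(m$species)) m$species <- "mol"
  if (is.null(m$tautomer)) m$tautomer <- NA_character_
  if (is.null(m$elements)) m$elements <- rep("C", nrow(m$frac))
  if (is.null(m$scaffold)) {
    idx <- which(m$elements != "H")
    m$scaffold <- stats::setNames(as.integer(idx), paste0("A", seq_along(idx)))
  }
  m
}

## Expand the asymmetric unit by all symmetry operations; molecules are
## wrapped by centroid into [0,1) and deduplicated by minimum-image centroid
## distance.
.expand_symmetry <- function(cell, symops, asym, tol = 1e-3) {
  M <- cell_matrix(cell)
  out <- list()
  cents <- NULL
  for (ai in seq_along(asym)) {
    mol <- asym[[ai]]
    for (si in seq_along(symops)) {
      frac <- apply_symop(symops[[si]], mol$frac)
      cent <- colMeans(frac)
      shift <- floor(cent)
      frac <- sweep(frac, 2, shift)
      cent <- cent - shift
      dup <- FALSE
      if (!is.null(cents)) {
        dd <- sweep(cents, 2, cent)
        dd <- dd - round(dd)                    # minimum image
        if (any(sqrt(rowSums((dd %*% t(M))^2)) < tol)) dup <- TRUE
      }
      if (!dup) {
        new <- mol
        new$frac <- frac
        new$asym_id <- ai
        new$symop_id <- si
        out[[length(out) + 1L]] <- new
        cents <- rbind(cents, cent)
      }
    }
  }
  out
}

#' @export
print.crystal_structure <- function(x, ...) {
  v <- cell_volume(x$cell)
  cat(sprintf("<crystal_structure> Z = %d, %d symop(s)\n", x$Z, length(x$symops)))
  cat(sprintf("  cell: a=%.4f b=%.4f c=%.4f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.2f A^3\n",
              x$cell$a, x$cell$b, x$cell$c,
              x$cell$alpha, x$cell$beta, x$cell$gamma, v))
  inv <- table(vapply(x$molecules, function(m) m$species, character(1)))
  cat("  molecules:", paste(sprintf("%s x%d", names(inv), inv), collapse = ", "), "\n")
  invisible(x)
}

#' Cartesian atom coordinates of a molecule in the cell
#' @param structure a [crystal_structure()].
#' @param i molecule index (1..Z).
#' @param offset integer lattice offset (length 3) added to the fractional
#'   coordinates before conversion.
#' @return n x 3 matrix (Angstrom).
#' @export
molecule_cart <- function(structure, i, offset = c(0, 0, 0)) {
  frac <- sweep(structure$molecules[[i]]$frac, 2, as.numeric(offset), "+")
  frac_to_cart(structure$cell, frac)
}

#' Molecule centroids (fractional) of the expanded cell
#' @param structure a [crystal_structure()].
#' @return Z x 3 matrix of fractional centroids.
#' @export
molecule_centroids <- function(structure) {
  t(vapply(structure$molecules, function(m) colMeans(m$frac), numeric(3)))
}

#' Build a supercell
#'
#' Replicates the expanded unit cell `na x nb x nc` times. The supercell is
#' returned as a `crystal_structure` in P1 (identity symmetry only) whose
#' sites remember their parent molecule index and lattice offset, which the
#' solid-solution enumeration uses for translation deduplication.
#'
#' @param structure a [crystal_structure()].
#' @param repeats integer vector `(na, nb, nc)`, all >= 1.
#' @return a `crystal_structure` with `Z * na * nb * nc` molecules and a
#'   `supercell` attribute (list with `repeats`, `parent_Z`, `sites`).
#' @examples
#' # a 3 x 3 x 1 supercell of a Z = 4 cell holds 36 molecules
#' @export
build_supercell <- function(structure, repeats) {
  repeats <- as.integer(repeats)
  if (length(repeats) != 3 || any(is.na(repeats)) || any(repeats < 1L))
    stop("build_supercell: repeats must be three positive integers", call. = FALSE)
  na <- repeats[1]; nb <- repeats[2]; nc <- repeats[3]
  if (all(repeats == 1L)) {
    sites <- data.frame(parent_mol = seq_len(structure$Z),
                        oa = 0L, ob = 0L, oc = 0L,
                        site = seq_len(structure$Z))
    attr(structure, "supercell") <- list(repeats = repeats,
                                         parent_Z = structure$Z, sites = sites,
                                         parent = structure)
    return(structure)
  }
  cell <- unit_cell(structure$cell$a * na, structure$cell$b * nb,
                    structure$cell$c * nc, structure$cell$alpha,
                    structure$cell$beta, structure$cell$gamma)
  mols <- list()
  sites <- NULL
  for (oc in 0:(nc - 1)) for (ob in 0:(nb - 1)) for (oa in 0:(na - 1)) {
    for (mi in seq_len(structure$Z)) {
      m <- structure$molecules[[mi]]
      m$frac <- sweep(m$frac, 2, c(oa, ob, oc), "+")
      m$frac <- sweep(m$frac, 2, repeats, "/")
      mols[[length(mols) + 1L]] <- m
      sites <- rbind(sites, c(mi, oa, ob, oc))
    }
  }
  sites <- as.data.frame(sites)
  names(sites) <- c("parent_mol", "oa", "ob", "oc")
  sites$site <- seq_len(nrow(sites))
  out <- structure(list(cell = cell, symops = list(.identity_symop()),
                        asym = mols, molecules = mols, Z = length(mols)),
                   class = "crystal_structure")
  attr(out, "supercell") <- list(repeats = repeats, parent_Z = structure$Z,
                                 sites = sites, parent = structure)
  out
}
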