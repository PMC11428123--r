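#' Molecule templates
#'
#' A rigid molecular fragment: element symbols, Cartesian coordinates
#' (Angstrom) and the subset of atoms forming the purine scaffold shared
#' between host and guest species. Scaffold atoms are *named* indices
#' (canonical labels `N1, C2, N3, C4, C5, C6, N7, C8, N9, O6`), so two
#' templates can be mapped onto each other by label intersection.
#'
#' @param name species label, e.g. `"guanine"`, `"hypoxanthine"`,
#'   `"xanthine"` or `"toy"`.
#' @param tautomer tautomer label, e.g. `"keto-N7H"`.
#' @param elements character vector of element symbols.
#' @param xyz n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param scaffold named integer vector of scaffold atom indices.
#' @return object of class `molecule_template`.
#' @export
molecule_template <- function(name, tautomer, elements, xyz, scaffold = NULL) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3 || nrow(xyz) < 1)
    stop("molecule_template: xyz must be an n x 3 numeric matrix with n >= 1",
         call. = FALSE)
  if (length(elements) != nrow(xyz))
    stop("molecule_template: one element symbol per atom required", call. = FALSE)
  if (nrow(xyz) > 1) {
    dmin <- min(stats::dist(xyz))
    if (dmin < 0.5)
      stop(sprintf(
        "molecule_template: atoms closer than 0.5 Angstrom (min %.3f)", dmin),
        call. = FALSE)
  }
  if (is.null(scaffold)) {
    scaffold <- which(elements != "H")
    names(scaffold) <- paste0("A", seq_along(scaffold))
  }
  scaffold <- as.integer(scaffold) |> stats::setNames(names(scaffold))
  if (any(scaffold < 1L) || any(scaffold > nrow(xyz)))
    stop("molecule_template: scaffold indices out of range", call. = FALSE)
  structure(list(name = name, tautomer = tautomer,
                 elements = as.character(elements), xyz = xyz,
                 scaffold = scaffold),
            class = "molecule_template")
}

#' @export
print.molecule_template <- function(x, ...) {
  cat(sprintf("<molecule_template> %s (%s): %d atoms, %d scaffold atoms\n",
              x$name, x$tautomer, nrow(x$xyz), length(x$scaffold)))
  invisible(x)
}

## Idealized planar purine scaffold: regular hexagon (bond 1.39 A) fused to a
## regular pentagon on the C4-C5 edge, exocyclic substituents placed radially.
## Not an experimental geometry; adequate for contact topology and rigid
## superposition, which is all the pipeline needs.
.purine_ring <- function() {
  r6 <- 1.39
  ang <- (0:5) * 60 * pi / 180
  hexa <- cbind(r6 * cos(ang), r6 * sin(ang), 0)
  rownames(hexa) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  C4 <- hexa["C4", 1:2]; C5 <- hexa["C5", 1:2]
  m <- (C4 + C5) / 2
  u <- m / sqrt(sum(m^2))              # outward normal of the shared edge
  s <- 1.39
  Rp <- s / (2 * sin(36 * pi / 180))   # pentagon circumradius
  ap <- Rp * cos(36 * pi / 180)        # apothem
  ctr <- m + ap * u
  # pentagon vertices: rotate C4 about ctr by k * 72 deg, pick the three new ones
  rot <- function(p, th) {
    d <- p - ctr
    ctr + c(cos(th) * d[1] - sin(th) * d[2], sin(th) * d[1] + cos(th) * d[2])
  }
  # orientation: rotating C4 away from C5 walks N9, C8, N7 around the pentagon
  th0 <- 72 * pi / 180
  cand <- rot(C4, th0)
  if (sum((cand - C5)^2) < 1e-6) th0 <- -th0  # walked the wrong way
  N9 <- rot(C4, th0); C8 <- rot(C4, 2 * th0); N7 <- rot(C4, 3 * th0)
  ring <- rbind(hexa,
                N7 = c(N7, 0), C8 = c(C8, 0), N9 = c(N9, 0))
  ring
}

.radial_substituent <- function(ring, at, bond) {
  p <- ring[at, 1:2]
  u <- p / sqrt(sum(p^2))
  c(p + bond * u, 0)
}

#' Idealized purine molecule templates
#'
#' Planar, idealized geometries of the three purines used throughout:
#' guanine (host), hypoxanthine and xanthine (guests). All three share the
#' nine-atom bicyclic ring; guanine adds O6 and the exocyclic amine N2,
#' hypoxanthine adds O6, xanthine adds O2 and O6. Hydrogens are omitted
#' (contact analysis treats all present atoms uniformly).
#'
#' @param name `"guanine"`, `"hypoxanthine"` or `"xanthine"`.
#' @param tautomer tautomer label carried on the template (metadata only).
#' @return a [molecule_template()].
#' @examples
#' gua <- purine_template("guanine")
#' hpx <- purine_template("hypoxanthine")
#' intersect(names(gua$scaffold), names(hpx$scaffold))
#' @export
purine_template <- function(name = c("guanine", "hypoxanthine", "xanthine"),
                            tautomer = NULL) {
  name <- match.arg(name)
  ring <- .purine_ring()
  xyz <- ring
  elements <- c("N", "C", "N", "C", "C", "C", "N", "C", "N")
  labels <- rownames(ring)
  add <- function(lab, el, at, bond) {
    xyz <<- rbind(xyz, .radial_substituent(ring, at, bond))
    elements <<- c(elements, el)
    labels <<- c(labels, lab)
  }
  if (name == "guanine") {
    add("O6", "O", "C6", 1.24); add("N2", "N", "C2", 1.36)
    if (is.null(tautomer)) tautomer <- "keto-N9H"
  } else if (name == "hypoxanthine") {
    add("O6", "O", "C6", 1.24)
    if (is.null(tautomer)) tautomer <- "keto-N7H"
  } else {
    add("O6", "O", "C6", 1.24); add("O2", "O", "C2", 1.24)
    if (is.null(tautomer)) tautomer <- "keto-enol-N7H"
  }
  scaff_labs <- intersect(c("N1", "C2", "N3", "C4", "C5", "C6",
                            "N7", "C8", "N9", "O6"), labels)
  scaffold <- match(scaff_labs, labels) |> stats::setNames(scaff_labs)
  rownames(xyz) <- labels
  molecule_template(name, tautomer, elements, xyz, scaffold)
}
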