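#' Read a crystal structure from a CIF file
#'
#' Minimal CIF 1.1 reader covering the subset the pipeline uses: cell
#' parameters, symmetry operations in "x,y,z" notation and the fractional
#' atom-site loop. Atom sites are expanded by the symmetry operations and
#' molecules are assembled by covalent-distance bonding (bond when the
#' interatomic distance is below the covalent-radii sum times `bond_tol`),
#' unwrapping molecules across periodic boundaries.
#'
#' @param path path to a CIF file.
#' @param bond_tol covalent bond tolerance factor (default 1.15).
#' @return a [crystal_structure()].
#' @export
read_cif <- function(path, bond_tol = 1.15) {
  if (!file.exists(path)) stop(sprintf("read_cif: no such file '%s'", path),
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- .cif_parse(lines)
  cellpar <- vapply(c("_cell_length_a", "_cell_length_b", "_cell_length_c",
                      "_cell_angle_alpha", "_cell_angle_beta",
                      "_cell_angle_gamma"),
                    function(k) {
                      v <- toks$pairs[[k]]
                      if (is.null(v)) stop(sprintf(
                        "read_cif: missing %s in '%s'", k, path), call. = FALSE)
                      .cif_num(v)
                    }, numeric(1))
  cellpar <- unname(cellpar)
  cell <- unit_cell(cellpar[1], cellpar[2], cellpar[3],
                    cellpar[4], cellpar[5], cellpar[6])
  symxyz <- toks$symops
  if (!length(symxyz)) symxyz <- "x,y,z"
  symops <- lapply(symxyz, parse_symop)
  if (!any(vapply(symops, .is_identity_symop, logical(1))))
    symops <- c(list(.identity_symop()), symops)
  at <- toks$atoms
  if (is.null(at) || !nrow(at))
    stop(sprintf("read_cif: no atom_site loop found in '%s'", path), call. = FALSE)
  if (any(abs(at$occupancy - 1) > 1e-6))
    stop("read_cif: partial occupancies are not supported", call. = FALSE)
  mols <- .assemble_molecules(cell, symops, at, bond_tol)
  crystal_structure(cell, symops, mols)
}

.cif_num <- function(x) as.numeric(sub("\\(.*\\)$", "", x))

## Very small CIF tokenizer: returns key/value pairs, symop strings and the
## atom-site table. Errors name the offending line.
.cif_parse <- function(lines) {
  pairs <- list(); symops <- character(); atoms <- NULL
  i <- 1; n <- length(lines)
  strip <- function(s) sub("#.*$", "", s)
  while (i <= n) {
    line <- trimws(strip(lines[i]))
    if (!nzchar(line) || startsWith(line, "data_")) { i <- i + 1; next }
    if (tolower(line) == "loop_") {
      i <- i + 1
      keys <- character()
      while (i <= n && grepl("^_", trimws(strip(lines[i])))) {
        keys <- c(keys, trimws(strip(lines[i]))); i <- i + 1
      }
      rows <- list()
      while (i <= n) {
        l2 <- trimws(strip(lines[i]))
        if (!nzchar(l2) || grepl("^(_|loop_|data_)", l2, ignore.case = TRUE)) break
        vals <- .cif_split(l2, i)
        if (length(keys) == 1L) {
          rows[[length(rows) + 1L]] <- paste(vals, collapse = " ")
        } else {
          if (length(vals) != length(keys))
            stop(sprintf("read_cif: line %d has %d fields, expected %d",
                         i, length(vals), length(keys)), call. = FALSE)
          rows[[length(rows) + 1L]] <- vals
        }
        i <- i + 1
      }
      lk <- tolower(keys)
      if (any(grepl("symop", lk) & grepl("xyz", lk)) ||
          any(lk == "_symmetry_equiv_pos_as_xyz")) {
        col <- which(grepl("xyz", lk))[1]
        symops <- vapply(rows, function(r)
          if (length(keys) == 1L) r else r[col], character(1))
      } else if (any(startsWith(lk, "_atom_site_"))) {
        tab <- do.call(rbind, rows)
        colnames(tab) <- lk
        atoms <- .cif_atom_table(tab)
      }
      next
    }
    if (startsWith(line, "_")) {
      sp <- regmatches(line, regexpr("[[:space:]]+", line))
      if (length(sp)) {
        key <- sub("[[:space:]].*$", "", line)
        val <- trimws(sub("^[^[:space:]]+[[:space:]]+", "", line))
        val <- gsub("^'|'$", "", val)
        pairs[[tolower(key)]] <- val
      }
      i <- i + 1
      next
    }
    stop(sprintf("read_cif: cannot parse line %d: '%s'", i, line), call. = FALSE)
  }
  list(pairs = pairs, symops = symops, atoms = atoms)
}

.cif_split <- function(line, lineno) {
  out <- character(); rest <- line
  while (nzchar(rest)) {
    rest <- sub("^[[:space:]]+", "", rest)
    if (!nzchar(rest)) break
    if (startsWith(rest, "'")) {
      m <- regmatches(rest, regexpr("^'[^']*'", rest))
      if (!length(m)) stop(sprintf("read_cif: unterminated quote on line %d",
                                   lineno), call. = FALSE)
      out <- c(out, gsub("^'|'$", "", m))
      rest <- substring(rest, nchar(m) + 1)
    } else {
      m <- regmatches(rest, regexpr("^[^[:space:]]+", rest))
      out <- c(out, m)
      rest <- substring(rest, nchar(m) + 1)
    }
  }
  out
}

.cif_atom_table <- function(tab) {
  cn <- colnames(tab)
  need <- c("_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z")
  if (!all(need %in% cn))
    stop("read_cif: atom_site loop lacks fractional coordinates", call. = FALSE)
  lab <- if ("_atom_site_label" %in% cn) tab[, "_atom_site_label"] else
    paste0("X", seq_len(nrow(tab)))
  el <- if ("_atom_site_type_symbol" %in% cn) tab[, "_atom_site_type_symbol"] else
    gsub("[^A-Za-z].*$", "", lab)
  occ <- if ("_atom_site_occupancy" %in% cn)
    vapply(tab[, "_atom_site_occupancy"], .cif_num, numeric(1)) else
      rep(1, nrow(tab))
  data.frame(label = lab, element = el,
             x = vapply(tab[, need[1]], .cif_num, numeric(1)),
             y = vapply(tab[, need[2]], .cif_num, numeric(1)),
             z = vapply(tab[, need[3]], .cif_num, numeric(1)),
             occupancy = occ, row.names = NULL)
}

## Expand atom sites by symmetry, deduplicate, then assemble molecules as
## connected components of the covalent bond graph over periodic images.
.assemble_molecules <- function(cell, symops, at, bond_tol) {
  M <- cell_matrix(cell)
  frac0 <- as.matrix(at[, c("x", "y", "z")])
  pos <- NULL; el <- character()
  for (op in symops) {
    f <- .wrap_frac(apply_symop(op, frac0))
    for (k in seq_len(nrow(f))) {
      if (!is.null(pos)) {
        dd <- sweep(pos, 2, f[k, ]); dd <- dd - round(dd)
        if (any(sqrt(rowSums((dd %*% t(M))^2)) < 0.05)) next
      }
      pos <- rbind(pos, f[k, ]); el <- c(el, at$element[k])
    }
  }
  natom <- nrow(pos)
  cart <- pos %*% t(M)
  radii <- .covalent_radius(el)
  offs <- as.matrix(expand.grid(a = -1:1, b = -1:1, c = -1:1))
  ## bonds: list of (i, j, offset row index)
  bonds <- vector("list", natom)
  maxbond <- (max(radii) * 2) * bond_tol
  for (o in seq_len(nrow(offs))) {
    shift <- as.numeric(offs[o, ] %*% M)
    D <- .cross_dist(cart, sweep(cart, 2, shift, "+"))
    lim <- outer(radii, radii, "+") * bond_tol
    hit <- which(D < lim & D > 1e-6, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; j <- hit[r, 2]
      bonds[[i]] <- c(bonds[[i]], list(c(j, offs[o, ])))
    }
  }
  ## BFS with unwrapping
  assigned <- rep(FALSE, natom)
  mols <- list()
  for (seed in seq_len(natom)) {
    if (assigned[seed]) next
    shifts <- matrix(NA_real_, natom, 3)
    shifts[seed, ] <- c(0, 0, 0)
    queue <- seed; assigned[seed] <- TRUE
    comp <- seed
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (b in bonds[[i]]) {
        j <- b[1]; off <- b[2:4]
        sj <- shifts[i, ] + off
        if (!assigned[j]) {
          assigned[j] <- TRUE; shifts[j, ] <- sj
          queue <- c(queue, j); comp <- c(comp, j)
        } else if (any(abs(shifts[j, ] - sj) > 1e-6)) {
          ## reached the same atom through a different lattice image:
          ## covalently periodic network, not a molecular crystal
          stop("read_cif: covalent network spans the lattice (not molecular)",
               call. = FALSE)
        }
      }
    }
    comp <- sort(comp)
    frac <- pos[comp, , drop = FALSE] + shifts[comp, , drop = FALSE]
    cent <- colMeans(frac)
    frac <- sweep(frac, 2, floor(cent))
    mols[[length(mols) + 1L]] <-
      list(species = paste0("mol", length(mols) + 1L),
           elements = el[comp], frac = frac)
  }
  mols
}

#' Write a crystal structure to a CIF file
#'
#' Writes the cell, the symmetry operations and the atoms of the asymmetric
#' unit (fractional coordinates).
#'
#' @param structure a [crystal_structure()].
#' @param path output path.
#' @param title data block name.
#' @param header optional comment lines written at the top of the file.
#' @return `path`, invisibly.
#' @export
write_cif <- function(structure, path, title = "xtalgrow", header = NULL) {
  cell <- structure$cell
  out <- character()
  if (!is.null(header)) out <- c(out, paste("#", header))
  out <- c(out, sprintf("data_%s", gsub("[[:space:]]", "_", title)),
           sprintf("_cell_length_a    %.6f", cell$a),
           sprintf("_cell_length_b    %.6f", cell$b),
           sprintf("_cell_length_c    %.6f", cell$c),
           sprintf("_cell_angle_alpha %.6f", cell$alpha),
           sprintf("_cell_angle_beta  %.6f", cell$beta),
           sprintf("_cell_angle_gamma %.6f", cell$gamma),
           "loop_", "_symmetry_equiv_pos_as_xyz",
           vapply(structure$symops, function(op)
             sprintf("'%s'", format_symop(op)), character(1)),
           "loop_", "_atom_site_label", "_atom_site_type_symbol",
           "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
           "_atom_site_occupancy")
  cnt <- new.env(); cnt$n <- 0L
  for (mi in seq_along(structure$asym)) {
    m <- structure$asym[[mi]]
    for (k in seq_len(nrow(m$frac))) {
      cnt$n <- cnt$n + 1L
      out <- c(out, sprintf("%s%d %s %.8f %.8f %.8f 1.0",
                            m$elements[k], cnt$n, m$elements[k],
                            m$frac[k, 1], m$frac[k, 2], m$frac[k, 3]))
    }
  }
  writeLines(out, path)
  invisible(path)
}
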