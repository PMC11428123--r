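#' Enumerate intermolecular neighbor contacts
#'
#' A molecule B is a neighbor of a central molecule A when the minimum
#' atom-atom distance between them, over all periodic images, does not exceed
#' `cutoff`. The default cutoff of 3.8 Angstrom is the dimer-partitioning
#' convention used for the free energies of crystallization. The periodic
#' image search is widened automatically when the cutoff (plus molecular
#' radii) exceeds the cell heights, so small cells are handled correctly.
#'
#' @param structure a [crystal_structure()].
#' @param cutoff contact cutoff in Angstrom (> 0).
#' @return data.frame of class `neighbor_contacts` with columns `i`, `j`
#'   (molecule indices in the cell), `oa`, `ob`, `oc` (lattice offset of j),
#'   `dist` (minimum atom-atom distance) and `va`, `vb`, `vc` (fractional
#'   centroid-to-centroid vector). The list is symmetric: if (i, j, t) is
#'   present so is (j, i, -t).
#' @export
enumerate_neighbors <- function(structure, cutoff = 3.8) {
  if (!inherits(structure, "crystal_structure"))
    stop("enumerate_neighbors: not a crystal_structure", call. = FALSE)
  if (!is.numeric(cutoff) || cutoff <= 0)
    stop("enumerate_neighbors: cutoff must be > 0", call. = FALSE)
  Z <- structure$Z
  M <- cell_matrix(structure$cell)
  carts <- lapply(seq_len(Z), function(i) molecule_cart(structure, i))
  cents <- t(vapply(carts, colMeans, numeric(3)))
  radii <- vapply(seq_len(Z), function(i)
    sqrt(max(rowSums(sweep(carts[[i]], 2, cents[i, ])^2))), numeric(1))
  rmax <- max(radii)
  heights <- .cell_heights(structure$cell)
  nimg <- pmax(1L, ceiling((cutoff + 2 * rmax) / heights))
  grid <- as.matrix(expand.grid(oa = -nimg[1]:nimg[1],
                                ob = -nimg[2]:nimg[2],
                                oc = -nimg[3]:nimg[3]))
  rows <- list()
  for (i in seq_len(Z)) {
    for (j in seq_len(Z)) {
      for (g in seq_len(nrow(grid))) {
        off <- grid[g, ]
        if (i == j && all(off == 0)) next
        shift <- as.numeric(off %*% t(M))
        dc <- sqrt(sum((cents[j, ] + shift - cents[i, ])^2))
        if (dc > cutoff + radii[i] + radii[j]) next
        d <- .min_dist(carts[[i]], sweep(carts[[j]], 2, shift, "+"))
        if (d <= cutoff) {
          v <- colMeans(structure$molecules[[j]]$frac) + off -
            colMeans(structure$molecules[[i]]$frac)
          rows[[length(rows) + 1L]] <-
            c(i, j, off, d, v)
        }
      }
    }
  }
  if (!length(rows)) {
    df <- data.frame(i = integer(), j = integer(), oa = integer(),
                     ob = integer(), oc = integer(), dist = numeric(),
                     va = numeric(), vb = numeric(), vc = numeric())
  } else {
    m <- do.call(rbind, rows)
    df <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                     oa = as.integer(m[, 3]), ob = as.integer(m[, 4]),
                     oc = as.integer(m[, 5]), dist = m[, 6],
                     va = m[, 7], vb = m[, 8], vc = m[, 9])
  }
  class(df) <- c("neighbor_contacts", "data.frame")
  attr(df, "cutoff") <- cutoff
  df
}

#' Classify contacts into symmetry-unique interaction types
#'
#' Two contacts belong to the same interaction type when a space-group
#' operation of the structure (combined, if needed, with exchanging the two
#' molecules of the pair) superposes one molecular pair onto the other within
#' `tol` RMSD. Returns the interaction table skeleton: one row per unique
#' type with its per-molecule multiplicity; the energy columns are unset
#' until [assemble_dg_cryst()] fills them.
#'
#' @param contacts result of [enumerate_neighbors()].
#' @param structure the same [crystal_structure()].
#' @param tol geometric RMSD tolerance in Angstrom (default 0.1).
#' @return data.frame of class `interaction_table` with columns `type`,
#'   `label`, `multiplicity`, `dist`, `dg_vacuum`, `dg_desolv`, `dg_cryst`,
#'   `solvent`; attribute `contact_type` maps each contact row to its type.
#' @export
classify_unique <- function(contacts, structure, tol = 0.1) {
  nc <- nrow(contacts)
  if (!nc) stop("classify_unique: empty contact list", call. = FALSE)
  M <- cell_matrix(structure$cell)
  Mi <- solve(M)
  carts <- lapply(seq_len(structure$Z), function(i) molecule_cart(structure, i))
  reps <- vector("list", nc)   # pair coordinates centered on central molecule
  swps <- vector("list", nc)   # exchanged pair
  spec <- character(nc)
  for (k in seq_len(nc)) {
    i <- contacts$i[k]; j <- contacts$j[k]
    off <- c(contacts$oa[k], contacts$ob[k], contacts$oc[k])
    Xi <- carts[[i]]
    Xj <- sweep(carts[[j]], 2, as.numeric(off %*% t(M)), "+")
    ci <- colMeans(Xi); cj <- colMeans(Xj)
    reps[[k]] <- sweep(rbind(Xi, Xj), 2, ci)
    swps[[k]] <- sweep(rbind(Xj, Xi), 2, cj)
    spec[k] <- paste(structure$molecules[[i]]$species,
                     structure$molecules[[j]]$species, sep = "|")
  }
  spec_sw <- vapply(strsplit(spec, "|", fixed = TRUE), function(p)
    paste(rev(p), collapse = "|"), character(1))
  rots <- lapply(structure$symops, function(op) M %*% op$R %*% Mi)
  rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))
  same <- function(k, l) {
    if (nrow(reps[[k]]) != nrow(reps[[l]])) return(FALSE)
    for (Rc in rots) {
      if (spec[k] == spec[l] &&
          rmsd(reps[[k]] %*% t(Rc), reps[[l]]) <= tol) return(TRUE)
      if (spec_sw[k] == spec[l] &&
          rmsd(swps[[k]] %*% t(Rc), reps[[l]]) <= tol) return(TRUE)
    }
    FALSE
  }
  type <- integer(nc)
  protos <- integer()
  for (k in seq_len(nc)) {
    hit <- 0L
    for (p in seq_along(protos)) {
      if (same(k, protos[p])) { hit <- p; break }
    }
    if (hit == 0L) { protos <- c(protos, k); hit <- length(protos) }
    type[k] <- hit
  }
  if (any(type == 0L))
    stop("classify_unique: classification incomplete", call. = FALSE)
  ntype <- length(protos)
  mult <- vapply(seq_len(ntype), function(tt)
    sum(type == tt & contacts$i == 1L), integer(1))
  tab <- data.frame(type = seq_len(ntype), label = NA_character_,
                    multiplicity = mult,
                    dist = vapply(seq_len(ntype), function(tt)
                      min(contacts$dist[type == tt]), numeric(1)),
                    dg_vacuum = NA_real_, dg_desolv = NA_real_,
                    dg_cryst = NA_real_, solvent = NA_character_)
  class(tab) <- c("interaction_table", "data.frame")
  attr(tab, "contact_type") <- type
  tab
}

#' Half-bond convention
#'
#' Interaction energies from a dimer calculation count the full pair; on the
#' growth lattice every contact is shared between two molecules, so each
#' molecule carries half.
#'
#' @param total_dimer_energy energy (any unit) of the full dimer interaction.
#' @return half the input.
#' @export
half_bond <- function(total_dimer_energy) total_dimer_energy / 2

#' Fill in per-interaction free energies of crystallization
#'
#' Attaches per-type vacuum and desolvation free energies and computes
#' `dg_cryst = dg_vacuum - dg_desolv`. Sign convention: positive `dg_cryst`
#' favours crystallization (a stronger interaction grows its direction
#' faster). A vacuum table simply has all `dg_desolv = 0`.
#'
#' @param table an [classify_unique()] interaction table.
#' @param dg_vacuum,dg_desolv numeric vectors with one value per type, in
#'   kJ/mol per interaction (half-bond convention); either unnamed in table
#'   order or named by type id.
#' @param solvent solvent label stored on the table.
#' @return the completed `interaction_table`.
#' @export
assemble_dg_cryst <- function(table, dg_vacuum, dg_desolv = NULL,
                              solvent = "vacuum") {
  n <- nrow(table)
  pick <- function(x, what) {
    if (is.null(x)) return(rep(0, n))
    if (!is.null(names(x))) x <- x[as.character(table$type)]
    if (length(x) != n || any(is.na(x)))
      stop(sprintf("assemble_dg_cryst: incomplete %s energies (need %d values)",
                   what, n), call. = FALSE)
    as.numeric(x)
  }
  table$dg_vacuum <- pick(dg_vacuum, "vacuum")
  table$dg_desolv <- pick(dg_desolv, "desolvation")
  table$dg_cryst <- table$dg_vacuum - table$dg_desolv
  table$solvent <- solvent
  table
}

#' Read/write interaction tables
#'
#' JSON (`.json`) or CSV (any other extension) serialization of an
#' interaction table.
#'
#' @param table an `interaction_table`.
#' @param path output path; format chosen by extension.
#' @return `path` invisibly, or the table for the reader.
#' @export
write_interaction_table <- function(table, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(table), path, digits = NA,
                         auto_unbox = FALSE, na = "null")
  } else {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_interaction_table
#' @export
read_interaction_table <- function(path) {
  tab <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("type", "label", "multiplicity", "dist",
            "dg_vacuum", "dg_desolv", "dg_cryst", "solvent")
  if (!all(need %in% names(tab)))
    stop("read_interaction_table: missing required columns", call. = FALSE)
  tab <- tab[, need]
  class(tab) <- c("interaction_table", "data.frame")
  tab
}
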