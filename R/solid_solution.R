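#' Solid-solution supercells
#'
#' A supercell with per-site occupancy (host or guest species) produced by
#' guest-for-host substitution. Substitution places the guest by optimal
#' rigid-body superposition (maximum atom overlap) over the scaffold atoms
#' the two templates share.
#'
#' @name solid_solution
NULL

.as_solid_solution <- function(supercell, host = NULL) {
  if (inherits(supercell, "solid_solution")) return(supercell)
  if (!inherits(supercell, "crystal_structure"))
    stop("expected a crystal_structure or solid_solution", call. = FALSE)
  occ <- vapply(supercell$molecules, function(m) m$species, character(1))
  if (is.null(host)) host <- occ[1]
  structure(list(base = supercell, occupants = occ,
                 N_cell = supercell$Z, N_h = sum(occ == host),
                 N_g = sum(occ != host), host = host,
                 guest = NA_character_),
            class = "solid_solution")
}

#' Substitute a guest molecule at a lattice site
#'
#' Replaces the host molecule at `site_index` with `guest`, rigidly
#' superposed by least squares over the scaffold atoms shared between the
#' host molecule and the guest template (matched by canonical scaffold
#' label). Unmatched substituents of the host (e.g. guanine's exocyclic
#' amine) are simply dropped with it.
#'
#' @param supercell a [crystal_structure()] (typically from
#'   [build_supercell()]) or an existing `solid_solution`.
#' @param site_index molecule index to replace (1..N_cell).
#' @param guest a [molecule_template()].
#' @param rmsd_max maximum acceptable scaffold RMSD (Angstrom) after
#'   superposition; above it an alignment-quality error is raised.
#' @return a `solid_solution` object.
#' @export
substitute_site <- function(supercell, site_index, guest, rmsd_max = 0.75) {
  ss <- .as_solid_solution(supercell)
  if (!inherits(guest, "molecule_template"))
    stop("substitute_site: guest must be a molecule_template", call. = FALSE)
  if (length(site_index) != 1 || site_index < 1 || site_index > ss$N_cell)
    stop("substitute_site: site_index out of range", call. = FALSE)
  mol <- ss$base$molecules[[site_index]]
  shared <- intersect(names(mol$scaffold), names(guest$scaffold))
  if (!length(shared))
    stop("substitute_site: host and guest share no scaffold atoms", call. = FALSE)
  cell <- ss$base$cell
  Xh <- frac_to_cart(cell, mol$frac[mol$scaffold[shared], , drop = FALSE])
  Xg <- guest$xyz[guest$scaffold[shared], , drop = FALSE]
  fit <- kabsch(Xg, Xh)
  if (fit$rmsd > rmsd_max)
    stop(sprintf(
      "substitute_site: alignment quality too poor (scaffold RMSD %.3f > %.3f)",
      fit$rmsd, rmsd_max), call. = FALSE)
  placed <- sweep(guest$xyz %*% t(fit$R), 2, fit$t, "+")
  was_host <- identical(ss$occupants[site_index], ss$host)
  new <- list(species = guest$name, tautomer = guest$tautomer,
              elements = guest$elements,
              frac = cart_to_frac(cell, placed),
              scaffold = guest$scaffold,
              asym_id = mol$asym_id, symop_id = mol$symop_id,
              align_rmsd = fit$rmsd)
  ss$base$molecules[[site_index]] <- new
  ss$base$asym <- ss$base$molecules
  ss$occupants[site_index] <- guest$name
  ss$N_h <- sum(ss$occupants == ss$host)
  ss$N_g <- ss$N_cell - ss$N_h
  if (!identical(guest$name, ss$host)) ss$guest <- guest$name
  ss
}

#' Guest mole fraction of a solid solution
#'
#' @param ss a `solid_solution`.
#' @return object of class `composition`: list with `x_g` = N_g / N_cell and
#'   `x_h` = 1 - x_g (exact rational arithmetic on the counts).
#' @export
mole_fraction <- function(ss) {
  if (!inherits(ss, "solid_solution")) ss <- .as_solid_solution(ss)
  if (ss$N_cell < 1) stop("mole_fraction: empty supercell", call. = FALSE)
  composition(ss$N_g / ss$N_cell)
}

#' @rdname mole_fraction
#' @param x_g guest mole fraction in [0, 1].
#' @export
composition <- function(x_g) {
  if (!is.numeric(x_g) || is.na(x_g) || x_g < 0 || x_g > 1)
    stop("composition: x_g must lie in [0, 1]", call. = FALSE)
  structure(list(x_g = x_g, x_h = 1 - x_g), class = "composition")
}

#' Enumerate translation-inequivalent guest configurations
#'
#' Generates the ensemble of doped supercells at a fixed guest count.
#' Occupancy patterns are deduplicated up to lattice translations of the
#' supercell (the periodicity actually present); the enumeration is capped by
#' `max_members` with deterministic seeded subsampling. With `permute_axes`,
#' supercell shapes with the a and b repeat counts exchanged (equal volume)
#' are sampled as well.
#'
#' @param supercell a [build_supercell()] result.
#' @param guest a [molecule_template()].
#' @param n_guest number of substituted sites, 0..N_cell.
#' @param permute_axes also include the supercell with `na` and `nb`
#'   exchanged (only meaningful when they differ).
#' @param max_members ensemble size cap (default 64).
#' @param seed RNG seed for the subsampling, recorded in the result.
#' @return object of class `configuration_ensemble`: list with `members`
#'   (list of `solid_solution`), `provenance` (data.frame of member site
#'   sets and supercell shapes), `n_patterns` (count of distinct patterns
#'   before capping), `seed`.
#' @export
enumerate_configurations <- function(supercell, guest, n_guest,
                                     permute_axes = FALSE,
                                     max_members = 64, seed = 1) {
  meta <- attr(supercell, "supercell")
  if (is.null(meta))
    meta <- list(repeats = c(1L, 1L, 1L), parent_Z = supercell$Z,
                 sites = data.frame(parent_mol = seq_len(supercell$Z),
                                    oa = 0L, ob = 0L, oc = 0L,
                                    site = seq_len(supercell$Z)))
  N <- supercell$Z
  if (n_guest < 0 || n_guest > N)
    stop("enumerate_configurations: n_guest out of range", call. = FALSE)
  shapes <- list(list(cell = supercell, meta = meta))
  if (isTRUE(permute_axes) && meta$repeats[1] != meta$repeats[2]) {
    parent <- attr(supercell, "supercell")$parent
    if (!is.null(parent)) {
      alt <- build_supercell(parent, meta$repeats[c(2, 1, 3)])
      shapes <- c(shapes, list(list(cell = alt, meta = attr(alt, "supercell"))))
    }
  }
  members <- list(); prov <- NULL; npat_total <- 0L
  for (sh in shapes) {
    pats <- .unique_patterns(sh$meta, n_guest, max_members, seed)
    npat_total <- npat_total + pats$n_patterns
    for (p in pats$patterns) {
      m <- sh$cell
      for (s in p) m <- substitute_site(m, s, guest)
      if (!length(p)) m <- .as_solid_solution(m)
      members[[length(members) + 1L]] <- m
      prov <- rbind(prov, data.frame(
        member = length(members),
        shape = paste(attr(sh$cell, "supercell")$repeats, collapse = "x"),
        sites = paste(p, collapse = ",")))
    }
  }
  if (length(members) > max_members) {
    set.seed(seed)
    keep <- sort(sample(length(members), max_members))
    members <- members[keep]
    prov <- prov[keep, , drop = FALSE]
    prov$member <- seq_along(members)
  }
  structure(list(members = members, provenance = prov,
                 n_patterns = npat_total, seed = seed),
            class = "configuration_ensemble")
}

## Distinct site subsets of size k up to lattice translation of the
## supercell. Returns canonical representatives.
.unique_patterns <- function(meta, k, max_members, seed) {
  sites <- meta$sites
  N <- nrow(sites)
  if (k == 0) return(list(patterns = list(integer()), n_patterns = 1L))
  if (k == N) return(list(patterns = list(seq_len(N)), n_patterns = 1L))
  rep3 <- meta$repeats
  ## site lookup by (parent_mol, oa, ob, oc)
  key <- function(pm, oa, ob, oc)
    paste(pm, oa %% rep3[1], ob %% rep3[2], oc %% rep3[3])
  lut <- stats::setNames(sites$site, key(sites$parent_mol, sites$oa,
                                         sites$ob, sites$oc))
  trans <- expand.grid(ta = 0:(rep3[1] - 1), tb = 0:(rep3[2] - 1),
                       tc = 0:(rep3[3] - 1))
  perms <- lapply(seq_len(nrow(trans)), function(r)
    unname(lut[key(sites$parent_mol, sites$oa + trans$ta[r],
                   sites$ob + trans$tb[r], sites$oc + trans$tc[r])]))
  canon <- function(set) {
    best <- NULL
    for (p in perms) {
      cand <- sort(p[set])
      if (is.null(best) || .lex_less(cand, best)) best <- cand
    }
    best
  }
  ncomb <- choose(N, k)
  seen <- new.env(hash = TRUE)
  patterns <- list()
  add <- function(set) {
    cc <- canon(set)
    id <- paste(cc, collapse = ",")
    if (is.null(seen[[id]])) {
      seen[[id]] <- TRUE
      patterns[[length(patterns) + 1L]] <<- cc
    }
  }
  if (ncomb <= 20000) {
    combs <- utils::combn(N, k)
    for (ci in seq_len(ncol(combs))) add(combs[, ci])
  } else {
    set.seed(seed)
    for (trial in seq_len(max(50L * max_members, 2000L)))
      add(sort(sample.int(N, k)))
  }
  n_patterns <- length(patterns)
  if (n_patterns > max_members) {
    set.seed(seed)
    patterns <- patterns[sort(sample(n_patterns, max_members))]
  }
  list(patterns = patterns, n_patterns = n_patterns)
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.solid_solution <- function(x, ...) {
  cat(sprintf("<solid_solution> N_cell=%d N_h=%d N_g=%d (host %s, guest %s)\n",
              x$N_cell, x$N_h, x$N_g, x$host,
              ifelse(is.na(x$guest), "-", x$guest)))
  invisible(x)
}

#' @export
print.configuration_ensemble <- function(x, ...) {
  cat(sprintf("<configuration_ensemble> %d member(s), %d distinct pattern(s), seed %d\n",
              length(x$members), x$n_patterns, x$seed))
  invisible(x)
}
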