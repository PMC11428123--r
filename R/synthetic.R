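#' Synthetic crystal structures
#'
#' Generators for every structural input the pipeline needs, so the full
#' analysis runs without external downloads. `make_toy_structure()` builds
#' small deterministic crystals; `synth_beta_guanine()` builds the packaged
#' beta-guanine-like fixture: a *synthetic approximation* of the monoclinic
#' beta polymorph's packing motif (pi-stacking along a, a triple-H-bonded
#' chain along b, a weaker H-bond dimer link in the bc plane), not the
#' published coordinates.
#'
#' @param a,b,c,alpha,beta,gamma cell parameters; defaults depend on motif.
#' @param Z requested molecules per cell (1 for the P1 motifs, 4 for the
#'   layered P21/c motif).
#' @param motif `"layered"` (monoclinic molecular-sheet motif, default) or
#'   `"cubic"` (one spherical molecule on a cubic lattice).
#' @return a [crystal_structure()].
#' @examples
#' toy <- make_toy_structure(motif = "cubic")
#' nrow(enumerate_neighbors(toy, cutoff = 4.1))  # 6 nearest neighbors
#' @export
make_toy_structure <- function(a = NULL, b = NULL, c = NULL,
                               alpha = NULL, beta = NULL, gamma = NULL,
                               Z = 1, motif = c("layered", "cubic")) {
  motif <- match.arg(motif)
  if (motif == "cubic") {
    a0 <- if (is.null(a)) 4 else a
    cell <- unit_cell(a0, if (is.null(b)) a0 else b, if (is.null(c)) a0 else c)
    mol <- list(species = "toy", elements = "C",
                frac = matrix(c(0, 0, 0), 1, 3),
                scaffold = stats::setNames(1L, "A1"))
    return(crystal_structure(cell, symops_for("P1"), list(mol)))
  }
  ## layered motif: planar cross-shaped "toy" molecule perpendicular to a,
  ## H-bond-like chain along b, oblique in-plane lattice giving a hexagonal
  ## in-plane net (b, c', b - c' contacts)
  xyz <- .toy_molecule_xyz()
  span <- max(xyz[, 2]) - min(xyz[, 2])
  a0 <- if (is.null(a)) 3.4 else a
  b0 <- if (is.null(b)) span + 2.9 else b
  c0 <- if (is.null(c)) 6.4 else c
  al <- if (is.null(alpha)) 49.4 else alpha   # oblique bc net
  cell <- unit_cell(a0, b0, c0, alpha = al, beta = 90, gamma = 90)
  mol <- list(species = "toy", elements = rep("C", nrow(xyz)),
              frac = cart_to_frac(cell, xyz),
              scaffold = stats::setNames(seq_len(nrow(xyz)),
                                         paste0("A", seq_len(nrow(xyz)))))
  if (Z != 1) stop("make_toy_structure: layered motif is Z = 1", call. = FALSE)
  st <- crystal_structure(cell, symops_for("P1"), list(mol))
  .check_no_overlap(st)
  st
}

## planar cross: 5-atom chain along y, 2+2 arm along z, 1.35 A bonds
.toy_molecule_xyz <- function() {
  ys <- c(-2.70, -1.35, 0, 1.35, 2.70)
  arm <- c(-2.70, -1.35, 1.35, 2.70)
  rbind(cbind(0, ys, 0), cbind(0, 0, arm))
}

.check_no_overlap <- function(st, min_sep = 1.0) {
  cont <- enumerate_neighbors(st, cutoff = 3.8)
  if (nrow(cont) && min(cont$dist) < min_sep)
    stop(sprintf("synthetic structure: molecules overlap (min contact %.2f A)",
                 min(cont$dist)), call. = FALSE)
  invisible(st)
}

#' @rdname make_toy_structure
#' @param params optional named list overriding the fixture's geometric
#'   parameters (advanced use; the defaults define the packaged fixture).
#' @export
synth_beta_guanine <- function(params = list()) {
  p <- modifyList(list(a = 3.55, b = 8.8, c = 16.5, beta = 96,
                       y0 = 0.25, z0 = 0.125, phi = 140.55, tilt = 30), params)
  tpl <- purine_template("guanine")
  xyz <- tpl$xyz
  ## orient: in-plane rotation phi about x, then tilt about b (y axis)
  rot_x <- function(th) {
    th <- th * pi / 180
    matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
           byrow = TRUE)
  }
  rot_y <- function(th) {
    th <- th * pi / 180
    matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
           byrow = TRUE)
  }
  ## template lies in the xy plane; move it to the yz plane first
  swap <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  X <- xyz %*% t(swap) %*% t(rot_x(p$phi)) %*% t(rot_y(p$tilt))
  X <- sweep(X, 2, colMeans(X))
  cell <- unit_cell(p$a, p$b, p$c, beta = p$beta)
  cent_frac <- c(0, p$y0, p$z0)
  frac <- sweep(cart_to_frac(cell, X), 2, cent_frac, "+")
  mol <- list(species = "guanine", tautomer = "keto-N9H",
              elements = tpl$elements, frac = frac, scaffold = tpl$scaffold)
  st <- crystal_structure(cell, symops_for("P21/c"), list(mol))
  .check_no_overlap(st)
  st
}

#' Geometric interaction labels
#'
#' Assigns field-standard labels to the symmetry-unique interaction types of
#' a layered monoclinic structure from the contact geometry alone:
#' `"pi-stack"` for the pure short-axis stacking contact, `"3H-bond"` for
#' the in-plane chain along b, `"2H-bond"` for the shortest remaining
#' in-plane dimer link, `"pi-other-k"` for the stacked-level diagonal
#' contacts (one level above or below the central molecule) and
#' `"other-k"` for the remaining in-plane contacts (distance-ordered).
#'
#' @param table an [classify_unique()] interaction table.
#' @param contacts the [enumerate_neighbors()] contacts it was built from.
#' @return the table with the `label` column filled.
#' @export
label_interactions <- function(table, contacts) {
  ct <- attr(table, "contact_type")
  n <- nrow(table)
  va <- vb <- vc <- numeric(n)
  for (tt in seq_len(n)) {
    k <- which(ct == tt)[1]
    va[tt] <- abs(contacts$va[k]); vb[tt] <- abs(contacts$vb[k])
    vc[tt] <- abs(contacts$vc[k])
  }
  lab <- rep(NA_character_, n)
  in_plane <- va < 0.4
  pure_pi <- va >= 0.4 & vb < 0.25 & vc < 0.25
  pure_b <- in_plane & vb >= 0.4 & vc < 0.1
  lab[pure_pi] <- "pi-stack"
  lab[pure_b] <- "3H-bond"
  rest_in <- which(in_plane & !pure_b)
  if (length(rest_in)) {
    two_h <- rest_in[which.min(table$dist[rest_in])]
    ## the same dimer family can split into +/- types when the structure is
    ## given without its symmetry (P1 supercells): same |vector|, same length
    fam <- rest_in[abs(table$dist[rest_in] - table$dist[two_h]) < 0.05 &
                     abs(va[rest_in] - va[two_h]) < 0.02 &
                     abs(vb[rest_in] - vb[two_h]) < 0.02 &
                     abs(vc[rest_in] - vc[two_h]) < 0.02]
    lab[fam] <- "2H-bond"
  }
  pio <- which(is.na(lab) & !in_plane)
  if (length(pio)) {
    pio <- pio[order(table$dist[pio])]
    lab[pio] <- paste0("pi-other-", seq_along(pio))
  }
  others <- which(is.na(lab))
  if (length(others)) {
    others <- others[order(table$dist[others])]
    lab[others] <- paste0("other-", seq_along(others))
  }
  table$label <- lab
  table
}

.label_class <- function(label) {
  ifelse(label %in% c("pi-stack", "3H-bond", "2H-bond"), label,
         ifelse(startsWith(label, "pi-other"), "pi-other", "other"))
}

#' Solvent desolvation profiles
#'
#' Qualitative per-interaction desolvation free energies (kJ/mol, half-bond
#' convention) keyed by interaction class. They encode the orderings the
#' solvation picture dictates, not computed values: water makes H-bond
#' desolvation costly and pi desolvation favourable (negative), a nonpolar
#' toluene-like solvent does the opposite, vacuum is identically zero.
#'
#' @param label one of `"vacuum"`, `"water"`, `"toluene"`, `"DMSO"`,
#'   `"formamide"`, or `"synthetic"` (then supply `offsets`).
#' @param offsets named numeric vector over classes
#'   `pi-stack, 3H-bond, 2H-bond, pi-other, other` used when
#'   `label = "synthetic"`.
#' @return object of class `solvent_profile`.
#' @export
solvent_profile <- function(label = c("vacuum", "water", "toluene", "DMSO",
                                      "formamide", "synthetic"),
                            offsets = NULL) {
  label <- match.arg(label)
  off <- switch(label,
    vacuum    = c("pi-stack" = 0,  "3H-bond" = 0,  "2H-bond" = 0,
                  "pi-other" = 0, other = 0),
    water     = c("pi-stack" = -16, "3H-bond" = 16, "2H-bond" = 10,
                  "pi-other" = -1, other = 8),
    toluene   = c("pi-stack" = 9,  "3H-bond" = 2,  "2H-bond" = 1,
                  "pi-other" = 3, other = 2),
    DMSO      = c("pi-stack" = -8, "3H-bond" = 14, "2H-bond" = 7,
                  "pi-other" = -1, other = 2),
    formamide = c("pi-stack" = -6, "3H-bond" = 15, "2H-bond" = 8,
                  "pi-other" = -1, other = 2),
    synthetic = {
      need <- c("pi-stack", "3H-bond", "2H-bond", "pi-other", "other")
      if (is.null(offsets) || !all(need %in% names(offsets)))
        stop("solvent_profile: synthetic profile needs named offsets for ",
             paste(need, collapse = ", "), call. = FALSE)
      offsets[need]
    })
  structure(list(label = label, offsets = off), class = "solvent_profile")
}

#' Guest perturbations of the vacuum interaction energies
#'
#' Multiplicative (and optionally additive) modifiers of the per-class
#' vacuum interaction energies, modelling how a guest disrupts the host's
#' H-bond network: both guests sharply weaken the triple-H-bond chain,
#' xanthine additionally weakens the secondary in-plane link.
#'
#' @param label `"none"`, `"hpx"`, `"xan"`, or `"synthetic"` (supply
#'   `scale` / `shift`).
#' @param scale,shift named vectors over classes
#'   `pi-stack, 3H-bond, 2H-bond, pi-other, other` for
#'   `label = "synthetic"`.
#' @return object of class `guest_perturbation`.
#' @export
guest_perturbation <- function(label = c("none", "hpx", "xan", "synthetic"),
                               scale = NULL, shift = NULL) {
  label <- match.arg(label)
  cls <- c("pi-stack", "3H-bond", "2H-bond", "pi-other", "other")
  one <- stats::setNames(rep(1, 5), cls)
  zero <- stats::setNames(rep(0, 5), cls)
  sc <- switch(label,
    none = one,
    hpx  = c("pi-stack" = 1, "3H-bond" = 0.70, "2H-bond" = 0.95,
             "pi-other" = 0.95, other = 0.95),
    xan  = c("pi-stack" = 1, "3H-bond" = 0.70, "2H-bond" = 0.60,
             "pi-other" = 0.90, other = 0.90),
    synthetic = { if (is.null(scale)) one else scale[cls] })
  sh <- if (label == "synthetic" && !is.null(shift)) shift[cls] else zero
  if (any(is.na(sc)) || any(is.na(sh)))
    stop("guest_perturbation: scale/shift must name all classes", call. = FALSE)
  structure(list(label = label, scale = sc, shift = sh),
            class = "guest_perturbation")
}

## base vacuum interaction energies per class (kJ/mol, half bond):
## the triple-H-bond chain dominates, the secondary in-plane link is about
## half of it, the pi-stack is weak, diagonal contacts weaker still
.BASE_VACUUM <- c("pi-stack" = 6, "3H-bond" = 20, "2H-bond" = 12,
                  "pi-other" = 4, other = 10)

#' Synthetic per-interaction free energies of crystallization
#'
#' Classifies and labels the structure's symmetry-unique interactions, then
#' attaches qualitative energies: vacuum interaction strengths per class,
#' optionally perturbed by a guest, minus the solvent's desolvation offsets;
#' `dg_cryst = dg_vacuum - dg_desolv` by construction. Positive values
#' favour crystallization.
#'
#' @param structure a [crystal_structure()].
#' @param solvent a [solvent_profile()] (or label string).
#' @param guest a [guest_perturbation()] (or label string), `NULL` for the
#'   pure host.
#' @param cutoff contact cutoff in Angstrom.
#' @param base named vacuum energies per class (kJ/mol); the default encodes
#'   the host ordering 3H-bond > 2H-bond > pi-stack.
#' @return a labelled, energy-complete `interaction_table`.
#' @export
make_interaction_table <- function(structure, solvent = "vacuum",
                                   guest = NULL, cutoff = 3.8,
                                   base = .BASE_VACUUM) {
  if (is.character(solvent)) solvent <- solvent_profile(solvent)
  if (is.character(guest)) guest <- guest_perturbation(guest)
  if (is.null(guest)) guest <- guest_perturbation("none")
  contacts <- enumerate_neighbors(structure, cutoff)
  tab <- classify_unique(contacts, structure)
  tab <- label_interactions(tab, contacts)
  cls <- .label_class(tab$label)
  vac <- base[cls] * guest$scale[cls] + guest$shift[cls]
  des <- solvent$offsets[cls]
  tab <- assemble_dg_cryst(tab, as.numeric(vac), as.numeric(des),
                           solvent = solvent$label)
  attr(tab, "guest") <- guest$label
  tab
}

#' Synthetic pairwise energy model
#'
#' A stand-in energy provider for the thermodynamic chain: the supercell
#' energy is a sum over neighbor contacts of per-class well depths
#' (negative, stabilizing), plus per-guest contact penalties (positive,
#' destabilizing -- the H-bond disruption), plus per-molecule gas-phase
#' reference terms. It is extensive by construction and exactly linear in
#' guest count when penalties are additive, so injected penalties can be
#' recovered from the computed lattice energies.
#'
#' @param depths named positive well depths per class (kJ/mol per half
#'   bond); the contact contribution is `-depth`.
#' @param guest_penalty named per-class additive penalties (kJ/mol per half
#'   bond) applied for each guest molecule in a contact.
#' @param E_ref named per-species gas-phase reference energies (kJ/mol).
#' @param phase_advantage stabilization (kJ/mol per molecule) of the pure
#'   guest compound's own crystal polymorph relative to the all-guest
#'   host-structure endpoint; this is what makes dilute solid solutions
#'   metastable rather than stable against the physical mixture.
#' @param cutoff contact cutoff used to build the supercell contact graph.
#' @param guest_kind `"hpx"` (default) or `"xan"`; the xan-like guest
#'   doubles the contact penalties (its lattice-energy slope is about twice
#'   the hpx-like slope) and the phase advantage.
#' @return object of class `pairwise_energy_model`.
#' @export
pairwise_energy_model <- function(depths = .BASE_VACUUM,
                                  guest_penalty = NULL,
                                  E_ref = c(guanine = 0, hypoxanthine = 0,
                                            xanthine = 0, toy = 0),
                                  phase_advantage = NULL,
                                  cutoff = 3.8,
                                  guest_kind = c("hpx", "xan")) {
  guest_kind <- match.arg(guest_kind)
  fac <- if (guest_kind == "xan") 2 else 1
  if (is.null(guest_penalty))
    guest_penalty <- fac * c("pi-stack" = 0, "3H-bond" = 5, "2H-bond" = 1,
                             "pi-other" = 0.5, other = 0.5)
  if (is.null(phase_advantage)) phase_advantage <- 9 * fac
  structure(list(depths = depths, guest_penalty = guest_penalty,
                 E_ref = E_ref, phase_advantage = phase_advantage,
                 cutoff = cutoff, guest_kind = guest_kind),
            class = "pairwise_energy_model")
}

#' Contact graph of a supercell, labelled by interaction class
#'
#' Computed once per supercell shape and reused for every ensemble member
#' (substitution does not move sites).
#'
#' @param supercell a [build_supercell()] result (or any structure).
#' @param cutoff contact cutoff in Angstrom.
#' @return data.frame of unordered contacts with columns `i`, `j`, `class`.
#' @export
supercell_contacts <- function(supercell, cutoff = 3.8) {
  contacts <- enumerate_neighbors(supercell, cutoff)
  tab <- classify_unique(contacts, supercell)
  tab <- label_interactions(tab, contacts)
  ct <- attr(tab, "contact_type")
  cls <- .label_class(tab$label)[ct]
  ## keep each unordered pair once (i < j, or i == j with positive offset)
  keep <- contacts$i < contacts$j |
    (contacts$i == contacts$j &
       (contacts$oa > 0 | (contacts$oa == 0 & contacts$ob > 0) |
          (contacts$oa == 0 & contacts$ob == 0 & contacts$oc > 0)))
  data.frame(i = contacts$i[keep], j = contacts$j[keep], class = cls[keep])
}

#' Supercell energy from the pairwise model
#'
#' @param model a [pairwise_energy_model()].
#' @param ss a `solid_solution` (or plain supercell).
#' @param contacts optional precomputed [supercell_contacts()].
#' @return an [energy_accounting()] for [lattice_energy_ss()].
#' @export
supercell_energy <- function(model, ss, contacts = NULL) {
  ss <- .as_solid_solution(ss)
  if (is.null(contacts)) contacts <- supercell_contacts(ss$base, model$cutoff)
  occ <- ss$occupants
  if (!all(occ %in% names(model$E_ref)))
    stop("supercell_energy: model lacks parameters for species ",
         paste(setdiff(occ, names(model$E_ref)), collapse = ", "),
         call. = FALSE)
  is_guest <- occ != ss$host
  pen <- model$guest_penalty[contacts$class] *
    (is_guest[contacts$i] + is_guest[contacts$j])
  E_pairs <- sum(-model$depths[contacts$class] + pen)
  E_cell <- E_pairs + sum(model$E_ref[occ])
  guest_sp <- if (any(is_guest)) occ[is_guest][1] else names(model$E_ref)[2]
  energy_accounting(E_cell,
                    E_h_ref = unname(model$E_ref[ss$host]),
                    E_g_ref = unname(model$E_ref[guest_sp]),
                    N_cell = ss$N_cell, N_h = ss$N_h, N_g = ss$N_g)
}
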