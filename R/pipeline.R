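#' Thermodynamic analysis chain
#'
#' Orchestrates the solid-solution free-energy analysis: build the host
#' structure and supercell, generate configuration ensembles across a
#' composition grid, score them with the pairwise energy model, reduce each
#' ensemble to one lattice energy, assemble the free-energy curve (with
#' vibrational trendline and mixing entropy) and classify stability against
#' the physical-mixture line.
#'
#' @param config named list; recognized entries (all with defaults):
#'   `structure` (a `crystal_structure`, default [synth_beta_guanine()]),
#'   `guest` (template, default hypoxanthine), `repeats` (supercell,
#'   default c(2, 2, 1)), `n_guest_grid` (guest counts, default
#'   0..N_cell by steps covering the range), `model`
#'   ([pairwise_energy_model()]), `T` (K), `aggregate`
#'   (`"min"`, `"mean"` or `"boltzmann"`), `max_members`, `seed`,
#'   `vib_samples` (data.frame x_g/F_vib or NULL), `threshold` (kJ/mol),
#'   `polymorph_gap` (kJ/mol or NULL). The physical-mixture line uses the
#'   model's `phase_advantage` for the pure-guest reference.
#' @return list of class `thermo_chain`: `curve` ([free_energy_curve()]),
#'   `verdicts` ([classify_stability()]), `line`, `lattice`
#'   (per-composition energies), `manifest`.
#' @export
run_thermo_chain <- function(config = list()) {
  t0 <- Sys.time()
  cfg <- modifyList(list(structure = NULL, guest = NULL,
                         repeats = c(2, 2, 1), n_guest_grid = NULL,
                         model = pairwise_energy_model(), T = 300,
                         aggregate = "min", max_members = 16, seed = 1,
                         vib_samples = NULL, threshold = NULL,
                         polymorph_gap = NULL), config)
  st <- if (is.null(cfg$structure)) synth_beta_guanine() else cfg$structure
  guest <- if (is.null(cfg$guest)) purine_template("hypoxanthine") else cfg$guest
  sc <- build_supercell(st, cfg$repeats)
  N <- sc$Z
  grid <- if (is.null(cfg$n_guest_grid))
    unique(round(seq(0, N, length.out = min(N + 1, 9)))) else cfg$n_guest_grid
  grid <- sort(unique(as.integer(grid)))
  contacts <- supercell_contacts(sc, cfg$model$cutoff)
  agg <- switch(cfg$aggregate,
                min = function(e) min(e),
                mean = function(e) mean(e),
                boltzmann = function(e) {
                  w <- exp(-(e - min(e)) / (.R_KJ * cfg$T))
                  sum(w * e) / sum(w)
                },
                stop("run_thermo_chain: unknown aggregate", call. = FALSE))
  lattice <- NULL
  for (ng in grid) {
    ens <- enumerate_configurations(sc, guest, ng,
                                    max_members = cfg$max_members,
                                    seed = cfg$seed)
    e <- vapply(ens$members, function(m)
      lattice_energy_ss(supercell_energy(cfg$model, m, contacts)), numeric(1))
    lattice <- rbind(lattice, data.frame(
      x_g = ng / N, n_guest = ng, E_latt = agg(e),
      E_min = min(e), E_mean = mean(e), n_members = length(e)))
  }
  trend <- if (!is.null(cfg$vib_samples))
    vib_trendline(cfg$vib_samples$x_g, cfg$vib_samples$F_vib) else NULL
  curve <- free_energy_curve(lattice, trend, T = cfg$T)
  ## physical-mixture reference: pure host in its own structure, pure guest
  ## in its own (more stable) polymorph
  eN <- if (max(curve$x_g) == 1) {
    curve$E_latt[curve$x_g == 1][1]
  } else {
    ensN <- enumerate_configurations(sc, guest, N, max_members = 1,
                                     seed = cfg$seed)
    lattice_energy_ss(supercell_energy(cfg$model, ensN$members[[1]], contacts))
  }
  line <- mixture_line(curve$G[curve$x_g == 0][1],
                       eN - cfg$model$phase_advantage)
  verdicts <- classify_stability(curve, line, threshold = cfg$threshold,
                                 polymorph_gap = cfg$polymorph_gap)
  manifest <- .manifest(cfg[setdiff(names(cfg), c("structure", "guest", "model"))],
                        list(guest = guest$name, N_cell = N), t0)
  structure(list(curve = curve, verdicts = verdicts, line = line,
                 lattice = lattice, manifest = manifest),
            class = "thermo_chain")
}

#' Morphology analysis chain
#'
#' Builds the interaction table for a structure / solvent / guest preset and
#' grows a crystal from it, returning the morphology report with facet
#' areas.
#'
#' @param config named list; recognized entries: `structure` (default
#'   [synth_beta_guanine()]), `solvent` (label or [solvent_profile()],
#'   default "vacuum"), `guest` (label or [guest_perturbation()] or NULL),
#'   `growth` (a [growth_config()], default the desk preset), `seed`
#'   (overrides the growth config seed), `facets` (logical, default TRUE).
#' @return list of class `morphology_chain`: `report`
#'   ([morphology_metrics()]), `state`, `table`, `manifest`.
#' @export
run_morphology_chain <- function(config = list()) {
  t0 <- Sys.time()
  cfg <- modifyList(list(structure = NULL, solvent = "vacuum", guest = NULL,
                         growth = growth_config(preset = "desk"),
                         seed = NULL, facets = TRUE), config)
  st <- if (is.null(cfg$structure)) synth_beta_guanine() else cfg$structure
  if (!is.null(cfg$seed)) cfg$growth$seed <- cfg$seed
  tab <- make_interaction_table(st, solvent = cfg$solvent, guest = cfg$guest)
  state <- run_growth(tab, st, cfg$growth)
  facets <- if (isTRUE(cfg$facets))
    tryCatch(identify_facets(state), error = function(e) NULL) else NULL
  report <- morphology_metrics(state, facets = facets)
  manifest <- .manifest(list(solvent = if (is.character(cfg$solvent))
    cfg$solvent else cfg$solvent$label,
    guest = if (is.null(cfg$guest)) "none" else
      if (is.character(cfg$guest)) cfg$guest else cfg$guest$label,
    seed = state$config$seed,
    iterations = state$config$total_iterations),
    list(n_molecules = report$n_molecules), t0)
  structure(list(report = report, state = state, table = tab,
                 manifest = manifest),
            class = "morphology_chain")
}

.manifest <- function(config, outputs, t0) {
  list(package = "xtalgrow",
       version = as.character(utils::packageVersion("xtalgrow")),
       config = config, outputs = outputs,
       elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' @export
print.thermo_chain <- function(x, ...) {
  cat("<thermo_chain>\n")
  print(cbind(round(x$curve, 4),
              margin = round(x$verdicts$margin, 4),
              class = x$verdicts$class))
  invisible(x)
}

#' @export
print.morphology_chain <- function(x, ...) {
  cat(sprintf("<morphology_chain> solvent=%s guest=%s\n",
              x$manifest$config$solvent, x$manifest$config$guest))
  print(x$report)
  invisible(x)
}
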