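#' Energy accounting for a solid-solution supercell
#'
#' Bundles the supercell electronic energy with the gas-phase reference
#' energies and molecule counts needed for the per-molecule lattice energy.
#' All energies in kJ/mol (use `unit = "kcal"` to convert inputs).
#'
#' @param E_cell electronic energy of the whole supercell.
#' @param E_h_ref,E_g_ref gas-phase reference energy per host / guest
#'   molecule.
#' @param N_cell,N_h,N_g molecule counts; `N_h + N_g` must equal `N_cell`.
#' @param unit `"kJ"` (default) or `"kcal"`; kcal inputs are converted to kJ.
#' @return object of class `energy_accounting`.
#' @export
energy_accounting <- function(E_cell, E_h_ref, E_g_ref, N_cell, N_h, N_g,
                              unit = c("kJ", "kcal")) {
  unit <- match.arg(unit)
  f <- if (unit == "kcal") .KCAL else 1
  if (N_h + N_g != N_cell)
    stop("energy_accounting: N_h + N_g must equal N_cell", call. = FALSE)
  if (N_cell < 1) stop("energy_accounting: N_cell must be >= 1", call. = FALSE)
  structure(list(E_cell = E_cell * f, E_h_ref = E_h_ref * f,
                 E_g_ref = E_g_ref * f, N_cell = N_cell, N_h = N_h, N_g = N_g),
            class = "energy_accounting")
}

#' Per-molecule lattice energy of a solid solution
#'
#' E_latt = (E_cell - N_h * E_h_ref - N_g * E_g_ref) / N_cell, the
#' multicomponent generalization of the standard lattice energy; it reduces
#' to the single-component definition when N_g = 0.
#'
#' @param acct an [energy_accounting()].
#' @return lattice energy per molecule (kJ/mol).
#' @export
lattice_energy_ss <- function(acct) {
  if (!inherits(acct, "energy_accounting"))
    stop("lattice_energy_ss: need an energy_accounting object", call. = FALSE)
  with(acct, (E_cell - N_h * E_h_ref - N_g * E_g_ref) / N_cell)
}

#' Ideal entropy of mixing
#'
#' dS_mix = -R (x_h ln x_h + x_g ln x_g), with the 0 * log 0 = 0 limit at the
#' endpoints. Vectorized over `x_g`.
#'
#' @param x_g guest mole fraction(s) in [0, 1], or a `composition`.
#' @return entropy in J mol^-1 K^-1 (nonnegative; maximal R ln 2 at 0.5).
#' @export
mixing_entropy <- function(x_g) {
  if (inherits(x_g, "composition")) x_g <- x_g$x_g
  if (any(x_g < 0 | x_g > 1)) stop("mixing_entropy: x_g outside [0, 1]",
                                   call. = FALSE)
  xlogx <- function(x) ifelse(x <= 0, 0, x * log(x))
  -.R_J * (xlogx(x_g) + xlogx(1 - x_g))
}

#' Cubic trendline for the vibrational free-energy contribution
#'
#' Fits a least-squares cubic through sampled vibrational free energies
#' (at 300 K relative to 0 K) versus guest fraction, so the vibrational term
#' can be evaluated at any composition. Mirrors a degree-3 polynomial fit
#' through samples at x in {0, 0.25, 0.5, 0.75, 1}.
#'
#' @param x_g sampled guest fractions (>= 4 distinct values).
#' @param F_vib vibrational free energies at those compositions (kJ/mol).
#' @return object of class `vib_trendline`; use `predict(fit, x)` to
#'   evaluate.
#' @export
vib_trendline <- function(x_g, F_vib) {
  if (length(unique(x_g)) < 4)
    stop("vib_trendline: need >= 4 distinct compositions for a cubic fit",
         call. = FALSE)
  fit <- stats::lm(F_vib ~ poly(x_g, 3, raw = TRUE))
  structure(list(coef = unname(coef(fit)),
                 residuals = unname(fit$residuals)),
            class = "vib_trendline")
}

#' @export
predict.vib_trendline <- function(object, newdata, ...) {
  x <- if (is.list(newdata)) newdata[[1]] else newdata
  cf <- object$coef
  cf[1] + cf[2] * x + cf[3] * x^2 + cf[4] * x^3
}

#' Free-energy curve of a solid solution
#'
#' G(x) = E_latt(x) + F_vib(x) - T * dS_mix(x), per molecule, with the
#' entropy converted from J to kJ at assembly.
#'
#' @param lattice data.frame with columns `x_g` and `E_latt` (kJ/mol per
#'   molecule), covering at least two compositions including x_g = 0.
#' @param trendline optional [vib_trendline()]; omitted means F_vib = 0.
#' @param T temperature in K (> 0), default 300.
#' @return data.frame of class `free_energy_curve` with columns `x_g`,
#'   `E_latt`, `F_vib`, `S_mix` (J/mol/K), `G` (kJ/mol), sorted by `x_g`;
#'   temperature stored as attribute `T`.
#' @export
free_energy_curve <- function(lattice, trendline = NULL, T = 300) {
  if (!is.numeric(T) || T <= 0)
    stop("free_energy_curve: temperature must be > 0", call. = FALSE)
  if (!all(c("x_g", "E_latt") %in% names(lattice)))
    stop("free_energy_curve: lattice needs columns x_g and E_latt", call. = FALSE)
  if (nrow(lattice) < 2 || min(lattice$x_g) > 1e-12)
    stop("free_energy_curve: need >= 2 compositions including x_g = 0",
         call. = FALSE)
  lattice <- lattice[order(lattice$x_g), , drop = FALSE]
  F_vib <- if (is.null(trendline)) rep(0, nrow(lattice)) else
    predict(trendline, lattice$x_g)
  S_mix <- mixing_entropy(lattice$x_g)
  out <- data.frame(x_g = lattice$x_g, E_latt = lattice$E_latt,
                    F_vib = F_vib, S_mix = S_mix,
                    G = lattice$E_latt + F_vib - T * S_mix / 1000)
  class(out) <- c("free_energy_curve", "data.frame")
  attr(out, "T") <- T
  out
}

#' Physical-mixture reference line
#'
#' Linear interpolation between the free energies of the pure host and pure
#' guest solids: the thermodynamic reference a solid solution competes with.
#'
#' @param G_host,G_guest per-molecule free energies of the pure phases
#'   (kJ/mol).
#' @return object of class `mixture_line`.
#' @export
mixture_line <- function(G_host, G_guest) {
  structure(list(G_host = G_host, G_guest = G_guest), class = "mixture_line")
}

#' @rdname mixture_line
#' @param line a `mixture_line`.
#' @param x_g guest fraction(s) in [0, 1].
#' @return energy per molecule at `x_g` (kJ/mol).
#' @export
physical_mixture <- function(line, x_g) {
  if (any(x_g < 0 | x_g > 1)) stop("physical_mixture: x_g outside [0, 1]",
                                   call. = FALSE)
  (1 - x_g) * line$G_host + x_g * line$G_guest
}

#' Classify solid-solution stability against the physical mixture
#'
#' Per composition: `stable` when the solid-solution free energy does not
#' exceed the mixture line, `metastable_accessible` when it exceeds it by at
#' most `threshold` (default 2RT, approximately 4.99 kJ/mol at 300 K),
#' `inaccessible` beyond that. If `polymorph_gap` is supplied (the free
#' energy difference between the two host polymorphs, kJ/mol), the verdict
#' also reports whether the margin drops below that gap.
#'
#' @param curve a [free_energy_curve()].
#' @param line a [mixture_line()].
#' @param threshold accessibility bound in kJ/mol; default `2 * R * T` with
#'   the curve's temperature.
#' @param polymorph_gap optional polymorph free-energy gap (kJ/mol).
#' @return data.frame of class `stability_verdicts` with columns `x_g`,
#'   `margin` (kJ/mol), `class`, and `below_gap` when `polymorph_gap` given.
#' @export
classify_stability <- function(curve, line, threshold = NULL,
                               polymorph_gap = NULL) {
  if (!inherits(curve, "free_energy_curve"))
    stop("classify_stability: need a free_energy_curve", call. = FALSE)
  T <- attr(curve, "T")
  if (is.null(threshold)) threshold <- 2 * .R_KJ * T
  margin <- curve$G - physical_mixture(line, curve$x_g)
  cls <- ifelse(margin <= 0, "stable",
                ifelse(margin <= threshold, "metastable_accessible",
                       "inaccessible"))
  out <- data.frame(x_g = curve$x_g, margin = margin, class = cls)
  if (!is.null(polymorph_gap)) out$below_gap <- margin < polymorph_gap
  class(out) <- c("stability_verdicts", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "T") <- T
  out
}

#' Plot a free-energy curve against its mixture line
#'
#' @param x a [free_energy_curve()].
#' @param line optional [mixture_line()] drawn dashed.
#' @param ... passed to [plot()].
#' @export
plot.free_energy_curve <- function(x, line = NULL, ...) {
  plot(x$x_g, x$G, type = "b", pch = 16,
       xlab = "guest fraction x_g", ylab = "G per molecule (kJ/mol)", ...)
  if (!is.null(line))
    graphics::lines(c(0, 1), c(line$G_host, line$G_guest), lty = 2)
  invisible(x)
}
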