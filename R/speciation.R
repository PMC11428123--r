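#' Uncharged fraction of a (de)protonatable species
#'
#' Henderson-Hasselbalch speciation for a molecule with an acidic
#' deprotonation (pKa_acid) and optionally a basic protonation (pKa_base):
#' f_neutral = 1 / (1 + 10^(pH - pKa_acid) + 10^(pKa_base - pH)),
#' omitting absent terms. Only uncharged molecules are considered available
#' for incorporation into the neutral crystal.
#'
#' @param pH solution pH, in (0, 14).
#' @param pKa_acid acid dissociation constant of the neutral species
#'   (deprotonation); `NULL` if not applicable.
#' @param pKa_base pKa of the conjugate acid (protonation of the neutral
#'   species); `NULL` if not applicable. Must be below `pKa_acid` when both
#'   are given.
#' @return neutral fraction in [0, 1].
#' @examples
#' neutral_fraction(9, pKa_acid = 8.94)  # hypoxanthine at pH 9: ~0.47
#' neutral_fraction(9, pKa_acid = 7.44)  # xanthine at pH 9: ~0.03
#' @export
neutral_fraction <- function(pH, pKa_acid = NULL, pKa_base = NULL) {
  if (!is.numeric(pH) || pH <= 0 || pH >= 14)
    stop("neutral_fraction: pH must lie in (0, 14)", call. = FALSE)
  if (is.null(pKa_acid) && is.null(pKa_base))
    stop("neutral_fraction: at least one pKa is required", call. = FALSE)
  if (!is.null(pKa_acid) && !is.null(pKa_base) && pKa_base >= pKa_acid)
    stop("neutral_fraction: pKa_base must be below pKa_acid", call. = FALSE)
  denom <- 1
  if (!is.null(pKa_acid)) denom <- denom + 10^(pH - pKa_acid)
  if (!is.null(pKa_base)) denom <- denom + 10^(pKa_base - pH)
  1 / denom
}

#' Boltzmann tautomer populations
#'
#' w_i = exp(-dE_i / RT) / sum_j exp(-dE_j / RT) from relative tautomer
#' energies. Invariant to adding a constant to all energies.
#'
#' @param dE named numeric vector of relative tautomer energies (kJ/mol; the
#'   reference tautomer has 0).
#' @param T temperature in K (> 0).
#' @return named weights summing to 1.
#' @export
tautomer_weights <- function(dE, T = 300) {
  if (!is.numeric(T) || T <= 0)
    stop("tautomer_weights: temperature must be > 0", call. = FALSE)
  if (!length(dE)) stop("tautomer_weights: need >= 1 tautomer", call. = FALSE)
  e <- exp(-(dE - min(dE)) / (.R_KJ * T))
  e / sum(e)
}

#' Speciation profile of a crystallizing additive
#'
#' Combines the neutral fraction at the given pH with the Boltzmann weight
#' of the crystal-compatible tautomer into the effective fraction of
#' molecules available to incorporate into the host lattice.
#'
#' @param species a species entry as returned by
#'   [default_speciation_config()]: list with `label`, `pKa_acid`,
#'   `pKa_base`, and `tautomers` (data.frame with `label`, `dE`,
#'   `compatible`).
#' @param pH solution pH.
#' @param T temperature in K.
#' @return object of class `speciation_profile`: list with `label`,
#'   `neutral_fraction`, `tautomer_weights`, `effective_fraction`.
#' @export
speciation_profile <- function(species, pH = 9, T = 300) {
  nf <- neutral_fraction(pH, species$pKa_acid, species$pKa_base)
  tw <- tautomer_weights(stats::setNames(species$tautomers$dE,
                                         species$tautomers$label), T)
  wcomp <- sum(tw[species$tautomers$compatible])
  structure(list(label = species$label, neutral_fraction = nf,
                 tautomer_weights = tw,
                 effective_fraction = nf * wcomp),
            class = "speciation_profile")
}

#' @export
print.speciation_profile <- function(x, ...) {
  cat(sprintf("<speciation_profile> %s: neutral %.3f, compatible-tautomer %.3g, effective %.3g\n",
              x$label, x$neutral_fraction,
              x$effective_fraction / max(x$neutral_fraction, 1e-300),
              x$effective_fraction))
  invisible(x)
}

#' Literature speciation configuration for the three purines
#'
#' pKa values are configuration, not constants: guanine 9.4 (acid) / 3.3
#' (base), hypoxanthine 8.94, xanthine 7.44 (common literature values).
#' Tautomer energies are qualitative placeholders ordered to reflect that
#' the guanine-compatible keto-N7H tautomer of hypoxanthine is the abundant
#' one while the compatible keto-enol-N7H tautomer of xanthine is a scarce,
#' high-energy form; they are not computed values.
#'
#' @return named list of species entries for [speciation_profile()].
#' @export
default_speciation_config <- function() {
  list(
    guanine = list(label = "guanine", pKa_acid = 9.4, pKa_base = 3.3,
                   tautomers = data.frame(
                     label = c("keto-N9H", "keto-N7H"),
                     dE = c(0, 2),
                     compatible = c(TRUE, TRUE))),
    hypoxanthine = list(label = "hypoxanthine", pKa_acid = 8.94,
                        pKa_base = NULL,
                        tautomers = data.frame(
                          label = c("keto-N7H", "keto-N9H"),
                          dE = c(0, 3),
                          compatible = c(TRUE, FALSE))),
    xanthine = list(label = "xanthine", pKa_acid = 7.44, pKa_base = NULL,
                    tautomers = data.frame(
                      label = c("diketo-N7H", "keto-enol-N7H"),
                      dE = c(0, 28),
                      compatible = c(FALSE, TRUE)))
  )
}
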