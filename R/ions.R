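#' Ion species (a dissociable salt of one cation and one counter-anion)
#'
#' Describes the salt in which a cation is dosed into an assay: the cation,
#' its charge, the counter-anion, and the stoichiometry of the formula unit.
#' The formula must be electroneutral, i.e.
#' `cation_per_formula * cation_charge + anion_per_formula * anion_charge = 0`.
#'
#' By default the counter-anion is chloride and the stoichiometry is filled
#' in automatically (`MCl` for monovalent cations, `MCl2` for divalent,
#' `MCl3` for trivalent), matching the common practice of dosing cations as
#' chloride salts; a different anion or stoichiometry can be given
#' explicitly.
#'
#' @param name Cation name, e.g. `"Na"`, `"Ca"`, `"Al"`.
#' @param cation_charge Integer charge of the cation (+1 to +3).
#' @param counter_anion Anion name, default `"Cl"`.
#' @param anion_charge Integer charge of the anion (-1 or -2).
#' @param cation_per_formula Cations per formula unit (default 1).
#' @param anion_per_formula Anions per formula unit. If `NULL`, the smallest
#'   integer satisfying electroneutrality is used (an error is raised if no
#'   integer solution exists for `cation_per_formula` cations).
#' @return An object of class `"ion_species"`.
#' @examples
#' ion_species("Ca", 2)                   # CaCl2
#' ion_species("Al", 3)                   # AlCl3
#' ion_species("Mg", 2, "SO4", -2)        # MgSO4
#' @export
ion_species <- function(name, cation_charge, counter_anion = "Cl",
                        anion_charge = -1L, cation_per_formula = 1L,
                        anion_per_formula = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is_count(cation_charge) || cation_charge < 1 || cation_charge > 3)
    stop("'cation_charge' must be an integer in +1..+3", call. = FALSE)
  if (!is_number(anion_charge) || anion_charge >= 0 || anion_charge < -2 ||
      anion_charge != round(anion_charge))
    stop("'anion_charge' must be an integer in -1..-2", call. = FALSE)
  if (!is_count(cation_per_formula))
    stop("'cation_per_formula' must be a positive integer", call. = FALSE)
  if (is.null(anion_per_formula)) {
    n <- cation_per_formula * cation_charge / abs(anion_charge)
    if (n != round(n))
      stop("no integer anion stoichiometry balances ", cation_per_formula,
           " x charge +", cation_charge, " against charge ", anion_charge,
           call. = FALSE)
    anion_per_formula <- as.integer(n)
  }
  if (!is_count(anion_per_formula))
    stop("'anion_per_formula' must be a positive integer", call. = FALSE)
  net <- cation_per_formula * cation_charge + anion_per_formula * anion_charge
  if (net != 0)
    stop("formula is not electroneutral (net charge ", net, ")", call. = FALSE)
  structure(
    list(name = name,
         cation_charge = as.integer(cation_charge),
         counter_anion = counter_anion,
         anion_charge = as.integer(anion_charge),
         cation_per_formula = as.integer(cation_per_formula),
         anion_per_formula = as.integer(anion_per_formula)),
    class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s (%s%+d, dosed as %s)\n",
              x$name, x$name, x$cation_charge, salt_formula(x)))
  invisible(x)
}

#' Salt formula string of an ion species
#'
#' @param x An [ion_species()].
#' @return A string such as `"CaCl2"`.
#' @export
salt_formula <- function(x) {
  stopifnot(inherits(x, "ion_species"))
  sub_n <- function(n) if (n > 1L) n else ""
  paste0(x$name, sub_n(x$cation_per_formula),
         x$counter_anion, sub_n(x$anion_per_formula))
}

#' Default charges of common inorganic ions
#'
#' A named integer vector mapping ion names to their charges, used to
#' resolve bare cation names into chloride [ion_species()] and to attach
#' charges to environment profiles.
#'
#' @return Named integer vector of charges.
#' @export
default_ion_charges <- function() {
  c(Na = 1L, K = 1L, Li = 1L, Rb = 1L, Cs = 1L, NH4 = 1L, H = 1L,
    Ca = 2L, Mg = 2L, Sr = 2L, Ba = 2L, Be = 2L, Mn = 2L, Fe2 = 2L,
    Zn = 2L, Ni = 2L, Co = 2L, Cu = 2L, Cd = 2L,
    Al = 3L, Fe3 = 3L, Cr = 3L, La = 3L,
    Cl = -1L, Br = -1L, F = -1L, I = -1L, NO3 = -1L, HCO3 = -1L,
    SO4 = -2L, CO3 = -2L, HPO4 = -2L, SiO3 = -2L)
}

#' Resolve ion names or species into a panel of ion_species
#'
#' Character names are resolved to chloride salts via
#' [default_ion_charges()]; `ion_species` objects pass through.
#'
#' @param panel Character vector of cation names, or a list of
#'   [ion_species()] objects (mixing the two is allowed in a list).
#' @return A named list of `ion_species`.
#' @export
as_ion_panel <- function(panel) {
  if (inherits(panel, "ion_species")) panel <- list(panel)
  if (is.character(panel)) panel <- as.list(panel)
  stopifnot(is.list(panel), length(panel) >= 1L)
  charges <- default_ion_charges()
  out <- lapply(panel, function(p) {
    if (inherits(p, "ion_species")) return(p)
    if (is.character(p) && length(p) == 1L) {
      if (!p %in% names(charges) || charges[[p]] < 0)
        stop("unknown cation '", p, "'; supply an ion_species()", call. = FALSE)
      return(ion_species(p, charges[[p]]))
    }
    stop("panel entries must be cation names or ion_species objects",
         call. = FALSE)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(names(out)))
    stop("duplicate cation names in panel", call. = FALSE)
  out
}

#' A compact panel of environmentally relevant cations
#'
#' The alkali metals, alkaline earth metals and Al3+ whose effects on phage
#' infection are of most interest in natural waters, dosed as chloride
#' salts.
#'
#' @return Named list of [ion_species()].
#' @export
default_ion_panel <- function() {
  as_ion_panel(c("Na", "K", "Li", "Rb", "Cs",
                 "Ca", "Mg", "Sr", "Ba", "Be", "Al"))
}

#' A synthetic panel of arbitrary size for simulation studies
#'
#' Generates `n` pseudo-cations named `ion001`, `ion002`, ... with charges
#' cycling through +1, +2, +3, each dosed as a chloride salt. Used to
#' emulate large dosing arrays (e.g. an 80-ion screen) in tests and power
#' analyses without asserting real chemistry.
#'
#' @param n Number of species (>= 1).
#' @return Named list of [ion_species()].
#' @export
synthetic_ion_panel <- function(n) {
  stopifnot(is_count(n))
  charges <- rep_len(1:3, n)
  out <- lapply(seq_len(n), function(i)
    ion_species(sprintf("ion%03d", i), charges[i]))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
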