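#' Ion concentration profile of an environment or solution
#'
#' A named set of dissolved-ion concentrations (mM) with their charges,
#' representing e.g. a freshwater, seawater, gut fluid or the bacterial
#' cytoplasm. Profiles are the common currency of the ionic-strength,
#' environment-comparison and hot-spot modules.
#'
#' @param name Profile name.
#' @param category One of `"freshwater"`, `"gut"`, `"seawater"`,
#'   `"cytoplasm"`, or `"solution"` (for lab solutions and salt
#'   contributions).
#' @param concentrations Named numeric vector, mM, all >= 0.
#' @param charges Named integer vector of charges for (at least) every ion
#'   in `concentrations`. Defaults to [default_ion_charges()] lookups; an
#'   error is raised for ions with no known charge.
#' @return An object of class `"ion_profile"`.
#' @examples
#' sw <- ion_profile("seawater", "seawater",
#'                   c(Na = 470, Mg = 53, Ca = 10, K = 10, Cl = 550, SO4 = 28))
#' ionic_strength(sw)
#' @export
ion_profile <- function(name, category = "solution", concentrations,
                        charges = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  category <- match.arg(category,
                        c("freshwater", "gut", "seawater", "cytoplasm",
                          "solution"))
  if (!is.numeric(concentrations) || is.null(names(concentrations)) ||
      any(!nzchar(names(concentrations))))
    stop("'concentrations' must be a named numeric vector (mM)", call. = FALSE)
  if (any(!is.finite(concentrations)) || any(concentrations < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  ions <- names(concentrations)
  if (is.null(charges)) charges <- default_ion_charges()
  missing <- setdiff(ions, names(charges))
  if (length(missing))
    stop("no charge known for ion(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  z <- charges[ions]
  if (any(z == 0) || any(z != round(z)))
    stop("charges must be nonzero integers", call. = FALSE)
  structure(
    list(name = name, category = category,
         concentrations = concentrations,
         charges = stats::setNames(as.integer(z), ions)),
    class = "ion_profile")
}

#' @export
print.ion_profile <- function(x, ...) {
  cat(sprintf("<ion_profile> %s [%s], I = %.4g mM\n",
              x$name, x$category, ionic_strength(x)))
  df <- data.frame(ion = names(x$concentrations),
                   charge = x$charges,
                   conc_mM = unname(x$concentrations))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Ionic strength of a profile
#'
#' Computes the concentration-based ionic strength
#' `I = 1/2 * sum(c_i * z_i^2)` over all ions `i`, in mM. No activity
#' corrections are applied.
#'
#' @param x An [ion_profile()] (or anything with a method).
#' @param ... Passed to methods.
#' @return Ionic strength in mM.
#' @export
ionic_strength <- function(x, ...) UseMethod("ionic_strength")

#' @rdname ionic_strength
#' @export
ionic_strength.ion_profile <- function(x, ...) {
  sum(x$concentrations * as.numeric(x$charges)^2) / 2
}

#' Combine or scale profiles
#'
#' `profile_union()` adds the concentrations of two profiles ion-by-ion
#' (charges must agree for shared ions); `profile_scale()` multiplies all
#' concentrations by a nonnegative factor. Ionic strength is additive under
#' the union and homogeneous of degree one under scaling.
#'
#' @param a,b [ion_profile()] objects.
#' @param name Name for the combined profile.
#' @return An [ion_profile()].
#' @export
profile_union <- function(a, b, name = paste(a$name, "+", b$name)) {
  stopifnot(inherits(a, "ion_profile"), inherits(b, "ion_profile"))
  shared <- intersect(names(a$concentrations), names(b$concentrations))
  if (any(a$charges[shared] != b$charges[shared]))
    stop("conflicting charges for shared ions", call. = FALSE)
  ions <- union(names(a$concentrations), names(b$concentrations))
  conc <- stats::setNames(numeric(length(ions)), ions)
  conc[names(a$concentrations)] <- a$concentrations
  conc[names(b$concentrations)] <- conc[names(b$concentrations)] +
    b$concentrations
  charges <- c(a$charges, b$charges[setdiff(names(b$charges), names(a$charges))])
  ion_profile(name, a$category, conc[ions], charges)
}

#' @rdname profile_union
#' @param x An [ion_profile()].
#' @param k Nonnegative scale factor.
#' @export
profile_scale <- function(x, k) {
  stopifnot(inherits(x, "ion_profile"), is_number(k), k >= 0)
  ion_profile(x$name, x$category, x$concentrations * k, x$charges)
}

#' Dissociate a dosed salt into an ion profile
#'
#' Expands an [ion_species()] at a given salt concentration into the
#' profile of its free ions: the cation at
#' `conc * cation_per_formula` mM and the anion at
#' `conc * anion_per_formula` mM (complete dissociation).
#'
#' @param salt An [ion_species()].
#' @param conc Salt concentration in mM, >= 0.
#' @return An [ion_profile()] with the two ions.
#' @examples
#' salt_to_profile(ion_species("Ca", 2), 1)  # Ca 1 mM, Cl 2 mM
#' @export
salt_to_profile <- function(salt, conc) {
  stopifnot(inherits(salt, "ion_species"))
  if (!is_number(conc) || conc < 0)
    stop("'conc' must be a single nonnegative number (mM)", call. = FALSE)
  conc_vec <- c(conc * salt$cation_per_formula, conc * salt$anion_per_formula)
  names(conc_vec) <- c(salt$name, salt$counter_anion)
  charges <- c(salt$cation_charge, salt$anion_charge)
  names(charges) <- names(conc_vec)
  # a salt of the form MX where cation name equals anion name is impossible,
  # so names are distinct
  ion_profile(paste0(salt_formula(salt), "@", format(conc), "mM"),
              "solution", conc_vec, charges)
}

#' Bundled ion profiles of reference environments
#'
#' Returns the package's built-in compartment profiles used for
#' threshold-vs-environment comparison:
#'
#' * `bacterial_cytoplasm` — Na+ 212 mM, K+ 38 mM, Ca2+ 0.5 mM, Mg2+ 1 mM
#'   (typical cytoplasmic concentrations of an enteric bacterium).
#' * `global_mean_freshwater` — Ca2+ 0.1 mM (global mean river/lake value);
#'   Na+, K+ and Mg2+ are set to representative world-average river
#'   concentrations.
#' * `sierra_springwater` — an illustrative very dilute granitic
#'   mountain-spring water (synthetic composition; see
#'   [springwater_scenario()]).
#' * `human_gut` — an illustrative small-intestinal lumen profile with
#'   Na+ ~140 mM.
#' * `seawater` — standard mean ocean water major ions.
#'
#' Only the cytoplasm values and the freshwater Ca2+ mean are literature
#' constants; the remaining compositions are representative values chosen
#' to place each compartment in its documented concentration regime.
#'
#' @return Named list of [ion_profile()] objects.
#' @export
environment_profiles <- function() {
  list(
    bacterial_cytoplasm = ion_profile(
      "bacterial_cytoplasm", "cytoplasm",
      c(Na = 212, K = 38, Ca = 0.5, Mg = 1)),
    global_mean_freshwater = ion_profile(
      "global_mean_freshwater", "freshwater",
      c(Na = 0.27, K = 0.059, Ca = 0.1, Mg = 0.17)),
    sierra_springwater = ion_profile(
      "sierra_springwater", "freshwater",
      c(Na = 0.13, K = 0.03, Ca = 0.05, Mg = 0.02)),
    human_gut = ion_profile(
      "human_gut", "gut",
      c(Na = 140, K = 15, Ca = 5, Mg = 5)),
    seawater = ion_profile(
      "seawater", "seawater",
      c(Na = 470, Mg = 53, Ca = 10, K = 10, Cl = 550, SO4 = 28))
  )
}
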