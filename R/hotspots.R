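#' Lysed-cell ion dilution model
#'
#' When a phage lyses a bacterial cell, its cytoplasmic ions are released
#' and dilute into the surrounding water. Approximating the cell as a
#' sphere of radius `r0` whose contents spread evenly through a sphere of
#' radius `r >= r0`, the concentration of each ion falls with the cube of
#' the radius ratio:
#' \deqn{C(r) = C_{cyto} (r_0 / r)^3}
#' This is the instantaneous even-dilution picture (total ion mass is
#' conserved), not a steady-state diffusion profile.
#'
#' @param cytoplasm [ion_profile()] of the cytoplasm; must contain Na, K,
#'   Ca and Mg. Default: the bundled bacterial cytoplasm profile.
#' @param r0 Cell radius in micron, > 0 (default 1).
#' @return An object of class `"lysis_model"`.
#' @export
lysis_model <- function(cytoplasm = environment_profiles()$bacterial_cytoplasm,
                        r0 = 1) {
  stopifnot(inherits(cytoplasm, "ion_profile"))
  if (!is_number(r0) || r0 <= 0)
    stop("'r0' must be > 0 (micron)", call. = FALSE)
  need <- c("Na", "K", "Ca", "Mg")
  missing <- setdiff(need, names(cytoplasm$concentrations))
  if (length(missing))
    stop("cytoplasm profile lacks ion(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(list(cytoplasm = cytoplasm, r0 = r0), class = "lysis_model")
}

#' @export
print.lysis_model <- function(x, ...) {
  cat(sprintf("<lysis_model> r0 = %g um, cytoplasm '%s' (I = %.4g mM)\n",
              x$r0, x$cytoplasm$name, ionic_strength(x$cytoplasm)))
  invisible(x)
}

.lysis_cyto <- function(model, ion) {
  conc <- model$cytoplasm$concentrations
  if (!ion %in% names(conc))
    stop("ion '", ion, "' absent from cytoplasm profile", call. = FALSE)
  conc[[ion]]
}

#' Ion concentration at distance r from a lysed cell
#'
#' @param model A [lysis_model()].
#' @param ion Ion name present in the cytoplasm profile.
#' @param r Radius (micron), vectorized, all >= `r0`.
#' @return Concentration(s) in mM.
#' @examples
#' m <- lysis_model()
#' lysis_concentration(m, "Na", c(1, 2, 5))
#' @export
lysis_concentration <- function(model, ion, r) {
  stopifnot(inherits(model, "lysis_model"))
  if (!is.numeric(r) || any(!is.finite(r)))
    stop("'r' must be finite numeric", call. = FALSE)
  if (any(r < model$r0))
    stop("out of domain: r must be >= r0 = ", model$r0, " um", call. = FALSE)
  .lysis_cyto(model, ion) * (model$r0 / r)^3
}

#' Distance at which a lysed cell's ion cloud falls below a threshold
#'
#' Returns the smallest radius `r >= r0` with `C(r) <= threshold`. When the
#' cytoplasmic concentration already lies at or below the threshold this is
#' `r0` itself; otherwise the closed form
#' `r = r0 * (C_cyto / threshold)^(1/3)`.
#'
#' @param model A [lysis_model()].
#' @param ion Ion name.
#' @param threshold Concentration threshold in mM, > 0 (e.g. a phage EC50).
#' @return Radius in micron.
#' @examples
#' lysis_crossing_distance(lysis_model(), "Na", 100)  # ~1.28 um
#' @export
lysis_crossing_distance <- function(model, ion, threshold) {
  stopifnot(inherits(model, "lysis_model"))
  if (!is.numeric(threshold) || any(!is.finite(threshold)) ||
      any(threshold <= 0))
    stop("'threshold' must be > 0", call. = FALSE)
  c_cyto <- .lysis_cyto(model, ion)
  model$r0 * pmax(1, (c_cyto / threshold))^(1 / 3)
}

#' Evaporative-concentration scenario for a dilute water
#'
#' During evaporation (e.g. drying soil porewater), conservative solutes
#' such as Na+ and K+ scale linearly with the concentration factor
#' `cf = V_initial / V_remaining`, while Ca2+ and Mg2+ are capped by the
#' solubility of carbonate and silicate phases. Ceilings are modeled as
#' fixed per-ion concentration caps rather than full mineral equilibria.
#'
#' @param initial [ion_profile()] of the un-evaporated water.
#' @param cf_max Largest concentration factor of the scenario grid, >= 1.
#' @param n_grid Number of (log-spaced) grid points from 1 to `cf_max`.
#' @param ceilings Named vector of solubility ceilings in mM (> 0); ions
#'   not named here are conservative (no ceiling).
#' @return An object of class `"evaporation_scenario"` with fields
#'   `initial`, `cf_grid`, `ceilings`, `conservative_ions`.
#' @export
evaporation_scenario <- function(initial, cf_max = 1000, n_grid = 200,
                                 ceilings = c(Ca = 0.5, Mg = 1)) {
  stopifnot(inherits(initial, "ion_profile"))
  if (!is_number(cf_max) || cf_max < 1)
    stop("invalid configuration: 'cf_max' must be >= 1", call. = FALSE)
  if (!is_count(n_grid, 2L))
    stop("'n_grid' must be an integer >= 2", call. = FALSE)
  if (length(ceilings) && (is.null(names(ceilings)) || any(ceilings <= 0)))
    stop("'ceilings' must be a named vector of positive mM values",
         call. = FALSE)
  ions <- names(initial$concentrations)
  structure(
    list(initial = initial,
         cf_grid = 10^seq(0, log10(cf_max), length.out = n_grid),
         ceilings = ceilings,
         conservative_ions = setdiff(ions, names(ceilings))),
    class = "evaporation_scenario")
}

#' @export
print.evaporation_scenario <- function(x, ...) {
  cat(sprintf("<evaporation_scenario> '%s', cf 1..%g (%d grid points)\n",
              x$initial$name, max(x$cf_grid), length(x$cf_grid)))
  cat("  conservative:", paste(x$conservative_ions, collapse = ", "), "\n")
  if (length(x$ceilings))
    cat("  ceilings (mM):",
        paste(sprintf("%s = %g", names(x$ceilings), x$ceilings),
              collapse = ", "), "\n")
  invisible(x)
}

#' Construct a dilute mountain-springwater evaporation scenario
#'
#' Convenience wrapper building an [evaporation_scenario()] from the four
#' major cations of a very dilute granitic springwater. The default
#' composition is illustrative (dilute Sierra-type spring water is in the
#' 0.1-0.3 mM Na+ class); all four initial concentrations are exposed and
#' should be set to measured values when available.
#'
#' @param na0,k0,ca0,mg0 Initial concentrations in mM, all > 0.
#' @param ceilings Solubility ceilings, default `c(Ca = 0.5, Mg = 1)` mM
#'   (illustrative carbonate/silicate caps); Na and K are conservative.
#' @param cf_max,n_grid Concentration-factor grid, see
#'   [evaporation_scenario()].
#' @return An `"evaporation_scenario"`.
#' @examples
#' sc <- springwater_scenario(na0 = 0.1)
#' evaporation_crossing_factor(sc, "Na", 100)  # 1000-fold
#' @export
springwater_scenario <- function(na0 = 0.13, k0 = 0.03, ca0 = 0.05,
                                 mg0 = 0.02, ceilings = c(Ca = 0.5, Mg = 1),
                                 cf_max = 1000, n_grid = 200) {
  vals <- c(Na = na0, K = k0, Ca = ca0, Mg = mg0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid configuration: initial concentrations must be > 0",
         call. = FALSE)
  evaporation_scenario(
    ion_profile("springwater", "freshwater", vals),
    cf_max = cf_max, n_grid = n_grid, ceilings = ceilings)
}

#' Evaporate a scenario to a given concentration factor
#'
#' Conservative ions scale as `c0 * cf`; ceiling-limited ions as
#' `min(c0 * cf, ceiling)`.
#'
#' @param scenario An [evaporation_scenario()].
#' @param cf Concentration factor, >= 1.
#' @return The evaporated [ion_profile()].
#' @export
evaporate <- function(scenario, cf) {
  stopifnot(inherits(scenario, "evaporation_scenario"))
  if (!is_number(cf) || cf < 1)
    stop("out of domain: 'cf' must be >= 1", call. = FALSE)
  conc <- scenario$initial$concentrations * cf
  capped <- intersect(names(conc), names(scenario$ceilings))
  conc[capped] <- pmin(conc[capped], scenario$ceilings[capped])
  ion_profile(sprintf("%s@cf=%g", scenario$initial$name, cf),
              scenario$initial$category, conc, scenario$initial$charges)
}

#' Concentration curves over the scenario's factor grid
#'
#' @param scenario An [evaporation_scenario()].
#' @return Data frame with column `cf` and one concentration column (mM)
#'   per ion.
#' @export
evaporation_curve <- function(scenario) {
  stopifnot(inherits(scenario, "evaporation_scenario"))
  ions <- names(scenario$initial$concentrations)
  out <- data.frame(cf = scenario$cf_grid)
  for (io in ions) {
    v <- scenario$initial$concentrations[[io]] * scenario$cf_grid
    if (io %in% names(scenario$ceilings))
      v <- pmin(v, scenario$ceilings[[io]])
    out[[io]] <- v
  }
  out
}

#' Concentration factor at which an ion reaches a threshold
#'
#' Smallest `cf` with evaporated concentration at or above `threshold`:
#' 1 when the initial water already meets it, `threshold / c0` for a
#' conservative ion, and `NA` when the ion's solubility ceiling lies below
#' the threshold (the ion can never reach it, however far evaporation
#' proceeds).
#'
#' @param scenario An [evaporation_scenario()].
#' @param ion Ion name in the initial profile.
#' @param threshold Concentration threshold in mM, > 0.
#' @return Concentration factor (>= 1), or `NA` if unreachable. The value
#'   is the exact closed form and may exceed the scenario's `cf_max` grid.
#' @export
evaporation_crossing_factor <- function(scenario, ion, threshold) {
  stopifnot(inherits(scenario, "evaporation_scenario"))
  if (!is_number(threshold) || threshold <= 0)
    stop("'threshold' must be > 0", call. = FALSE)
  conc <- scenario$initial$concentrations
  if (!ion %in% names(conc))
    stop("ion '", ion, "' absent from scenario", call. = FALSE)
  c0 <- conc[[ion]]
  if (c0 >= threshold) return(1)
  ceiling_i <- if (ion %in% names(scenario$ceilings))
    scenario$ceilings[[ion]] else Inf
  if (ceiling_i < threshold) return(NA_real_)
  threshold / c0
}
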