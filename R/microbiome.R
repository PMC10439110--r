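#' Community-weighted DNRA genetic potential
#'
#' The fraction of a sample's community capable of dissimilatory nitrate
#' reduction to ammonium: the summed relative abundance of taxa carrying
#' both the nitrate-to-nitrite and the nitrite-to-ammonium capability.
#'
#' @param abundances Named numeric vector of relative abundances (one
#'   sample), or a taxa x samples matrix with rownames.
#' @param caps Capability table: data frame with columns `taxon`,
#'   `can_nitrate_to_nitrite`, `can_nitrite_to_ammonium` (see
#'   [fn_capability_table()]). Every taxon with nonzero abundance must be
#'   present.
#' @return A fraction in `[0, 1]` (one per sample for matrix input).
#' @examples
#' dnra_potential(c(Escherichia = 0.5, Klebsiella = 0.5),
#'                fn_capability_table())
#' @export
dnra_potential <- function(abundances, caps) {
  if (is.matrix(abundances))
    return(apply(abundances, 2L, dnra_potential, caps = caps))
  if (!is.numeric(abundances) || is.null(names(abundances)))
    stop("'abundances' must be a named numeric vector", call. = FALSE)
  stopifnot(is.data.frame(caps),
            all(c("taxon", "can_nitrate_to_nitrite",
                  "can_nitrite_to_ammonium") %in% names(caps)))
  present <- names(abundances)[abundances > 0]
  missing <- setdiff(present, caps$taxon)
  if (length(missing))
    stop("capability flags missing for taxa: ",
         paste(missing, collapse = ", "), call. = FALSE)
  dnra_taxa <- caps$taxon[caps$can_nitrate_to_nitrite &
                            caps$can_nitrite_to_ammonium]
  sum(abundances[names(abundances) %in% dnra_taxa])
}

#' Phage-cocktail effect on ammonium production, per carbon source
#'
#' For each carbon source, compares ammonium in minus- vs plus-cocktail
#' samples with a two-sample Welch t-test and reports the mean difference
#' (minus minus plus: positive means the cocktail suppressed ammonium
#' production), the dominant taxon of the minus-cocktail community (argmax
#' of mean abundance, ties broken lexicographically), and, when a
#' capability table is supplied, whether that taxon is phage-targeted and
#' the mean DNRA genetic potential in each condition.
#'
#' @param community An `"fn_community"` from [simulate_community()], or a
#'   list with elements `abundances` (taxa x samples matrix) and `meta`
#'   (data frame with `sample`, `carbon_source`, `phage` coded
#'   `"minus"`/`"plus"`, `replicate`, `ammonium_mM`).
#' @param caps Optional capability table (see [fn_capability_table()]).
#' @param alpha Significance level, default 0.05.
#' @param p_adjust Multiple-testing correction across carbon sources
#'   (default `"none"`, matching per-contrast reporting; `"BH"` etc. as in
#'   [stats::p.adjust()]).
#' @return Data frame with one row per carbon source: `carbon_source`,
#'   `n_minus`, `n_plus`, `mean_minus_mM`, `mean_plus_mM`, `mean_diff_mM`,
#'   `p_value`, `significant`, `dominant_taxon`, and (with `caps`)
#'   `dominant_targeted`, `dnra_potential_minus`, `dnra_potential_plus`.
#' @export
phage_effect_by_carbon <- function(community, caps = NULL, alpha = 0.05,
                                   p_adjust = "none") {
  stopifnot(is.list(community),
            all(c("abundances", "meta") %in% names(community)))
  meta <- community$meta
  ab <- community$abundances
  need <- c("sample", "carbon_source", "phage", "ammonium_mM")
  if (!all(need %in% names(meta)))
    stop("meta lacks column(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  if (!all(meta$phage %in% c("minus", "plus")))
    stop("'phage' must be coded 'minus'/'plus'", call. = FALSE)
  out <- lapply(unique(meta$carbon_source), function(cs) {
    m <- meta[meta$carbon_source == cs, , drop = FALSE]
    a_minus <- m$ammonium_mM[m$phage == "minus"]
    a_plus <- m$ammonium_mM[m$phage == "plus"]
    if (length(a_minus) < 2L || length(a_plus) < 2L)
      stop("insufficient replication for carbon source '", cs,
           "': need >= 2 replicates per condition", call. = FALSE)
    p <- if (stats::var(a_minus) == 0 && stats::var(a_plus) == 0) {
      if (mean(a_minus) == mean(a_plus)) 1 else 0
    } else {
      stats::t.test(a_minus, a_plus)$p.value
    }
    minus_ids <- m$sample[m$phage == "minus"]
    mean_ab <- rowMeans(ab[, minus_ids, drop = FALSE])
    dom <- sort(names(mean_ab)[mean_ab == max(mean_ab)])[1L]
    row <- data.frame(
      carbon_source = cs,
      n_minus = length(a_minus), n_plus = length(a_plus),
      mean_minus_mM = mean(a_minus), mean_plus_mM = mean(a_plus),
      mean_diff_mM = mean(a_minus) - mean(a_plus),
      p_value = p,
      dominant_taxon = dom,
      stringsAsFactors = FALSE)
    if (!is.null(caps)) {
      row$dominant_targeted <-
        isTRUE(caps$phage_targeted[match(dom, caps$taxon)])
      row$dnra_potential_minus <-
        mean(dnra_potential(ab[, minus_ids, drop = FALSE], caps))
      plus_ids <- m$sample[m$phage == "plus"]
      row$dnra_potential_plus <-
        mean(dnra_potential(ab[, plus_ids, drop = FALSE], caps))
    }
    row
  })
  out <- do.call(rbind, out)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  # keep the significance flag next to the p-value
  front <- c("carbon_source", "n_minus", "n_plus", "mean_minus_mM",
             "mean_plus_mM", "mean_diff_mM", "p_value", "significant",
             "dominant_taxon")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}

#' Nitrogen assimilated into biomass from culture optical density
#'
#' Estimates biomass nitrogen from OD600 using 0.3 g/L dry weight per OD600
#' unit and 12% nitrogen by dry weight, returning both g/L and the molar
#' equivalent (molar mass of N, 14.007 g/mol).
#'
#' @param od600 Optical density at 600 nm, >= 0 (vectorized).
#' @return Data frame with columns `od600`, `nitrogen_g_per_l`,
#'   `nitrogen_mM`.
#' @examples
#' nitrogen_assimilated(1)    # 0.036 g/L, ~2.57 mM
#' @export
nitrogen_assimilated <- function(od600) {
  if (!is.numeric(od600) || any(!is.finite(od600)) || any(od600 < 0))
    stop("'od600' must be finite and >= 0", call. = FALSE)
  g_per_l <- od600 * 0.3 * 0.12
  data.frame(od600 = od600,
             nitrogen_g_per_l = g_per_l,
             nitrogen_mM = g_per_l / 14.007 * 1000)
}

#' Ion dose-response of phage-cocktail efficacy against community function
#'
#' Fits paired plus/minus-cocktail dose-response curves to a community
#' assay in which ammonium production (or growth) is measured across a
#' serial dilution of an ion (e.g. Na+ or Ca2+): a thin wrapper around
#' [analyze_plate()] with the functional readout as the response. The
#' resulting EC50 is the ion concentration the cocktail needs to suppress
#' half of the community's ammonium production.
#'
#' @param plate Plate table in the [simulate_plate()] schema with the
#'   response column populated (e.g. `ammonium_mM`).
#' @param response Response column, default `"ammonium_mM"`.
#' @param control_condition Label of the minus-cocktail series, default
#'   `"none"`.
#' @param ... Passed to [analyze_plate()] (`n_boot`, `alpha`, `seed`).
#' @return A `"plate_fits"` table; see [analyze_plate()].
#' @export
cocktail_ion_dose_response <- function(plate, response = "ammonium_mM",
                                       control_condition = "none", ...) {
  if (!response %in% names(plate))
    stop("plate table lacks response column '", response, "'", call. = FALSE)
  analyze_plate(plate, response = response,
                control_condition = control_condition, ...)
}
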