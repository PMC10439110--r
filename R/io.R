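# Readers and writers for the package's plain-text interchange formats:
# plate CSV, fits/thresholds/community TSV, profiles/capabilities/truth JSON.

#' Read and write long-format plate tables
#'
#' Plate CSV schema: `well`, `ion`, `salt_formula`, `conc_mM`, `phage`,
#' `replicate`, `od600` and optionally `ammonium_mM`; zero-concentration
#' control wells use `conc_mM = 0`. The same schema is accepted for real
#' plate-reader exports.
#'
#' @param path File path.
#' @return `read_plate()` returns the plate data frame.
#' @export
read_plate <- function(path) {
  plate <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ion", "conc_mM", "phage", "replicate")
  missing <- setdiff(need, names(plate))
  if (length(missing))
    stop("plate file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!any(c("od600", "ammonium_mM") %in% names(plate)))
    stop("plate file needs an 'od600' or 'ammonium_mM' response column",
         call. = FALSE)
  if (any(!is.finite(plate$conc_mM)) || any(plate$conc_mM < 0))
    stop("conc_mM must be finite and >= 0", call. = FALSE)
  plate
}

#' @rdname read_plate
#' @param plate Plate data frame.
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read plate ground truth as JSON
#'
#' The truth sidecar is keyed by `ion:phage` and stores the true 4PL
#' parameters plus the generator's noise level and seed.
#'
#' @param truth A [plate_truth()].
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "plate_truth"))
  recs <- lapply(seq_len(nrow(truth)), function(i)
    list(ion = truth$ion[i], phage = truth$phage[i],
         true_ec50 = truth$true_ec50[i], true_hill = truth$true_hill[i],
         true_top = truth$true_top[i], true_bottom = truth$true_bottom[i]))
  names(recs) <- paste(truth$ion, truth$phage, sep = ":")
  jsonlite::write_json(
    list(noise_sd = attr(truth, "noise_sd"), seed = attr(truth, "seed"),
         curves = recs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- x$curves
  df <- do.call(rbind, lapply(curves, function(r)
    data.frame(ion = r$ion, phage = r$phage,
               true_ec50 = as.numeric(r$true_ec50),
               true_hill = as.numeric(r$true_hill),
               true_top = as.numeric(r$true_top),
               true_bottom = as.numeric(r$true_bottom),
               stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  attr(df, "noise_sd") <- x$noise_sd
  attr(df, "seed") <- as.integer(x$seed)
  class(df) <- c("plate_truth", class(df))
  df
}

#' Write a plate fits table as TSV
#'
#' @param fits A `"plate_fits"` table from [analyze_plate()].
#' @param path File path.
#' @export
write_fits <- function(fits, path) {
  utils::write.table(as.data.frame(fits), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a thresholds table
#'
#' TSV with columns `phage`, `ion`, `threshold_mM` and optionally `source`
#' (`"fitted"` or `"literature"`).
#'
#' @param path File path.
#' @return Data frame of thresholds.
#' @export
read_thresholds <- function(path) {
  thr <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phage", "ion", "threshold_mM")
  missing <- setdiff(need, names(thr))
  if (length(missing))
    stop("thresholds file lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  thr
}

#' Write and read community abundance + metadata tables
#'
#' Abundances are written as TSV with taxa as rows and samples as columns;
#' metadata as a separate TSV (`sample`, `carbon_source`, `phage`,
#' `replicate`, `ammonium_mM`, `od600`).
#'
#' @param community An `"fn_community"` (or compatible list).
#' @param abundance_path,meta_path File paths.
#' @return `read_community()` returns a list with `abundances` and `meta`
#'   usable by [phage_effect_by_carbon()].
#' @export
write_community <- function(community, abundance_path, meta_path) {
  ab <- data.frame(taxon = rownames(community$abundances),
                   community$abundances, check.names = FALSE)
  utils::write.table(ab, abundance_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(community$meta, meta_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(abundance_path, meta_path))
}

#' @rdname write_community
#' @export
read_community <- function(abundance_path, meta_path) {
  ab <- utils::read.delim(abundance_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"taxon" %in% names(ab))
    stop("abundance file lacks a 'taxon' column", call. = FALSE)
  m <- as.matrix(ab[, setdiff(names(ab), "taxon"), drop = FALSE])
  rownames(m) <- ab$taxon
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  structure(list(abundances = m, meta = meta), class = "fn_community")
}

#' Write and read capability tables
#'
#' JSON (list keyed by taxon) or TSV are both supported; the format is
#' chosen from the file extension.
#'
#' @param caps Capability data frame (see [fn_capability_table()]).
#' @param path File path ending in `.json` or `.tsv`.
#' @export
write_capabilities <- function(caps, path) {
  if (grepl("\\.json$", path)) {
    recs <- lapply(seq_len(nrow(caps)), function(i)
      as.list(caps[i, setdiff(names(caps), "taxon")]))
    names(recs) <- caps$taxon
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(caps, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_capabilities
#' @export
read_capabilities <- function(path) {
  caps <- if (grepl("\\.json$", path)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- do.call(rbind, lapply(names(x), function(tx)
      data.frame(taxon = tx, as.data.frame(x[[tx]]),
                 stringsAsFactors = FALSE)))
    df
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
  need <- c("taxon", "can_nitrate_to_nitrite", "can_nitrite_to_ammonium")
  missing <- setdiff(need, names(caps))
  if (length(missing))
    stop("capability table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  caps
}

#' Write and read ion profiles as JSON
#'
#' @param profiles A list of [ion_profile()] objects (or one).
#' @param path File path.
#' @return `read_profiles_json()` returns a named list of profiles.
#' @export
write_profiles_json <- function(profiles, path) {
  if (inherits(profiles, "ion_profile")) profiles <- list(profiles)
  recs <- lapply(profiles, function(p)
    list(name = p$name, category = p$category,
         concentrations_mM = as.list(p$concentrations),
         charges = as.list(p$charges)))
  names(recs) <- vapply(profiles, `[[`, "", "name")
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_profiles_json
#' @export
read_profiles_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(x, function(r)
    ion_profile(r$name, r$category,
                unlist(r$concentrations_mM),
                stats::setNames(as.integer(unlist(r$charges)),
                                names(r$charges))))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
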