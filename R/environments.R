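#' Classify an environment against phage ion requirements
#'
#' Compares each (phage, ion) threshold with the environment's ion
#' concentration, ion by ion. A concentration at or above the threshold is
#' `permissive` (the half-maximal requirement is met); below it is
#' `limiting`, with `fold_deficit = threshold / concentration` quantifying
#' how far short the environment falls (Inf when the ion is absent).
#'
#' @param profile An [ion_profile()].
#' @param thresholds Data frame with columns `phage`, `ion`,
#'   `threshold_mM` (> 0) and optionally `source` (`"fitted"` or
#'   `"literature"`).
#' @return Data frame with one row per (phage, ion): `environment`,
#'   `category`, `phage`, `ion`, `concentration_mM`, `threshold_mM`,
#'   `status`, `fold_deficit` (NA when permissive).
#' @examples
#' thr <- data.frame(phage = "T4", ion = c("Na", "Ca"),
#'                   threshold_mM = c(100, 2.38))
#' classify_environment(environment_profiles()$bacterial_cytoplasm, thr)
#' @export
classify_environment <- function(profile, thresholds) {
  stopifnot(inherits(profile, "ion_profile"))
  if (!is.data.frame(thresholds) || nrow(thresholds) == 0L ||
      !all(c("phage", "ion", "threshold_mM") %in% names(thresholds)))
    stop("'thresholds' must be a nonempty data frame with columns ",
         "phage, ion, threshold_mM", call. = FALSE)
  if (any(!is.finite(thresholds$threshold_mM)) ||
      any(thresholds$threshold_mM <= 0))
    stop("thresholds must be finite and > 0", call. = FALSE)
  if (length(profile$concentrations) == 0L)
    stop("empty profile", call. = FALSE)
  conc <- profile$concentrations
  ci <- ifelse(thresholds$ion %in% names(conc),
               conc[thresholds$ion], 0)
  permissive <- ci >= thresholds$threshold_mM
  data.frame(
    environment = profile$name,
    category = profile$category,
    phage = thresholds$phage,
    ion = thresholds$ion,
    concentration_mM = as.numeric(ci),
    threshold_mM = thresholds$threshold_mM,
    status = ifelse(permissive, "permissive", "limiting"),
    fold_deficit = ifelse(permissive, NA_real_,
                          thresholds$threshold_mM / as.numeric(ci)),
    stringsAsFactors = FALSE)
}

#' Summarize many environments against phage ion requirements
#'
#' Applies [classify_environment()] to each profile and aggregates: per
#' (environment, phage) whether any single ion is permissive (one
#' sufficient ion is enough for infection), and per (category, phage) the
#' fraction of environments with at least one permissive ion. Output rows
#' are ordered by category, then environment name, for reproducible
#' reports.
#'
#' @param profiles A list of [ion_profile()] objects (or a single one).
#' @param thresholds As in [classify_environment()].
#' @return A list of class `"env_summary"`: `verdicts` (all per-ion rows),
#'   `by_environment` (`environment`, `category`, `phage`,
#'   `any_permissive_ion`), `by_category` (`category`, `phage`,
#'   `n_environments`, `fraction_permissive`).
#' @export
summarize_environments <- function(profiles, thresholds) {
  if (inherits(profiles, "ion_profile")) profiles <- list(profiles)
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  verdicts <- do.call(rbind, lapply(profiles, classify_environment,
                                    thresholds = thresholds))
  ord <- order(verdicts$category, verdicts$environment, verdicts$phage,
               verdicts$ion)
  verdicts <- verdicts[ord, , drop = FALSE]
  rownames(verdicts) <- NULL
  key <- interaction(verdicts$environment, verdicts$phage, drop = TRUE)
  by_env <- do.call(rbind, lapply(split(verdicts, key), function(d) {
    data.frame(environment = d$environment[1L], category = d$category[1L],
               phage = d$phage[1L],
               any_permissive_ion = any(d$status == "permissive"),
               stringsAsFactors = FALSE)
  }))
  by_env <- by_env[order(by_env$category, by_env$environment, by_env$phage), ]
  rownames(by_env) <- NULL
  ckey <- interaction(by_env$category, by_env$phage, drop = TRUE)
  by_cat <- do.call(rbind, lapply(split(by_env, ckey), function(d) {
    data.frame(category = d$category[1L], phage = d$phage[1L],
               n_environments = nrow(d),
               fraction_permissive = mean(d$any_permissive_ion),
               stringsAsFactors = FALSE)
  }))
  by_cat <- by_cat[order(by_cat$category, by_cat$phage), ]
  rownames(by_cat) <- NULL
  structure(list(verdicts = verdicts, by_environment = by_env,
                 by_category = by_cat),
            class = "env_summary")
}

#' @export
print.env_summary <- function(x, ...) {
  cat("<env_summary>\n\nPer environment:\n")
  print(x$by_environment, row.names = FALSE)
  cat("\nPer category:\n")
  print(x$by_category, row.names = FALSE)
  invisible(x)
}
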