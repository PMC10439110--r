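#' Classify an ion's effect on phage infection from paired fits
#'
#' Compares the no-phage toxicity fit (IC50) with the plus-phage fit (EC50)
#' for the same ion and classifies the ion:
#'
#' * `enables_infection` — the ion threshold with phage is significantly
#'   below the toxicity threshold (EC50 < IC50 with disjoint intervals), or
#'   the ion is not toxic in the tested range but inhibits growth once
#'   phage is present. These are the ions whose presence allows lytic
#'   infection.
#' * `protective` — growth is inhibited at significantly *higher* ion
#'   concentration with phage than without (EC50 > IC50 with disjoint
#'   intervals, the Al3+/T4 pattern), or ion toxicity disappears entirely
#'   in the presence of phage.
#' * `toxic_only` — both curves inhibit with statistically
#'   indistinguishable thresholds: direct ion toxicity, no phage-specific
#'   effect.
#' * `no_inhibition` — neither curve shows inhibition in the tested range.
#'
#' Significance (`shifted = TRUE`) means disjoint bootstrap percentile
#' intervals of the two half-maximal concentrations; both fits must carry
#' intervals from [bootstrap_ci()] unless one of them is flat.
#'
#' @param ic_fit [fit_4pl()] of the series measured without phage.
#' @param ec_fit [fit_4pl()] of the series measured with phage.
#' @return An object of class `"threshold_call"`: a list with `ion`,
#'   `ic_fit`, `ec_fit`, `shifted` and `classification`.
#' @export
call_threshold <- function(ic_fit, ec_fit) {
  stopifnot(inherits(ic_fit, "fit4pl"), inherits(ec_fit, "fit4pl"))
  if (!is.null(ic_fit$ion) && !is.null(ec_fit$ion) &&
      !identical(ic_fit$ion, ec_fit$ion))
    stop("pairing error: fits are for different ions ('", ic_fit$ion,
         "' vs '", ec_fit$ion, "')", call. = FALSE)
  ic_flat <- ic_fit$no_inhibition
  ec_flat <- ec_fit$no_inhibition
  if (ic_flat && ec_flat) {
    shifted <- FALSE
    classification <- "no_inhibition"
  } else if (ic_flat) {
    # not toxic by itself, but inhibits once phage is present: the ion
    # enables infection (its effective threshold is far below any toxicity)
    shifted <- TRUE
    classification <- "enables_infection"
  } else if (ec_flat) {
    # toxic alone, not with phage: complete protection
    shifted <- TRUE
    classification <- "protective"
  } else {
    if (any(is.na(ic_fit$ci)) || any(is.na(ec_fit$ci)))
      stop("both fits need bootstrap intervals; run bootstrap_ci() first",
           call. = FALSE)
    disjoint <- ec_fit$ci[2L] < ic_fit$ci[1L] || ic_fit$ci[2L] < ec_fit$ci[1L]
    shifted <- disjoint
    classification <- if (!disjoint) {
      "toxic_only"
    } else if (ec_fit$half_max < ic_fit$half_max) {
      "enables_infection"
    } else {
      "protective"
    }
  }
  structure(
    list(ion = ic_fit$ion %||% ec_fit$ion,
         ic_fit = ic_fit, ec_fit = ec_fit,
         shifted = shifted, classification = classification),
    class = "threshold_call")
}

#' @export
print.threshold_call <- function(x, digits = 4, ...) {
  fmt <- function(f, what) {
    if (f$no_inhibition) sprintf("%s: no inhibition", what)
    else sprintf("%s = %s mM [%s, %s]", what,
                 format(f$half_max, digits = digits),
                 format(f$ci[1L], digits = digits),
                 format(f$ci[2L], digits = digits))
  }
  cat(sprintf("<threshold_call> %s: %s (shifted = %s)\n",
              x$ion %||% "?", x$classification, x$shifted))
  cat(" ", fmt(x$ic_fit, "IC50 (-phage)"), "\n")
  cat(" ", fmt(x$ec_fit, "EC50 (+phage)"), "\n")
  invisible(x)
}

#' Fit every (ion, phage condition) series of a plate table
#'
#' The workhorse driver for a whole dosing array: for each ion it
#' normalizes responses by the mean of that ion's no-phage, zero-ion
#' control wells, fits a 4PL curve per phage condition, attaches bootstrap
#' intervals, and classifies each phage condition against the no-phage
#' toxicity curve via [call_threshold()].
#'
#' @param plate Long-format plate data frame as produced by
#'   [simulate_plate()] or [read_plate()]: columns `ion`, `conc_mM`,
#'   `phage`, `replicate`, and the response column. `phage == control_condition`
#'   marks the no-phage series; `conc_mM == 0` rows are controls.
#' @param response Name of the response column, default `"od600"`.
#' @param n_boot,alpha Passed to [bootstrap_ci()].
#' @param seed Integer seed for the bootstrap (one stream per ion x
#'   condition, derived deterministically).
#' @param control_condition Label of the no-phage condition, default
#'   `"none"`.
#' @return A data frame of class `"plate_fits"` with one row per (ion,
#'   phage condition): `ion`, `phage`, `half_max_mM`, `ci_low`, `ci_high`,
#'   `hill`, `top`, `bottom`, `rss`, `converged`, `direction`,
#'   `no_inhibition`, `classification` and `shifted` (NA for the control
#'   condition rows). The full `fit4pl` objects and `threshold_call`s are
#'   attached as attributes `"fits"` and `"calls"`.
#' @export
analyze_plate <- function(plate, response = "od600", n_boot = 1000,
                          alpha = 0.05, seed = 1,
                          control_condition = "none") {
  need <- c("ion", "conc_mM", "phage", response)
  missing <- setdiff(need, names(plate))
  if (length(missing))
    stop("plate table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ions <- unique(plate$ion)
  fits <- list()
  calls <- list()
  rows <- list()
  k <- 0L
  for (io in ions) {
    sub <- plate[plate$ion == io, , drop = FALSE]
    ctrl_raw <- sub[[response]][sub$conc_mM == 0 &
                                  sub$phage == control_condition]
    if (!length(ctrl_raw))
      stop("no zero-concentration control wells for ion '", io,
           "' in condition '", control_condition, "'", call. = FALSE)
    cmean <- mean(ctrl_raw)
    conditions <- unique(sub$phage)
    conditions <- c(control_condition,
                    setdiff(conditions, control_condition))
    cond_fits <- list()
    for (cond in conditions) {
      ss <- sub[sub$phage == cond & sub$conc_mM > 0, , drop = FALSE]
      ctrl_norm <- normalize_responses(
        sub[[response]][sub$conc_mM == 0 & sub$phage == cond], cmean)
      fit <- fit_4pl(ss$conc_mM,
                     normalize_responses(ss[[response]], cmean),
                     controls = if (length(ctrl_norm)) ctrl_norm else NULL,
                     ion = io, phage = cond)
      if (!fit$no_inhibition) {
        k <- k + 1L
        fit <- bootstrap_ci(fit, n_boot = n_boot, alpha = alpha,
                            seed = seed + 7L * k)
      }
      cond_fits[[cond]] <- fit
    }
    for (cond in setdiff(conditions, control_condition)) {
      calls[[paste(io, cond, sep = ":")]] <-
        call_threshold(cond_fits[[control_condition]], cond_fits[[cond]])
    }
    for (cond in conditions) {
      f <- cond_fits[[cond]]
      cl <- if (cond == control_condition) NULL else
        calls[[paste(io, cond, sep = ":")]]
      rows[[paste(io, cond, sep = ":")]] <- data.frame(
        ion = io, phage = cond,
        half_max_mM = f$half_max,
        ci_low = f$ci[1L], ci_high = f$ci[2L],
        hill = f$hill, top = f$top, bottom = f$bottom, rss = f$rss,
        converged = f$converged, direction = f$direction,
        no_inhibition = f$no_inhibition,
        classification = if (is.null(cl)) NA_character_ else cl$classification,
        shifted = if (is.null(cl)) NA else cl$shifted,
        stringsAsFactors = FALSE)
    }
    fits[[io]] <- cond_fits
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "calls") <- calls
  class(out) <- c("plate_fits", class(out))
  out
}

#' Express a fitted threshold as ionic strength
#'
#' Converts the half-maximal salt concentration of a converged fit into the
#' ionic strength contributed by the fully dissociated salt at that
#' concentration, optionally adding the ionic strength of a background
#' medium profile (off by default; the background is usually reported
#' separately).
#'
#' @param fit A converged [fit_4pl()] with an inhibition threshold.
#' @param salt The [ion_species()] in which the ion was dosed.
#' @param background Optional [ion_profile()] of the assay medium.
#' @return Ionic strength in mM.
#' @examples
#' conc <- rep(8 / 2^(0:7), each = 2)
#' fit <- fit_4pl(conc, 1 / (1 + (conc / 0.5)^2))
#' ec50_to_ionic_strength(fit, ion_species("Ca", 2))  # 3 x 0.5 = 1.5 mM
#' @export
ec50_to_ionic_strength <- function(fit, salt, background = NULL) {
  stopifnot(inherits(fit, "fit4pl"))
  if (!fit$converged)
    stop("fit did not converge", call. = FALSE)
  if (fit$no_inhibition || is.na(fit$half_max))
    stop("undefined threshold: series shows no inhibition", call. = FALSE)
  out <- ionic_strength(salt_to_profile(salt, fit$half_max))
  if (!is.null(background)) out <- out + ionic_strength(background)
  out
}

#' Add an ionic-strength column to a plate fits table
#'
#' @param fits A `"plate_fits"` table from [analyze_plate()].
#' @param panel Panel used for the plate (list of [ion_species()] or
#'   cation names); salts are matched by ion name.
#' @param background Optional background [ion_profile()] added to each value.
#' @return `fits` with an `ec50_ionic_strength_mM` column (NA where the
#'   series showed no inhibition).
#' @export
add_ionic_strength <- function(fits, panel, background = NULL) {
  panel <- as_ion_panel(panel)
  fits$ec50_ionic_strength_mM <- vapply(seq_len(nrow(fits)), function(i) {
    if (isTRUE(fits$no_inhibition[i]) || is.na(fits$half_max_mM[i]))
      return(NA_real_)
    salt <- panel[[fits$ion[i]]]
    if (is.null(salt)) return(NA_real_)
    base <- ionic_strength(salt_to_profile(salt, fits$half_max_mM[i]))
    if (!is.null(background)) base <- base + ionic_strength(background)
    base
  }, numeric(1))
  fits
}
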