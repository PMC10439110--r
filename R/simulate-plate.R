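#' Ground-truth parameters for a simulated dosing plate
#'
#' Builds the true 4PL parameters for every (ion, phage condition) pair of
#' a simulated microplate experiment. Scalars are recycled; `ec50` may also
#' be a matrix with one row per ion and one column per condition (in
#' `ions` x `conditions` order) to give, e.g., a lower threshold in the
#' phage condition than the toxicity threshold without phage.
#'
#' @param ions Character vector of ion names (must match the panel used in
#'   [simulate_plate()]).
#' @param conditions Phage-condition labels; the first is conventionally
#'   the no-phage control condition `"none"`.
#' @param ec50 True half-maximal concentrations, mM, > 0.
#' @param hill True hill slopes, > 0.
#' @param top,bottom True asymptotes of the normalized response
#'   (`top > bottom`).
#' @param noise_sd Gaussian noise standard deviation, expressed as a
#'   fraction of the dynamic range `top - bottom`, >= 0.
#' @param seed Integer seed stored with the truth; [simulate_plate()] uses
#'   it so that identical truth implies identical tables.
#' @return A data frame of class `"plate_truth"` with columns `ion`,
#'   `phage`, `true_ec50`, `true_hill`, `true_top`, `true_bottom`, and
#'   attributes `noise_sd` and `seed`.
#' @export
plate_truth <- function(ions, conditions = c("none", "phage"),
                        ec50 = 10, hill = 2, top = 1, bottom = 0,
                        noise_sd = 0.05, seed = 1) {
  stopifnot(is.character(ions), length(ions) >= 1L,
            is.character(conditions), length(conditions) >= 1L)
  if (!is_number(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  grid <- expand.grid(ion = ions, phage = conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand_par <- function(p, what) {
    if (is.matrix(p)) {
      stopifnot(nrow(p) == length(ions), ncol(p) == length(conditions))
      p <- as.vector(p)
    } else {
      p <- rep_len(p, nrow(grid))
    }
    if (any(!is.finite(p))) stop("'", what, "' must be finite", call. = FALSE)
    p
  }
  grid$true_ec50 <- expand_par(ec50, "ec50")
  grid$true_hill <- expand_par(hill, "hill")
  grid$true_top <- expand_par(top, "top")
  grid$true_bottom <- expand_par(bottom, "bottom")
  if (any(grid$true_ec50 <= 0)) stop("'ec50' must be > 0", call. = FALSE)
  if (any(grid$true_hill <= 0)) stop("'hill' must be > 0", call. = FALSE)
  if (any(grid$true_top <= grid$true_bottom))
    stop("'top' must exceed 'bottom'", call. = FALSE)
  attr(grid, "noise_sd") <- noise_sd
  attr(grid, "seed") <- as.integer(seed)
  class(grid) <- c("plate_truth", class(grid))
  grid
}

#' Simulate a serially diluted ion-array microplate
#'
#' Generates the long-format table of a plate experiment in which each ion
#' of a panel is serially diluted (geometric series of `n_dilutions` steps
#' of factor `dilution_factor` down from `top_conc`) and host growth is
#' read at the assay endpoint in each phage condition. Responses are drawn
#' from the 4PL curve of the matching [plate_truth()] row plus Gaussian
#' noise (sd = `noise_sd` x dynamic range), truncated at 0. One zero-ion
#' control well per (ion, condition, replicate) is appended with the
#' no-ion response (`true_top` plus noise): in ion-depleted medium phage
#' cannot infect, so the control level is uninhibited growth in both
#' conditions.
#'
#' @param panel Ion panel: cation names or list of [ion_species()]
#'   (see [as_ion_panel()]).
#' @param truth A [plate_truth()] covering every (panel ion, condition).
#' @param n_dilutions Number of nonzero dilution steps, >= 4 (default 10).
#' @param dilution_factor Serial dilution factor, > 1 (default 2).
#' @param top_conc Highest tested concentration, mM (scalar or one per
#'   ion), > 0.
#' @param n_replicates Replicate wells per (ion, condition, concentration),
#'   >= 1 (default 2).
#' @param ammonium_scale If non-`NULL`, an `ammonium_mM` column is added:
#'   the same dose-response curve scaled to `ammonium_scale` mM at the top
#'   asymptote, with independent noise of the same fractional size. Used
#'   for cocktail-efficacy assays where ammonium production is the
#'   functional readout.
#' @return Data frame with columns `well`, `ion`, `salt_formula`,
#'   `conc_mM`, `phage`, `replicate`, `od600` (plus `ammonium_mM` when
#'   requested); the truth is attached as attribute `"truth"`. Rows with
#'   `conc_mM == 0` are controls.
#' @examples
#' tr <- plate_truth(c("Na", "Ca"), ec50 = c(100, 100, 2, 2), seed = 7)
#' plate <- simulate_plate(c("Na", "Ca"), tr, top_conc = c(400, 32))
#' head(plate)
#' @export
simulate_plate <- function(panel, truth, n_dilutions = 10,
                           dilution_factor = 2, top_conc = 100,
                           n_replicates = 2, ammonium_scale = NULL) {
  panel <- as_ion_panel(panel)
  stopifnot(inherits(truth, "plate_truth"))
  if (!is_count(n_dilutions, 4L))
    stop("invalid configuration: 'n_dilutions' must be an integer >= 4",
         call. = FALSE)
  if (!is_number(dilution_factor) || dilution_factor <= 1)
    stop("invalid configuration: 'dilution_factor' must be > 1",
         call. = FALSE)
  if (!is.numeric(top_conc) || any(!is.finite(top_conc)) ||
      any(top_conc <= 0))
    stop("invalid configuration: 'top_conc' must be > 0", call. = FALSE)
  if (!is_count(n_replicates))
    stop("invalid configuration: 'n_replicates' must be an integer >= 1",
         call. = FALSE)
  ions <- names(panel)
  top_conc <- stats::setNames(rep_len(top_conc, length(ions)), ions)
  missing <- setdiff(ions, unique(truth$ion))
  if (length(missing))
    stop("truth lacks ion(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  conditions <- unique(truth$phage)
  noise_sd <- attr(truth, "noise_sd")
  key <- paste(truth$ion, truth$phage, sep = ":")

  rows <- expand.grid(replicate = seq_len(n_replicates),
                      conc_step = seq_len(n_dilutions) - 1L,
                      phage = conditions, ion = ions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("ion", "phage", "conc_step", "replicate")]
  rows$conc_mM <- top_conc[rows$ion] / dilution_factor^rows$conc_step
  ctrl <- expand.grid(replicate = seq_len(n_replicates),
                      phage = conditions, ion = ions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ctrl$conc_step <- NA_integer_
  ctrl$conc_mM <- 0
  rows <- rbind(rows, ctrl[, names(rows)])
  # stable, layout-independent ordering
  rows <- rows[order(match(rows$ion, ions), match(rows$phage, conditions),
                     -rows$conc_mM, rows$replicate), ]
  ti <- match(paste(rows$ion, rows$phage, sep = ":"), key)
  mu <- ifelse(rows$conc_mM == 0,
               truth$true_top[ti],
               truth$true_bottom[ti] +
                 (truth$true_top[ti] - truth$true_bottom[ti]) /
                 (1 + (rows$conc_mM / truth$true_ec50[ti])^truth$true_hill[ti]))
  rng <- truth$true_top[ti] - truth$true_bottom[ti]
  noise <- with_seed(attr(truth, "seed"), {
    n1 <- stats::rnorm(nrow(rows), 0, noise_sd * rng)
    n2 <- if (is.null(ammonium_scale)) NULL else
      stats::rnorm(nrow(rows), 0, noise_sd * rng * ammonium_scale)
    list(od = n1, amm = n2)
  })
  od <- pmax(0, mu + noise$od)
  out <- data.frame(
    well = sprintf("W%05d", seq_len(nrow(rows))),
    ion = rows$ion,
    salt_formula = vapply(panel[rows$ion], salt_formula, ""),
    conc_mM = rows$conc_mM,
    phage = rows$phage,
    replicate = rows$replicate,
    od600 = od,
    stringsAsFactors = FALSE)
  if (!is.null(ammonium_scale)) {
    stopifnot(is_number(ammonium_scale), ammonium_scale > 0)
    out$ammonium_mM <- pmax(0, mu * ammonium_scale + noise$amm)
  }
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}
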