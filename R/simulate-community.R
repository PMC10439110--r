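#' Ground truth for a simulated nitrate-reducing community experiment
#'
#' Defines, per carbon source, the baseline community composition and, per
#' taxon, the ammonium yield and whether the phage cocktail targets it.
#' [simulate_community()] draws replicated plus/minus-cocktail samples from
#' this truth.
#'
#' @param base_abundance Numeric matrix, taxa as rows, carbon sources as
#'   columns; each column sums to 1.
#' @param phage_target_taxa Character vector of taxa lysed by the cocktail.
#' @param depletion_factor Multiplicative survival of targeted taxa in
#'   plus-cocktail samples, in (0, 1] (1 = no depletion).
#' @param ammonium_yield Named numeric vector, mM ammonium produced per
#'   unit baseline abundance of each taxon (0 for taxa that do not perform
#'   nitrite reduction to ammonium).
#' @return An object of class `"community_truth"`.
#' @export
community_truth <- function(base_abundance, phage_target_taxa,
                            depletion_factor = 0.1, ammonium_yield) {
  stopifnot(is.matrix(base_abundance), !is.null(rownames(base_abundance)),
            !is.null(colnames(base_abundance)))
  if (any(base_abundance < 0))
    stop("abundances must be >= 0", call. = FALSE)
  sums <- colSums(base_abundance)
  if (any(abs(sums - 1) > 1e-9))
    stop("each carbon-source column of 'base_abundance' must sum to 1",
         call. = FALSE)
  taxa <- rownames(base_abundance)
  if (!all(phage_target_taxa %in% taxa))
    stop("unknown phage target taxa", call. = FALSE)
  if (!is_number(depletion_factor) || depletion_factor <= 0 ||
      depletion_factor > 1)
    stop("'depletion_factor' must be in (0, 1]", call. = FALSE)
  if (is.null(names(ammonium_yield)) || !all(taxa %in% names(ammonium_yield)))
    stop("'ammonium_yield' must be named and cover every taxon",
         call. = FALSE)
  if (any(ammonium_yield < 0))
    stop("yields must be >= 0", call. = FALSE)
  structure(
    list(base_abundance = base_abundance,
         phage_target_taxa = phage_target_taxa,
         depletion_factor = depletion_factor,
         ammonium_yield = ammonium_yield[taxa]),
    class = "community_truth")
}

#' Default truth emulating a freshwater nitrate-reducing (FN) enrichment
#'
#' A seven-taxon community whose structure mirrors the canonical
#' carbon-source patterns of a freshwater nitrate-reducing sediment
#' enrichment: sugars and lactate enrich DNRA-capable *Escherichia* and
#' *Citrobacter* (the cocktail targets), cellobiose and sorbose enrich a
#' *Klebsiella* capable only of nitrate reduction to nitrite (low ammonium,
#' nothing for the cocktail to deplete), and ethanol/formate enrich an
#' untargeted DNRA-capable *Sulfurospirillum* (high ammonium, unaffected by
#' the cocktail). Compositions and yields are illustrative, not measured
#' values.
#'
#' @param depletion_factor Survival fraction of targeted taxa with the
#'   cocktail, default 0.1.
#' @return A [community_truth()].
#' @export
fn_community_truth <- function(depletion_factor = 0.1) {
  taxa <- c("Escherichia", "Citrobacter_1", "Citrobacter_2", "Klebsiella",
            "Sulfurospirillum", "Pseudomonas", "other")
  ab <- cbind(
    `D-trehalose`  = c(0.55, 0.15, 0.10, 0.05, 0.02, 0.08, 0.05),
    `D-glucose`    = c(0.30, 0.30, 0.15, 0.05, 0.02, 0.10, 0.08),
    `DL-lactate`   = c(0.15, 0.40, 0.25, 0.05, 0.03, 0.07, 0.05),
    `D-cellobiose` = c(0.00, 0.00, 0.00, 0.70, 0.00, 0.15, 0.15),
    `L-sorbose`    = c(0.00, 0.00, 0.00, 0.65, 0.00, 0.15, 0.20),
    ethanol        = c(0.00, 0.00, 0.00, 0.05, 0.75, 0.10, 0.10),
    formate        = c(0.00, 0.00, 0.00, 0.05, 0.70, 0.12, 0.13))
  rownames(ab) <- taxa
  community_truth(
    base_abundance = ab,
    phage_target_taxa = c("Escherichia", "Citrobacter_1", "Citrobacter_2"),
    depletion_factor = depletion_factor,
    ammonium_yield = c(Escherichia = 12, Citrobacter_1 = 10,
                       Citrobacter_2 = 10, Klebsiella = 0,
                       Sulfurospirillum = 12, Pseudomonas = 0, other = 0))
}

#' Respiratory capability flags matching [fn_community_truth()]
#'
#' DNRA capability requires both the nitrate-to-nitrite and the
#' nitrite-to-ammonium flag.
#'
#' @return Data frame with columns `taxon`, `can_nitrate_to_nitrite`,
#'   `can_nitrite_to_ammonium`, `phage_targeted`.
#' @export
fn_capability_table <- function() {
  data.frame(
    taxon = c("Escherichia", "Citrobacter_1", "Citrobacter_2", "Klebsiella",
              "Sulfurospirillum", "Pseudomonas", "other"),
    can_nitrate_to_nitrite = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    can_nitrite_to_ammonium = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    phage_targeted = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Simulate a plus/minus-cocktail community-function experiment
#'
#' For every (carbon source, condition, replicate) the generator (i)
#' depletes phage-target taxa by the truth's `depletion_factor` in
#' plus-cocktail samples, (ii) computes deterministic ammonium as the
#' yield-weighted sum over the depleted (pre-renormalization) abundances,
#' (iii) perturbs abundances with multiplicative lognormal noise and
#' renormalizes them to sum to 1, and (iv) adds Gaussian noise to ammonium
#' (sd = `noise_sd` x the largest no-cocktail deterministic ammonium
#' across carbon sources), flooring at 0. OD600 is proportional to total
#' surviving biomass.
#'
#' @param truth A [community_truth()].
#' @param carbon_sources Carbon sources to simulate (default: all in the
#'   truth). Unknown names raise an error.
#' @param n_replicates Replicates per (carbon source, condition), >= 1
#'   (default 4).
#' @param noise_sd Noise level (lognormal sd on abundances; fraction of the
#'   ammonium dynamic range), >= 0 (default 0.05).
#' @param seed Integer seed.
#' @param od_scale OD600 of an undepleted community (default 0.5).
#' @return A list of class `"fn_community"`: `abundances` (taxa x samples
#'   matrix, columns sum to 1) and `meta` (data frame `sample`,
#'   `carbon_source`, `phage` in `"minus"`/`"plus"`, `replicate`,
#'   `ammonium_mM`, `od600`), with the truth attached.
#' @export
simulate_community <- function(truth, carbon_sources = NULL,
                               n_replicates = 4, noise_sd = 0.05, seed = 1,
                               od_scale = 0.5) {
  stopifnot(inherits(truth, "community_truth"))
  all_cs <- colnames(truth$base_abundance)
  if (is.null(carbon_sources)) carbon_sources <- all_cs
  unknown <- setdiff(carbon_sources, all_cs)
  if (length(unknown))
    stop("unknown carbon source(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is_count(n_replicates))
    stop("'n_replicates' must be an integer >= 1", call. = FALSE)
  if (!is_number(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0", call. = FALSE)
  taxa <- rownames(truth$base_abundance)
  targeted <- taxa %in% truth$phage_target_taxa
  meta <- expand.grid(replicate = seq_len(n_replicates),
                      phage = c("minus", "plus"),
                      carbon_source = carbon_sources,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("carbon_source", "phage", "replicate")]
  meta$sample <- sprintf("S%03d", seq_len(nrow(meta)))
  # ammonium noise scale: fraction of the largest no-cocktail signal
  a_ref <- max(colSums(truth$base_abundance[, carbon_sources, drop = FALSE] *
                         truth$ammonium_yield))
  a_ref <- max(a_ref, 1)  # floor so zero-signal carbons still get plate noise
  sim <- with_seed(seed, {
    ab <- matrix(0, nrow = length(taxa), ncol = nrow(meta),
                 dimnames = list(taxa, meta$sample))
    amm <- numeric(nrow(meta))
    od <- numeric(nrow(meta))
    for (i in seq_len(nrow(meta))) {
      base <- truth$base_abundance[, meta$carbon_source[i]]
      depl <- ifelse(targeted & meta$phage[i] == "plus",
                     truth$depletion_factor, 1)
      biomass <- base * depl
      amm_det <- sum(biomass * truth$ammonium_yield)
      noisy <- biomass * exp(stats::rnorm(length(taxa), 0, noise_sd))
      ab[, i] <- noisy / sum(noisy)
      amm[i] <- max(0, amm_det + stats::rnorm(1, 0, noise_sd * a_ref))
      od[i] <- max(0, od_scale * sum(biomass) +
                     stats::rnorm(1, 0, noise_sd * od_scale))
    }
    list(ab = ab, amm = amm, od = od)
  })
  meta$ammonium_mM <- sim$amm
  meta$od600 <- sim$od
  structure(list(abundances = sim$ab, meta = meta, truth = truth),
            class = "fn_community")
}

#' @export
print.fn_community <- function(x, ...) {
  cat(sprintf("<fn_community> %d taxa x %d samples (%d carbon sources, +/- cocktail)\n",
              nrow(x$abundances), ncol(x$abundances),
              length(unique(x$meta$carbon_source))))
  invisible(x)
}
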