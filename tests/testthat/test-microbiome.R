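test_that("DNRA potential is the abundance sum over doubly capable taxa", {
  caps <- fn_capability_table()
  expect_equal(dnra_potential(c(Escherichia = 1), caps), 1)
  # half DNRA-capable, half nitrate-to-nitrite only
  expect_equal(dnra_potential(c(Escherichia = 0.5, Klebsiella = 0.5), caps),
               0.5)
  expect_equal(dnra_potential(c(Klebsiella = 0.6, Pseudomonas = 0.4), caps),
               0)
  expect_error(dnra_potential(c(Vibrio = 1), caps), "Vibrio")
  # zero-abundance taxa need no flags
  expect_equal(dnra_potential(c(Escherichia = 1, Vibrio = 0), caps), 1)
  # matrix input gives one value per sample
  m <- cbind(s1 = c(Escherichia = 0.5, Klebsiella = 0.5),
             s2 = c(Escherichia = 1, Klebsiella = 0))
  expect_equal(dnra_potential(m, caps), c(s1 = 0.5, s2 = 1))
})

test_that("DNRA potential is invariant under merging same-flag taxa", {
  caps <- rbind(fn_capability_table(),
                data.frame(taxon = "Escherichia_B",
                           can_nitrate_to_nitrite = TRUE,
                           can_nitrite_to_ammonium = TRUE,
                           phage_targeted = TRUE))
  split_ab <- c(Escherichia = 0.3, Escherichia_B = 0.4, Klebsiella = 0.3)
  merged_ab <- c(Escherichia = 0.7, Klebsiella = 0.3)
  expect_equal(dnra_potential(split_ab, caps),
               dnra_potential(merged_ab, caps))
})

test_that("cocktail effects per carbon source recover the designed patterns", {
  comm <- simulate_community(fn_community_truth(0.1), n_replicates = 4,
                             noise_sd = 0.05, seed = 31)
  eff <- phage_effect_by_carbon(comm, caps = fn_capability_table())
  eff <- eff[match(c("D-trehalose", "D-cellobiose", "ethanol"),
                   eff$carbon_source), ]
  # sugar enriching targeted DNRA strains: strong suppression
  expect_true(eff$significant[1])
  expect_gt(eff$mean_diff_mM[1], 5)
  expect_equal(eff$dominant_taxon[1], "Escherichia")
  expect_true(eff$dominant_targeted[1])
  expect_gt(eff$dnra_potential_minus[1], eff$dnra_potential_plus[1])
  # cellobiose enriches nitrate-to-nitrite-only Klebsiella: nothing to lose
  expect_equal(eff$dominant_taxon[2], "Klebsiella")
  expect_false(eff$dominant_targeted[2])
  expect_lt(abs(eff$mean_diff_mM[2]), 2)
  # ethanol enriches untargeted DNRA Sulfurospirillum: high but unaffected
  expect_equal(eff$dominant_taxon[3], "Sulfurospirillum")
  expect_false(eff$dominant_targeted[3])
  expect_gt(eff$mean_minus_mM[3], 5)
})

test_that("identical conditions yield zero difference and no flag", {
  comm <- simulate_community(fn_community_truth(depletion_factor = 1),
                             carbon_sources = "D-glucose",
                             n_replicates = 3, noise_sd = 0, seed = 5)
  eff <- phage_effect_by_carbon(comm)
  expect_equal(eff$mean_diff_mM, 0)
  expect_false(eff$significant)
  expect_equal(eff$p_value, 1)
})

test_that("replication below two per group is rejected", {
  comm <- simulate_community(fn_community_truth(),
                             carbon_sources = "D-glucose",
                             n_replicates = 1, seed = 1)
  expect_error(phage_effect_by_carbon(comm), "insufficient replication")
})

test_that("dominant-taxon ties break lexicographically", {
  ab <- matrix(c(0.5, 0.5), 2, 1,
               dimnames = list(c("zeta", "alpha"), "glucose"))
  tr <- community_truth(ab, phage_target_taxa = "alpha",
                        depletion_factor = 0.5,
                        ammonium_yield = c(zeta = 1, alpha = 1))
  comm <- simulate_community(tr, n_replicates = 2, noise_sd = 0, seed = 1)
  eff <- phage_effect_by_carbon(comm)
  expect_equal(eff$dominant_taxon, "alpha")
})

test_that("nitrogen assimilation is linear with the printed constants", {
  expect_equal(nitrogen_assimilated(0)$nitrogen_g_per_l, 0)
  n1 <- nitrogen_assimilated(1)
  expect_identical(n1$nitrogen_g_per_l, 0.3 * 0.12)
  expect_equal(n1$nitrogen_mM, 0.036 / 14.007 * 1000)  # ~2.57 mM
  expect_equal(nitrogen_assimilated(0.5)$nitrogen_g_per_l, 0.018)
  # linearity
  od <- c(0.2, 0.4, 1.6)
  expect_equal(nitrogen_assimilated(od)$nitrogen_g_per_l, od * 0.036)
  expect_error(nitrogen_assimilated(-0.1), ">= 0")
})

test_that("cocktail ion dose-response reuses the paired 4PL machinery", {
  # +cocktail suppresses ammonium with EC50 50 mM; -cocktail flat
  tr <- plate_truth("Na", c("none", "cocktail"),
                    ec50 = cbind(none = 1e6, cocktail = 50),
                    hill = 2, noise_sd = 0, seed = 11)
  plate <- simulate_plate("Na", tr, top_conc = 800, ammonium_scale = 10)
  fits <- cocktail_ion_dose_response(plate, n_boot = 100, seed = 2)
  ec <- fits[fits$phage == "cocktail", ]
  ic <- fits[fits$phage == "none", ]
  expect_lt(abs(ec$half_max_mM - 50) / 50, 1e-4)
  # far-off toxicity threshold looks flat within the tested range
  expect_true(ic$no_inhibition)
  expect_equal(ec$classification, "enables_infection")
  expect_true(ec$shifted)
})

test_that("welch comparison holds its nominal size under the null", {
  # no depletion: plus and minus draws are exchangeable
  tr <- fn_community_truth(depletion_factor = 1)
  rej <- vapply(1:1000, function(s) {
    comm <- simulate_community(tr, carbon_sources = "D-glucose",
                               n_replicates = 4, noise_sd = 0.05, seed = s)
    phage_effect_by_carbon(comm)$significant
  }, logical(1))
  expect_lte(mean(rej), 0.075)
})
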