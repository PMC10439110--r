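test_that("disjoint-interval rule classifies enables_infection by hand", {
  ic <- fit_with_ci(50, c(40, 60))
  ec <- fit_with_ci(5, c(3, 7))
  call <- call_threshold(ic, ec)
  expect_true(call$shifted)
  expect_equal(call$classification, "enables_infection")
})

test_that("overlapping intervals with both curves inhibiting is toxic_only", {
  ic <- fit_with_ci(50, c(40, 60))
  ec <- fit_with_ci(55, c(45, 70))
  call <- call_threshold(ic, ec)
  expect_false(call$shifted)
  expect_equal(call$classification, "toxic_only")
  # identical fits trivially overlap
  call2 <- call_threshold(ic, ic)
  expect_false(call2$shifted)
  expect_equal(call2$classification, "toxic_only")
})

test_that("higher threshold with phage and disjoint intervals is protective", {
  # the Al3+/T4 pattern: phage raises the toxicity threshold
  ic <- fit_with_ci(50, c(40, 54))
  ec <- fit_with_ci(70, c(55, 80))
  call <- call_threshold(ic, ec)
  expect_true(call$shifted)
  expect_equal(call$classification, "protective")
})

test_that("flat curves route to no_inhibition / enables / protective", {
  both_flat <- call_threshold(flat_fit(), flat_fit())
  expect_equal(both_flat$classification, "no_inhibition")
  expect_false(both_flat$shifted)
  # ion harmless alone but required for infection
  enab <- call_threshold(flat_fit(), fit_with_ci(5, c(3, 7)))
  expect_equal(enab$classification, "enables_infection")
  expect_true(enab$shifted)
  # toxic alone, harmless with phage: complete protection
  prot <- call_threshold(fit_with_ci(50, c(40, 60)), flat_fit())
  expect_equal(prot$classification, "protective")
  expect_true(prot$shifted)
})

test_that("shifted is true exactly for enables_infection and protective", {
  cases <- list(
    call_threshold(fit_with_ci(50, c(40, 60)), fit_with_ci(5, c(3, 7))),
    call_threshold(fit_with_ci(50, c(40, 60)), fit_with_ci(55, c(45, 70))),
    call_threshold(fit_with_ci(50, c(40, 54)), fit_with_ci(70, c(55, 80))),
    call_threshold(flat_fit(), flat_fit()),
    call_threshold(flat_fit(), fit_with_ci(5, c(3, 7))))
  for (cl in cases) {
    expect_identical(cl$shifted,
                     cl$classification %in% c("enables_infection",
                                              "protective"))
  }
})

test_that("mismatched ions raise a pairing error; missing CIs are caught", {
  expect_error(call_threshold(fit_with_ci(50, c(40, 60), ion = "Na"),
                              fit_with_ci(5, c(3, 7), ion = "Ca")),
               "pairing")
  d <- gen_series(10, 2)
  no_ci <- fit_4pl(d$conc, d$response)
  expect_error(call_threshold(no_ci, no_ci), "bootstrap")
})

test_that("analyze_plate fits, classifies and tabulates a whole array", {
  ions <- c("Na", "K", "Ca")
  # +phage thresholds 10x below toxicity for Na and Ca; K unchanged
  ec50 <- cbind(none = c(200, 150, 20), T4 = c(20, 150, 2))
  tr <- plate_truth(ions, c("none", "T4"), ec50 = ec50, hill = 2,
                    noise_sd = 0.02, seed = 5)
  plate <- simulate_plate(ions, tr, top_conc = c(800, 600, 80))
  fits <- analyze_plate(plate, n_boot = 120, seed = 3)
  expect_s3_class(fits, "plate_fits")
  expect_equal(nrow(fits), 6L)
  expect_setequal(fits$phage, c("none", "T4"))
  na_call <- fits[fits$ion == "Na" & fits$phage == "T4", ]
  expect_equal(na_call$classification, "enables_infection")
  expect_true(na_call$shifted)
  k_call <- fits[fits$ion == "K" & fits$phage == "T4", ]
  expect_equal(k_call$classification, "toxic_only")
  # recovered thresholds are close to truth
  got <- fits$half_max_mM[fits$ion == "Na"]
  expect_equal(sort(got), c(20, 200), tolerance = 0.15)
  # ionic strength column: CaCl2 fit at ~2 mM -> ~6 mM ionic strength
  isfits <- add_ionic_strength(fits, ions)
  ca_t4 <- isfits[isfits$ion == "Ca" & isfits$phage == "T4", ]
  expect_equal(ca_t4$ec50_ionic_strength_mM, 3 * ca_t4$half_max_mM)
})

test_that("analyze_plate requires control wells and known columns", {
  tr <- plate_truth("Na", c("none", "T4"), seed = 2)
  plate <- simulate_plate("Na", tr)
  expect_error(analyze_plate(plate[plate$conc_mM > 0, ]), "control wells")
  expect_error(analyze_plate(plate, response = "fluorescence"), "lacks")
})
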