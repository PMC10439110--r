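test_that("lysed-cell dilution follows the cubic law", {
  m <- lysis_model()
  # at the cell surface the concentration is the cytoplasmic one
  expect_equal(lysis_concentration(m, "Na", 1), 212)
  expect_equal(lysis_concentration(m, "K", 1), 38)
  # doubling the radius dilutes 8-fold
  expect_equal(lysis_concentration(m, "Na", 2), 212 / 8)
  # monotone non-increasing in r for every ion
  r <- seq(1, 20, length.out = 50)
  for (ion in c("Na", "K", "Ca", "Mg")) {
    conc <- lysis_concentration(m, ion, r)
    expect_true(all(diff(conc) <= 0))
  }
  expect_error(lysis_concentration(m, "Na", 0.5), "out of domain")
  expect_error(lysis_concentration(m, "Fe3", 2), "absent")
})

test_that("lysis model conserves ion mass", {
  m <- lysis_model(r0 = 1.3)
  for (r in c(1.3, 2, 5, 50)) {
    for (ion in c("Na", "Mg")) {
      expect_equal(lysis_concentration(m, ion, r) * r^3,
                   m$cytoplasm$concentrations[[ion]] * m$r0^3,
                   tolerance = 1e-12)
    }
  }
})

test_that("crossing distance matches a bisection oracle to 1e-9", {
  m <- lysis_model()
  bisect <- function(ion, thr) {
    f <- function(r) lysis_concentration(m, ion, r) - thr
    if (f(m$r0) <= 0) return(m$r0)
    uniroot(f, c(m$r0, 1e6), tol = 1e-12)$root
  }
  expect_equal(lysis_crossing_distance(m, "Na", 100),
               (212 / 100)^(1 / 3), tolerance = 1e-12)
  for (thr in c(0.01, 1, 37, 100, 250)) {
    expect_equal(lysis_crossing_distance(m, "Na", thr),
                 bisect("Na", thr), tolerance = 1e-9)
    expect_equal(lysis_crossing_distance(m, "K", thr),
                 bisect("K", thr), tolerance = 1e-9)
  }
  # at/above the cytoplasmic level the cloud is below threshold everywhere
  expect_equal(lysis_crossing_distance(m, "Na", 212), 1)
  expect_equal(lysis_crossing_distance(m, "Na", 500), 1)
})

test_that("crossing distance scales linearly with cell radius", {
  m1 <- lysis_model(r0 = 1)
  m3 <- lysis_model(r0 = 3)
  expect_equal(lysis_crossing_distance(m3, "Na", 10),
               3 * lysis_crossing_distance(m1, "Na", 10))
})

test_that("evaporation scales conservative ions and caps limited ones", {
  sc <- springwater_scenario(na0 = 0.1, k0 = 0.03, ca0 = 0.1, mg0 = 0.02,
                             ceilings = c(Ca = 0.5, Mg = 1))
  # identity at cf = 1
  expect_equal(evaporate(sc, 1)$concentrations,
               sc$initial$concentrations)
  # conservative: linear
  expect_equal(evaporate(sc, 1000)$concentrations[["Na"]], 100)
  # capped: min(c0 * cf, ceiling)
  expect_equal(evaporate(sc, 10)$concentrations[["Ca"]], 0.5)
  expect_equal(evaporate(sc, 3)$concentrations[["Ca"]], 0.3)
  expect_error(evaporate(sc, 0.5), "out of domain")
  # monotone non-decreasing in cf for every ion
  cur <- evaporation_curve(sc)
  for (ion in c("Na", "K", "Ca", "Mg"))
    expect_true(all(diff(cur[[ion]]) >= 0))
  # sequential evaporation equals one-shot for conservative ions
  two_step <- evaporate(evaporation_scenario(evaporate(sc, 10),
                                             ceilings = sc$ceilings), 5)
  expect_equal(two_step$concentrations[["Na"]],
               evaporate(sc, 50)$concentrations[["Na"]])
})

test_that("cf grid is logarithmic, starts at 1, and inputs are validated", {
  sc <- springwater_scenario(cf_max = 1000, n_grid = 31)
  expect_equal(sc$cf_grid[1], 1)
  expect_equal(max(sc$cf_grid), 1000)
  expect_equal(diff(log10(sc$cf_grid)),
               rep(log10(1000) / 30, 30), tolerance = 1e-12)
  expect_error(springwater_scenario(na0 = -0.1), "invalid configuration")
  expect_error(springwater_scenario(ca0 = -1), "invalid configuration")
  expect_error(springwater_scenario(cf_max = 0.5), "invalid configuration")
})

test_that("evaporation crossing factor: closed form and edge cases", {
  sc <- springwater_scenario(na0 = 0.1, ca0 = 0.1,
                             ceilings = c(Ca = 0.5, Mg = 1))
  expect_equal(evaporation_crossing_factor(sc, "Na", 100), 1000)
  # threshold at/below the initial level crosses immediately
  expect_equal(evaporation_crossing_factor(sc, "Na", 0.05), 1)
  # ceiling below the threshold: never crosses
  expect_true(is.na(evaporation_crossing_factor(sc, "Ca", 2.38)))
  # ceiling above the threshold: crossing happens before the cap binds
  expect_equal(evaporation_crossing_factor(sc, "Ca", 0.4), 4)
  expect_error(evaporation_crossing_factor(sc, "Sr", 1), "absent")
  expect_error(evaporation_crossing_factor(sc, "Na", -1), "threshold")
})

test_that("both crossing solvers agree with dense-grid brute force", {
  grid_lysis <- function(m, ion, thr) {
    r <- m$r0 * 10^seq(0, 3, length.out = 1e4)
    below <- lysis_concentration(m, ion, r) <= thr
    r[which(below)[1]]
  }
  grid_evap <- function(sc, ion, thr) {
    cf <- 10^seq(0, 8, length.out = 1e4)
    conc <- pmin(sc$initial$concentrations[[ion]] * cf,
                 if (ion %in% names(sc$ceilings)) sc$ceilings[[ion]] else Inf)
    i <- which(conc >= thr)[1]
    if (is.na(i)) NA_real_ else cf[i]
  }
  set.seed(13)
  for (i in 1:100) {
    cyto <- ion_profile("c", "cytoplasm",
                        c(Na = runif(1, 50, 400), K = runif(1, 5, 100),
                          Ca = runif(1, 0.1, 2), Mg = runif(1, 0.1, 5)))
    m <- lysis_model(cyto, r0 = runif(1, 0.5, 2))
    ion <- sample(c("Na", "K", "Ca", "Mg"), 1)
    thr <- 10^runif(1, -2, 2)
    exact <- lysis_crossing_distance(m, ion, thr)
    approx <- grid_lysis(m, ion, thr)
    step <- approx * (10^(3 / 9999) - 1)  # one grid step
    expect_lt(abs(exact - approx), step + 1e-12)

    sc <- springwater_scenario(na0 = 10^runif(1, -2, 0),
                               k0 = 10^runif(1, -2, 0),
                               ca0 = 10^runif(1, -2, 0),
                               mg0 = 10^runif(1, -2, 0))
    thr2 <- 10^runif(1, -1, 2.5)
    exact2 <- evaporation_crossing_factor(sc, ion, thr2)
    approx2 <- grid_evap(sc, ion, thr2)
    if (is.na(exact2)) {
      expect_true(is.na(approx2))
    } else {
      step2 <- approx2 * (10^(8 / 9999) - 1)
      expect_lt(abs(exact2 - approx2), step2 + 1e-12)
    }
  }
})
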