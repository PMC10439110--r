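# Shared fixtures. The 4PL evaluator and series generator here are written
# directly from the model definition and kept independent of the package's
# simulate_plate()/fit_4pl() internals, so they can serve as oracles.

pl4 <- function(conc, ec50, hill, top = 1, bottom = 0) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

# Serial-dilution series with optional truncated Gaussian noise.
gen_series <- function(ec50, hill = 2, top = 1, bottom = 0, noise = 0,
                       n_dil = 10, dil = 2, top_conc = ec50 * 16, reps = 2) {
  conc <- rep(top_conc / dil^(0:(n_dil - 1)), each = reps)
  mu <- pl4(conc, ec50, hill, top, bottom)
  resp <- if (noise > 0) pmax(0, mu + rnorm(length(mu), 0, noise)) else mu
  data.frame(conc = conc, response = resp)
}

# A fit4pl object with a hand-set confidence interval, for exercising the
# threshold-call rules without running a bootstrap.
fit_with_ci <- function(half_max, ci, ion = "X", hill = 2) {
  d <- gen_series(half_max, hill)
  f <- fit_4pl(d$conc, d$response, ion = ion)
  f$ci <- ci
  f$ci_alpha <- 0.05
  f$n_boot <- 100L
  f
}

# A flat (no-inhibition) fit for the same ion.
flat_fit <- function(ion = "X") {
  conc <- rep(100 / 2^(0:9), each = 2)
  fit_4pl(conc, rep(1, length(conc)), ion = ion)
}
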