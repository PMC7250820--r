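test_that("turnover time inverts the exponential uptake model", {
  expect_equal(turnover_time(1 - exp(-1), 60), 60)
  expect_equal(turnover_time(0.5, 60), 60 / log(2))
  expect_equal(turnover_time(0.5, 60), 86.6, tolerance = 1e-3)
  ## small-fraction limit: T -> t/f within 1% at f <= 0.01
  expect_equal(turnover_time(0.01, 60), 60 / 0.01, tolerance = 0.01)
  expect_error(turnover_time(1, 60), "between 0 and 1")
  expect_error(turnover_time(0, 60), "between 0 and 1")
})

test_that("noiseless bioassay series round-trip to the generating truth", {
  amb <- 5e-9; v <- 1e-10
  ## two-point noiseless series: exact recovery
  s2 <- generate_bioassay(amb, v, added_concs = c(0, 1e-8), times = 60)
  fit2 <- isotope_dilution_fit(s2)
  expect_equal(fit2$ambient_conc, amb, tolerance = 1e-9)
  expect_equal(fit2$uptake_velocity, v, tolerance = 1e-9)
  ## multi-concentration, multi-time series
  s <- generate_bioassay(amb, v, added_concs = c(0, 2e-9, 5e-9, 1e-8, 2e-8),
                         times = c(30, 60, 120))
  fit <- isotope_dilution_fit(s)
  expect_equal(fit$ambient_conc, amb, tolerance = 1e-9)
  expect_equal(fit$uptake_velocity, v, tolerance = 1e-9)
  ## the fitted turnover line has positive slope whenever v > 0
  expect_gt(coef(fit$line)[2], 0)
})

test_that("bioassay fit is scale-equivariant", {
  amb <- 5e-9; v <- 1e-10; k <- 1000
  s1 <- generate_bioassay(amb, v, c(0, 2e-9, 8e-9), c(30, 90))
  sk <- generate_bioassay(k * amb, k * v, k * c(0, 2e-9, 8e-9), c(30, 90))
  f1 <- isotope_dilution_fit(s1)
  fk <- isotope_dilution_fit(sk)
  expect_equal(fk$ambient_conc, k * f1$ambient_conc, tolerance = 1e-8)
  expect_equal(fk$uptake_velocity, k * f1$uptake_velocity, tolerance = 1e-8)
})

test_that("bioassay fit rejects degenerate designs", {
  s <- generate_bioassay(5e-9, 1e-10, added_concs = 1e-8,
                         times = c(30, 60, 90))
  expect_error(isotope_dilution_fit(s), "2 distinct")
  ## non-decaying data
  bad <- bioassay_series(c(0, 0, 1e-8, 1e-8), c(30, 60, 30, 60),
                         c(0.5, 0.5, 0.5, 0.5))
  expect_error(isotope_dilution_fit(bad))
})

test_that("clearance is recovered exactly from clean depletion curves", {
  cl <- 1.78e-13; rho <- 2.5e10
  tt <- c(10, 30, 60, 120, 240)
  f <- exp(-cl * rho * tt)
  fit <- clearance_from_depletion(f, tt, rho)
  expect_equal(fit$clearance_cl, cl, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("clearance estimate is unbiased under Poisson counting noise", {
  cl <- 1.78e-13; rho <- 2.5e10
  tt <- c(10, 30, 60, 120, 240)
  f <- exp(-cl * rho * tt)
  ests <- vapply(1:10, function(s) {
    set.seed(s)
    fhat <- rpois(length(f), 1e4 * f) / 1e4
    clearance_from_depletion(fhat, tt, rho)$clearance_cl
  }, numeric(1))
  expect_lt(abs(mean(ests) - cl) / cl, 0.02)
})

test_that("clearance estimate ignores the initial concentration", {
  ## the remaining-fraction curve is concentration-free, so estimates agree
  ## to within +/-1% across seven orders of magnitude of starting Pi
  cl <- 4e-13; rho <- 1e10
  tt <- c(15, 45, 90, 180)
  ests <- vapply(10^seq(-13, -6), function(c0) {
    conc <- c0 * exp(-cl * rho * tt)
    clearance_from_depletion(conc / c0, tt, rho)$clearance_cl
  }, numeric(1))
  expect_lt(diff(range(ests)) / mean(ests), 0.01)
})

test_that("clearance fit flags gross non-monotone increases and degenerate data", {
  ## smooth decay with one clear tracer increase mid-series
  tt <- seq(10, 80, by = 10)
  f <- exp(-0.02 * tt)
  f[5] <- f[4] * 1.5
  expect_warning(fit <- clearance_from_depletion(f, tt, 1e10),
                 "non-monotone")
  expect_true(fit$flagged_nonmonotone)
  expect_error(clearance_from_depletion(c(0.5, 0.5, 0.5), c(1, 2, 3), 1e10),
               "identical|degenerate")
  ## censoring below the detection floor
  fit2 <- clearance_from_depletion(c(0.5, 0.1, 1e-8), c(10, 20, 30), 1e10)
  expect_equal(fit2$n_used, 2)
})

test_that("X-ray fluorescence quantification recovers a perfect line exactly", {
  const <- physical_constants()
  q <- 1.9e7  # atoms per calibrant cell
  blank <- 1e-18  # blank-filter background mass
  cells <- c(5e4, 1e5, 2e5, 5e5)
  sig <- blank + cells * q * const$phosphorus_molar_mass / const$avogadro
  cal <- sxrf_calibration(cells, sig)
  expect_equal(cal$intercept_g, blank, tolerance = 1e-6)
  out <- sxrf_quantify(cal, sig[2], cells[2])
  expect_equal(out$p_atoms_per_cell, q, tolerance = 1e-9)
  expect_false(out$out_of_range)
  ## below the sensitivity floor of 2e4 cells -> flagged
  out_lo <- sxrf_quantify(cal, blank + 1e4 * q *
                            const$phosphorus_molar_mass / const$avogadro,
                          1e4)
  expect_true(out_lo$out_of_range)
  ## above the linear range -> flagged
  expect_true(sxrf_quantify(cal, sig[4] * 2, 1e6)$out_of_range)
  ## signal at or below the blank: below detection, not an error
  below <- sxrf_quantify(cal, blank / 2, 1e5)
  expect_true(below$below_detection)
  expect_equal(below$p_atoms_per_cell, 0)
})

test_that("X-ray quantification tolerates 10% calibration noise", {
  const <- physical_constants()
  q <- 1.9e7
  cells <- c(5e4, 1e5, 2e5, 4e5, 7e5)
  true_sig <- cells * q * const$phosphorus_molar_mass / const$avogadro
  set.seed(2)
  errs <- vapply(1:50, function(i) {
    sig <- true_sig * rnorm(length(cells), 1, 0.1)
    cal <- sxrf_calibration(cells, pmax(sig, 0))
    got <- sxrf_quantify(cal, true_sig[4], cells[4])
    abs(got$p_atoms_per_cell - q) / q
  }, numeric(1))
  expect_lt(median(errs), 0.08)
})

test_that("genome-equivalent arithmetic uses 2 P atoms per base pair", {
  expect_equal(genome_p_equivalents(1.9e7, 2.4e6), 3.958, tolerance = 1e-3)
  expect_equal(round(genome_p_equivalents(1.9e7, 2.4e6)), 4)
  expect_equal(genome_p_equivalents(0, 2.4e6), 0)
  expect_equal(genome_p_equivalents(2 * 2.4e6, 2.4e6), 1)
  ## the convention is adjustable
  expect_equal(genome_p_equivalents(2.4e6, 2.4e6, p_per_bp = 1), 1)
  expect_error(genome_p_equivalents(1e7, 0), "> 0|positive")
})
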