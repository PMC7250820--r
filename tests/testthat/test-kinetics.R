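test_that("zero clearance gives empty cells and constant seawater", {
  p <- fig3_parameters(clearance_cl = 0)
  traj <- simulate_kinetics(p, fig3_design())
  expect_true(all(traj$periplasm == 0))
  expect_true(all(traj$cyto_labile == 0))
  expect_true(all(traj$macromolecule == 0))
  s33 <- traj$seawater_mol_per_l[traj$channel == "P33"]
  expect_equal(s33, rep(1e-8, length(s33)))
  s32 <- traj[traj$channel == "P32", ]
  expect_equal(s32$seawater_mol_per_l[s32$time_min > 120],
               rep(1e-6, sum(s32$time_min > 120)))
})

test_that("linear-regime trajectories match the matrix-exponential oracle", {
  p <- linear_params()
  rho <- 2.5e10
  d <- fig3_design(additions = data.frame(
    time_min = c(0, 120), channel = c("P33", "P32"),
    conc_mol_l = c(1e-6, 1e-5)))
  traj <- simulate_kinetics(p, d, grid = c(0, 30, 60, 120, 180, 300))
  K <- p$import_km * N_A * p$periplasm_volume
  lam <- p$clearance_cl * rho
  ki <- p$import_vmax / K
  for (variant in c("independent", "proportional")) {
    tr <- if (variant == "independent") traj else
      simulate_kinetics(fig3_parameters(
        clearance_cl = p$clearance_cl, import_vmax = p$import_vmax,
        import_km = p$import_km, assim_rate = p$assim_rate,
        import_sharing = "proportional"), d,
        grid = c(0, 30, 60, 120, 180, 300))
    for (ch in c("P33", "P32")) {
      S0 <- ifelse(ch == "P33", 1e-6, 1e-5) * N_A / rho
      toff <- ifelse(ch == "P33", 0, 120)
      pools <- traj_pools(tr, ch, rho)
      for (tt in c(30, 60, 120, 180, 300)) {
        if (tt <= toff) next
        want <- expm_chain_oracle(S0, lam, ki, p$assim_rate, tt - toff)
        got <- pools[pools[, "time"] == tt, c("S", "P", "L", "M")]
        expect_lt(max(abs(got - want) / abs(want)), 1e-6)
      }
    }
  }
})

test_that("label is conserved per channel between additions", {
  ## include adsorption and a leak: every flux must still balance
  p <- fig3_parameters(adsorption_on = 5e-14, adsorption_off = 0.01,
                       leak_rate = 1e-3)
  traj <- simulate_kinetics(p, fig3_design())
  mb <- mass_balance(traj)
  for (ch in c("P33", "P32")) {
    tot <- mb$total_molecules_per_cell[mb$channel == ch &
                                         mb$time_min > 120]
    expect_lt(diff(range(tot)) / max(tot), 1e-9)
  }
  ## pulse channel also conserved across the whole pre-chase window
  tot33 <- mb$total_molecules_per_cell[mb$channel == "P33"]
  expect_lt(diff(range(tot33)) / max(tot33), 1e-9)
})

test_that("macromolecules never shrink and seawater never grows", {
  traj <- simulate_kinetics(fig3_parameters(), fig3_design())
  for (ch in c("P33", "P32")) {
    d <- traj[traj$channel == ch, ]
    expect_true(all(diff(d$macromolecule) >= -1e-9))
    post <- d[d$time_min > 120, ]
    expect_true(all(diff(post$seawater_mol_per_l) <= 1e-20))
  }
})

test_that("buffered model keeps the pulse assimilation slope through the chase", {
  traj <- simulate_kinetics(fig3_parameters(), fig3_design())
  pre <- macro_slope(traj, "P33", 0, 120)
  post <- macro_slope(traj, "P33", 120, 300)
  expect_lt(abs(post / pre - 1), 0.10)
  ## and the chase channel is imported in parallel, not excluded
  expect_gt(macro_slope(traj, "P32", 120, 300), 0)
})

test_that("bypassing the buffer collapses the post-chase pulse slope >10x", {
  traj <- simulate_kinetics(fig3_parameters(buffer_bypass = TRUE),
                            fig3_design())
  pre <- macro_slope(traj, "P33", 0, 120)
  post <- macro_slope(traj, "P33", 120, 300)
  expect_gt(pre / post, 10)
  expect_true(all(traj$periplasm == 0))
})

test_that("labile pool is 10-20x the assimilated pool at 3 h", {
  traj <- simulate_kinetics(fig3_parameters(), fig3_design())
  st <- traj[traj$time_min == 180 & traj$channel == "P33", ]
  asw <- st$adsorbed + st$periplasm + st$cyto_labile + st$macromolecule
  pfa <- st$macromolecule + fig3_parameters()$pfa_retained_fraction *
    st$periplasm
  ratio <- (asw - pfa) / pfa
  expect_gte(ratio, 10)
  expect_lte(ratio, 20)
})

test_that("accumulation rate is proportional to concentration over 7 decades", {
  p <- fig3_parameters()
  concs <- 10^seq(-13, -6, by = 1)
  acc <- vapply(concs, function(c0) {
    d <- short_design(conc = c0, times = c(5, 10))
    traj <- simulate_kinetics(p, d)
    st <- traj[traj$time_min == 10 & traj$channel == "P33", ]
    st$adsorbed + st$periplasm + st$cyto_labile + st$macromolecule
  }, numeric(1))
  slope <- coef(lm(log10(acc) ~ log10(concs)))[2]
  expect_equal(unname(slope), 1, tolerance = 0.01)
})

test_that("measurement operators are the documented pool sums", {
  state <- data.frame(time_min = 0, channel = "P33",
                      seawater_mol_per_l = 0, adsorbed = 0,
                      periplasm = 100, cyto_labile = 10, macromolecule = 5)
  p0 <- fig3_parameters(pfa_retained_fraction = 0)
  expect_equal(apply_measurement(state, "ASW", p0)$value_molecules_per_cell,
               115)
  expect_equal(apply_measurement(state, "DW", p0)$value_molecules_per_cell,
               15)
  expect_equal(apply_measurement(state, "PFA", p0)$value_molecules_per_cell,
               5)
  expect_equal(apply_measurement(state, "TCA", p0)$value_molecules_per_cell,
               5)
  ## PFA retains a configurable fraction of the periplasm
  p5 <- fig3_parameters(pfa_retained_fraction = 0.05)
  expect_equal(apply_measurement(state, "PFA", p5)$value_molecules_per_cell,
               10)
  ## all-zero state measures zero under every protocol
  z <- data.frame(time_min = 0, channel = "P33", seawater_mol_per_l = 0,
                  adsorbed = 0, periplasm = 0, cyto_labile = 0,
                  macromolecule = 0)
  for (prot in c("ASW", "DW", "PFA", "TCA"))
    expect_equal(apply_measurement(z, prot, p5)$value_molecules_per_cell, 0)
  expect_error(apply_measurement(state, "XYZ", p5))
})

test_that("protocol ordering ASW >= DW >= TCA and ASW >= PFA >= TCA holds", {
  traj <- simulate_kinetics(fig3_parameters(), fig3_design())
  p <- fig3_parameters()
  v <- function(prot) apply_measurement(traj, prot,
                                        p)$value_molecules_per_cell
  asw <- v("ASW"); dw <- v("DW"); pfa <- v("PFA"); tca <- v("TCA")
  expect_true(all(asw - dw >= -1e-9))
  expect_true(all(dw - tca >= -1e-9))
  expect_true(all(asw - pfa >= -1e-9))
  expect_true(all(pfa - tca >= -1e-9))
})

test_that("inhibitor gating follows the onset-delay rules", {
  p <- fig3_parameters()
  none <- apply_inhibitor(p, "none", 0)
  expect_equal(none$g(c(0, 100, 1e4)), c(1, 1, 1))
  cccp <- apply_inhibitor(p, "CCCP", 10)
  expect_equal(cccp$g(c(13.9, 14.1)), c(1, 0))
  expect_equal(cccp$import_gate(c(13.9, 14.1)), c(1, 1))
  dccd <- apply_inhibitor(p, "DCCD", 10)
  expect_equal(dccd$g(c(21.9, 22.1)), c(1, 0))
  expect_equal(dccd$import_gate(c(21.9, 22.1)), c(1, 0))
  ## DCCD onset is three times the CCCP onset with the defaults
  expect_equal((dccd$onset_time - 10) / (cccp$onset_time - 10), 3)
  ion <- apply_inhibitor(p, "ionophore", 5, factor = 0.4)
  expect_equal(ion$clearance_factor(c(4.9, 5.1)), c(1, 0.4))
  expect_error(apply_inhibitor(p, "unknown", 0))
  ## CCCP blocks import too when configured
  pc <- fig3_parameters(cccp_blocks_import = TRUE)
  cccp2 <- apply_inhibitor(pc, "CCCP", 0)
  expect_equal(cccp2$import_gate(c(3.9, 4.1)), c(1, 0))
})

test_that("CCCP freezes total cell label at its 4-minute value", {
  p <- fig3_parameters()
  d <- short_design(times = c(1, 2, 4, 10, 30, 60))
  d$inhibitor_events <- data.frame(time_min = 0, kind = "CCCP",
                                   factor = NA_real_)
  traj <- simulate_kinetics(p, d)
  tot <- function(tt) {
    st <- traj[traj$time_min == tt & traj$channel == "P33", ]
    st$adsorbed + st$periplasm + st$cyto_labile + st$macromolecule
  }
  ## accumulated label at t >> delay equals the label at the onset time
  expect_equal(tot(60), tot(4), tolerance = 1e-8)
  expect_equal(tot(30), tot(10), tolerance = 1e-8)
  ## but assimilation continued from the buffer after the halt
  st4 <- traj[traj$time_min == 4 & traj$channel == "P33", ]
  st60 <- traj[traj$time_min == 60 & traj$channel == "P33", ]
  expect_gt(st60$macromolecule, st4$macromolecule)
})

test_that("an ionophore scales clearance by its factor from addition time", {
  p <- fig3_parameters()
  d <- short_design(times = c(30, 60))
  dion <- d
  dion$inhibitor_events <- data.frame(time_min = 0, kind = "ionophore",
                                      factor = 0.5)
  s_ctl <- simulate_kinetics(p, d)
  s_ion <- simulate_kinetics(p, dion)
  lam <- p$clearance_cl * 2.5e10
  f_ctl <- s_ctl$seawater_mol_per_l[s_ctl$time_min == 60 &
                                      s_ctl$channel == "P33"] / 1e-8
  f_ion <- s_ion$seawater_mol_per_l[s_ion$time_min == 60 &
                                      s_ion$channel == "P33"] / 1e-8
  expect_equal(log(f_ctl), -lam * 60, tolerance = 1e-6)
  expect_equal(log(f_ion), -0.5 * lam * 60, tolerance = 1e-6)
})

test_that("light schedule multiplies clearance while illuminated", {
  p <- fig3_parameters(light_factor = 2)
  d <- short_design(times = c(30, 60), light_on = matrix(c(0, 30), 1))
  traj <- simulate_kinetics(p, d)
  lam <- p$clearance_cl * 2.5e10
  f30 <- traj$seawater_mol_per_l[traj$time_min == 30 &
                                   traj$channel == "P33"] / 1e-8
  f60 <- traj$seawater_mol_per_l[traj$time_min == 60 &
                                   traj$channel == "P33"] / 1e-8
  expect_equal(log(f30), -2 * lam * 30, tolerance = 1e-6)
  ## light off after 30 min: plain clearance for the second half hour
  expect_equal(log(f60 / f30), -lam * 30, tolerance = 1e-6)
})

test_that("seawater depletion matches the closed form", {
  p <- fig3_parameters()
  rho <- 2.5e10
  expect_equal(seawater_depletion_closed_form(p, rho, 1e-8, 0), 1e-8)
  ## six orders of magnitude once CL*rho*t = ln(1e6)
  t6 <- log(1e6) / (p$clearance_cl * rho)
  expect_equal(seawater_depletion_closed_form(p, rho, 1e-9, t6), 1e-15,
               tolerance = 1e-9)
  ## the full simulation reproduces the curve to < 0.1%
  traj <- simulate_kinetics(p, fig3_design())
  d33 <- traj[traj$channel == "P33", ]
  want <- seawater_depletion_closed_form(p, rho, 1e-8, d33$time_min)
  expect_lt(max(abs(d33$seawater_mol_per_l - want) / want), 1e-3)
})

test_that("constructors validate kinetic and design invariants", {
  expect_error(kinetic_parameters(clearance_cl = -1, import_vmax = 1,
                                  assim_rate = 0.1), ">= 0|nonneg")
  expect_error(fig3_parameters(pfa_retained_fraction = 1.5), "0, 1")
  expect_error(fig3_design(cell_density = 0), "> 0|positive")
  expect_error(experiment_design(
    cell_density = 1e10,
    additions = data.frame(time_min = 0, channel = "P31", conc_mol_l = 1e-8),
    sampling_times = 10), "channel")
  expect_error(experiment_design(
    cell_density = 1e10,
    additions = data.frame(time_min = c(10, 0), channel = "P33",
                           conc_mol_l = 1e-8),
    sampling_times = 10), "nondecreasing")
})
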