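## shared fixtures and independent oracles, built in code at test time

N_A <- physical_constants()$avogadro

## short single-pulse design used where the 23 h horizon is not needed
short_design <- function(conc = 1e-8, channel = "P33",
                         times = c(15, 30, 60, 120),
                         protocols = c("ASW", "DW", "PFA", "TCA"),
                         replicates = 1, cell_density = 2.5e10, ...) {
  experiment_design(
    cell_density = cell_density,
    additions = data.frame(time_min = 0, channel = channel,
                           conc_mol_l = conc),
    sampling_times = times, protocols = protocols,
    replicates = replicates, ...)
}

## deep-linear-regime parameters: K is so large that the saturable import is
## indistinguishable from a first-order rate Vmax/K, and every pool is far
## above the integrator's absolute tolerance
linear_params <- function(...) {
  kinetic_parameters(clearance_cl = 1.78e-13, import_vmax = 2e13,
                     import_km = 1e8, assim_rate = 0.05, ...)
}

## independent matrix-exponential oracle for the linearised single-channel
## chain S -> P -> L -> M (states in molecules per cell)
expm_chain_oracle <- function(S0, lam, ki, ka, t) {
  A <- matrix(0, 4, 4)
  A[1, 1] <- -lam
  A[2, 1] <- lam; A[2, 2] <- -ki
  A[3, 2] <- ki; A[3, 3] <- -ka
  A[4, 3] <- ka
  as.vector(Matrix::expm(A * t) %*% c(S0, 0, 0, 0))
}

## pull one channel of a trajectory as a molecules-per-cell matrix
traj_pools <- function(traj, ch, rho) {
  d <- traj[traj$channel == ch, ]
  cbind(time = d$time_min,
        S = d$seawater_mol_per_l * N_A / rho,
        P = d$periplasm, L = d$cyto_labile, M = d$macromolecule)
}

## mean macromolecule slope of a channel between two times
macro_slope <- function(traj, ch, t0, t1) {
  m <- traj[traj$channel == ch, ]
  (m$macromolecule[m$time_min == t1] - m$macromolecule[m$time_min == t0]) /
    (t1 - t0)
}
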